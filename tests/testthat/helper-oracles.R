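# Independent oracles: brute-force and enumeration references kept separate
# from the implementation paths they check.

# Brute-force signed distance: per voxel, the minimum center-to-center
# distance to the opposite class (negative inside).
bruteForceSignedEDT <- function(mask) {
  dims <- gridDims(mask); sp <- gridSpacing(mask)
  w <- sweep(arrayInd(seq_len(prod(dims)), dims) - 1, 2, sp, "*")
  inside <- as.vector(voxelValues(mask))
  a <- w[inside, , drop = FALSE]; b <- w[!inside, , drop = FALSE]
  minDist <- function(P, Q) {
    out <- numeric(nrow(P))
    chunk <- 2000L
    for (s in seq(1, nrow(P), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(P))
      d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(Q^2), "+") -
        2 * P[s:e, , drop = FALSE] %*% t(Q)
      out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    out
  }
  res <- numeric(prod(dims))
  res[inside] <- -minDist(a, b)
  res[!inside] <- minDist(b, a)
  array(res, dim = dims)
}

# Brute-force Euclidean-ball dilation: a voxel is set iff any structure
# voxel center lies within r of its center.
bruteForceDilate <- function(mask, r) {
  dims <- gridDims(mask); sp <- gridSpacing(mask)
  w <- sweep(arrayInd(seq_len(prod(dims)), dims) - 1, 2, sp, "*")
  inside <- as.vector(voxelValues(mask))
  src <- w[inside, , drop = FALSE]
  out <- logical(prod(dims))
  for (i in seq_len(nrow(w))) {
    d2 <- rowSums(sweep(src, 2, w[i, ])^2)
    out[i] <- any(d2 <= r^2 + 1e-12)
  }
  array(out, dim = dims)
}

# Monte-Carlo permutation reference for the Kruskal-Wallis p-value,
# vectorized over blocks of label shuffles.
kwPermOracle <- function(groups, nPerm = 1e5, blocks = 10L) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  ns <- lengths(groups)
  ind <- outer(g, seq_along(groups), "==") * 1 # n x k membership
  statFromRanks <- function(R) { # R: n x B matrix of permuted ranks
    S <- crossprod(ind, R) # k x B group rank sums
    colSums(S^2 / ns)
  }
  obs <- statFromRanks(matrix(r, ncol = 1))[1]
  per <- nPerm %/% blocks
  hits <- 0L
  for (b in seq_len(blocks)) {
    U <- matrix(stats::runif(n * per), n, per)
    P <- apply(U, 2, order)
    R <- matrix(r[P], n, per)
    hits <- hits + sum(statFromRanks(R) >= obs - 1e-9)
  }
  (hits + 1) / (blocks * per + 1)
}

# Exhaustive 2 x k Fisher enumeration, written independently of the
# implementation: recursion over first-row cell values.
fisherEnumOracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  k <- ncol(tab)
  lp <- function(row1) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1) -
      sum(lgamma(row1 + 1)) - sum(lgamma(cs - row1 + 1))
  }
  obs <- lp(tab[1, ])
  total <- 0
  recurse <- function(j, sofar) {
    if (j == k) {
      last <- rs[1] - sum(sofar)
      if (last < 0 || last > cs[k]) return()
      p <- lp(c(sofar, last))
      if (p <= obs + 1e-7) total <<- total + exp(p)
      return()
    }
    for (v in 0:min(cs[j], rs[1] - sum(sofar)))
      recurse(j + 1, c(sofar, v))
  }
  recurse(1, numeric(0))
  min(1, total)
}

# Exhaustive two-sided permutation p of the standardized pairwise rank
# statistic (raw rank-sum enumerated via combn, standardized afterwards).
pairRankEnumOracle <- function(xi, xj) {
  pool <- c(xi, xj)
  ni <- length(xi)
  n <- length(pool)
  r <- rank(pool)
  E <- ni * (n + 1) / 2
  V <- ni * length(xj) / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (V <= 0) return(1)
  tObs <- abs(sum(r[seq_len(ni)]) - E) / sqrt(V)
  sel <- utils::combn(n, ni)
  W <- colSums(matrix(r[sel], nrow = ni))
  mean(abs(W - E) / sqrt(V) >= tObs - 1e-9)
}
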