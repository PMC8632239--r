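# Group statistics: Kruskal-Wallis, Steel-Dwass-Critchlow-Fligner post-hoc,
# Fisher exact 2 x k, zone-table comparisons and the intraindividual gain.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic across k groups. The default p-value is the
#' chi-square approximation with k - 1 degrees of freedom; a Monte-Carlo
#' permutation p-value (label shuffles of the pooled ranks) is available via
#' \code{pMethod = "permutation"}. With all observations identical the test
#' degenerates to H = 0, p = 1.
#'
#' @param groups list of numeric vectors (each non-empty, total n >= 3), or a
#'   numeric vector when \code{g} gives group labels.
#' @param g optional group labels matching \code{groups} as a vector.
#' @param pMethod "asymptotic" or "permutation".
#' @param nPerm permutation count (permutation method).
#' @return list with \code{statistic} (H), \code{p.value}, \code{df},
#'   \code{method}.
#' @export
kruskalWallis <- function(groups, g = NULL,
                          pMethod = c("asymptotic", "permutation"),
                          nPerm = 10000L) {
  pMethod <- match.arg(pMethod)
  if (!is.null(g)) {
    x <- as.numeric(groups)
    grp <- as.integer(factor(g))
  } else {
    x <- unlist(groups, use.names = FALSE)
    grp <- rep(seq_along(groups), lengths(groups))
  }
  if (any(tabulate(grp) == 0L)) stop("each group must be non-empty")
  n <- length(x)
  if (n < 3L) stop("total n must be at least 3")
  k <- max(grp)
  r <- rank(x)
  rs <- tapply(r, grp, sum)
  ns <- tabulate(grp, k)
  S <- sum(rs^2 / ns)
  H <- 12 / (n * (n + 1)) * S - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / C
    p <- if (pMethod == "asymptotic") {
      stats::pchisq(H, k - 1, lower.tail = FALSE)
    } else {
      .cpp_kw_perm(r, grp, k, as.integer(nPerm), S)
    }
  }
  if (H < 1e-12) p <- 1 # all group rank means equal
  list(statistic = H, p.value = p, df = k - 1,
       method = paste0("Kruskal-Wallis (", pMethod, ")"))
}

# Standardized two-sample rank statistic for one pair (tie-corrected
# variance), the building block of the all-pairs procedure.
.pairRankStat <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj)
  n <- ni + nj
  r <- rank(c(xi, xj))
  W <- sum(r[seq_len(ni)])
  E <- ni * (n + 1) / 2
  V <- ni * nj / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass-Critchlow-Fligner all-pairs comparison
#'
#' Nonparametric post-hoc procedure after Kruskal-Wallis: for every pair of
#' groups the two-sample rank statistic is computed on that pair alone and
#' referred to the studentized-range distribution with k groups. With
#' \code{method = "exact"} the per-pair reference is the exhaustive
#' permutation distribution of the standardized rank statistic (all
#' \code{choose(ni+nj, ni)} splits) instead of the normal limit, mapped
#' through the same studentized-range adjustment; \code{adjust = "none"}
#' returns the unadjusted per-pair p-values.
#'
#' @param groups list of >= 3 numeric vectors, each of size >= 2.
#' @param method "asymptotic" or "exact" per-pair reference.
#' @param adjust "tukey" (studentized range, the Steel-Dwass adjustment) or
#'   "none".
#' @return symmetric matrix of p-values with diagonal 1.
#' @export
steelDwassTest <- function(groups, method = c("asymptotic", "exact"),
                           adjust = c("tukey", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 3L) stop("at least 3 groups required")
  if (any(lengths(groups) < 2L)) stop("each group must have size >= 2")
  P <- matrix(1, k, k)
  if (!is.null(names(groups))) dimnames(P) <- list(names(groups), names(groups))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    t0 <- .pairRankStat(groups[[i]], groups[[j]])
    if (method == "asymptotic") {
      pPair <- 2 * stats::pnorm(abs(t0), lower.tail = FALSE)
    } else {
      xi <- groups[[i]]; xj <- groups[[j]]
      pool <- c(xi, xj)
      ni <- length(xi)
      sel <- utils::combn(length(pool), ni)
      stats0 <- apply(sel, 2, function(ix)
        .pairRankStat(pool[ix], pool[-ix]))
      pPair <- mean(abs(stats0) >= abs(t0) - 1e-9)
    }
    p <- if (adjust == "none") {
      pPair
    } else {
      # map the per-pair two-sided p back to |z| and refer sqrt(2)|z| to the
      # studentized range with k groups (Steel-Dwass scale)
      z <- stats::qnorm(pmax(pPair / 2, 1e-300), lower.tail = FALSE)
      stats::ptukey(sqrt(2) * z, k, Inf, lower.tail = FALSE)
    }
    P[i, j] <- P[j, i] <- min(1, p)
  }
  P
}

#' Fisher exact test for 2 x k tables
#'
#' Freeman-Halton extension by direct enumeration: the p-value sums the
#' conditional hypergeometric probabilities of every table with the observed
#' margins whose probability does not exceed the observed table's. A table
#' with a zero row or column margin is degenerate and returns p = 1.
#'
#' @param tab 2 x k matrix of non-negative integer counts (k >= 2).
#' @return the exact two-sided p-value.
#' @export
fisherExactRxC <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L) stop("table must be 2 x k with k >= 2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  n <- sum(tab)
  k <- ncol(tab)
  logConst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logProb <- function(row1) {
    row2 <- cs - row1
    logConst - sum(lgamma(row1 + 1)) - sum(lgamma(row2 + 1))
  }
  lpObs <- logProb(tab[1, ])
  # enumerate all first rows consistent with the margins
  grid <- list(0:min(rs[1], cs[1]))
  if (k >= 3L) for (j in 2:(k - 1)) grid[[j]] <- 0:min(rs[1], cs[j])
  combos <- do.call(expand.grid, grid)
  partial <- rowSums(combos)
  keep <- partial <= rs[1] & (rs[1] - partial) <= cs[k]
  combos <- combos[keep, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(combos))) {
    row1 <- c(as.numeric(combos[i, ]), rs[1] - sum(combos[i, ]))
    lp <- logProb(row1)
    if (lp <= lpObs + 1e-7) total <- total + exp(lp)
  }
  min(1, total)
}

#' Compare guidance settings across trial records
#'
#' The zone-table analysis: per zone code, the mean percentage of plane
#' points per setting with a Kruskal-Wallis test across settings on the
#' plane-level percentages and the Steel-Dwass-Critchlow-Fligner all-pairs
#' post-hoc; plus Fisher exact tests on the 2 x k count tables of the
#' intratumoral and carotid-damaged plane flags.
#'
#' @param records list of \linkS4class{TrialRecord} or the data.frame from
#'   \code{\link{recordsTable}}.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(records, alpha = 0.05) {
  df <- if (is.data.frame(records)) records else recordsTable(records)
  counts <- table(df$setting)
  empty <- setdiff(c("unguided", "tumor_guided", "carotid_guided"),
                   names(counts))
  if (length(empty))
    warning("settings with zero records excluded: ",
            paste(empty, collapse = ", "))
  settings <- intersect(c("unguided", "tumor_guided", "carotid_guided"),
                        unique(df$setting))
  if (length(settings) < 2L) stop("at least 2 settings required")
  df <- df[df$setting %in% settings, ]
  df <- df[order(df$setting, df$surgeonId, df$presetId, df$portion), ]

  zs <- list()
  posthoc <- list()
  canPosthoc <- length(settings) >= 3L
  for (zc in zoneCodes()) {
    v <- df[[paste0("pct_", zc)]]
    groups <- split(v, factor(df$setting, levels = settings))
    kw <- kruskalWallis(groups)
    zs[[zc]] <- data.frame(zone = zc,
                           t(vapply(groups, mean, numeric(1))),
                           H = kw$statistic, p = kw$p.value,
                           check.names = FALSE)
    posthoc[[zc]] <- if (canPosthoc) steelDwassTest(groups) else NULL
  }
  zoneStats <- do.call(rbind, zs)
  rownames(zoneStats) <- NULL

  flagTests <- list()
  for (fl in c("intratumoral", "icaDamaged")) {
    tabs <- table(factor(df[[fl]], levels = c(TRUE, FALSE)),
                  factor(df$setting, levels = settings))
    tab <- matrix(as.integer(tabs), nrow = 2,
                  dimnames = dimnames(tabs))
    flagTests[[fl]] <- list(table = tab, p.value = fisherExactRxC(tab))
  }
  new("GroupComparison", zoneStats = zoneStats, posthoc = posthoc,
      flagTests = flagTests, settings = settings, alpha = alpha)
}

#' Intraindividual guidance gain
#'
#' Per surgeon, the difference between the pooled guided settings and the
#' unguided setting in (a) the rate of clear-margin planes (no point at or
#' inside the tumor) and (b) the rate of carotid-spared planes (no point at
#' or inside the vessel wall), in percentage points. Surgeons missing the
#' unguided or all guided settings are excluded with a warning.
#'
#' @param records list of \linkS4class{TrialRecord} or a records data.frame.
#' @return a \linkS4class{GainResult}.
#' @export
computeGain <- function(records) {
  df <- if (is.data.frame(records)) records else recordsTable(records)
  rows <- list()
  for (s in sort(unique(df$surgeonId))) {
    d <- df[df$surgeonId == s, ]
    ung <- d[d$setting == "unguided", ]
    gui <- d[d$setting %in% c("tumor_guided", "carotid_guided"), ]
    if (!nrow(ung) || !nrow(gui)) {
      warning("surgeon ", s, " lacks unguided or guided records; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      surgeonId = s,
      clearUnguided = 100 * mean(ung$adequateMargin),
      clearGuided = 100 * mean(gui$adequateMargin),
      sparedUnguided = 100 * mean(!ung$icaDamaged),
      sparedGuided = 100 * mean(!gui$icaDamaged))
  }
  if (!length(rows)) stop("no surgeon has both unguided and guided records")
  per <- do.call(rbind, rows)
  per$gainClearMargin <- per$clearGuided - per$clearUnguided
  per$gainCarotidSpared <- per$sparedGuided - per$sparedUnguided
  new("GainResult", perSurgeon = per,
      meanGain = c(clearMargin = mean(per$gainClearMargin),
                   carotidSpared = mean(per$gainCarotidSpared)),
      rangeGain = list(clearMargin = range(per$gainClearMargin),
                       carotidSpared = range(per$gainCarotidSpared)))
}

#' Render a group comparison as a Markdown table
#'
#' Zone rows with per-setting mean percentages and p-values in the
#' standard zone-table layout, followed by the flag tests.
#'
#' @param comparison a \linkS4class{GroupComparison}.
#' @param path optional output path; when NULL the text is returned.
#' @return the Markdown text (invisibly when written to a file).
#' @export
reportMarkdown <- function(comparison, path = NULL) {
  zs <- comparison@zoneStats
  descr <- c(R = "Into the carotid",
             O1 = "<2 mm carotid, into the tumor",
             O2 = "<2 mm carotid, <5 mm tumor",
             O3 = "<2 mm carotid, 5-10 mm tumor",
             O4 = "<2 mm carotid, >10 mm tumor",
             Y1 = ">2 mm carotid, into the tumor",
             Y2 = ">2 mm carotid, <5 mm tumor",
             G = ">2 mm carotid, 5-10 mm tumor",
             B = ">2 mm carotid, >10 mm tumor")
  hdr <- paste0("| Color code | Description | ",
                paste(comparison@settings, collapse = " | "),
                " | p-value |")
  sep <- paste0("|", paste(rep("---", length(comparison@settings) + 3),
                           collapse = "|"), "|")
  lines <- c(hdr, sep)
  for (i in seq_len(nrow(zs))) {
    means <- sprintf("%.1f", as.numeric(zs[i, comparison@settings]))
    pv <- zs$p[i]
    pTxt <- if (pv < 1e-4) "p < 0.0001" else sprintf("p = %.4f", pv)
    lines <- c(lines, paste0("| ", zs$zone[i], " | ", descr[[zs$zone[i]]],
                             " | ", paste(means, collapse = " | "),
                             " | ", pTxt, " |"))
  }
  for (fl in names(comparison@flagTests)) {
    ft <- comparison@flagTests[[fl]]
    pv <- ft$p.value
    pTxt <- if (pv < 1e-4) "p < 0.0001" else sprintf("p = %.4f", pv)
    lines <- c(lines, "",
               paste0("Fisher exact on ", fl, " counts (",
                      paste(ft$table[1, ], collapse = "/"), " of ",
                      paste(colSums(ft$table), collapse = "/"), "): ", pTxt))
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
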