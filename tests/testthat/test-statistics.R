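# Rank tests, exact tests, the zone-table comparison and the gain metric.

test_that("Kruskal-Wallis H matches the hand-ranked value and kruskal.test", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  set.seed(9)
  for (i in 1:20) {
    x <- round(rnorm(24), 1) # induces occasional ties
    g <- sample(rep(1:3, 8))
    kw <- kruskalWallis(x, g)
    ref <- kruskal.test(x, g)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups degenerate to H = 0, p = 1", {
  kw <- kruskalWallis(list(rep(2, 4), rep(2, 4), rep(2, 4)))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
})

test_that("the permutation p-value matches an independent permutation oracle", {
  set.seed(15)
  for (i in 1:5) {
    groups <- lapply(1:3, function(j) rnorm(6, mean = 0.4 * j))
    set.seed(100 + i)
    p1 <- kruskalWallis(groups, pMethod = "permutation", nPerm = 2e4)$p.value
    set.seed(200 + i)
    p2 <- kwPermOracle(groups, nPerm = 2e4, blocks = 4L)
    se <- sqrt(2 * p2 * (1 - p2) / 2e4)
    expect_lt(abs(p1 - p2), max(3 * se, 0.01))
  }
})

test_that("Steel-Dwass p-values are symmetric with sane ordering", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1.5, 2.5, 3.5, 4.5, 5.5),
            c = c(30, 31, 32, 33, 34))
  P <- steelDwassTest(g)
  expect_equal(P, t(P))
  expect_equal(diag(P), rep(1, 3), ignore_attr = TRUE)
  # the extreme group separates more strongly than the similar pair
  expect_lt(P["a", "c"], P["a", "b"])
  expect_lt(P["b", "c"], P["a", "b"])
  # identical samples are not distinguished
  same <- list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4), z = c(9, 9.5, 10, 10.5))
  expect_gt(steelDwassTest(same)["x", "y"], 0.95)
  expect_error(steelDwassTest(list(1:3, 2, 1:3)), "size >= 2")
  expect_error(steelDwassTest(list(1:3, 4:6)), "at least 3")
})

test_that("exact per-pair Steel-Dwass reference equals exhaustive enumeration", {
  set.seed(44)
  for (i in 1:5) {
    g <- list(rnorm(4), rnorm(4, 1), rnorm(4, 2))
    P <- steelDwassTest(g, method = "exact", adjust = "none")
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      pEnum <- pairRankEnumOracle(g[[pair[1]]], g[[pair[2]]])
      expect_lt(abs(P[pair[1], pair[2]] - pEnum), 0.01)
    }
  }
})

test_that("Fisher 2x2 equals the classical hypergeometric two-sided p", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisherExactRxC(tab), fisher.test(tab)$p.value,
               tolerance = 1e-12)
  expect_equal(fisherExactRxC(matrix(c(5, 5, 5, 5), 2)), 1)
})

test_that("degenerate tables with a zero margin return p = 1", {
  expect_equal(fisherExactRxC(matrix(c(0, 3, 0, 4), 2)), 1)
  expect_equal(fisherExactRxC(matrix(c(0, 0, 2, 3, 4, 5), 2)), 1)
})

test_that("Fisher 2x3 equals full enumeration and fisher.test on random tables", {
  set.seed(33)
  for (i in 1:20) {
    tab <- matrix(rpois(6, sample(2:6, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherExactRxC(tab)
    expect_equal(p, fisherEnumOracle(tab), tolerance = 1e-9)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

# small synthetic record set with known fractions
makeRecord <- function(surgeon, setting, dTumor, dIca, preset = "S1",
                       portion = "superior") {
  m <- handMap(matrix(dTumor, length(dTumor), 1),
               matrix(dIca, length(dIca), 1))
  new("TrialRecord", surgeonId = as.integer(surgeon), presetId = preset,
      setting = setting, portion = portion, summary = summarizePlane(m),
      pose = pointerPose(c(0, 0, 0), c(0, 0, 1)))
}

test_that("duplicated identical records give flat comparisons with p = 1", {
  rec <- makeRecord(1, "unguided", c(7, 7, -1, 7), c(3, 3, 3, 1))
  recs <- list()
  for (s in 1:2) for (set0 in c("unguided", "tumor_guided", "carotid_guided"))
    recs <- c(recs, list(makeRecord(s, set0, c(7, 7, -1, 7), c(3, 3, 3, 1))))
  cmp <- compareGroups(recs)
  expect_true(all(cmp@zoneStats$p == 1))
  fr <- zoneFractions(rec@summary)
  for (set0 in cmp@settings)
    expect_equal(unname(unlist(cmp@zoneStats[, set0])), unname(100 * fr))
  expect_equal(cmp@flagTests$intratumoral$p.value, 1)
})

test_that("group means match hand-computed percentages on a 6-record set", {
  recs <- list(
    makeRecord(1, "unguided", c(-1, 7), c(3, 3)),      # 50% Y1, 50% G
    makeRecord(1, "unguided", c(7, 7), c(3, 3)),       # 100% G
    makeRecord(1, "tumor_guided", c(7, 7), c(3, 3)),   # 100% G
    makeRecord(1, "tumor_guided", c(7, 12), c(3, 3)),  # 50% G, 50% B
    makeRecord(1, "carotid_guided", c(7, 7), c(1, 3)), # 50% O3, 50% G
    makeRecord(1, "carotid_guided", c(7, 7), c(3, 3))) # 100% G
  cmp <- compareGroups(recs)
  zs <- cmp@zoneStats
  expect_equal(zs[zs$zone == "G", "unguided"], 75)
  expect_equal(zs[zs$zone == "Y1", "unguided"], 25)
  expect_equal(zs[zs$zone == "G", "tumor_guided"], 75)
  expect_equal(zs[zs$zone == "B", "tumor_guided"], 25)
  expect_equal(zs[zs$zone == "O3", "carotid_guided"], 25)
  # percentages per setting sum to 100
  for (set0 in cmp@settings)
    expect_equal(sum(zs[[set0]]), 100, tolerance = 0.1)
})

test_that("comparisons are invariant to record order", {
  set.seed(50)
  recs <- list()
  for (s in 1:3) for (set0 in c("unguided", "tumor_guided", "carotid_guided"))
    for (r in 1:3)
      recs <- c(recs, list(makeRecord(s, set0, rnorm(5, 6), rnorm(5, 4))))
  c1 <- compareGroups(recs)
  c2 <- compareGroups(recs[sample(length(recs))])
  expect_equal(c1@zoneStats, c2@zoneStats)
  expect_equal(c1@flagTests, c2@flagTests)
})

test_that("a setting with zero records is excluded with a warning", {
  recs <- list(makeRecord(1, "unguided", c(7, 7), c(3, 3)),
               makeRecord(1, "tumor_guided", c(7, 7), c(3, 3)),
               makeRecord(2, "unguided", c(7, -1), c(3, 3)),
               makeRecord(2, "tumor_guided", c(7, 7), c(1, 3)))
  expect_warning(cmp <- compareGroups(recs), "carotid_guided")
  expect_identical(cmp@settings, c("unguided", "tumor_guided"))
})

test_that("gains are zero when guided equals unguided and match hand values otherwise", {
  recs <- list()
  for (s in 1:2) for (set0 in c("unguided", "tumor_guided"))
    recs <- c(recs, list(makeRecord(s, set0, c(7, 7), c(3, 3))))
  g0 <- computeGain(recs)
  expect_equal(unname(g0@meanGain), c(0, 0))

  # surgeon 1: clear rate 0.5 -> 0.8; surgeon 2: 0.6 -> 0.9
  mk <- function(surgeon, setting, nClear, nTotal) {
    lapply(seq_len(nTotal), function(i)
      makeRecord(surgeon, setting,
                 dTumor = if (i <= nClear) c(7, 7) else c(-1, 7),
                 dIca = c(3, 3)))
  }
  recs2 <- c(mk(1, "unguided", 5, 10), mk(1, "tumor_guided", 8, 10),
             mk(2, "unguided", 6, 10), mk(2, "carotid_guided", 9, 10))
  g <- computeGain(recs2)
  expect_equal(g@perSurgeon$gainClearMargin, c(30, 30))
  expect_equal(unname(g@meanGain[["clearMargin"]]), 30)

  recs3 <- c(mk(1, "unguided", 5, 6), mk(1, "tumor_guided", 6, 6),
             mk(2, "unguided", 3, 6))
  expect_warning(g3 <- computeGain(recs3), "surgeon 2")
  expect_equal(nrow(g3@perSurgeon), 1)
})

test_that("the Markdown report mirrors the nine-zone table layout", {
  recs <- list()
  for (s in 1:2) for (set0 in c("unguided", "tumor_guided", "carotid_guided"))
    recs <- c(recs, list(makeRecord(s, set0, c(7, -1), c(3, 1))))
  txt <- reportMarkdown(compareGroups(recs))
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(grep("^\\| (R|O1|O2|O3|O4|Y1|Y2|G|B) \\|", lines), 9)
  expect_match(txt, "Fisher exact on intratumoral")
})
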