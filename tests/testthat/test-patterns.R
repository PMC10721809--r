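## build a deviations table with quarterly rows from a matrix
quarterDevTable <- function(M, p = 0.01) {
  do.call(rbind, lapply(rownames(M), function(id)
    data.frame(entity_id = id, timeframe_type = "quarter",
               timeframe = colnames(M), delta = M[id, ], p_adjusted = p,
               stringsAsFactors = FALSE)))
}

test_that("quarterly matrix maps calendar months and checks completeness", {
  qs <- defaultQuarters()
  expect_true("2020-07" %in% qs[["2020-Q3"]])
  expect_true("2021-12" %in% qs[["2021-Q4"]])
  expect_false("2020-06" %in% unlist(qs))   # June 2020 is unclustered

  M <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("E%02d", 1:10), names(qs)))
  dev <- quarterDevTable(M)
  expect_equal(quarterlyMatrix(dev, names(qs)), M)
  ## a missing cell errors naming the entity and quarter
  devMiss <- dev[!(dev$entity_id == "E03" & dev$timeframe == "2021-Q2"), ]
  expect_error(quarterlyMatrix(devMiss, names(qs)), "E03.*2021-Q2")
})

test_that("complete-linkage clustering matches hand-computed merges", {
  M <- rbind(a = c(0, 0), b = c(0, 0.1), c = c(10, 10), d = c(10, 10.1))
  cl <- hierarchicalCluster(M, k = 2)
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
  expect_true(all(diff(cl$height) >= 0))    # complete linkage is monotone
  ## hand check: final merge height = max pairwise distance
  expect_equal(max(cl$height), sqrt(10^2 + 10.1^2))
  ## identical rows merge at height 0
  cl0 <- hierarchicalCluster(rbind(x = c(1, 1), y = c(1, 1), z = c(5, 5)))
  expect_equal(min(cl0$height), 0)
  expect_error(hierarchicalCluster(M, k = 9), "k exceeds")
  expect_error(hierarchicalCluster(M[1, , drop = FALSE]), ">= 2 rows")
})

test_that("clustering is invariant to row order up to label permutation", {
  set.seed(17)
  M <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(12, 5, 0.1), 6, 2))
  rownames(M) <- sprintf("E%02d", 1:12)
  l1 <- hierarchicalCluster(M, k = 2)$labels
  perm <- sample(12)
  l2 <- hierarchicalCluster(M[perm, ], k = 2)$labels[rownames(M)]
  expect_equal(ariOracle(l1, l2), 1)
})

test_that("heatmap intensity is the signed |delta| x -log10 p product", {
  expect_equal(heatmapIntensity(-0.5, 0.01), -1)
  expect_equal(heatmapIntensity(0.8, 1), 0)
  expect_equal(heatmapIntensity(0, 0.001), 0)
  ## odd in delta, monotone in -log p at fixed |delta|
  expect_equal(heatmapIntensity(0.3, 0.05), -heatmapIntensity(-0.3, 0.05))
  ps <- c(0.5, 0.1, 0.01, 1e-12)
  expect_true(all(diff(heatmapIntensity(0.3, ps)) > 0))
  ## p floor keeps intensities finite
  expect_equal(heatmapIntensity(1, 1e-300), 10)
  expect_error(heatmapIntensity(0.1, 0), "0, 1")
})

test_that("severity regression equals closed-form least squares", {
  r <- severityRegression(c(-0.8, -0.7, -0.6), 1:3)
  expect_equal(r$slope, 0.1)
  expect_equal(severityRegression(rep(-0.5, 4), 1:4)$slope, 0)
  ## normal-equations oracle on random pairs
  set.seed(23)
  x <- sample(1:5, 30, replace = TRUE)
  y <- -0.5 + 0.05 * x + rnorm(30, 0, 0.1)
  r2 <- severityRegression(y, x)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  n <- 30
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  expect_equal(r2$slope, slope)
  expect_equal(r2$p_value, 2 * pt(-abs(slope / se), n - 2))
  expect_error(severityRegression(y, rep(2, 30)), "variance")
  expect_error(severityRegression(y[1:2], x[1:2]), ">= 3")
})

test_that("rank-sum test: exact enumeration for small untied groups", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)   # 2 * 1/20 from C(6,3) = 20 assignments
  expect_equal(rankSumTest(1.5, 1.5)$p_value, 1)
  ## exact p matches full enumeration for all group sizes <= 6
  set.seed(29)
  for (m in 2:6) for (n in 2:6) {
    x <- sample(seq(0, 1, length.out = 50), m + n)  # no ties
    a <- x[seq_len(m)]; b <- x[-seq_len(m)]
    expect_equal(rankSumTest(a, b)$p_value, mwEnumOracle(a, b),
                 info = sprintf("m=%d n=%d", m, n))
  }
})

test_that("rank-sum normal approximation tracks enumeration at m = n = 6", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(seq_len(100), 12)
    a <- x[1:6]; b <- x[7:12]
    pApprox <- rankSumTest(a, b, exact = FALSE)$p_value
    expect_lt(abs(pApprox - mwEnumOracle(a, b)), 0.02)
  }
})

test_that("Kruskal-Wallis H matches the rank-sum formula", {
  r <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(unname(r$statistic), 7.2)
  expect_equal(r$p_value, pchisq(7.2, df = 2, lower.tail = FALSE))
  ## two identical groups have equal mean ranks
  expect_equal(unname(kruskalWallis(list(c(1, 2), c(1, 2)))$statistic), 0)
  ## fully tied data: undefined after tie correction -> H = 0, p = 1
  rt <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 1)
  ## formula oracle on random small groups with ties
  set.seed(37)
  for (i in 1:20) {
    g <- lapply(1:3, function(j) sample(1:6, sample(3:6, 1), replace = TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(unname(kruskalWallis(g)$statistic), kwFormulaOracle(g))
  }
  expect_error(kruskalWallis(list(1:3)), ">= 2")
})

test_that("hiatus/post-hiatus correlation is Pearson's r", {
  set.seed(41)
  h <- rnorm(20); p <- 0.5 * h + rnorm(20, 0, 0.3)
  r <- hiatusPostHiatusCorrelation(h, p)
  expect_equal(r$r, cor(h, p))
  expect_equal(r$n, 20)
})
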