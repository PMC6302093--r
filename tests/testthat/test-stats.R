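# Statistical layer against independent oracles.

test_that("Grubbs screening matches the critical-value formula", {
  r <- grubbsScreen(c(1, 2, 3, 4, 100))
  expect_identical(r$outliers, 5L)
  expect_equal(r$G[1], max(abs(c(1, 2, 3, 4, 100) -
    mean(c(1, 2, 3, 4, 100)))) / sd(c(1, 2, 3, 4, 100)),
    tolerance = 1e-12)
  expect_gt(r$G[1], 1.71)                       # n = 5 critical value
  expect_identical(grubbsScreen(c(1, 2, 3, 4, 5))$outliers, integer(0))
  expect_warning(rz <- grubbsScreen(rep(3, 6)), "zero variance")
  expect_identical(rz$outliers, integer(0))
  expect_error(grubbsScreen(c(1, 2)), "at least 3")
  # never reduces a sample below 3
  rx <- grubbsScreen(c(0, 0.1, 50))
  expect_identical(length(rx$cleaned), 3L)
  # 100 random small samples: first-pass decision matches the formula
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    if (runif(1) < 0.4) x[1] <- x[1] + runif(1, 3, 8)
    # first-pass decision must equal the direct critical-value formula
    expect_identical(length(grubbsScreen(x)$G) > 0, grubbsFlagOnce(x))
  }
})

test_that("two-way ANOVA matches brute-force sums of squares on balanced toys", {
  set.seed(4)
  for (i in 1:5) {
    v <- rnorm(12) + rep(c(0, 0, 2, 2), each = 3) +
      rep(rep(c(0, 1), each = 3), 2)
    A <- rep(c("wt", "ko"), each = 6)
    B <- rep(rep(c("wt", "ko"), each = 3), 2)
    tbl <- FactorialTable(v, A, B)
    a <- twoWayAnova(tbl)
    bf <- bruteForceAnovaF(v, A, B)
    expect_equal(a$Fa, unname(bf["Fa"]), tolerance = 1e-8)
    expect_equal(a$Fb, unname(bf["Fb"]), tolerance = 1e-8)
    expect_equal(a$Fab, unname(bf["Fab"]), tolerance = 1e-8)
  }
  # pure factor-A shift with (numerically) negligible within-cell noise
  v <- rep(c(0, 0, 5, 5), each = 3) + rep(c(-1, 0, 1), 4) * 1e-3
  a2 <- twoWayAnova(FactorialTable(v, rep(c("wt", "ko"), each = 6),
                                   rep(rep(c("wt", "ko"), each = 3), 2)))
  expect_gt(a2$Fa, 1e6)
  expect_lt(a2$Fb, 1e-3)
  expect_lt(a2$Fab, 1e-3)
  # all four cell means identical -> all F = 0 exactly
  v0 <- rep(c(1, 2, 3), 4)
  a0 <- twoWayAnova(FactorialTable(v0, rep(c("wt", "ko"), each = 6),
                                   rep(rep(c("wt", "ko"), each = 3), 2)))
  expect_equal(a0$Fa + a0$Fb + a0$Fab, 0, tolerance = 1e-12)
  expect_error(twoWayAnova(FactorialTable(rnorm(9)[1:9],
    rep(c("wt", "ko", "wt"), each = 3),
    rep(c("wt", "ko", "ko"), each = 3))), "cell")
})

test_that("Tukey post-hoc: identical groups, shifted group, conservativeness", {
  set.seed(6)
  A <- rep(c("wt", "ko"), each = 12)
  B <- rep(rep(c("wt", "ko"), each = 6), 2)
  # literally identical groups: every cell holds the same six values
  tk <- tukeyPosthoc(FactorialTable(rep(rnorm(6), 4), A, B))
  expect_identical(nrow(tk), 6L)
  expect_true(all(tk$p > 0.99))
  v <- rnorm(24)
  vs <- v + ifelse(A == "ko" & B == "ko", 10 * sd(v), 0)
  tks <- tukeyPosthoc(FactorialTable(vs, A, B))
  hit <- grepl("ko:ko", tks$pair)
  expect_true(all(tks$p[hit] < 0.001))
  # conservativeness: the studentized-range adjustment never yields a
  # smaller p than the unadjusted t test on the same pooled model
  cell <- factor(paste(A, B, sep = ":"))
  fit <- aov(vs ~ cell)
  s2 <- sum(residuals(fit)^2) / fit$df.residual
  combs <- combn(levels(cell), 2)
  for (i in seq_len(ncol(combs))) {
    x <- vs[cell == combs[1, i]]; y <- vs[cell == combs[2, i]]
    tstat <- (mean(y) - mean(x)) /
      sqrt(s2 * (1 / length(x) + 1 / length(y)))
    pUnadj <- 2 * pt(-abs(tstat), fit$df.residual)
    pr <- paste(combs[2, i], combs[1, i], sep = "-")
    expect_gte(tks$p[tks$pair == pr], pUnadj - 1e-12)
  }
  # the unpaired-t option reports the same six pairs
  tt <- tukeyPosthoc(FactorialTable(vs, A, B), method = "t")
  expect_identical(nrow(tt), 6L)
})

test_that("KS comparison equals the brute-force ECDF supremum", {
  expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ksCompare(c(1, 2, 3), c(4, 5, 6))$D, 1)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.3)
    r <- ksCompare(a, b)
    expect_equal(r$D, bruteForceKsD(a, b), tolerance = 1e-12)
    expect_equal(r$D, ksCompare(b, a)$D, tolerance = 1e-12)
    expect_true(r$D >= 0 && r$D <= 1)
  }
  expect_warning(ru <- ksCompare(1, c(1, 2)), "unreliable")
  expect_true(ru$unreliable)
})

test_that("type-I error of the factorial layer is controlled on null cohorts", {
  set.seed(12)
  sig <- replicate(60, {
    v <- rnorm(20)
    tbl <- FactorialTable(v, rep(c("wt", "ko"), each = 10),
                          rep(rep(c("wt", "ko"), each = 5), 2))
    a <- twoWayAnova(tbl)
    any(c(a$pA, a$pB, a$pAb) < 0.05)
  })
  # three tests at alpha = .05 -> family rate ~ .14; must stay modest
  expect_lt(mean(sig), 0.30)
  oneEff <- replicate(60, twoWayAnova(FactorialTable(rnorm(20),
    rep(c("wt", "ko"), each = 10),
    rep(rep(c("wt", "ko"), each = 5), 2)))$pA < 0.05)
  expect_lt(mean(oneEff), 0.12)
})
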