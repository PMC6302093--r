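# Shared helpers and independent oracles used across the test files.

# Greedy matching of detected event times against planted ground truth.
matchEvents <- function(det, tru, tol = 5e-3) {
  used <- logical(length(tru))
  tp <- 0L
  for (t in det) {
    i <- which(!used & abs(tru - t) <= tol)
    if (length(i)) { used[i[1]] <- TRUE; tp <- tp + 1L }
  }
  list(precision = if (length(det)) tp / length(det) else 1,
       recall = if (length(tru)) tp / length(tru) else 1,
       tp = tp)
}

# Brute-force balanced two-way ANOVA F statistics from explicit sums of
# squares (projection decomposition), independent of lm/car.
bruteForceAnovaF <- function(v, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(v)
  nA <- tapply(v, A, length); nB <- tapply(v, B, length)
  ssA <- sum(nA * (tapply(v, A, mean) - gm)^2)
  ssB <- sum(nB * (tapply(v, B, mean) - gm)^2)
  cellMean <- tapply(v, list(A, B), mean)
  nCell <- table(A, B)
  eff <- cellMean - outer(tapply(v, A, mean), tapply(v, B, mean), `+`) +
    gm
  ssAB <- sum(nCell * eff^2)
  ssE <- sum((v - ave(v, interaction(A, B)))^2)
  dfE <- length(v) - nlevels(A) * nlevels(B)
  c(Fa = (ssA / (nlevels(A) - 1)) / (ssE / dfE),
    Fb = (ssB / (nlevels(B) - 1)) / (ssE / dfE),
    Fab = (ssAB / ((nlevels(A) - 1) * (nlevels(B) - 1))) / (ssE / dfE))
}

# Brute-force two-sample KS D: sup over all ECDF evaluation points.
bruteForceKsD <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# Direct (non-iterated) Grubbs decision from the critical-value formula.
grubbsFlagOnce <- function(x, alpha = 0.05) {
  n <- length(x)
  g <- max(abs(x - mean(x))) / sd(x)
  tcrit <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  g > gcrit
}

# Evaluate the planted four-group pattern on one analyzed cohort,
# using the study's own statistical layer: Tukey post-hoc comparisons
# across the four genotype cells (pooled variance), plus a one-sided
# within-group sign test for the planted beta-distance gradient.
cohortPattern <- function(analysis) {
  beh <- analysis$behavior; lfp <- analysis$lfp; mins <- analysis$minis
  g <- function(d, grp, col) d[[col]][d$group == grp]
  # group label -> factorial cell label used by tukeyPosthoc
  cellOf <- c(wt = "wt:wt", nlgn2ko = "ko:wt", igsf9bko = "wt:ko",
              dko = "ko:ko")
  tukeyP <- function(d, col, g1, g2) {
    d <- d[is.finite(d[[col]]), ]
    ff <- AmygQuant:::factorialFactors(d$group)
    tk <- tryCatch(tukeyPosthoc(FactorialTable(d[[col]], ff$factorA,
      ff$factorB)), error = function(e) NULL)
    if (is.null(tk)) return(NA_real_)
    want <- c(paste(cellOf[g1], cellOf[g2], sep = "-"),
              paste(cellOf[g2], cellOf[g1], sep = "-"))
    tk$p[tk$pair %in% want][1]
  }
  checks <- c(
    bCenterReduced = mean(g(beh, "nlgn2ko", "timeInCenter")) <
      mean(g(beh, "wt", "timeInCenter")) &&
      tukeyP(beh, "timeInCenter", "nlgn2ko", "wt") < 0.05,
    # planted truth for group B is a within-group gradient of beta on
    # distance: one-sided signed-rank test of the per-subject slopes
    bBetaTowardCenter = mean(g(lfp, "nlgn2ko", "betaSlope")) <
      mean(g(lfp, "wt", "betaSlope")) &&
      tryCatch(suppressWarnings(stats::wilcox.test(
        g(lfp, "nlgn2ko", "betaSlope"),
        alternative = "less")$p.value), error = function(e) NA) < 0.05,
    bSapElevated = mean(g(lfp, "nlgn2ko", "sapRatio"), na.rm = TRUE) >
      mean(g(lfp, "wt", "sapRatio"), na.rm = TRUE) &&
      tukeyP(lfp, "sapRatio", "nlgn2ko", "wt") < 0.05,
    # group D is planted identical to control: the Tukey comparison
    # must come out non-significant
    dCenterNormal = tukeyP(beh, "timeInCenter", "dko", "wt") > 0.05,
    dBetaNormal = tukeyP(lfp, "betaSlope", "dko", "wt") > 0.05,
    cMiniElevated = mean(g(mins, "igsf9bko", "miniFrequency")) >
      mean(g(mins, "wt", "miniFrequency")) &&
      tukeyP(mins, "miniFrequency", "igsf9bko", "wt") < 0.05)
  checks
}
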