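# Statistical layer: Grubbs outlier screening, 2x2 factorial ANOVA with
# Tukey post-hoc tests, Kolmogorov-Smirnov distribution comparisons.

# Grubbs critical value (two-sided) for sample size n at level alpha.
grubbsCritical <- function(n, alpha = 0.05) {
  tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Iterated Grubbs outlier screening
#'
#' Two-sided Grubbs test: G = max |x - mean| / sd compared against the
#' t-based critical value; at most one value is removed per pass and the
#' test is repeated until nothing is flagged. Removal never shrinks the
#' sample below 3.
#'
#' @param values numeric vector (n >= 3).
#' @param alpha significance level.
#' @return list: \code{outliers} (indices into the input),
#'   \code{cleaned} values, \code{G} statistics per pass.
#' @export
grubbsScreen <- function(values, alpha = 0.05) {
  stopIfNot(length(values) >= 3, "need at least 3 values")
  idx <- seq_along(values)
  out <- integer()
  G <- numeric()
  repeat {
    x <- values[idx]
    n <- length(x)
    if (n < 3 || n - 1 < 3) break
    s <- stats::sd(x)
    if (s == 0) { warning("zero variance; no outliers flagged"); break }
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g <= grubbsCritical(n, alpha)) break
    worst <- idx[which.max(dev)]
    out <- c(out, worst)
    G <- c(G, g)
    idx <- setdiff(idx, worst)
  }
  list(outliers = out, cleaned = values[idx], G = G)
}

#' Assemble a 2x2 factorial table
#'
#' @param value numeric observations.
#' @param factorA,factorB two-level factors (e.g. wt/ko for each gene).
#' @param subject optional subject identifiers.
#' @return data.frame of class \code{FactorialTable}.
#' @export
FactorialTable <- function(value, factorA, factorB, subject = NULL) {
  d <- data.frame(value = value, factorA = factor(factorA),
                  factorB = factor(factorB),
                  subject = subject %||% seq_along(value))
  stopIfNot(nlevels(d$factorA) == 2 && nlevels(d$factorB) == 2,
            "both factors need exactly two levels")
  class(d) <- c("FactorialTable", "data.frame")
  d
}

#' Two-way factorial ANOVA (partial, Type-III-style sums of squares)
#'
#' Fits value ~ A * B with sum-to-zero contrasts and partial
#' (Type-III-style) sums of squares, so balanced designs reproduce the
#' sequential decomposition exactly and unbalanced group sizes are
#' handled the way common ANOVA software does.
#'
#' @param tbl a \code{\link{FactorialTable}}.
#' @return list of class \code{AnovaResult}: Fa, Fb, Fab; dfA, dfB,
#'   dfAb, dfResid; pA, pB, pAb.
#' @export
twoWayAnova <- function(tbl) {
  counts <- table(tbl$factorA, tbl$factorB)
  stopIfNot(all(counts > 0), "every factorial cell must be occupied")
  stopIfNot(all(counts >= 2),
            "need >= 2 observations per occupied cell")
  fit <- stats::lm(value ~ factorA * factorB, data = tbl,
    contrasts = list(factorA = stats::contr.sum,
                     factorB = stats::contr.sum))
  a <- car::Anova(fit, type = 3)
  rn <- rownames(a)
  pick <- function(term) {
    i <- match(term, rn)
    c(F = a[i, "F value"], df = a[i, "Df"], p = a[i, "Pr(>F)"])
  }
  fa <- pick("factorA"); fb <- pick("factorB")
  fab <- pick("factorA:factorB")
  resid <- match("Residuals", rn)
  structure(list(Fa = unname(fa["F"]), Fb = unname(fb["F"]),
    Fab = unname(fab["F"]), dfA = unname(fa["df"]),
    dfB = unname(fb["df"]), dfAb = unname(fab["df"]),
    dfResid = a[resid, "Df"], pA = unname(fa["p"]),
    pB = unname(fb["p"]), pAb = unname(fab["p"])),
    class = "AnovaResult")
}

#' Tukey post-hoc comparisons across the four factorial groups
#'
#' Studentized-range-adjusted p-values for all six pairwise comparisons
#' of the 2x2 cells (via a one-way fit on the cell factor). An unpaired
#' Welch t alternative is available for the histology convention.
#'
#' @param tbl a \code{\link{FactorialTable}}.
#' @param method "tukey" or "t" (unadjusted unpaired t-tests).
#' @return data.frame: pair, diff, p.
#' @export
tukeyPosthoc <- function(tbl, method = c("tukey", "t")) {
  method <- match.arg(method)
  cell <- factor(paste(tbl$factorA, tbl$factorB, sep = ":"))
  if (method == "tukey") {
    fit <- stats::aov(tbl$value ~ cell)
    tk <- stats::TukeyHSD(fit)$cell
    return(data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p = tk[, "p adj"], row.names = NULL))
  }
  lv <- levels(cell)
  combs <- utils::combn(lv, 2)
  do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    x <- tbl$value[cell == combs[1, i]]
    y <- tbl$value[cell == combs[2, i]]
    tt <- stats::t.test(y, x)
    data.frame(pair = paste(combs[2, i], combs[1, i], sep = "-"),
               diff = mean(y) - mean(x), p = tt$p.value)
  }))
}

#' Two-sample Kolmogorov-Smirnov comparison of per-cell distributions
#'
#' D is the supremum distance between the two empirical CDFs; p comes
#' from the asymptotic two-sample formula.
#'
#' @param a,b numeric samples (non-empty).
#' @return list: D, p, unreliable (TRUE when either n < 2).
#' @export
ksCompare <- function(a, b) {
  stopIfNot(length(a) >= 1 && length(b) >= 1,
            "both samples must be non-empty")
  unreliable <- length(a) < 2 || length(b) < 2
  if (unreliable) warning("n < 2; KS p-value unreliable")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       unreliable = unreliable)
}
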