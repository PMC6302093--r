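# Cohort orchestration: simulate -> analyze -> statistics -> report.

#' Options controlling cohort simulation and analysis problem sizes
#'
#' @param lfpFs LFP synthesis rate (Hz, >= 2000).
#' @param trackingDt trajectory sample interval (s).
#' @param miniDur voltage-clamp record length per cell (s).
#' @param miniSweeps sweeps per cell (the step transient is averaged
#'   across sweeps before fitting, suppressing mini contamination).
#' @param miniFs voltage-clamp sampling rate (Hz).
#' @param sapHop fine hop (s) for per-time-point SAP beta power.
#' @param withLfp,withMinis,withImages,withBehavior stage toggles.
#' @return list of options.
#' @export
CohortOpts <- function(lfpFs = 2000, trackingDt = 0.05, miniDur = 15,
                       miniSweeps = 30, miniFs = 10000, sapHop = 0.05,
                       withLfp = TRUE, withMinis = TRUE,
                       withImages = TRUE, withBehavior = TRUE) {
  list(lfpFs = lfpFs, trackingDt = trackingDt, miniDur = miniDur,
       miniSweeps = miniSweeps, miniFs = miniFs, sapHop = sapHop,
       withLfp = withLfp, withMinis = withMinis,
       withImages = withImages, withBehavior = withBehavior)
}

#' Simulate a full cohort with planted ground truth
#'
#' One subject = one trajectory, optionally an LFP recording tied to it,
#' a voltage-clamp record (one "cell" per subject), and a perisomatic
#' puncta image. Per-subject seeds are derived reproducibly from the
#' cohort seed.
#'
#' @param cfg a \code{\link{CohortConfig}}.
#' @param opts a \code{\link{CohortOpts}}.
#' @return list of subject records (group, subject, traj, lfp, sweeps,
#'   image, roi, ra/leak QC metadata).
#' @export
simulateCohort <- function(cfg, opts = CohortOpts()) {
  nTot <- length(cfg$groups) * cfg$nSubjectsPerGroup
  seeds <- deriveSeeds(cfg$seed, 4 * nTot)
  subjects <- vector("list", nTot)
  k <- 0
  for (g in seq_along(cfg$groups)) {
    gp <- cfg$groups[[g]]
    for (s in seq_len(cfg$nSubjectsPerGroup)) {
      k <- k + 1
      traj <- genTrajectory(gp, cfg, seed = seeds[k], dt = opts$trackingDt)
      lfp <- NULL
      if (opts$withLfp) {
        lp <- LfpGenParams(fsRaw = opts$lfpFs)
        lfp <- genLfp(traj, gp, lp, seed = seeds[nTot + k])
      }
      sweeps <- NULL; ra <- NULL
      if (opts$withMinis) {
        vp <- VcGenParams(fs = opts$miniFs)
        sweeps <- genVcSweeps(gp, vp, nSweeps = opts$miniSweeps,
          seed = seeds[2 * nTot + k],
          sweepDur = opts$miniDur / opts$miniSweeps)
        set.seed(seeds[2 * nTot + k] + 1L)
        raInit <- stats::runif(1, 8, 12.5)
        ra <- list(raInitial = raInit,
                   raFinal = raInit * stats::runif(1, 0.95, 1.15),
                   leak = stats::runif(1, 20, 150))
      }
      image <- NULL; roi <- NULL
      if (opts$withImages) {
        im <- genImages(gp, "puncta", seed = seeds[3 * nTot + k])
        image <- im$image; roi <- im$roi
      }
      subjects[[k]] <- list(group = gp$label,
        subject = sprintf("%s_%02d", gp$label, s), traj = traj,
        lfp = lfp, sweeps = sweeps, ra = ra, image = image, roi = roi)
    }
  }
  subjects
}

# Fine-hop SAP beta for one subject: per-time-point beta inside event
# spans (hop sapHop) plus coarse-hop baseline points outside events.
subjectSapBeta <- function(lfp, saps, band, mt, sapHop) {
  coarse <- bandPowerTimecourse(lfp, band, mt)
  if (is.null(saps) || nrow(saps) == 0) return(NULL)
  fs <- sampleRate(lfp)
  winLen <- round(band$window * fs)
  n <- length(samples(lfp))
  starts <- integer()
  for (i in seq_len(nrow(saps))) {
    lo <- max(1L, floor((saps$tStart[i] - lfp@t0) * fs) -
                round(winLen / 2))
    hi <- min(n - winLen + 1L,
              ceiling((saps$tEnd[i] - lfp@t0) * fs) - round(winLen / 2))
    if (lo <= hi) starts <- c(starts, seq(lo, hi,
      by = max(1L, round(sapHop * fs))))
  }
  if (!length(starts)) return(NULL)
  r <- slidingBandPower(samples(lfp), fs, winLen,
    hop = 1L, mt = mt, fLo = band$fLo, fHi = band$fHi,
    starts = sort(unique(starts)))
  fine <- data.frame(t = lfp@t0 + (r$starts - 1 + winLen / 2) / fs,
                     power = r$power)
  inEv <- rep(FALSE, nrow(coarse))
  for (i in seq_len(nrow(saps)))
    inEv[coarse$t >= saps$tStart[i] - band$window / 2 &
         coarse$t <= saps$tEnd[i] + band$window / 2] <- TRUE
  series <- rbind(fine, coarse[!inEv, ])
  sapTriggeredBeta(series[order(series$t), ], saps)
}

#' Analyze a simulated (or loaded) cohort
#'
#' Runs the behavior, LFP, mini and puncta stages per subject and
#' collects per-subject measures. Stage failures are caught so one
#' modality cannot abort the others.
#'
#' @param subjects list from \code{\link{simulateCohort}}.
#' @param zones a \code{\link{ZoneConfig}}.
#' @param opts a \code{\link{CohortOpts}}.
#' @param tp \code{\link{TemplateParams}} for mini detection.
#' @return list of data.frames: behavior, lfp (betaSlope, sapRatio per
#'   subject), minis (frequency, amplitude, qcPass), puncta, plus
#'   \code{binned} (per-subject distance-binned beta) and \code{notices}.
#' @export
analyzeCohort <- function(subjects, zones = ZoneConfig(),
                          opts = CohortOpts(), tp = TemplateParams()) {
  notices <- character()
  safely <- function(expr, what, subj) tryCatch(expr, error = function(e) {
    notices <<- c(notices, sprintf("%s failed for %s: %s", what, subj,
                                   conditionMessage(e)))
    NULL
  })
  behavior <- list(); lfpRows <- list(); miniRows <- list()
  punctaRows <- list(); binned <- list()
  band <- betaBand(); mt <- MultitaperParams()
  for (sub in subjects) {
    id <- sub$subject
    if (!is.null(sub$traj)) {
      bm <- safely(zoneMetrics(sub$traj, zones), "behavior", id)
      if (!is.null(bm))
        behavior[[id]] <- cbind(data.frame(subject = id,
          group = sub$group), bm)
    }
    if (!is.null(sub$lfp)) {
      row <- safely({
        pre <- preprocessLfp(sub$lfp)
        tc <- bandPowerTimecourse(pre, band, mt)
        db <- distanceBinnedBeta(tc, sub$traj, zones)
        binned[[id]] <- db
        slope <- betaDistanceTrend(list(db))$slope
        sap <- subjectSapBeta(pre, sapEvents(sub$traj), band, mt,
                              opts$sapHop)
        data.frame(subject = id, group = sub$group, betaSlope = slope,
          sapRatio = if (is.null(sap)) NA_real_ else sap$ratio,
          sapEventMean = if (is.null(sap)) NA_real_ else sap$groupMean)
      }, "lfp", id)
      if (!is.null(row)) lfpRows[[id]] <- row
    }
    if (!is.null(sub$sweeps)) {
      row <- safely({
        cell <- CellRecord(sub$sweeps, raInitial = sub$ra$raInitial,
          raFinal = sub$ra$raFinal, leak = sub$ra$leak, mode = "vc_mipsc")
        qc <- qcFilter(cell)
        fit <- tryCatch(fitCapacitiveTransient(sub$sweeps),
                        error = function(e) NULL)
        det <- detectMinisSweepSet(sub$sweeps, tp, fit)
        summ <- suppressWarnings(perCellSummary(data.frame(
          t = det$events$t, amplitude = det$events$scale),
          det$duration))
        pp <- tryCatch(passiveProperties(fit,
          stepDv = sub$sweeps@protocol$stepAmp %||% 10),
          error = function(e) list(rs = NA_real_, rm = NA_real_,
                                   cm = NA_real_))
        data.frame(subject = id, group = sub$group,
          miniFrequency = summ$frequency,
          miniAmplitude = summ$meanAmplitude, nEvents = summ$n,
          rs = pp$rs, rm = pp$rm, cm = pp$cm, qcPass = qc$pass)
      }, "minis", id)
      if (!is.null(row)) miniRows[[id]] <- row
    }
    if (!is.null(sub$image)) {
      row <- safely({
        bgGt <- groundTruth(sub$image)$background %||% 100
        pr <- perisomaticPuncta(sub$image, sub$roi, expansion = 1.4,
                                threshold = 3 * bgGt)
        data.frame(subject = id, group = sub$group,
          punctaDensity = pr$density[1], nPuncta = pr$nPuncta[1])
      }, "images", id)
      if (!is.null(row)) punctaRows[[id]] <- row
    }
  }
  bindOrNull <- function(l) if (length(l)) do.call(rbind, c(l,
    make.row.names = FALSE)) else NULL
  list(behavior = bindOrNull(behavior), lfp = bindOrNull(lfpRows),
       minis = bindOrNull(miniRows), puncta = bindOrNull(punctaRows),
       binned = binned, notices = notices)
}

# Map the four canonical group labels onto the 2x2 factorial design.
factorialFactors <- function(groups) {
  map <- list(wt = c("wt", "wt"), nlgn2ko = c("ko", "wt"),
              igsf9bko = c("wt", "ko"), dko = c("ko", "ko"))
  if (!all(groups %in% names(map))) return(NULL)
  m <- t(vapply(groups, function(g) map[[g]], character(2)))
  data.frame(factorA = m[, 1], factorB = m[, 2])
}

#' Statistics over cohort measures
#'
#' Per measure: iterated Grubbs screening within each group, then (when
#' the group labels map onto the 2x2 design) a two-way factorial ANOVA
#' with Tukey post-hoc comparisons.
#'
#' @param analysis result of \code{\link{analyzeCohort}}.
#' @param measures named list mapping measure name to c(table, column).
#' @param alpha Grubbs level.
#' @return named list per measure: cleaned table, anova, tukey,
#'   outliers.
#' @export
cohortStats <- function(analysis, measures = NULL, alpha = 0.05) {
  if (is.null(measures)) {
    measures <- list(
      timeInCenter = c("behavior", "timeInCenter"),
      centerEntries = c("behavior", "centerEntries"),
      totalDistance = c("behavior", "totalDistance"),
      betaSlope = c("lfp", "betaSlope"),
      sapRatio = c("lfp", "sapRatio"),
      miniFrequency = c("minis", "miniFrequency"),
      miniAmplitude = c("minis", "miniAmplitude"),
      punctaDensity = c("puncta", "punctaDensity"))
  }
  out <- list()
  for (nm in names(measures)) {
    tab <- analysis[[measures[[nm]][1]]]
    col <- measures[[nm]][2]
    if (is.null(tab) || !col %in% names(tab)) next
    d <- tab[is.finite(tab[[col]]), c("subject", "group", col)]
    if (!nrow(d)) next
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$group), function(ii) {
      if (length(ii) < 3) return(ii)
      gs <- grubbsScreen(d[[col]][ii], alpha)
      setdiff(ii, ii[gs$outliers])
    }))
    dc <- d[sort(keep), ]
    ff <- factorialFactors(dc$group)
    res <- list(data = dc, outliers = d$subject[setdiff(seq_len(nrow(d)),
                                                        keep)])
    if (!is.null(ff) && length(unique(dc$group)) == 4) {
      tbl <- FactorialTable(dc[[col]], ff$factorA, ff$factorB,
                            subject = dc$subject)
      res$anova <- tryCatch(twoWayAnova(tbl), error = function(e) NULL)
      res$tukey <- tryCatch(tukeyPosthoc(tbl), error = function(e) NULL)
    }
    out[[nm]] <- res
  }
  out
}

#' Write the consolidated cohort report
#'
#' One CSV per analysis table, per-measure ANOVA/Tukey tables, optional
#' summary figures, and a \code{manifest.json} recording the seed and
#' package version. Missing stages are omitted with a notice.
#'
#' @param analysis result of \code{\link{analyzeCohort}}.
#' @param stats result of \code{\link{cohortStats}}.
#' @param outDir output directory (created).
#' @param seed seed recorded in the manifest.
#' @param figures write PNG figures?
#' @return invisible list of written paths.
#' @export
cohortReport <- function(analysis, stats, outDir, seed = NA,
                         figures = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in c("behavior", "lfp", "minis", "puncta")) {
    tab <- analysis[[nm]]
    if (is.null(tab)) {
      analysis$notices <- c(analysis$notices,
        sprintf("stage '%s' missing; section omitted", nm))
      next
    }
    p <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths[[nm]] <- p
  }
  anovaRows <- list(); tukeyRows <- list()
  for (nm in names(stats)) {
    a <- stats[[nm]]$anova
    if (!is.null(a))
      anovaRows[[nm]] <- data.frame(measure = nm, Fa = a$Fa, pA = a$pA,
        Fb = a$Fb, pB = a$pB, Fab = a$Fab, pAb = a$pAb,
        dfResid = a$dfResid)
    tk <- stats[[nm]]$tukey
    if (!is.null(tk))
      tukeyRows[[nm]] <- cbind(measure = nm, tk)
  }
  if (length(anovaRows)) {
    p <- file.path(outDir, "anova.csv")
    utils::write.csv(do.call(rbind, c(anovaRows,
      make.row.names = FALSE)), p, row.names = FALSE)
    paths$anova <- p
  }
  if (length(tukeyRows)) {
    p <- file.path(outDir, "tukey.csv")
    utils::write.csv(do.call(rbind, c(tukeyRows,
      make.row.names = FALSE)), p, row.names = FALSE)
    paths$tukey <- p
  }
  if (figures && !is.null(analysis$behavior)) {
    p <- file.path(outDir, "behavior.png")
    gg <- ggplot2::ggplot(analysis$behavior,
        ggplot2::aes(x = group, y = timeInCenter)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
      ggplot2::labs(y = "time in center (s)", x = NULL) +
      ggplot2::theme_classic()
    ggplot2::ggsave(p, gg, width = 4, height = 3, dpi = 120)
    paths$behaviorFigure <- p
  }
  if (figures && !is.null(analysis$lfp)) {
    p <- file.path(outDir, "beta_slope.png")
    gg <- ggplot2::ggplot(analysis$lfp,
        ggplot2::aes(x = group, y = betaSlope)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
      ggplot2::labs(y = "normalized beta vs distance slope (1/cm)",
                    x = NULL) +
      ggplot2::theme_classic()
    ggplot2::ggsave(p, gg, width = 4, height = 3, dpi = 120)
    paths$lfpFigure <- p
  }
  manifest <- list(package = "AmygQuant",
    version = as.character(utils::packageVersion("AmygQuant")),
    seed = seed, tables = names(paths),
    notices = analysis$notices %||% character())
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(outDir, "manifest.json")
  invisible(paths)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file with fields \code{seed}, \code{out},
#'   \code{cohort} (nSubjectsPerGroup, sessionDuration, arenaSide),
#'   \code{opts} (see \code{\link{CohortOpts}}), \code{band}
#'   (fLo, fHi, window, overlap).
#' @return validated RunConfig list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
validateRunConfig <- function(cfg) {
  stopIfNot(!is.null(cfg$seed), "config$seed is mandatory")
  cohort <- cfg$cohort %||% list()
  cc <- defaultCohortConfig(
    nSubjectsPerGroup = cohort$nSubjectsPerGroup %||% 5,
    seed = cfg$seed,
    sessionDuration = cohort$sessionDuration %||% 300)
  opts <- do.call(CohortOpts, cfg$opts %||% list())
  band <- if (is.null(cfg$band)) betaBand() else
    do.call(BandSpec, c(list(name = "beta"), cfg$band))
  stopIfNot(band$fHi < (opts$lfpFs / (opts$lfpFs %/% 1000) / 2) &&
            band$fHi < 500,
            "band upper edge must be below the analysis Nyquist rate")
  list(seed = cfg$seed, out = cfg$out %||% "cohort_report",
       cohort = cc, opts = opts, band = band)
}

#' Run the full pipeline: simulate, analyze, test, report
#'
#' @param cfg RunConfig list from \code{\link{readRunConfig}} /
#'   \code{\link{validateRunConfig}}.
#' @param figures write figures?
#' @return list: analysis, stats, reportPaths, outDir.
#' @export
runAll <- function(cfg, figures = TRUE) {
  cfg <- validateRunConfig(cfg)
  subjects <- simulateCohort(cfg$cohort, cfg$opts)
  analysis <- analyzeCohort(subjects, opts = cfg$opts)
  stats <- cohortStats(analysis)
  paths <- cohortReport(analysis, stats, cfg$out, seed = cfg$seed,
                        figures = figures)
  list(analysis = analysis, stats = stats, reportPaths = paths,
       outDir = cfg$out)
}
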