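#' Planted-effect parameters for one experimental group
#'
#' The generator plants group-level effects through these knobs: center
#' avoidance of the open field, SAP (stretch-attend posture) rate, spatial
#' and SAP modulation of beta-band LFP amplitude, miniature-PSC rate and
#' amplitude, and perisomatic puncta density. The defaults describe a
#' wild-type-like animal; see \code{\link{defaultCohortConfig}} for the
#' four-group configuration used throughout.
#'
#' @param label group label.
#' @param centerAvoidance dimensionless outward drift strength (0 = no
#'   avoidance beyond ordinary thigmotaxis-free wandering).
#' @param sapRate SAP episodes per minute.
#' @param betaDistanceGain dimensionless slope of beta amplitude versus
#'   (1 - distance/dmax); 0 plants no spatial effect.
#' @param betaSapGain multiplicative beta amplitude factor during SAPs
#'   (> 0; 1 plants no effect).
#' @param miniRate miniature-PSC rate (Hz).
#' @param miniAmpMean,miniAmpCv mean amplitude (pA) and coefficient of
#'   variation of planted minis.
#' @param punctaDensity planted puncta per um of soma perimeter.
#' @return A \code{GroupParams} list.
#' @export
GroupParams <- function(label = "wt", centerAvoidance = 0.3, sapRate = 1.5,
                        betaDistanceGain = 0.1, betaSapGain = 1.1,
                        miniRate = 5, miniAmpMean = 50, miniAmpCv = 0.3,
                        punctaDensity = 0.20) {
  stopIfNot(sapRate >= 0 && miniRate >= 0 && punctaDensity >= 0,
            "rates must be >= 0")
  stopIfNot(betaSapGain > 0, "betaSapGain must be > 0")
  stopIfNot(miniAmpMean > 0, "miniAmpMean must be > 0")
  structure(list(label = label, centerAvoidance = centerAvoidance,
    sapRate = sapRate, betaDistanceGain = betaDistanceGain,
    betaSapGain = betaSapGain, miniRate = miniRate,
    miniAmpMean = miniAmpMean, miniAmpCv = miniAmpCv,
    punctaDensity = punctaDensity), class = "GroupParams")
}

#' Cohort-level configuration for the synthetic generator
#'
#' @param groups list of \code{\link{GroupParams}}.
#' @param nSubjectsPerGroup subjects per group (>= 1).
#' @param seed master seed; a fixed seed makes every generated byte
#'   reproducible.
#' @param arenaSide open-field arena side (cm).
#' @param sessionDuration session length (s).
#' @return A \code{CohortConfig} list.
#' @export
CohortConfig <- function(groups, nSubjectsPerGroup = 5, seed = 1,
                         arenaSide = 50, sessionDuration = 300) {
  stopIfNot(nSubjectsPerGroup >= 1, "nSubjectsPerGroup must be >= 1")
  stopIfNot(arenaSide > 0, "arenaSide must be > 0")
  stopIfNot(sessionDuration > 0, "sessionDuration must be > 0")
  structure(list(groups = groups, nSubjectsPerGroup = nSubjectsPerGroup,
    seed = seed, arenaSide = arenaSide, sessionDuration = sessionDuration),
    class = "CohortConfig")
}

#' The four-group study configuration used by the pipeline
#'
#' Wild type; a high-anxiety group with elevated center avoidance and
#' planted spatial/SAP beta gains (mirroring Nlgn2 loss); a group with
#' elevated inhibitory mini rate (mirroring IgSF9b loss); and a "double"
#' group whose avoidance and beta gains are normalized back to control
#' values while the mini-rate elevation persists.
#'
#' @inheritParams CohortConfig
#' @return A \code{CohortConfig}.
#' @export
defaultCohortConfig <- function(nSubjectsPerGroup = 5, seed = 1,
                                sessionDuration = 300) {
  groups <- list(
    GroupParams("wt"),
    GroupParams("nlgn2ko", centerAvoidance = 1.2, betaDistanceGain = 0.8,
                betaSapGain = 2.0, punctaDensity = 0.12),
    GroupParams("igsf9bko", miniRate = 8, punctaDensity = 0.30),
    GroupParams("dko", miniRate = 6.5, punctaDensity = 0.25))
  CohortConfig(groups, nSubjectsPerGroup = nSubjectsPerGroup, seed = seed,
               sessionDuration = sessionDuration)
}

#' LFP generator parameters
#'
#' @param fsRaw raw sampling rate (Hz, >= 2000).
#' @param oneOverFExponent exponent of the 1/f^alpha background.
#' @param thetaFreq,betaFreq oscillation frequencies (Hz).
#' @param baseBetaAmp baseline beta amplitude (uV).
#' @param thetaAmp theta amplitude (uV).
#' @param noiseSd standard deviation of the 1/f background (uV).
#' @return An \code{LfpGenParams} list.
#' @export
LfpGenParams <- function(fsRaw = 32000, oneOverFExponent = 1.5,
                         thetaFreq = 8, betaFreq = 24, baseBetaAmp = 30,
                         thetaAmp = 40, noiseSd = 15) {
  stopIfNot(fsRaw >= 2000, "fsRaw must be >= 2000 Hz")
  stopIfNot(baseBetaAmp >= 0 && thetaAmp >= 0 && noiseSd >= 0,
            "amplitudes must be >= 0")
  structure(list(fsRaw = fsRaw, oneOverFExponent = oneOverFExponent,
    thetaFreq = thetaFreq, betaFreq = betaFreq, baseBetaAmp = baseBetaAmp,
    thetaAmp = thetaAmp, noiseSd = noiseSd), class = "LfpGenParams")
}

#' Voltage-clamp / membrane-model generator parameters
#'
#' @param fs sampling rate (Hz).
#' @param rs series (access) resistance (MOhm).
#' @param rm membrane resistance (MOhm).
#' @param cm membrane capacitance (pF).
#' @param stepDv test-step amplitude (mV).
#' @param stepDur test-step duration (ms).
#' @param miniRiseTau,miniDecayTau mini kernel time constants (ms).
#' @param noiseSd Gaussian current noise SD (pA).
#' @param leak leak (holding) current (pA).
#' @return A \code{VcGenParams} list.
#' @export
VcGenParams <- function(fs = 20000, rs = 10, rm = 500, cm = 30,
                        stepDv = 10, stepDur = 20, miniRiseTau = 0.5,
                        miniDecayTau = 15, noiseSd = 2, leak = 50) {
  stopIfNot(rs > 0 && rm > 0 && cm > 0, "rs, rm, cm must be > 0")
  stopIfNot(fs > 0, "fs must be > 0")
  structure(list(fs = fs, rs = rs, rm = rm, cm = cm, stepDv = stepDv,
    stepDur = stepDur, miniRiseTau = miniRiseTau,
    miniDecayTau = miniDecayTau, noiseSd = noiseSd, leak = leak),
    class = "VcGenParams")
}
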