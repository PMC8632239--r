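# Simulated surgeon behavior: ideal plane, noisy pose sampling with
# guidance-dependent calibration, and the factorial study runner.

#' Behavior model constructor
#'
#' @param setting "unguided", "tumor_guided" or "carotid_guided".
#' @param rotSd angular noise SD (degrees) about the two in-plane axes.
#' @param transSd translational noise SD (mm) along the plane normal.
#' @param angulationChoices pointer angulations offered, subset of
#'   c(0, 30, 45, 60, 90).
#' @param angulationWeights sampling weights (defaults to the observed usage
#'   frequencies of the 30/45/60/90-degree pointers).
#' @param maxResample carotid-guided resampling budget on breach.
#' @return a \linkS4class{BehaviorModel}.
#' @export
behaviorModel <- function(setting, rotSd, transSd,
                          angulationChoices = c(30, 45, 60, 90),
                          angulationWeights = c(11, 18, 45, 25),
                          maxResample = 0L) {
  new("BehaviorModel", setting = setting, rotSd = rotSd, transSd = transSd,
      angulationChoices = angulationChoices,
      angulationWeights = angulationWeights,
      maxResample = as.integer(maxResample))
}

#' Default behavior calibration per guidance setting
#'
#' Unguided placement is noisier (rotSd 8 degrees, transSd 3 mm) than
#' navigation-guided placement (4 degrees, 1.5 mm); the carotid-guided
#' setting additionally resamples poses whose plane would breach the vessel
#' (the beeping alarm), up to 5 times. These are stated defaults for an
#' ordinal comparison of settings, not a claim of fidelity to human
#' performance.
#'
#' @param setting one of "unguided", "tumor_guided", "carotid_guided".
#' @return a \linkS4class{BehaviorModel}.
#' @export
defaultBehavior <- function(setting = c("unguided", "tumor_guided",
                                        "carotid_guided")) {
  setting <- match.arg(setting)
  switch(setting,
    unguided = behaviorModel("unguided", rotSd = 8, transSd = 3),
    tumor_guided = behaviorModel("tumor_guided", rotSd = 4, transSd = 1.5),
    carotid_guided = behaviorModel("carotid_guided", rotSd = 4,
                                   transSd = 1.5, maxResample = 5L))
}

#' Ideal delineation plane for a phantom
#'
#' The vertical plane tangent to the tumor's posterior offset surface at
#' half the local tumor-carotid gap: every plane point keeps at least half
#' the clearance from the tumor and from the carotid, so a noise-free
#' delineation is both clear-margin and carotid-sparing. The superior or
#' inferior posterior-margin portion selects whether the sampled window runs
#' upward or downward from the split plane.
#'
#' @param model a \linkS4class{PhantomModel}.
#' @param portion "superior" or "inferior".
#' @return a \linkS4class{PointerPose}.
#' @export
idealPose <- function(model, portion = c("superior", "inferior")) {
  portion <- match.arg(portion)
  tp <- model@preset@tumorParams
  g <- model@preset@tcClearance
  u <- tp$posteriorDir
  zSplit <- .PHANTOM_GEOM$zSplit
  anchor <- tp$lobeCenter + (tp$lobeRadius + g / 2) * u
  tip <- c(anchor[1], anchor[2], zSplit)
  shaft <- if (portion == "superior") c(0, 0, 1) else c(0, 0, -1)
  poseFromFrame(tip, shaft, u)
}

#' Sample a simulated surgeon pointer pose
#'
#' The ideal plane perturbed by rotations about the two in-plane axes
#' (N(0, rotSd^2) degrees each) and a translation along the plane normal
#' (N(0, transSd^2) mm). In the carotid-guided setting, poses whose sampled
#' area would enter the vessel (checked against the analytic tube surface,
#' the stand-in for the real-time breach alarm) are resampled up to
#' \code{maxResample} times; an exhausted budget returns the last pose
#' flagged \code{breachUnresolved}.
#'
#' @param model a \linkS4class{PhantomModel}.
#' @param behavior a \linkS4class{BehaviorModel}.
#' @param portion "superior" or "inferior".
#' @param samplingSpec \linkS4class{PlaneSamplingSpec} used for the breach
#'   check window.
#' @param noiseScale multiplier on both noise SDs (per-surgeon experience).
#' @return a \linkS4class{PointerPose}. Uses the R random number generator;
#'   fix \code{set.seed} for reproducibility.
#' @export
samplePointerPose <- function(model, behavior, portion = "superior",
                              samplingSpec = planeSamplingSpec(),
                              noiseScale = 1) {
  base <- idealPose(model, portion)
  fr <- poseFrame(base)
  rotSd <- behavior@rotSd * noiseScale
  transSd <- behavior@transSd * noiseScale
  tries <- if (behavior@setting == "carotid_guided") behavior@maxResample + 1L else 1L
  ang <- behavior@angulationChoices[
    sample.int(length(behavior@angulationChoices), 1,
               prob = behavior@angulationWeights)]
  pose <- NULL
  for (i in seq_len(tries)) {
    th1 <- stats::rnorm(1, 0, rotSd)
    th2 <- stats::rnorm(1, 0, rotSd)
    dn <- stats::rnorm(1, 0, transSd)
    Rot <- rotationAboutAxis(fr$lateral, th2) %*%
      rotationAboutAxis(fr$shaft, th1)
    shaft <- as.vector(Rot %*% fr$shaft)
    normal <- as.vector(Rot %*% fr$normal)
    tip <- base@tip + dn * fr$normal
    pose <- poseFromFrame(tip, shaft, normal, angulation = ang)
    if (behavior@setting != "carotid_guided") return(pose)
    pts <- isolateArea(pose, samplingSpec)
    if (min(icaDistanceAnalytic(model, pts)) > 0) return(pose)
  }
  pose@breachUnresolved <- TRUE
  pose
}

# Deterministic sub-seed from a top-level seed and a stream key, kept within
# the 32-bit integer range.
.subSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000000007
  as.integer((h * 31 + (seed %% 2147483647) * 17 + 7) %% 2147483646) + 1L
}

#' Run a simulated delineation study
#'
#' Factorial runner: every surgeon delineates the superior and inferior
#' posterior-margin portions on every phantom under every guidance setting
#' (optionally several replicates). Per-surgeon experience heterogeneity is
#' modeled as a multiplicative noise factor drawn once per surgeon from
#' LogNormal(0, 0.25^2). Deterministic under a fixed seed: every pose draws
#' from a stream keyed by (preset, surgeon, setting, portion, replicate), so
#' changing the surgeon count does not perturb other streams.
#'
#' @param presets list of \linkS4class{PhantomPreset} (or ids); default all
#'   four stock presets.
#' @param nSurgeons number of simulated surgeons (default 8).
#' @param behaviors named list of \linkS4class{BehaviorModel}s; default the
#'   three stock settings.
#' @param seed top-level seed.
#' @param nReplicates replicates per cell (default 1).
#' @param spec \linkS4class{VolumeSpec} for mask/distance-field generation.
#' @param samplingSpec \linkS4class{PlaneSamplingSpec} for plane evaluation.
#' @return list of \linkS4class{TrialRecord}.
#' @export
simulateStudy <- function(presets = phantomPresets(), nSurgeons = 8,
                          behaviors = list(defaultBehavior("unguided"),
                                           defaultBehavior("tumor_guided"),
                                           defaultBehavior("carotid_guided")),
                          seed = 1, nReplicates = 1,
                          spec = volumeSpec(),
                          samplingSpec = planeSamplingSpec()) {
  if (!length(presets)) stop("empty preset list")
  if (nSurgeons < 1) stop("nSurgeons must be >= 1")
  presets <- lapply(presets, function(p)
    if (is.character(p)) phantomPreset(p) else p)

  oldSeed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })

  set.seed(.subSeed(seed, "surgeon-multipliers"))
  mult <- stats::rlnorm(nSurgeons, 0, 0.25)

  records <- list()
  for (preset in presets) {
    model <- buildPhantom(preset, spec)
    tumorField <- signedDistance(tumorMask(model))
    icaField <- signedDistance(icaMask(model))
    for (s in seq_len(nSurgeons)) {
      for (behavior in behaviors) {
        for (portion in c("superior", "inferior")) {
          for (rep in seq_len(nReplicates)) {
            key <- paste(preset@id, s, behavior@setting, portion, rep,
                         sep = "|")
            set.seed(.subSeed(seed, key))
            pose <- samplePointerPose(model, behavior, portion,
                                      samplingSpec, noiseScale = mult[s])
            map <- evaluatePlane(pose, tumorField, icaField, samplingSpec)
            records[[length(records) + 1L]] <-
              new("TrialRecord", surgeonId = as.integer(s),
                  presetId = preset@id, setting = behavior@setting,
                  portion = portion, summary = summarizePlane(map),
                  pose = pose)
          }
        }
      }
    }
  }
  records
}

#' Tabulate trial records
#'
#' One row per record with the zone fractions (as percentages), plane flags
#' and design factors; the CSV-facing representation of a study.
#'
#' @param records list of \linkS4class{TrialRecord}.
#' @return a data.frame.
#' @export
recordsTable <- function(records) {
  stopifnot(length(records) > 0)
  fr <- t(vapply(records, function(r) r@summary@fractions,
                 numeric(length(zoneCodes()))))
  colnames(fr) <- paste0("pct_", zoneCodes())
  fl <- t(vapply(records, function(r) r@summary@flags, logical(5)))
  data.frame(
    surgeonId = vapply(records, function(r) r@surgeonId, integer(1)),
    presetId = vapply(records, function(r) r@presetId, character(1)),
    setting = vapply(records, function(r) r@setting, character(1)),
    portion = vapply(records, function(r) r@portion, character(1)),
    angulation = vapply(records, function(r) r@pose@angulation, numeric(1)),
    breachUnresolved = vapply(records, function(r) r@pose@breachUnresolved,
                              logical(1)),
    100 * fr, fl,
    stringsAsFactors = FALSE)
}

#' Read/write trial records as CSV
#'
#' @param records list of \linkS4class{TrialRecord} (for writing) .
#' @param path file path.
#' @return \code{readRecordsCsv} returns the records data.frame.
#' @export
writeRecordsCsv <- function(records, path) {
  df <- if (is.data.frame(records)) records else recordsTable(records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecordsCsv
#' @export
readRecordsCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
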