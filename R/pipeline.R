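# End-to-end orchestration: phantom generation, plane analysis and the
# simulated study, with fully serialized run configuration.

#' Run configuration
#'
#' Bundles everything a reproducible run needs: seed, presets, grid,
#' behavior calibration, plane sampling window and registration gate. The
#' resolved configuration is written next to every run's outputs.
#'
#' @param seed top-level seed fanned out to named substreams.
#' @param presets preset ids to include.
#' @param spec a \linkS4class{VolumeSpec}.
#' @param behaviors named list of \linkS4class{BehaviorModel}s.
#' @param samplingSpec a \linkS4class{PlaneSamplingSpec}.
#' @param registrationThreshold FRE gate, mm.
#' @param nSurgeons surgeons simulated by \code{\link{cmdStudy}}.
#' @param nReplicates replicates per study cell.
#' @param alertMargin proximity alert margin, mm.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(seed = 1L, presets = c("S1", "S2", "S3", "S4"),
                      spec = volumeSpec(),
                      behaviors = list(unguided = defaultBehavior("unguided"),
                                       tumor_guided = defaultBehavior("tumor_guided"),
                                       carotid_guided = defaultBehavior("carotid_guided")),
                      samplingSpec = planeSamplingSpec(),
                      registrationThreshold = 1.0,
                      nSurgeons = 8L, nReplicates = 1L, alertMargin = 2) {
  structure(list(seed = as.integer(seed), presets = presets, spec = spec,
                 behaviors = behaviors, samplingSpec = samplingSpec,
                 registrationThreshold = registrationThreshold,
                 nSurgeons = as.integer(nSurgeons),
                 nReplicates = as.integer(nReplicates),
                 alertMargin = alertMargin),
            class = "RunConfig")
}

.configAsList <- function(config) {
  list(
    seed = config$seed,
    presets = config$presets,
    volume = list(dims = config$spec@dims, spacing = config$spec@spacing,
                  origin = config$spec@origin,
                  intensities = as.list(config$spec@intensities)),
    behaviors = lapply(config$behaviors, function(b)
      list(setting = b@setting, rot_sd = b@rotSd, trans_sd = b@transSd,
           angulation_choices = b@angulationChoices,
           angulation_weights = b@angulationWeights,
           max_resample = b@maxResample)),
    sampling = list(length = config$samplingSpec@length,
                    half_width = config$samplingSpec@halfWidth,
                    step = config$samplingSpec@step),
    registration_threshold = config$registrationThreshold,
    n_surgeons = config$nSurgeons,
    n_replicates = config$nReplicates,
    alert_margin = config$alertMargin,
    conventions = list(
      world = "RAS mm; voxel (0,0,0) center at origin; 0-based indices",
      distance_sign = "negative inside the structure",
      zone_boundaries = "d_ica = 2 mm -> danger zone; d_tumor = 5 and 10 mm -> clear (G)"))
}

#' Write / read a run configuration as YAML
#'
#' @param config a RunConfig.
#' @param path file path.
#' @return \code{readRunConfig} returns a RunConfig.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  behaviors <- lapply(x$behaviors, function(b)
    behaviorModel(b$setting, b$rot_sd, b$trans_sd,
                  angulationChoices = unlist(b$angulation_choices),
                  angulationWeights = unlist(b$angulation_weights),
                  maxResample = b$max_resample))
  runConfig(seed = x$seed, presets = unlist(x$presets),
            spec = volumeSpec(dims = unlist(x$volume$dims),
                              spacing = unlist(x$volume$spacing),
                              origin = unlist(x$volume$origin),
                              intensities = unlist(x$volume$intensities)),
            behaviors = behaviors,
            samplingSpec = planeSamplingSpec(x$sampling$length,
                                             x$sampling$half_width,
                                             x$sampling$step),
            registrationThreshold = x$registration_threshold,
            nSurgeons = x$n_surgeons, nReplicates = x$n_replicates,
            alertMargin = x$alert_margin)
}

.validatePresets <- function(ids) {
  bad <- setdiff(ids, .presetTable$id)
  if (length(bad))
    stop("invalid preset id(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(.presetTable$id, collapse = ", "))
  invisible(ids)
}

#' Generate phantom files for the configured presets
#'
#' Writes, per preset: the synthesized volume and the tumor/ICA/bone masks
#' as NIfTI, the three surface meshes as binary STL, the fiducial CSV, and a
#' metadata JSON with the measured tumor-carotid clearance and the seed.
#'
#' @param config a RunConfig.
#' @param outDir output directory (created if missing).
#' @return named list of per-preset metadata, invisibly.
#' @export
cmdGenerate <- function(config, outDir) {
  .validatePresets(config$presets)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  meta <- list()
  for (id in config$presets) {
    model <- buildPhantom(id, config$spec)
    pdir <- file.path(outDir, id)
    dir.create(pdir, showWarnings = FALSE)
    vol <- synthesizeVolume(model)
    writeNiftiGrid(vol, file.path(pdir, "volume.nii.gz"))
    writeNiftiGrid(tumorMask(model), file.path(pdir, "tumor_mask.nii.gz"))
    writeNiftiGrid(icaMask(model), file.path(pdir, "ica_mask.nii.gz"))
    writeNiftiGrid(boneMask(model), file.path(pdir, "bone_mask.nii.gz"))
    writeSTL(model@tumorMesh, file.path(pdir, "tumor.stl"))
    writeSTL(model@icaMesh, file.path(pdir, "ica.stl"))
    writeSTL(model@boneMesh, file.path(pdir, "bone.stl"))
    writeFiducialCsv(fiducials(model), file.path(pdir, "fiducials.csv"))
    m <- list(preset = id,
              configured_tc_clearance_mm = model@preset@tcClearance,
              measured_tc_clearance_mm = measureClearance(model),
              seed = config$seed,
              dims = config$spec@dims, spacing = config$spec@spacing)
    jsonlite::write_json(m, file.path(pdir, "metadata.json"),
                         digits = NA, auto_unbox = TRUE)
    meta[[id]] <- m
  }
  invisible(meta)
}

#' Analyze pointer poses against a generated model directory
#'
#' Loads (or regenerates) the tumor and ICA distance fields for the model,
#' evaluates each pose file and writes the map CSV, the color-scaled PNG and
#' a summary JSON per pose.
#'
#' @param poseFiles character vector of pose JSON paths.
#' @param modelDir a per-preset directory written by \code{\link{cmdGenerate}}.
#' @param config a RunConfig.
#' @param outDir output directory.
#' @return list of \linkS4class{ZoneSummary}, invisibly.
#' @export
cmdAnalyze <- function(poseFiles, modelDir, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fields <- .loadOrComputeFields(modelDir)
  out <- list()
  for (pf in poseFiles) {
    pose <- readPoseJson(pf)
    map <- evaluatePlane(pose, fields$tumor, fields$ica, config$samplingSpec)
    summ <- summarizePlane(map)
    alert <- evaluateAlert(pose@tip, fields$ica, config$alertMargin)
    stem <- tools::file_path_sans_ext(basename(pf))
    writeMapCsv(map, file.path(outDir, paste0(stem, "_map.csv")))
    renderColormap(map, file.path(outDir, paste0(stem, "_map.png")))
    jsonlite::write_json(
      list(pose = stem,
           fractions = as.list(summ@fractions),
           flags = as.list(summ@flags),
           tip_alert = alert,
           n_points = summ@nPoints),
      file.path(outDir, paste0(stem, "_summary.json")),
      digits = NA, auto_unbox = TRUE)
    out[[stem]] <- summ
  }
  invisible(out)
}

.loadOrComputeFields <- function(modelDir) {
  out <- list()
  for (nm in c("tumor", "ica")) {
    fieldPath <- file.path(modelDir, paste0(nm, "_distance.nii.gz"))
    if (file.exists(fieldPath)) {
      out[[nm]] <- readNiftiGrid(fieldPath, as = "field")
    } else {
      maskPath <- file.path(modelDir, paste0(nm, "_mask.nii.gz"))
      if (!file.exists(maskPath))
        stop("neither distance field nor mask found for '", nm,
             "' in ", modelDir)
      message("distance field for '", nm, "' missing; regenerating from mask")
      f <- signedDistance(readNiftiGrid(maskPath, as = "mask"))
      out[[nm]] <- f
      writeNiftiGrid(f, fieldPath)
    }
  }
  out
}

#' Run the full simulated study
#'
#' End-to-end: phantoms, distance fields, registration gate check, surgeon
#' pose sampling, plane evaluation and the group statistics. Writes the
#' records CSV, the comparison report (JSON + Markdown) and the resolved
#' configuration; deterministic under the configured seed.
#'
#' @param config a RunConfig (needs >= 2 configured behaviors).
#' @param outDir output directory.
#' @return list with \code{records}, \code{comparison}, \code{gain},
#'   invisibly.
#' @export
cmdStudy <- function(config, outDir) {
  if (length(config$behaviors) < 2L)
    stop("at least 2 guidance settings must be configured")
  .validatePresets(config$presets)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(config, file.path(outDir, "config.yaml"))

  # registration gate: each phantom's divots must register under the
  # configured threshold before its simulations count
  regOk <- list()
  set.seed(.subSeed(config$seed, "registration"))
  for (id in config$presets) {
    model <- buildPhantom(id, config$spec, voxelize = FALSE)
    fids <- perturbFiducials(fiducials(model), sd = 0.25)
    reg <- registerFiducials(fids, threshold = config$registrationThreshold)
    regOk[[id]] <- list(fre_mm = fre(reg), accepted = isAccepted(reg))
    if (!isAccepted(reg))
      warning("preset ", id, " failed the registration gate (FRE ",
              round(fre(reg), 3), " mm)")
  }

  records <- simulateStudy(presets = as.list(config$presets),
                           nSurgeons = config$nSurgeons,
                           behaviors = config$behaviors,
                           seed = config$seed,
                           nReplicates = config$nReplicates,
                           spec = config$spec,
                           samplingSpec = config$samplingSpec)
  df <- recordsTable(records)
  writeRecordsCsv(df, file.path(outDir, "records.csv"))

  comparison <- compareGroups(df)
  gain <- computeGain(df)
  reportMarkdown(comparison, file.path(outDir, "report.md"))
  jsonlite::write_json(
    list(seed = config$seed,
         registration = regOk,
         zone_stats = comparison@zoneStats,
         flag_tests = lapply(comparison@flagTests, function(x)
           list(table = as.data.frame(x$table), p = x$p.value)),
         gain = list(mean = as.list(gain@meanGain),
                     per_surgeon = gain@perSurgeon),
         alpha = comparison@alpha),
    file.path(outDir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(records = records, comparison = comparison, gain = gain))
}

#' Re-render the Markdown report from a study directory
#'
#' @param studyDir directory written by \code{\link{cmdStudy}}.
#' @param path optional output path (defaults to report.md in studyDir).
#' @return the Markdown text, invisibly.
#' @export
cmdReport <- function(studyDir, path = file.path(studyDir, "report.md")) {
  df <- readRecordsCsv(file.path(studyDir, "records.csv"))
  comparison <- compareGroups(df)
  invisible(reportMarkdown(comparison, path))
}
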