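#' Image volume and ROI mask containers
#'
#' An `ImageVolume` is a 3-D scalar array (Hounsfield units) with voxel
#' spacing (mm), physical origin (mm) and a vascular phase label, one of
#' `"PP"`, `"AP"`, `"PVP"`, `"DP"` (precontrast, arterial, portal venous,
#' delayed). An `RoiMask` is a binary array on the same grid with at least one
#' foreground voxel.
#'
#' @param voxels 3-D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm, all positive.
#' @param origin numeric length-3, physical origin in mm.
#' @param phase phase label; one of `PP`, `AP`, `PVP`, `DP`.
#' @return An object of class `ImageVolume` (resp. `RoiMask`).
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         phase = "PP") {
  .assert(is.array(voxels) && length(dim(voxels)) == 3L, "voxels must be a 3-D array")
  .assert(all(is.finite(voxels)), "voxel array must be finite-valued")
  .assert(length(spacing) == 3L && all(spacing > 0), "spacing must be 3 positive values")
  .assert(phase %in% PHASE_LEVELS,
          "phase must be one of %s", paste(PHASE_LEVELS, collapse = ", "))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "ImageVolume")
}

#' @param volume companion `ImageVolume`; the mask must share its grid.
#' @rdname image_volume
#' @export
roi_mask <- function(voxels, volume = NULL) {
  .assert(is.array(voxels) && length(dim(voxels)) == 3L, "mask must be a 3-D array")
  vox <- array(as.numeric(voxels) != 0, dim = dim(voxels))
  .assert(sum(vox) >= 1, "mask has no foreground voxels")
  if (!is.null(volume)) {
    .assert(identical(dim(vox), dim(volume$voxels)),
            "mask shape %s does not match volume shape %s",
            paste(dim(vox), collapse = "x"), paste(dim(volume$voxels), collapse = "x"))
  }
  structure(list(voxels = vox,
                 spacing = if (is.null(volume)) c(1, 1, 1) else volume$spacing,
                 origin = if (is.null(volume)) c(0, 0, 0) else volume$origin),
            class = "RoiMask")
}

#' Read / write image volumes as NRRD
#'
#' `read_volume()` reads a (3-D) NRRD file into an [image_volume()];
#' `write_volume()` writes one. Non-isotropic spacing is allowed and noted
#' with a message. Encodings `ascii` and `raw` (little-endian) are supported.
#'
#' @param path NRRD file path.
#' @param phase phase label to attach on read.
#' @param quiet suppress the anisotropy note.
#' @return `read_volume()`: an `ImageVolume`. `write_volume()`: `path`,
#'   invisibly.
#' @export
read_volume <- function(path, phase = "PP", quiet = FALSE) {
  nr <- read_nrrd(path)
  .assert(length(dim(nr$data)) == 3L, "expected a 3-D volume in %s", path)
  if (!quiet && length(unique(nr$spacing)) > 1L)
    message("note: non-isotropic spacing (", paste(nr$spacing, collapse = ", "), ") mm")
  image_volume(nr$data, spacing = nr$spacing, origin = nr$origin, phase = phase)
}

#' @param volume an `ImageVolume` or `RoiMask`.
#' @param encoding `"ascii"` (plain text, default) or `"raw"`.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path, encoding = "ascii") {
  write_nrrd(volume$voxels + 0, path, spacing = volume$spacing,
             origin = volume$origin, encoding = encoding)
}

#' Read / write per-phase static feature tables
#'
#' The on-disk format is a long CSV with columns `patient_id`, `phase`, then
#' one numeric column per feature. `read_feature_csv()` returns a named list
#' of per-phase matrices (patients x features, row names = patient ids),
#' phases ordered PP, AP, PVP, DP.
#'
#' @param path CSV path.
#' @return Named list of numeric matrices, one per phase present.
#' @export
read_feature_csv <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(all(c("patient_id", "phase") %in% names(df)),
          "feature CSV must have patient_id and phase columns")
  .assert(all(df$phase %in% PHASE_LEVELS),
          "unknown phase label(s): %s",
          paste(setdiff(unique(df$phase), PHASE_LEVELS), collapse = ", "))
  key <- paste(df$patient_id, df$phase)
  .assert(!anyDuplicated(key), "duplicated (patient, phase) rows in %s", path)
  fcols <- setdiff(names(df), c("patient_id", "phase"))
  .assert(length(fcols) > 0, "no feature columns in %s", path)
  for (f in fcols)
    .assert(is.numeric(df[[f]]), "non-numeric feature column: %s", f)
  phases <- PHASE_LEVELS[PHASE_LEVELS %in% unique(df$phase)]
  pats <- unique(df$patient_id)
  out <- lapply(phases, function(p) {
    sub <- df[df$phase == p, , drop = FALSE]
    .assert(setequal(sub$patient_id, pats) && nrow(sub) == length(pats),
            "phase %s does not cover every patient exactly once", p)
    m <- as.matrix(sub[match(pats, sub$patient_id), fcols, drop = FALSE])
    rownames(m) <- pats
    m
  })
  names(out) <- phases
  out
}

#' @param phase_matrices named list of per-phase matrices as returned by
#'   `read_feature_csv()`.
#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(phase_matrices, path) {
  .assert(is.list(phase_matrices) && length(phase_matrices) > 0,
          "phase_matrices must be a non-empty named list")
  rows <- lapply(names(phase_matrices), function(p) {
    m <- phase_matrices[[p]]
    data.frame(patient_id = rownames(m), phase = p, as.data.frame(m),
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with the package
#' defaults. All downstream under-specified choices surface here.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param simulation a [sim_config()] describing the synthetic cohort (used
#'   when no `feature_csv` input is given).
#' @param feature_csv optional path to a per-phase feature CSV to analyse
#'   instead of simulating.
#' @param cohort_csv optional path to a clinical/outcome CSV
#'   (`patient_id, response, pfs_days, event, ...`) matching `feature_csv`.
#' @param kinds dynamic transform kinds to construct.
#' @param classifiers classifier set for the response grid.
#' @param alpha t-test screening level.
#' @param onepass logical; `FALSE` (default) refits selection inside every
#'   leave-one-out fold, `TRUE` selects once on the full data before
#'   cross-validation (the leakage-prone one-pass variant).
#' @param horizons time-dependent ROC horizons in days, strictly increasing.
#' @param degree polynomial degree for the P transform (default `k - 1`).
#' @param times phase times: `"ordinal"` (1..k) or `"seconds"`
#'   (acquisition-window midpoints 0, 32.5, 67.5, 110 for k = 4).
#' @param out_dir output directory for [run_pipeline()].
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulation = sim_config(seed = seed),
                            feature_csv = NULL, cohort_csv = NULL,
                            kinds = c("SD", "DC", "RCR", "RACR", "P"),
                            classifiers = c("LDA", "RF", "SVM"),
                            alpha = 0.05, onepass = FALSE,
                            horizons = c(90, 180, 270, 360),
                            degree = NULL, times = c("ordinal", "seconds"),
                            out_dir = tempfile("dynrad_run_")) {
  times <- match.arg(times)
  .assert(length(seed) == 1L && is.finite(seed), "seed must be a single integer")
  .assert(all(diff(horizons) > 0) && all(horizons > 0),
          "horizons must be strictly increasing positive days")
  structure(list(seed = as.integer(seed), simulation = simulation,
                 feature_csv = feature_csv, cohort_csv = cohort_csv,
                 kinds = kinds, classifiers = classifiers, alpha = alpha,
                 onepass = onepass, horizons = horizons, degree = degree,
                 times = times, out_dir = out_dir),
            class = "PipelineConfig")
}

phase_times <- function(k, mode = "ordinal") {
  if (mode == "seconds" && k == 4L) unname(PHASE_SECONDS) else seq_len(k)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> dynamic construction -> screening ->
#' leave-one-out response evaluation -> PFS risk-score workflow -> baseline
#' table, writing CSV/JSON results and a stage log under `config$out_dir`.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `grid`, `pfs`, `baseline`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  .assert(inherits(config, "PipelineConfig"), "config must be a pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- inputs -----------------------------------------------------------
  if (!is.null(config$feature_csv)) {
    phases <- stage("ingest", read_feature_csv(config$feature_csv))
    .assert(!is.null(config$cohort_csv), "feature_csv requires cohort_csv")
    cohort_tab <- stage("ingest", read_cohort_csv(config$cohort_csv))
    cohort <- list(features = phases, cohort = cohort_tab, informative = character())
    say("ingest: %d patients, %d phases, %d features",
        nrow(phases[[1]]), length(phases), ncol(phases[[1]]))
  } else {
    simcfg <- config$simulation
    simcfg$seed <- config$seed
    cohort <- stage("simulate", simulate_feature_cohort(simcfg))
    say("simulate: %d patients, %d phases, %d features (%d informative)",
        nrow(cohort$features[[1]]), length(cohort$features),
        ncol(cohort$features[[1]]), length(cohort$informative))
  }
  .assert(nrow(cohort$cohort) > 0, "empty cohort")
  k <- length(cohort$features)
  write_feature_csv(cohort$features, file.path(config$out_dir, "static_features.csv"))

  # -- static hygiene + dynamic construction ----------------------------
  phases <- stage("extract", lapply(cohort$features, identity))
  tms <- phase_times(k, config$times)
  degree <- config$degree %||% (k - 1L)
  dyn <- stage("dynamics", build_dynamic_matrix(phases, kinds = config$kinds,
                                                times = tms, degree = degree))
  say("dynamics: kinds {%s} -> %d columns (k = %d, %d pairs)",
      paste(config$kinds, collapse = ", "), ncol(dyn), k, k * (k - 1) / 2)
  dyn_kept <- stage("dynamics", drop_constant_features(dyn))
  say("dynamics: %d constant columns removed, %d kept",
      ncol(dyn) - ncol(dyn_kept), ncol(dyn_kept))

  labels <- factor(cohort$cohort$response, levels = c("NOR", "OR"))

  # -- selection + response grid ---------------------------------------
  sets <- intersect(c(config$kinds, names(phases), "Multi_static"),
                    c("SD", "DC", "RCR", "RACR", "P", names(phases), "Multi_static"))
  grid <- stage("evaluate",
                compare_feature_sets(cohort, kinds = sets,
                                     classifiers = config$classifiers,
                                     alpha = config$alpha,
                                     onepass = config$onepass,
                                     seed = config$seed, times = tms,
                                     degree = degree))
  write.csv(grid$auc, file.path(config$out_dir, "auc_grid.csv"))
  write.csv(grid$accuracy, file.path(config$out_dir, "accuracy_grid.csv"))
  best <- arrayInd(which.max(grid$auc), dim(grid$auc))
  say("evaluate: best AUC %.3f at %s / %s", max(grid$auc),
      rownames(grid$auc)[best[1]], colnames(grid$auc)[best[2]])

  # -- survival ---------------------------------------------------------
  rcr <- build_dynamic_matrix(phases, kinds = "RCR", times = tms)
  rcr <- drop_constant_features(rcr)
  pfs <- stage("survival",
               pfs_pipeline(rcr, time = cohort$cohort$pfs_days,
                            event = cohort$cohort$event,
                            horizons = config$horizons, alpha = config$alpha,
                            seed = config$seed))
  say("survival: %d features kept by Cox screen, log-rank p = %.3g",
      length(pfs$kept), pfs$logrank_p)
  surv_json <- list(
    risk_scores = as.numeric(pfs$risk), groups = as.character(pfs$group),
    logrank_chi2 = pfs$logrank_chi2, logrank_p = pfs$logrank_p,
    tdauc = as.list(pfs$tdauc))
  jsonlite::write_json(surv_json, file.path(config$out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA)
  km <- rbind(data.frame(group = "high", pfs$km$high),
              data.frame(group = "low", pfs$km$low))
  write.csv(km, file.path(config$out_dir, "km_curves.csv"), row.names = FALSE)

  # -- baseline table ---------------------------------------------------
  baseline <- stage("baseline", table2_report(cohort$cohort))
  write.csv(baseline, file.path(config$out_dir, "baseline_table.csv"),
            row.names = FALSE)

  writeLines(log_lines, logf)
  invisible(list(cohort = cohort, grid = grid, pfs = pfs, baseline = baseline,
                 out_dir = config$out_dir))
}

#' Read a clinical/outcome cohort table
#'
#' Expects columns `patient_id`, `response` (OR/NOR), `pfs_days`, `event`
#' and optionally `age`, `sex`, `site`, `tumor_size`, `cea`, `afp`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

validate_cohort <- function(df) {
  .assert(all(c("patient_id", "response", "pfs_days", "event") %in% names(df)),
          "cohort table needs patient_id, response, pfs_days, event")
  .assert(!anyDuplicated(df$patient_id), "patient_id not unique")
  .assert(all(df$response %in% c("OR", "NOR")), "response must be OR or NOR")
  .assert(all(df$pfs_days >= 0), "pfs_days must be nonnegative")
  .assert(all(df$event %in% c(0, 1)), "event must be 0/1")
  if ("sex" %in% names(df))
    .assert(all(df$sex %in% c("male", "female")), "sex must be male/female")
  if ("site" %in% names(df))
    .assert(all(df$site %in% c("left", "rectum", "right")),
            "site must be left/rectum/right")
  for (v in c("cea", "afp")) if (v %in% names(df))
    .assert(all(df[[v]] %in% c("normal", "high")), "%s must be normal/high", v)
  df
}
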