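#' Default pipeline configuration
#'
#' All stage parameters with their defaults: rolling 30 px, median 1 px,
#' morphological radius 25 px, neurosphere gate 1,000-50,000 px^2 at
#' circularity 0.5-1.0, nucleus gate 10-1,000 px^2 at 0.3-1.0, marker
#' thresholds 10 a.u. (HU, green, far-red) and 30 a.u. (red), DAPI window
#' 0-13 a.u. after inversion. The permissive multichannel nucleus gate
#' (0.001-1,000 px^2, circularity 0.1-1.0) is carried in the `migration`
#' block.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    channels = list(
      labels = c("DAPI", "HU"),   # plane order of input TIFFs
      dapi = "DAPI",
      neurosphere = "HU"),
    neurosphere_stage = list(
      invert = TRUE, threshold_lo = 0, threshold_hi = 100,
      morph_radius = 25, watershed_min_distance = 25,
      area_min = 1000, area_max = 50000, circ_min = 0.5, circ_max = 1.0),
    nucleus_stage = list(
      invert = TRUE, rolling_radius = 30, threshold_lo = 0, threshold_hi = 13,
      median_radius = 1, watershed_min_distance = 5,
      area_min = 10, area_max = 1000, circ_min = 0.3, circ_max = 1.0),
    markers = list(
      thresholds = list(HU = 10),
      subtract_marker_background = TRUE),
    combinations = c("HU+", "HU-"),
    migration = list(
      invert = TRUE, rolling_radius = 30, threshold_lo = 0, threshold_hi = 60,
      median_radius = 1, watershed_min_distance = 5,
      area_min = 0.001, area_max = 1000, circ_min = 0.1, circ_max = 1.0),
    stats = list(omnibus = "kruskal", posthoc = "dunn", adjust = "holm"),
    roi_dir = NULL,   # optional: directory of <image>.roi.csv manual ROI files
    seed = 1L), class = "pipeline_config")
}

# recursive merge of user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop(sprintf("configuration error: unknown key '%s'", full))
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    else
      defaults[[key]] <- user[[key]]
  }
  defaults
}

check_stage <- function(st, name) {
  chk <- function(cond, msg)
    if (!cond) stop(sprintf("configuration error in '%s': %s", name, msg))
  if (!is.null(st$threshold_lo)) {
    chk(st$threshold_lo >= 0 && st$threshold_hi <= 255,
        "threshold window must lie in [0, 255]")
    chk(st$threshold_lo <= st$threshold_hi, "threshold_lo must not exceed threshold_hi")
  }
  if (!is.null(st$area_min)) {
    chk(st$area_min >= 0 && st$area_min <= st$area_max,
        "need 0 <= area_min <= area_max")
    chk(st$circ_min >= 0 && st$circ_min <= st$circ_max && st$circ_max <= 1,
        "need 0 <= circ_min <= circ_max <= 1")
  }
  for (r in intersect(c("rolling_radius", "median_radius", "morph_radius",
                        "watershed_min_distance"), names(st)))
    chk(st[[r]] >= 1, sprintf("%s must be >= 1 px", r))
}

#' Read, default and range-check a pipeline configuration
#'
#' An empty or absent YAML body yields the full default configuration;
#' unknown keys and out-of-range gates or thresholds are configuration
#' errors naming the key.
#'
#' @param path YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) cfg <- merge_config(unclass(cfg), user)
  check_stage(cfg$neurosphere_stage, "neurosphere_stage")
  check_stage(cfg$nucleus_stage, "nucleus_stage")
  check_stage(cfg$migration, "migration")
  for (m in names(cfg$markers$thresholds)) {
    t <- cfg$markers$thresholds[[m]]
    if (t < 0 || t > 255)
      stop(sprintf("configuration error: marker threshold '%s' outside [0, 255]", m))
  }
  structure(cfg, class = "pipeline_config")
}

stage_params <- function(st) {
  preprocess_params(
    invert = if (is.null(st$invert)) TRUE else st$invert,
    rolling_radius = if (is.null(st$rolling_radius)) 30 else st$rolling_radius,
    median_radius = if (is.null(st$median_radius)) 1 else st$median_radius,
    threshold_lo = st$threshold_lo, threshold_hi = st$threshold_hi,
    morph_radius = if (is.null(st$morph_radius)) 25 else st$morph_radius,
    watershed_min_distance = st$watershed_min_distance)
}

stage_gate <- function(st) {
  particle_gate(st$area_min, st$area_max, st$circ_min, st$circ_max)
}

#' Run the full pipeline over a set of images
#'
#' For each input TIFF: segment neurospheres on the configured channel (or
#' load manual ROIs from `<image>.roi.csv` in `config$roi_dir` if present),
#' isolate nuclei per ROI on the DAPI channel, measure and classify marker
#' positivity, and integrate per-neurosphere summaries. Writes
#' `nuclei.csv`, `neurospheres.csv`, one QC overlay PNG per image, and
#' `run_log.txt` (effective configuration echo plus library versions) into
#' `out_dir`. A failing image is logged and skipped; remaining images are
#' still processed.
#'
#' @param config A `pipeline_config` (see [default_config],
#'   [validate_config]).
#' @param inputs Character vector of TIFF paths.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, `list(status, out_dir, failures)`; `status` is 0 on
#'   success, 1 if any image failed.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    "spherequant pipeline run",
    paste0("R version: ", R.version.string),
    paste0("EBImage: ", as.character(utils::packageVersion("EBImage"))),
    paste0("inputs: ", paste(inputs, collapse = ", ")),
    "--- effective configuration ---",
    strsplit(yaml::as.yaml(unclass(config)), "\n")[[1L]])
  all_records <- list()
  all_summaries <- list()
  failures <- character(0)
  for (input in inputs) {
    image_id <- tools::file_path_sans_ext(basename(input))
    res <- tryCatch({
      stack <- read_stack(input, config$channels$labels)
      roi_file <- if (!is.null(config$roi_dir))
        file.path(config$roi_dir, paste0(image_id, ".roi.csv")) else ""
      rois <- if (nzchar(roi_file) && file.exists(roi_file)) {
        manual_rois_from_file(roi_file, stack$shape)
      } else {
        segment_neurospheres(get_channel(stack, config$channels$neurosphere),
                             stage_params(config$neurosphere_stage),
                             stage_gate(config$neurosphere_stage))
      }
      for (i in seq_along(rois)) rois[[i]]$roi_id <- i
      dapi <- get_channel(stack, config$channels$dapi)
      nuclei <- list()
      for (roi in rois)
        nuclei <- c(nuclei, segment_nuclei_in_roi(
          dapi, roi, stage_params(config$nucleus_stage),
          stage_gate(config$nucleus_stage)))
      thresholds <- do.call(marker_thresholds, config$markers$thresholds)
      rec <- classify_stack(stack, rois, nuclei, thresholds,
                            stage_params(config$nucleus_stage),
                            config$markers$subtract_marker_background)
      rec$nucleus_id <- seq_len(nrow(rec))
      rec <- cbind(image = image_id, rec)
      summaries <- lapply(rois, function(roi)
        summarize_roi(rec, roi$roi_id, config$combinations, image_id))
      cls <- if (nrow(rec) > 0 && any(startsWith(names(rec), "pos_"))) {
        poscols <- names(rec)[startsWith(names(rec), "pos_")]
        apply(rec[poscols], 1L, function(z)
          paste0(sub("pos_", "", poscols[as.logical(z)]), collapse = "+"))
      } else NULL
      write_qc_overlay(stack, rois, nuclei,
                       file.path(out_dir, paste0(image_id, "_overlay.png")),
                       nucleus_class = cls)
      list(rec = rec, summaries = summaries)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, input)
      log_lines <- c(log_lines,
                     sprintf("ERROR processing '%s': %s", input, conditionMessage(res)))
    } else {
      all_records[[image_id]] <- res$rec
      all_summaries <- c(all_summaries, res$summaries)
      log_lines <- c(log_lines,
                     sprintf("processed '%s': %d ROI(s), %d nuclei", input,
                             length(res$summaries), nrow(res$rec)))
    }
  }
  if (length(all_records) > 0)
    write_nucleus_csv(do.call(rbind, all_records),
                      file.path(out_dir, "nuclei.csv"))
  write_summary_csv(all_summaries, file.path(out_dir, "neurospheres.csv"))
  writeLines(log_lines, log_path)
  invisible(list(status = if (length(failures) > 0) 1L else 0L,
                 out_dir = out_dir, failures = failures))
}
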