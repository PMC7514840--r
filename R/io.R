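# Cohort serialisation, candidate ingestion and end-to-end pipeline
# orchestration.

.write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
}

#' Write a phantom cohort to disk
#'
#' Patches as PNG, truth maps as 0/255 single-channel PNG, candidate crops
#' as paired PNGs (`<id>_bbox.png`, `<id>_masked.png`) and one metadata CSV
#' with 0-based, half-open bounding-box pixel coordinates
#' (`x0,y0,x1,y1` = col0, row0, col1, row1).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "patches"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(dir, "candidates"), showWarnings = FALSE)
  meta <- list()
  for (k in seq_along(cohort$patches)) {
    p <- cohort$patches[[k]]
    png::writePNG(p$rgb / 255, file.path(dir, "patches",
                                         sprintf("patch_%03d.png", k)))
    for (comp in c("lumen", "cytoplasm", "stroma", "nuclei")) {
      .write_mask_png(p$truth_maps[[comp]],
                      file.path(dir, "maps",
                                sprintf("patch_%03d_%s.png", k, comp)))
    }
    for (ci in seq_along(p$candidates)) {
      cd <- p$candidates[[ci]]
      id <- sprintf("p%03d_c%02d", k, ci)
      png::writePNG(cd$rgb_bbox / 255,
                    file.path(dir, "candidates", paste0(id, "_bbox.png")))
      png::writePNG(cd$masked_rgb / 255,
                    file.path(dir, "candidates", paste0(id, "_masked.png")))
      bb <- cd$bbox
      meta[[length(meta) + 1]] <- data.frame(
        candidate_id = id, patient_id = cd$patient_id, class = cd$label,
        patch = k,
        x0 = bb[2] - 1L, y0 = bb[1] - 1L, x1 = bb[4], y1 = bb[3],
        stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, meta), file.path(dir, "candidates.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read gland candidates from a cohort directory
#'
#' Reads the `candidates.csv` metadata and the paired bounding-box/masked
#' PNGs written by [write_cohort()] (the same layout as an externally
#' segmented candidate database). Pairs with mismatched crop sizes are
#' rejected with a warning naming the files.
#'
#' @param dir cohort directory.
#' @return list of `gland_candidate`; empty (with a warning) if the
#'   directory holds no candidates.
#' @export
ingest_candidates <- function(dir) {
  csv <- file.path(dir, "candidates.csv")
  if (!file.exists(csv)) {
    warning("no candidates.csv in ", dir)
    return(list())
  }
  meta <- read.csv(csv, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$candidate_id[i]
    f1 <- file.path(dir, "candidates", paste0(id, "_bbox.png"))
    f2 <- file.path(dir, "candidates", paste0(id, "_masked.png"))
    if (!file.exists(f1) || !file.exists(f2)) {
      warning("missing image pair for ", id)
      next
    }
    a <- png::readPNG(f1) * 255
    b <- png::readPNG(f2) * 255
    if (!identical(dim(a), dim(b))) {
      warning("crop size mismatch for ", id, " (", f1, " vs ", f2, ")")
      next
    }
    bbox <- c(meta$y0[i] + 1L, meta$x0[i] + 1L, meta$y1[i], meta$x1[i])
    out[[length(out) + 1]] <- gland_candidate(
      rgb_bbox = a, masked_rgb = b, bbox = bbox,
      patient_id = meta$patient_id[i], label = meta$class[i])
  }
  out
}

#' Run the full pipeline on a phantom cohort
#'
#' Generates (or loads) a cohort, computes tissue maps and the 241-entry
#' descriptors, performs patient-wise nested cross-validation with the
#' requested classifier, and writes the feature table, selection audit,
#' metric report and a reproducibility manifest to `out_dir`.
#'
#' @param config named list (or path to a YAML file) with entries
#'   `phantom` (arguments for [phantom_spec()]), `maps` ("truth" or
#'   "computed"), `classifier` ("svm"/"mlp"), `alpha`, `r_thresh`, `tuner`,
#'   `budget`, `k_outer`, `k_inner`, `seed`, `out_dir`.
#' @return the `cv_report`, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(maps = "truth", classifier = "svm", alpha = 1e-6,
                   r_thresh = 0.95, tuner = "bo", budget = 30,
                   k_outer = 5, k_inner = 10, seed = 1,
                   out_dir = "glandclass_run")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$phantom)) stop("config$phantom is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- do.call(phantom_spec, c(config$phantom,
                                  list(seed = config$seed)))
  cohort <- generate_cohort(spec)
  tab <- cohort_features(cohort, maps = config$maps,
                         seed = config$seed + 10000L)
  utils::write.csv(
    data.frame(candidate_id = tab$candidate_ids, patient_id = tab$patients,
               class = tab$labels, tab$x, check.names = FALSE),
    file.path(config$out_dir, "features.csv"), row.names = FALSE)

  report <- nested_cv(tab, classifier = config$classifier,
                      k_outer = config$k_outer, k_inner = config$k_inner,
                      alpha = config$alpha, r_thresh = config$r_thresh,
                      tuner = config$tuner, budget = config$budget,
                      seed = config$seed + 20000L)

  jsonlite::write_json(list(
    metrics = report$metrics,
    multiclass_accuracy = report$multiclass_accuracy,
    score_significance = as.list(report$score_significance),
    selected_sizes = report$selected_sizes),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$folds[[1]]$selection$record,
                       file.path(config$out_dir, "selection_fold1.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("glandclass")),
    config = config[setdiff(names(config), "out_dir")],
    n_candidates = nrow(tab$x)),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(report)
}
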