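# Assembly of the full 241-entry hand-crafted descriptor.

#' Grayscale channels of a candidate crop
#'
#' The cyan, hematoxylin and eosin channels of an RGB crop, at full
#' resolution, all in \[0, 1\]. Texture and fractal features are computed
#' from the unmasked bounding box by default; set `use_masked = TRUE` to
#' compute them from the masked crop instead.
#'
#' @param candidate a [gland_candidate()].
#' @param use_masked use `masked_rgb` instead of `rgb_bbox`.
#' @return named list with `cyan`, `hematoxylin`, `eosin` matrices.
#' @export
candidate_channels <- function(candidate, use_masked = FALSE) {
  rgb <- if (use_masked) candidate$masked_rgb else candidate$rgb_bbox
  ch <- compute_channels(rgb)
  list(cyan = ch$c_cmyk, hematoxylin = ch$hematoxylin, eosin = ch$eosin)
}

#' Feature schema
#'
#' The fixed, ordered naming of the 241-entry descriptor: 20 morphological,
#' 15 fractal, 186 textural (126 GLCM + 60 LBP-family) and 20 contextual
#' features.
#'
#' @return data frame with columns `name`, `family`, `index`.
#' @export
feature_schema <- function() {
  morph <- c("area", "convexArea", "eccent", "equivDiam", "extent",
             "orientation", "perimeter", "solidity", "roundness",
             "compactness")
  nm_morph <- c(paste0("morph.gland.", morph), paste0("morph.lumen.", morph))
  chans <- c("cyan", "hematoxylin", "eosin")
  nm_fractal <- as.vector(t(outer(chans, c(0, 30, 45, 60, 90),
                                  function(ch, a) paste0("fractal.", ch, ".h", a))))
  gstat <- c("homogeneity", "contrast", "energy", "correlation", "entropy",
             paste0("mu", 1:8), paste0("sigma", 1:8))
  nm_glcm <- unlist(lapply(chans, function(ch) {
    unlist(lapply(c("d0", "d45"), function(off) {
      paste0("glcm.", ch, ".", off, ".", gstat)
    }))
  }))
  nm_lbp <- unlist(lapply(chans, function(ch) {
    c(paste0("lbp.", ch, ".riu2.b", 1:10), paste0("lbp.", ch, ".var.b", 1:10))
  }))
  nm_ctx <- c("ctx.nuclei.bbox.count", "ctx.nuclei.bbox.count_ratio",
              "ctx.nuclei.gland.count", "ctx.nuclei.gland.count_ratio",
              "ctx.nuclei.gland_bbox.count_ratio",
              "ctx.nuclei.bbox.pix", "ctx.nuclei.bbox.pix_ratio",
              "ctx.nuclei.gland.pix", "ctx.nuclei.gland.pix_ratio",
              "ctx.nuclei.gland_bbox.pix_ratio",
              "ctx.cyto.bbox.pix", "ctx.cyto.bbox.pix_ratio",
              "ctx.cyto.gland.pix", "ctx.cyto.gland.pix_ratio",
              "ctx.cyto.gland_bbox.pix_ratio",
              "ctx.lumen.gland.area_ratio",
              "ctx.lumen.edge_dist.mean", "ctx.lumen.edge_dist.sd",
              "ctx.toroid.cytonuclei.pix", "ctx.toroid.cytonuclei.pix_ratio")
  nm <- c(nm_morph, nm_fractal, nm_glcm, nm_lbp, nm_ctx)
  fam <- c(rep("morphology", length(nm_morph)),
           rep("fractal", length(nm_fractal)),
           rep("glcm", length(nm_glcm)),
           rep("lbp", length(nm_lbp)),
           rep("contextual", length(nm_ctx)))
  data.frame(name = nm, family = fam, index = seq_along(nm),
             stringsAsFactors = FALSE)
}

#' Write the feature schema as JSON
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_schema <- function(path) {
  jsonlite::write_json(list(version = "1.0", features = feature_schema()),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract the full 241-entry feature vector of one candidate
#'
#' Concatenates, in fixed schema order, the morphological (20), fractal
#' (15), textural (186) and contextual (20) features. Non-finite entries
#' (degenerate ratios or estimates) are mapped to 0 and recorded in the
#' `invalid` attribute.
#'
#' @param candidate a [gland_candidate()].
#' @param masks `candidate_masks` from [extract_masks()].
#' @param maps `tissue_maps` cropped to the candidate's bounding box.
#' @param use_masked_texture compute texture/fractal channels from the
#'   masked crop instead of the full bounding box.
#' @return named numeric vector of 241 finite values.
#' @export
extract_features <- function(candidate, masks, maps,
                             use_masked_texture = FALSE) {
  channels <- candidate_channels(candidate, use_masked = use_masked_texture)
  v <- c(morphological_features(masks),
         fractal_features(channels),
         texture_features(channels),
         contextual_features(masks, maps))
  schema <- feature_schema()
  v <- v[schema$name]
  names(v) <- schema$name
  bad <- !is.finite(v)
  v[bad] <- 0
  attr(v, "invalid") <- schema$name[bad]
  v
}

#' Feature table of a phantom cohort
#'
#' Runs mask extraction and the full descriptor over every candidate of a
#' cohort and assembles the candidates x features matrix with labels and
#' patient identifiers. Component maps come either from the generator's
#' ground truth (`maps = "truth"`) or from the tissue-mapping pipeline
#' applied to each patch (`maps = "computed"`). Candidates whose extraction
#' fails are skipped and listed in the `errors` attribute.
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param maps `"truth"` or `"computed"`.
#' @param seed seed for the tissue-mapping clustering when
#'   `maps = "computed"`.
#' @param verbose print progress every 25 patches.
#' @return a `feature_table`: list with `x` (matrix), `labels`, `patients`,
#'   `candidate_ids`.
#' @export
cohort_features <- function(cohort, maps = c("truth", "computed"), seed = 1,
                            verbose = FALSE) {
  maps <- match.arg(maps)
  schema <- feature_schema()
  rows <- list()
  labs <- pats <- ids <- character(0)
  errors <- character(0)
  for (k in seq_along(cohort$patches)) {
    p <- cohort$patches[[k]]
    pm <- if (maps == "truth") {
      p$truth_maps
    } else {
      tissue_component_maps(p$rgb, seed = seed + k)
    }
    for (ci in seq_along(p$candidates)) {
      cd <- p$candidates[[ci]]
      id <- sprintf("p%03d_c%02d", k, ci)
      v <- tryCatch({
        cropped <- crop_maps(pm, cd$bbox)
        msk <- extract_masks(cd, cropped$lumen)
        extract_features(cd, msk, cropped)
      }, error = function(e) e)
      if (inherits(v, "error")) {
        errors <- c(errors, paste0(id, ": ", conditionMessage(v)))
        next
      }
      rows[[length(rows) + 1]] <- as.numeric(v)
      labs <- c(labs, cd$label)
      pats <- c(pats, cd$patient_id)
      ids <- c(ids, id)
    }
    if (verbose && k %% 25 == 0) {
      message("processed ", k, "/", length(cohort$patches), " patches")
    }
  }
  x <- do.call(rbind, rows)
  colnames(x) <- schema$name
  rownames(x) <- ids
  structure(list(x = x, labels = labs, patients = pats, candidate_ids = ids),
            class = "feature_table", errors = errors)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %d candidates x %d features>\n",
              nrow(x$x), ncol(x$x)))
  print(table(x$labels))
  invisible(x)
}

#' Construct a feature table from components
#' @param x numeric matrix (candidates x features).
#' @param labels class per candidate.
#' @param patients patient id per candidate.
#' @param candidate_ids optional ids.
#' @return a `feature_table`.
#' @export
feature_table <- function(x, labels, patients,
                          candidate_ids = rownames(x)) {
  stopifnot(nrow(x) == length(labels), nrow(x) == length(patients))
  if (is.null(candidate_ids)) candidate_ids <- sprintf("c%05d", seq_len(nrow(x)))
  structure(list(x = x, labels = labels, patients = patients,
                 candidate_ids = candidate_ids),
            class = "feature_table")
}

#' Subset a feature table by row
#' @param tab a `feature_table`.
#' @param idx integer or logical row index.
#' @return a `feature_table`.
#' @export
subset_table <- function(tab, idx) {
  feature_table(tab$x[idx, , drop = FALSE], tab$labels[idx],
                tab$patients[idx], tab$candidate_ids[idx])
}
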