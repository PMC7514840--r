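# Contextual features: relations between the candidate's gland/lumen masks
# and the tissue-component maps in its bounding box.

#' Contextual features of a candidate
#'
#' Twenty features relating the candidate to the nuclei and cytoplasm maps
#' of its bounding box: counts and pixel totals of nuclei elements
#' (8-connected components, counted inside a region only when every pixel
#' of the element lies inside), the analogous cytoplasm pixel totals, the
#' lumen/gland area ratio, the mean and standard deviation of the
#' centroid-to-edge distance of the lumen, and the cytoplasm+nuclei content
#' of the toroid (gland minus lumen). Ratios with zero denominators return
#' 0 and are recorded in the `validity` attribute.
#'
#' @param masks a `candidate_masks` object (bounding-box coordinates).
#' @param maps a `tissue_maps` object cropped to the same bounding box
#'   (see [crop_maps()]).
#' @return named numeric vector of 20 features with attribute `validity`.
#' @export
contextual_features <- function(masks, maps) {
  g <- .as_mask(masks$gland_mask)
  l <- .as_mask(masks$lumen_mask)
  if (!any(g)) stop("empty gland mask")
  stopifnot(identical(dim(g), dim(maps$nuclei)))
  bbox_area <- length(g)
  garea <- sum(g)
  invalid <- character(0)
  ratio0 <- function(num, den, what) {
    if (den > 0) {
      num / den
    } else {
      invalid <<- c(invalid, what)
      0
    }
  }

  # nuclei elements: 8-connected components of the nuclei map in the bbox
  lab <- label_components(maps$nuclei, 8)
  n_elem <- max(lab)
  if (n_elem > 0) {
    sizes <- tabulate(lab[lab > 0], n_elem)
    # an element is inside the gland iff all its pixels are
    in_gland <- tabulate(lab[lab > 0 & g], n_elem) == sizes
    nuc_bb_num <- n_elem
    nuc_g_num <- sum(in_gland)
    nuc_bb_pix <- sum(sizes)
    nuc_g_pix <- sum(sizes[in_gland])
  } else {
    nuc_bb_num <- nuc_g_num <- nuc_bb_pix <- nuc_g_pix <- 0
  }

  cyto_bb_pix <- sum(maps$cytoplasm)
  cyto_g_pix <- sum(maps$cytoplasm & g)

  # lumen centroid-to-edge distances (largest lumen component)
  if (any(l)) {
    edge <- .contour_walk(l)
    lc <- largest_component(l, 8)
    ctr <- colMeans(which(lc, arr.ind = TRUE))
    dists <- sqrt((edge[, 1] - ctr[1])^2 + (edge[, 2] - ctr[2])^2)
    mu_edge <- mean(dists)
    sd_edge <- if (length(dists) > 1) sd(dists) else 0
  } else {
    invalid <- c(invalid, "lumen_edge")
    mu_edge <- sd_edge <- 0
  }

  toroid <- g & !l
  tor_cn <- sum(toroid & (maps$cytoplasm | maps$nuclei))

  out <- c(
    ctx.nuclei.bbox.count = nuc_bb_num,
    ctx.nuclei.bbox.count_ratio = nuc_bb_num / bbox_area,
    ctx.nuclei.gland.count = nuc_g_num,
    ctx.nuclei.gland.count_ratio = ratio0(nuc_g_num, garea, "nuc_count_gland"),
    ctx.nuclei.gland_bbox.count_ratio =
      ratio0(nuc_g_num, nuc_bb_num, "nuc_count_gb"),
    ctx.nuclei.bbox.pix = nuc_bb_pix,
    ctx.nuclei.bbox.pix_ratio = nuc_bb_pix / bbox_area,
    ctx.nuclei.gland.pix = nuc_g_pix,
    ctx.nuclei.gland.pix_ratio = ratio0(nuc_g_pix, garea, "nuc_pix_gland"),
    ctx.nuclei.gland_bbox.pix_ratio =
      ratio0(nuc_g_pix, nuc_bb_pix, "nuc_pix_gb"),
    ctx.cyto.bbox.pix = cyto_bb_pix,
    ctx.cyto.bbox.pix_ratio = cyto_bb_pix / bbox_area,
    ctx.cyto.gland.pix = cyto_g_pix,
    ctx.cyto.gland.pix_ratio = ratio0(cyto_g_pix, garea, "cyto_pix_gland"),
    ctx.cyto.gland_bbox.pix_ratio =
      ratio0(cyto_g_pix, cyto_bb_pix, "cyto_pix_gb"),
    ctx.lumen.gland.area_ratio = ratio0(sum(l), garea, "lumen_gland"),
    ctx.lumen.edge_dist.mean = mu_edge,
    ctx.lumen.edge_dist.sd = sd_edge,
    ctx.toroid.cytonuclei.pix = tor_cn,
    ctx.toroid.cytonuclei.pix_ratio = ratio0(tor_cn, sum(toroid), "toroid"))
  attr(out, "validity") <- invalid
  out
}
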