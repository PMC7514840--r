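# Tissue-component mapping: colour transforms, per-channel k-means pixel
# clustering, binarisation and morphological clean-up, producing binary maps
# of the four H&E components (lumen, cytoplasm, stroma, nuclei).

#' Tissue component maps container
#' @param lumen,cytoplasm,stroma,nuclei logical matrices of equal shape.
#' @return object of class `tissue_maps`.
#' @export
tissue_component_maps_new <- function(lumen, cytoplasm, stroma, nuclei) {
  maps <- list(lumen = .as_mask(lumen), cytoplasm = .as_mask(cytoplasm),
               stroma = .as_mask(stroma), nuclei = .as_mask(nuclei))
  d <- dim(maps$lumen)
  stopifnot(all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
  structure(maps, class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat(sprintf("<tissue_maps %dx%d | lumen %d, cytoplasm %d, stroma %d, nuclei %d px>\n",
              nrow(x$lumen), ncol(x$lumen), sum(x$lumen), sum(x$cytoplasm),
              sum(x$stroma), sum(x$nuclei)))
  invisible(x)
}

#' Tile an image into non-overlapping patches
#'
#' Splits an RGB image into square patches in row-major order, dropping
#' partial border tiles and tiles whose tissue fraction falls below
#' `min_tissue_fraction`. A pixel counts as tissue when `min(R,G,B)` is
#' below `background_level` (near-white pixels are background).
#'
#' @param image HxWx3 array, 0-255.
#' @param patch_size tile side in pixels (default 1024).
#' @param min_tissue_fraction minimum tissue proportion to keep a tile.
#' @param background_level intensity above which a pixel is background.
#' @return list of patches, each a list with `rgb` and `origin` (row, col
#'   offset of the tile's top-left pixel, 0-based).
#' @export
patch_image <- function(image, patch_size = 1024, min_tissue_fraction = 0.05,
                        background_level = 220) {
  stopifnot(patch_size >= 1, min_tissue_fraction >= 0, min_tissue_fraction <= 1)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < patch_size || W < patch_size) {
    warning("image smaller than one patch; returning no patches")
    return(list())
  }
  out <- list()
  for (i in seq_len(H %/% patch_size)) {
    for (j in seq_len(W %/% patch_size)) {
      r0 <- (i - 1) * patch_size
      c0 <- (j - 1) * patch_size
      tile <- image[r0 + seq_len(patch_size), c0 + seq_len(patch_size), ,
                    drop = FALSE]
      tissue <- pmin(tile[, , 1], tile[, , 2], tile[, , 3]) < background_level
      if (mean(tissue) >= min_tissue_fraction) {
        out[[length(out) + 1]] <- list(rgb = tile, origin = c(r0, c0))
      }
    }
  }
  out
}

# Ruifrok-Johnston H&E optical-density stain vectors (columns normalised);
# the third column is the normalised residual (cross product).
.stain_matrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  cbind(hematoxylin = h, eosin = e, residual = r)
}

.resize_bilinear <- function(m, new_r, new_c) {
  out <- EBImage::resize(EBImage::Image(m), w = new_r, h = new_c,
                         filter = "bilinear")
  matrix(EBImage::imageData(out), new_r, new_c)
}

.resize_nearest_mask <- function(mask, new_r, new_c) {
  ri <- pmin(nrow(mask), pmax(1L, ceiling(seq_len(new_r) * nrow(mask) / new_r)))
  ci <- pmin(ncol(mask), pmax(1L, ceiling(seq_len(new_c) * ncol(mask) / new_c)))
  mask[ri, ci, drop = FALSE]
}

#' Colour channels used for tissue mapping and feature extraction
#'
#' Computes the saturation channel (HSV), the cyan channel (CMYK with black
#' key correction), the colour grid used for nuclei clustering, and the
#' hematoxylin/eosin stain channels obtained by optical-density colour
#' deconvolution with the standard H&E stain matrix
#' (`OD = -log10((I + 1)/255)`; stain concentrations are mapped to bounded
#' pseudo-intensity channels `1 - 10^(-C)` so all channels live in \[0, 1\]).
#'
#' @param rgb HxWx3 array, 0-255.
#' @param downscale scale factor in (0, 1]; applied by bilinear resampling
#'   before any colour conversion when below 1.
#' @return list with `s_hsv`, `c_cmyk`, `v_rgb` (HxWx3 in \[0,1\]),
#'   `hematoxylin`, `eosin`; all share one shape.
#' @export
compute_channels <- function(rgb, downscale = 1) {
  stopifnot(length(dim(rgb)) == 3, downscale > 0, downscale <= 1)
  if (downscale < 1) {
    nr <- max(1L, round(dim(rgb)[1] * downscale))
    nc <- max(1L, round(dim(rgb)[2] * downscale))
    rgb <- array(c(.resize_bilinear(rgb[, , 1], nr, nc),
                   .resize_bilinear(rgb[, , 2], nr, nc),
                   .resize_bilinear(rgb[, , 3], nr, nc)), c(nr, nc, 3))
  }
  d12 <- dim(rgb)[1:2]
  r <- matrix(rgb[, , 1], d12[1], d12[2]) / 255
  g <- matrix(rgb[, , 2], d12[1], d12[2]) / 255
  b <- matrix(rgb[, , 3], d12[1], d12[2]) / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(mx > 0, 1 - mn / mx, 0)
  k <- 1 - mx
  cyan <- ifelse(k < 1, (1 - r - k) / (1 - k), 0)
  od1 <- -log10((r * 255 + 1) / 255)
  od2 <- -log10((g * 255 + 1) / 255)
  od3 <- -log10((b * 255 + 1) / 255)
  minv <- solve(.stain_matrix())
  conc_h <- minv[1, 1] * od1 + minv[1, 2] * od2 + minv[1, 3] * od3
  conc_e <- minv[2, 1] * od1 + minv[2, 2] * od2 + minv[2, 3] * od3
  list(s_hsv = s, c_cmyk = cyan, v_rgb = rgb / 255,
       hematoxylin = 1 - 10^(-pmax(conc_h, 0)),
       eosin = 1 - 10^(-pmax(conc_e, 0)))
}

#' Cluster a channel's pixels by intensity
#'
#' k-means over pixel intensities (scalar channel) or pixel colours (HxWx3
#' grid). Labels are renumbered in ascending order of centroid mean
#' intensity, so label 1 is always the darkest cluster regardless of the
#' k-means initialisation.
#'
#' @param channel matrix, or HxWx3 array for colour clustering.
#' @param k number of clusters (>= 2).
#' @param seed integer seed; clustering uses `nstart` seeded restarts with
#'   initial centres drawn from distinct observed values.
#' @param nstart number of restarts.
#' @param channel_name used in error messages.
#' @return list with `labels` (integer matrix, 1..k) and `centroids`
#'   (k x d matrix ordered by mean intensity).
#' @export
cluster_channel <- function(channel, k = 3, seed = 1, nstart = 10,
                            channel_name = "channel") {
  stopifnot(k >= 2)
  if (length(dim(channel)) == 3) {
    d <- dim(channel)
    x <- cbind(as.vector(channel[, , 1]), as.vector(channel[, , 2]),
               as.vector(channel[, , 3]))
    shape <- d[1:2]
  } else {
    x <- matrix(as.vector(channel), ncol = 1)
    shape <- dim(channel)
  }
  ux <- unique(x)
  if (nrow(ux) < k) {
    stop("channel '", channel_name, "' has fewer than k = ", k,
         " distinct values")
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- ux[sample(nrow(ux), k), , drop = FALSE]
    km <- tryCatch(kmeans(x, centers = init, iter.max = 100),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on channel '", channel_name, "'")
  ord <- order(rowMeans(best$centers))
  relab <- match(seq_len(k), ord)
  labels <- matrix(relab[best$cluster], shape[1], shape[2])
  list(labels = labels, centroids = best$centers[ord, , drop = FALSE])
}

#' Binarise a labelled image
#'
#' Selects one cluster of a labelled image. Under the ascending-intensity
#' relabelling of [cluster_channel()], `min_label` selects the darkest
#' cluster and `max_label` the brightest.
#'
#' @param labelled integer label matrix (1..k).
#' @param rule one of "min_label", "max_label", "label_index".
#' @param index cluster index when `rule = "label_index"`.
#' @return logical matrix.
#' @export
binarize_component <- function(labelled, rule = c("min_label", "max_label",
                                                  "label_index"),
                               index = NULL) {
  rule <- match.arg(rule)
  kmax <- max(labelled)
  if (rule == "min_label") return(labelled == 1L)
  if (rule == "max_label") return(labelled == kmax)
  if (is.null(index) || index < 1 || index > kmax) {
    stop("label_index must lie in 1..", kmax)
  }
  labelled == as.integer(index)
}

#' Morphological post-processing of a component map
#'
#' Component-specific clean-up: lumen maps get an area opening
#' (`lambda = 20`) then a disk dilation (r = 1); cytoplasm and stroma maps a
#' disk opening then an area opening; nuclei maps a disk dilation (to
#' emphasise the epithelial ring) then an area opening that removes nuclei
#' scattered in the stroma. Connected components use 8-connectivity.
#'
#' @param map logical matrix.
#' @param component one of lumen/cytoplasm/stroma/nuclei.
#' @param lambda minimum component area (default 20 for every component).
#' @return logical matrix.
#' @export
postprocess_map <- function(map, component = c("lumen", "cytoplasm",
                                               "stroma", "nuclei"),
                            lambda = 20) {
  component <- match.arg(component)
  map <- .as_mask(map)
  switch(component,
         lumen = dilate_disk(area_opening(map, lambda), 1),
         cytoplasm = area_opening(open_disk(map, 1), lambda),
         stroma = area_opening(open_disk(map, 1), lambda),
         nuclei = area_opening(dilate_disk(map, 1), lambda))
}

#' Tissue component maps of a patch
#'
#' The full mapping pipeline: channels are computed at `downscale`
#' resolution; the lumen map is the darkest of k = 3 saturation clusters;
#' cytoplasm and stroma are the highest- and middle-cyan of k = 3 cyan
#' clusters; nuclei are the darkest of k = 4 colour clusters. Each map is
#' binarised at the clustering resolution, restored to full resolution by
#' nearest-neighbour upsampling, and then post-processed, so the area
#' threshold `lambda` is expressed in full-resolution pixels — the same
#' units as the candidate-mask area opening used downstream.
#'
#' @param rgb HxWx3 array, 0-255.
#' @param seed integer seed for the clustering restarts.
#' @param downscale resolution factor for clustering (default 0.5).
#' @param lambda area-opening threshold passed to [postprocess_map()].
#' @return a [tissue_component_maps_new()] object at full resolution, with
#'   attribute `centroids` recording the cluster centres.
#' @export
tissue_component_maps <- function(rgb, seed = 1, downscale = 0.5, lambda = 20) {
  ch <- compute_channels(rgb, downscale = downscale)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]

  up <- function(mask) .resize_nearest_mask(mask, H, W)

  cl_s <- cluster_channel(ch$s_hsv, k = 3, seed = seed + 1L,
                          channel_name = "s_hsv")
  lumen <- postprocess_map(up(binarize_component(cl_s$labels, "min_label")),
                           "lumen", lambda)

  cl_c <- cluster_channel(ch$c_cmyk, k = 3, seed = seed + 2L,
                          channel_name = "c_cmyk")
  cyto <- postprocess_map(up(binarize_component(cl_c$labels, "max_label")),
                          "cytoplasm", lambda)
  stroma <- postprocess_map(up(binarize_component(cl_c$labels, "label_index",
                                                  index = 2)),
                            "stroma", lambda)

  cl_v <- cluster_channel(ch$v_rgb, k = 4, seed = seed + 3L,
                          channel_name = "v_rgb")
  nuclei <- postprocess_map(up(binarize_component(cl_v$labels, "min_label")),
                            "nuclei", lambda)

  maps <- tissue_component_maps_new(lumen = lumen, cytoplasm = cyto,
                                    stroma = stroma, nuclei = nuclei)
  attr(maps, "centroids") <- list(s_hsv = cl_s$centroids,
                                  c_cmyk = cl_c$centroids,
                                  v_rgb = cl_v$centroids)
  maps
}

#' Crop tissue maps to a bounding box
#' @param maps a `tissue_maps` object.
#' @param bbox `c(row0, col0, row1, col1)`, 1-based inclusive.
#' @return cropped `tissue_maps`.
#' @export
crop_maps <- function(maps, bbox) {
  tissue_component_maps_new(
    lumen = maps$lumen[bbox[1]:bbox[3], bbox[2]:bbox[4]],
    cytoplasm = maps$cytoplasm[bbox[1]:bbox[3], bbox[2]:bbox[4]],
    stroma = maps$stroma[bbox[1]:bbox[3], bbox[2]:bbox[4]],
    nuclei = maps$nuclei[bbox[1]:bbox[3], bbox[2]:bbox[4]])
}
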