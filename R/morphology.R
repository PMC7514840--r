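# Candidate mask extraction and morphological descriptors of gland and
# lumen regions.

#' Extract gland and lumen masks of a candidate
#'
#' The gland mask is obtained from the masked RGB crop: the three colour
#' components are summed, thresholded with Otsu's method, area-opened
#' (4-connectivity, `lambda = 20`), hole-filled, and the largest connected
#' component is kept. The lumen mask is the part of the supplied lumen map
#' whose connected components lie (by majority of their pixels) inside the
#' gland mask.
#'
#' @param candidate a [gland_candidate()].
#' @param lumen_map logical matrix in bounding-box coordinates (e.g. the
#'   lumen component map cropped to the candidate's bbox).
#' @param lambda area-opening threshold in pixels.
#' @return list of class `candidate_masks` with `gland_mask`, `lumen_mask`;
#'   errors if the gland mask is empty after filtering.
#' @export
extract_masks <- function(candidate, lumen_map, lambda = 20) {
  m <- candidate$masked_rgb
  s <- m[, , 1] + m[, , 2] + m[, , 3]
  thr <- otsu_threshold(s)
  mask <- s > thr
  mask <- area_opening(mask, lambda, connectivity = 4)
  if (!any(mask)) stop("empty gland mask after filtering")
  mask <- fill_holes(mask)
  mask <- largest_component(mask, connectivity = 4)
  lum <- .as_mask(lumen_map)
  stopifnot(identical(dim(lum), dim(mask)))
  lab <- label_components(lum, connectivity = 8)
  keep <- integer(0)
  if (max(lab) > 0) {
    for (i in seq_len(max(lab))) {
      inside <- mean(mask[lab == i])
      if (inside > 0.5) keep <- c(keep, i)
    }
  }
  lmask <- matrix(lab %in% keep, nrow(lum), ncol(lum)) & mask
  structure(list(gland_mask = mask, lumen_mask = lmask),
            class = "candidate_masks")
}

#' Otsu threshold of a numeric image
#'
#' Exhaustive maximisation of between-class variance over a 256-bin
#' histogram of the observed value range.
#'
#' @param x numeric matrix.
#' @return threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(rng[1])
  }
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(v, br, rightmost.closed = TRUE)), nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1L]
}

# pixel count inside/on the convex hull of the TRUE pixel centres
.convex_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) <= 2) {
    return(nrow(pts))
  }
  h <- chull(pts[, 2], pts[, 1])          # (x = col, y = row)
  hx <- pts[h, 2]; hy <- pts[h, 1]
  nh <- length(h)
  # orient the hull anticlockwise in (x, y) so the half-plane test below
  # keeps the interior on the non-negative side
  signed2 <- sum(hx * hy[c(2:nh, 1)] - hx[c(2:nh, 1)] * hy)
  if (signed2 < 0) {
    hx <- rev(hx); hy <- rev(hy)
  }
  bb <- .tight_bbox(mask)
  grid <- expand.grid(row = bb[1]:bb[3], col = bb[2]:bb[4])
  inside <- rep(TRUE, nrow(grid))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    crossp <- (hx[j] - hx[i]) * (grid$row - hy[i]) -
      (hy[j] - hy[i]) * (grid$col - hx[i])
    inside <- inside & (crossp >= -1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

# perimeter as the length of the ordered 8-connected boundary walk
.perimeter <- function(mask) {
  w <- .contour_walk(mask)
  if (nrow(w) < 2) {
    return(if (nrow(w) == 1) 1 else 0)
  }
  d <- sqrt(rowSums((w - w[c(2:nrow(w), 1), ])^2))
  sum(d)
}

#' Morphological descriptors of a binary region
#'
#' The ten shape/geometry descriptors computed for the gland and lumen
#' masks: area, convex area, eccentricity and orientation of the
#' second-moment equivalent ellipse, equivalent diameter, extent, perimeter
#' (boundary walk length), solidity, roundness
#' (`equivDiam/2 * perimeter / area`) and the perimeter/area ratio.
#' Multi-component masks use their largest component (with a warning).
#'
#' @param mask logical matrix, non-empty.
#' @return named numeric vector of 10 descriptors.
#' @export
region_morphology <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask, 8)
  if (max(lab) > 1) {
    warning("mask has multiple components; using the largest")
    mask <- largest_component(mask, 8)
  }
  area <- sum(mask)
  pts <- which(mask, arr.ind = TRUE)
  bb <- .tight_bbox(mask)
  bbox_area <- (bb[3] - bb[1] + 1) * (bb[4] - bb[2] + 1)
  # central second moments with the 1/12 pixel-extent correction;
  # x = col, y = -row so orientation is measured anticlockwise from x-axis
  xc <- pts[, 2] - mean(pts[, 2])
  yc <- -(pts[, 1] - mean(pts[, 1]))
  mu20 <- mean(xc^2) + 1 / 12
  mu02 <- mean(yc^2) + 1 / 12
  mu11 <- mean(xc * yc)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
  orient <- if (mu20 == mu02 && mu11 == 0) 0 else
    atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi
  perim <- .perimeter(mask)
  equiv <- sqrt(4 * area / pi)
  conv <- .convex_area(mask)
  c(area = area,
    convexArea = conv,
    eccent = ecc,
    equivDiam = equiv,
    extent = area / bbox_area,
    orientation = orient,
    perimeter = perim,
    solidity = area / conv,
    roundness = (equiv / 2) * perim / area,
    compactness = perim / area)
}

#' Gland and lumen morphology of one candidate
#'
#' [region_morphology()] applied to the gland mask and to the lumen mask;
#' an empty lumen mask yields zero lumen features and sets the
#' `lumen_valid` attribute to FALSE.
#'
#' @param masks a `candidate_masks` object from [extract_masks()].
#' @return named numeric vector of 20 features (`morph.gland.*`,
#'   `morph.lumen.*`).
#' @export
morphological_features <- function(masks) {
  g <- region_morphology(masks$gland_mask)
  if (any(masks$lumen_mask)) {
    l <- suppressWarnings(region_morphology(masks$lumen_mask))
    valid <- TRUE
  } else {
    l <- setNames(rep(0, length(g)), names(g))
    valid <- FALSE
  }
  out <- c(setNames(as.numeric(g), paste0("morph.gland.", names(g))),
           setNames(as.numeric(l), paste0("morph.lumen.", names(g))))
  attr(out, "lumen_valid") <- valid
  out
}
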