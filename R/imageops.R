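#' @importFrom stats fft mvfft lm.fit kmeans rnorm runif sd cor ks.test
#'   kruskal.test pt lm anova aggregate quantile plogis predict coef dnorm
#'   pnorm binomial glm setNames var
#' @importFrom utils head read.csv write.csv
#' @importFrom grDevices rgb2hsv chull
NULL

# Binary masks are logical matrices (rows = image rows). EBImage stores images
# with dim1 = x, so matrices pass through transposed; all operations used here
# are orientation-symmetric, so no transposition is needed.

.as_mask <- function(m) {
  if (is.logical(m)) m else m > 0.5
}

.eb <- function(mask) EBImage::Image(mask * 1)

#' Disk-shaped structuring element
#'
#' Pixels at Euclidean distance at most `r` from the centre of a
#' `(2r+1) x (2r+1)` kernel. `disk_kernel(1)` is the 5-pixel plus shape.
#'
#' @param r integer radius in pixels.
#' @return 0/1 matrix usable as an EBImage kernel.
#' @keywords internal
disk_kernel <- function(r) {
  d <- 2L * r + 1L
  cc <- r + 1L
  idx <- expand.grid(i = seq_len(d), j = seq_len(d))
  k <- matrix(0, d, d)
  k[as.matrix(idx[, c("i", "j")])] <-
    as.numeric((idx$i - cc)^2 + (idx$j - cc)^2 <= r^2)
  k
}

#' Binary dilation by a disk
#' @param mask logical matrix.
#' @param r disk radius (default 1).
#' @return logical matrix containing `mask`.
#' @export
dilate_disk <- function(mask, r = 1) {
  mask <- .as_mask(mask)
  out <- EBImage::dilate(.eb(mask), disk_kernel(r))
  matrix(EBImage::imageData(out) > 0.5, nrow(mask), ncol(mask))
}

#' Binary erosion by a disk
#' @inheritParams dilate_disk
#' @return logical matrix contained in `mask`.
#' @export
erode_disk <- function(mask, r = 1) {
  mask <- .as_mask(mask)
  out <- EBImage::erode(.eb(mask), disk_kernel(r))
  matrix(EBImage::imageData(out) > 0.5, nrow(mask), ncol(mask))
}

#' Morphological opening (erosion then dilation) by a disk
#' @inheritParams dilate_disk
#' @export
open_disk <- function(mask, r = 1) {
  dilate_disk(erode_disk(mask, r), r)
}

#' Label connected components
#'
#' 4- or 8-connected component labelling. EBImage's `bwlabel` provides the
#' 4-connected pass; for 8-connectivity, labels that touch diagonally are
#' merged with a union-find.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- .as_mask(mask)
  lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(.eb(mask)))),
                nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (connectivity == 4 || nmax <= 1L) {
    return(lab)
  }
  stopifnot(connectivity == 8)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal label adjacencies between distinct 4-components
  a <- lab[-nr, -nc]; b <- lab[-1, -1]          # (i,j) vs (i+1,j+1)
  c1 <- lab[-nr, -1]; d1 <- lab[-1, -nc]        # (i,j+1) vs (i+1,j)
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c1), as.vector(d1)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nmax)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Area opening
#'
#' Keeps the union of connected components whose pixel area is at least
#' `lambda`; smaller components are removed.
#'
#' @param mask logical matrix.
#' @param lambda minimum component area in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix, a subset of `mask`.
#' @export
area_opening <- function(mask, lambda = 20, connectivity = 8) {
  mask <- .as_mask(mask)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    return(mask & FALSE)
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= lambda)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Fill interior holes of a binary mask
#' @param mask logical matrix.
#' @return logical matrix with all enclosed background regions set TRUE.
#' @export
fill_holes <- function(mask) {
  mask <- .as_mask(mask)
  out <- EBImage::fillHull(.eb(mask))
  matrix(EBImage::imageData(out) > 0.5, nrow(mask), ncol(mask))
}

#' Keep the largest connected component
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix with only the largest component (empty stays empty).
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    return(.as_mask(mask) & FALSE)
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Ordered boundary walk of the largest object, 1-based (row, col) matrix.
.contour_walk <- function(mask) {
  mask <- largest_component(.as_mask(mask))
  oc <- EBImage::ocontour(.eb(mask))
  if (length(oc) == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  oc[[1]] + 1
}
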