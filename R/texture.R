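# Texture descriptors: symmetric normalised gray-level co-occurrence
# matrices with Haralick-style statistics, and rotation-invariant uniform
# local binary patterns with the local-variance (LBPV) histogram.

#' Gray-level co-occurrence matrix
#'
#' Intensities in \[0, 1\] are uniformly quantised to `levels` gray levels;
#' co-occurring pairs at the pixel offset `(drow, dcol)` are counted,
#' symmetrised by adding the transpose, and normalised to sum 1.
#'
#' @param channel numeric matrix with values in \[0, 1\].
#' @param offset integer `c(drow, dcol)`; the defaults used downstream are
#'   `c(0, 2)` (0 degrees, distance 2) and `c(-2, 2)` (45 degrees).
#' @param levels number of gray levels (default 8).
#' @return `levels x levels` normalised symmetric matrix.
#' @export
glcm <- function(channel, offset = c(0, 2), levels = 8) {
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  H <- nrow(channel); W <- ncol(channel)
  if (H <= abs(dr) || W <= abs(dc)) {
    stop("crop (", H, "x", W, ") is smaller than the offset span")
  }
  q <- floor(channel * levels) + 1L
  q[q > levels] <- levels
  q[q < 1L] <- 1L
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  a <- q[r1, c1]
  b <- q[r1 + dr, c1 + dc]
  counts <- matrix(tabulate((a - 1L) * levels + b, levels * levels),
                   levels, levels, byrow = TRUE)
  s <- counts + t(counts)
  s / sum(s)
}

#' GLCM statistics
#'
#' Twenty-one statistics of one normalised GLCM: homogeneity, contrast,
#' energy (angular second moment), correlation, entropy (natural log,
#' `0 log 0 = 0`), plus the per-column mean and standard deviation of the
#' matrix entries (8 + 8 values for an 8x8 matrix). Correlation is 0 when a
#' marginal standard deviation vanishes.
#'
#' @param n normalised symmetric GLCM (entries sum to 1).
#' @return named numeric vector of `5 + 2*ncol(n)` statistics.
#' @export
glcm_features <- function(n) {
  if (abs(sum(n) - 1) > 1e-8) stop("GLCM is not normalised")
  k <- nrow(n)
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  homo <- sum(n / (1 + abs(i - j)))
  contr <- sum((i - j)^2 * n)
  ener <- sum(n^2)
  pos <- n > 0
  entr <- -sum(n[pos] * log(n[pos]))
  pi_ <- rowSums(n); pj_ <- colSums(n)
  mu_i <- sum(seq_len(k) * pi_); mu_j <- sum(seq_len(k) * pj_)
  sd_i <- sqrt(sum((seq_len(k) - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((seq_len(k) - mu_j)^2 * pj_))
  corr <- if (sd_i * sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * n) / (sd_i * sd_j)
  } else {
    0
  }
  mu_col <- colMeans(n)
  sd_col <- apply(n, 2, sd)
  c(homogeneity = homo, contrast = contr, energy = ener,
    correlation = corr, entropy = entr,
    setNames(mu_col, paste0("mu", seq_len(k))),
    setNames(sd_col, paste0("sigma", seq_len(k))))
}

# circular neighbour samples of the interior pixels: list with gc (centre
# values) and an (npix x P) matrix of neighbour values, bilinear for
# off-grid positions
.circular_neighbours <- function(m, P = 8, R = 1) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(H >= 2 * R + 1, W >= 2 * R + 1)
  ri <- (1 + R):(H - R); ci <- (1 + R):(W - R)
  gc <- m[ri, ci]
  neigh <- vector("list", P)
  for (p in 0:(P - 1)) {
    ang <- 2 * pi * p / P
    dr <- R * sin(ang); dc <- R * cos(ang)
    dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
    dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
    if (dr == round(dr) && dc == round(dc)) {
      v <- m[ri + dr, ci + dc]
    } else {
      f_r <- floor(dr); f_c <- floor(dc)
      wr <- dr - f_r; wc <- dc - f_c
      v <- (1 - wr) * (1 - wc) * m[ri + f_r, ci + f_c] +
        (1 - wr) * wc * m[ri + f_r, ci + f_c + 1] +
        wr * (1 - wc) * m[ri + f_r + 1, ci + f_c] +
        wr * wc * m[ri + f_r + 1, ci + f_c + 1]
    }
    neigh[[p + 1]] <- v
  }
  list(gc = gc, neigh = neigh, dim = c(length(ri), length(ci)))
}

#' Rotation-invariant uniform LBP labels
#'
#' The LBP riu2 operator with `P` circular neighbours at radius `R`
#' (bilinear interpolation off-grid, sign convention `s(0) = 1`): uniform
#' patterns (at most two 0/1 transitions) map to their number of set bits
#' (0..P), non-uniform patterns to `P + 1`. Border pixels (within `R` of
#' the edge) are excluded.
#'
#' @param channel numeric matrix.
#' @param P neighbours (default 8).
#' @param R radius (default 1).
#' @return integer matrix of labels in `0..(P+1)` over the interior pixels.
#' @export
lbp_riu2 <- function(channel, P = 8, R = 1) {
  cn <- .circular_neighbours(channel, P, R)
  # tolerance absorbs bilinear floating-point error so equal-valued
  # neighbourhoods honour the s(0) = 1 convention
  s <- lapply(cn$neigh, function(v) (v - cn$gc >= -1e-12) * 1L)
  u <- abs(s[[P]] - s[[1]])
  bits <- s[[1]]
  for (p in 2:P) {
    u <- u + abs(s[[p]] - s[[p - 1]])
    bits <- bits + s[[p]]
  }
  lab <- ifelse(u <= 2, bits, P + 1L)
  matrix(as.integer(lab), cn$dim[1], cn$dim[2])
}

#' Local circular-neighbourhood variance (VAR)
#'
#' Per-pixel population variance of the `P` circular neighbour samples;
#' the contrast-sensitive complement of the LBP riu2 operator.
#'
#' @inheritParams lbp_riu2
#' @return numeric matrix over the interior pixels (non-negative).
#' @export
var_map <- function(channel, P = 8, R = 1) {
  cn <- .circular_neighbours(channel, P, R)
  mu <- Reduce(`+`, cn$neigh) / P
  v <- Reduce(`+`, lapply(cn$neigh, function(g) (g - mu)^2)) / P
  matrix(pmax(v, 0), cn$dim[1], cn$dim[2])
}

#' LBP-variance (LBPV) histogram
#'
#' Accumulates the local variance into the bin of each pixel's LBP riu2
#' label: bin `k` is the sum of `var` over pixels labelled `k`.
#'
#' @param labels integer label matrix from [lbp_riu2()].
#' @param var numeric matrix from [var_map()], same shape.
#' @param n_bins number of bins (default `P + 2 = 10`).
#' @return numeric vector of `n_bins` accumulated variances (labels 0..9).
#' @export
lbpv_histogram <- function(labels, var, n_bins = 10) {
  if (!identical(dim(labels), dim(var))) {
    stop("labels and var must have the same shape")
  }
  out <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    out[k] <- sum(var[labels == (k - 1L)])
  }
  out
}

#' Textural features of a candidate
#'
#' The 186-entry textural block: for each of the cyan, hematoxylin and
#' eosin channels, GLCM statistics at offsets `(0,2)` and `(-2,2)`
#' (21 x 2 x 3 = 126), plus the 10-bin LBP riu2 label histogram and the
#' 10-bin LBPV histogram (20 x 3 = 60), both L1-normalised by the interior
#' pixel count so candidates of different sizes are comparable.
#'
#' @param channels named list with `cyan`, `hematoxylin`, `eosin` matrices.
#' @return named numeric vector of 186 features.
#' @export
texture_features <- function(channels) {
  offsets <- list(d0 = c(0L, 2L), d45 = c(-2L, 2L))
  out <- numeric(0)
  for (ch in c("cyan", "hematoxylin", "eosin")) {
    m <- channels[[ch]]
    for (off in names(offsets)) {
      g <- glcm_features(glcm(m, offsets[[off]]))
      names(g) <- paste0("glcm.", ch, ".", off, ".", names(g))
      out <- c(out, g)
    }
  }
  for (ch in c("cyan", "hematoxylin", "eosin")) {
    m <- channels[[ch]]
    lab <- lbp_riu2(m)
    v <- var_map(m)
    npix <- length(lab)
    hist_lbp <- tabulate(as.vector(lab) + 1L, 10L) / npix
    hist_lbpv <- lbpv_histogram(lab, v) / npix
    out <- c(out,
             setNames(hist_lbp, paste0("lbp.", ch, ".riu2.b", 1:10)),
             setNames(hist_lbpv, paste0("lbp.", ch, ".var.b", 1:10)))
  }
  out
}
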