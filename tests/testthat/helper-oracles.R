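# Independent brute-force oracles and small fixture builders used across
# the test files. These are deliberately naive per-pixel loops, kept
# separate from the package implementations they check.

# quantise [0,1] to 8 levels exactly as documented
oracle_quantise <- function(m, levels = 8) {
  q <- floor(m * levels) + 1L
  q[q > levels] <- levels
  q[q < 1L] <- 1L
  q
}

# raw (unsymmetrised) GLCM pair counts by explicit double loop
oracle_glcm_counts <- function(m, offset, levels = 8) {
  q <- oracle_quantise(m, levels)
  out <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + offset[1]; j2 <- j + offset[2]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        out[q[i, j], q[i2, j2]] <- out[q[i, j], q[i2, j2]] + 1
      }
    }
  }
  out
}

# per-pixel LBP riu2 labels and VAR by explicit loops (P = 8, R = 1)
oracle_lbp_var <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(NA_integer_, H - 2, W - 2)
  va <- matrix(NA_real_, H - 2, W - 2)
  bil <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    wr <- r - r0; wc <- c - c0
    (1 - wr) * (1 - wc) * m[r0, c0] + (1 - wr) * wc * m[r0, c0 + 1] +
      wr * (1 - wc) * m[r0 + 1, c0] + wr * wc * m[r0 + 1, c0 + 1]
  }
  for (i in 2:(H - 1)) {
    for (j in 2:(W - 1)) {
      g <- numeric(8)
      for (p in 0:7) {
        ang <- 2 * pi * p / 8
        dr <- sin(ang); dc <- cos(ang)
        dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
        dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
        g[p + 1] <- if (dr == round(dr) && dc == round(dc)) {
          m[i + dr, j + dc]
        } else {
          bil(i + dr, j + dc)
        }
      }
      s <- as.integer(g >= m[i, j])
      u <- abs(s[8] - s[1]) + sum(abs(diff(s)))
      lab[i - 1, j - 1] <- if (u <= 2) sum(s) else 9L
      va[i - 1, j - 1] <- mean((g - mean(g))^2)
    }
  }
  list(lab = lab, var = va)
}

oracle_lbpv <- function(lab, va) {
  sapply(0:9, function(k) sum(va[lab == k]))
}

# rasterised ellipse mask (axis-aligned), semi-axes (a, b), for morphology
raster_ellipse <- function(n, a, b) {
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((col - ctr) / a)^2 + ((row - ctr) / b)^2 <= 1
}

# small phantom spec used by several tests (3 candidates fit a 320-px
# patch even when all draw the largest benign geometry)
tiny_spec <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(patch_size = 320, candidates_per_patch = 3,
         patches_per_patient = 2, n_patients = 5, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
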