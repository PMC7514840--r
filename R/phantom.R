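# Synthetic H&E gland phantoms.
#
# The generator emulates the appearance model that drives the descriptor
# families downstream: white/near-white lumen blobs, a cytoplasm ring, an
# epithelial nuclei ring (dense/multilayer for benign glands, sparse for
# Gleason grade 3, absent for artefacts), a stroma background, per-class
# lumen size and elongation differences, and a per-patient random effect on
# stain tint and geometry so patient-wise cross-validation is meaningful.

#' Phantom cohort specification
#'
#' Parameters of the synthetic H&E gland-phantom generator. Defaults encode
#' the intended class semantics: benign glands have large, fusiform lumens
#' and a dense (two-layer) epithelial nuclei ring; grade-3 glands have small,
#' near-circular lumens and a sparse nuclei ring; artefacts are bare
#' lumen-coloured blobs with neither cytoplasm nor nuclei.
#'
#' @param patch_size side of the square patch in pixels.
#' @param class_mix named proportions over artefact/benign/grade3 (sum 1).
#' @param lumen_radius_px named list of per-class `c(min, max)` equivalent
#'   lumen radii in pixels.
#' @param elongation named list of per-class `c(min, max)` major/minor axis
#'   ratios of the lumen ellipse.
#' @param cytoplasm_ring_px `c(min, max)` cytoplasm ring thickness in pixels.
#' @param nuclei_density named per-class fraction of the ring perimeter
#'   covered by nuclei; must satisfy artefact < grade3 < benign.
#' @param nuclei_radius_px `c(min, max)` radius of individual nuclei.
#' @param stain_palette named list of mean RGB (0-255) for
#'   lumen/cytoplasm/stroma/nuclei. The default stroma tint is a
#'   magenta-lavender (blue slightly above red) so that the CMYK cyan channel
#'   orders lumen < stroma < cytoplasm, which the tissue-map clustering
#'   assignment assumes.
#' @param noise_sd additive Gaussian intensity noise, 0-255 units.
#' @param n_patients number of patients in a cohort.
#' @param patches_per_patient,candidates_per_patch cohort layout.
#' @param patient_palette_sd,patient_geometry_sd standard deviations of the
#'   per-patient random offsets on stain RGB means and on the geometry scale
#'   multiplier.
#' @param seed integer root seed for cohort generation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(patch_size = 1024,
                         class_mix = c(artefact = 1/3, benign = 1/3, grade3 = 1/3),
                         lumen_radius_px = list(artefact = c(8, 18),
                                                benign = c(16, 26),
                                                grade3 = c(7, 12)),
                         elongation = list(artefact = c(1.0, 1.8),
                                           benign = c(1.6, 2.6),
                                           grade3 = c(1.0, 1.3)),
                         cytoplasm_ring_px = c(7, 12),
                         nuclei_density = c(artefact = 0, benign = 0.9, grade3 = 0.4),
                         nuclei_radius_px = c(2, 3),
                         stain_palette = list(lumen = c(250, 248, 250),
                                              cytoplasm = c(140, 160, 235),
                                              stroma = c(200, 150, 240),
                                              nuclei = c(60, 50, 120)),
                         noise_sd = 5,
                         n_patients = 15,
                         patches_per_patient = 4,
                         candidates_per_patch = 15,
                         patient_palette_sd = 4,
                         patient_geometry_sd = 0.06,
                         seed = 1L) {
  spec <- list(patch_size = as.integer(patch_size), class_mix = class_mix,
               lumen_radius_px = lumen_radius_px, elongation = elongation,
               cytoplasm_ring_px = cytoplasm_ring_px,
               nuclei_density = nuclei_density,
               nuclei_radius_px = nuclei_radius_px,
               stain_palette = stain_palette, noise_sd = noise_sd,
               n_patients = as.integer(n_patients),
               patches_per_patient = as.integer(patches_per_patient),
               candidates_per_patch = as.integer(candidates_per_patch),
               patient_palette_sd = patient_palette_sd,
               patient_geometry_sd = patient_geometry_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#' @param spec a `phantom_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cls <- c("artefact", "benign", "grade3")
  if (abs(sum(spec$class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1")
  }
  if (!all(cls %in% names(spec$class_mix))) {
    stop("class_mix must name artefact, benign and grade3")
  }
  for (cl in cls) {
    r <- spec$lumen_radius_px[[cl]]
    e <- spec$elongation[[cl]]
    if (r[2] < r[1] || r[1] <= 0) stop("degenerate lumen radius range for ", cl)
    if (e[2] < e[1] || e[1] < 1) stop("degenerate elongation range for ", cl)
    if (4 * r[2] >= spec$patch_size) {
      stop("lumen radius range for ", cl, " does not fit the patch")
    }
  }
  nd <- spec$nuclei_density
  if (!(nd["artefact"] < nd["grade3"] && nd["grade3"] < nd["benign"])) {
    stop("nuclei_density must increase from artefact to grade3 to benign")
  }
  if (spec$patch_size < 64) stop("patch_size must be at least 64")
  invisible(spec)
}

# deterministic 31-bit hash of a patient identifier string
.id_hash <- function(id) {
  v <- utf8ToInt(as.character(id))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# per-patient random effects, deterministic in (spec$seed, patient_id)
.patient_effects <- function(spec, patient_id) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((spec$seed + .id_hash(patient_id)) %% 2147483647)
  pal <- lapply(spec$stain_palette, function(rgb) {
    pmin(255, pmax(0, rgb + rnorm(3, 0, spec$patient_palette_sd)))
  })
  geom <- exp(rnorm(1, 0, spec$patient_geometry_sd))
  list(palette = pal, geometry = geom)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# elliptical normalised radius field with radial Fourier perturbation,
# evaluated on the pixel grid rows x cols for a gland centred at (cy, cx)
.rho_field <- function(rows, cols, cy, cx, a, b, phi, pert_amp, pert_phase) {
  nr <- length(rows); nc <- length(cols)
  row <- matrix(rows, nr, nc) - cy
  col <- matrix(cols, nr, nc, byrow = TRUE) - cx
  # rotate into the ellipse frame (phi from x-axis, y up = -row)
  xr <- col * cos(phi) - row * sin(phi)
  yr <- col * sin(phi) + row * cos(phi)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  theta <- atan2(yr / b, xr / a)
  mod <- 1
  for (k in seq_along(pert_amp)) {
    mod <- mod + pert_amp[k] * cos((k + 1) * theta + pert_phase[k])
  }
  rho / pmax(mod, 0.5)
}

#' Generate one phantom patch
#'
#' Deterministic for fixed `(spec, patient_id, seed)`. Gland geometry is a
#' radially perturbed ellipse; candidates are placed by rejection sampling
#' and generation fails with an error if a candidate cannot be placed within
#' a bounded number of attempts.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id character scalar; drives the per-patient random effect.
#' @param seed integer seed for this patch.
#' @param classes optional character vector of candidate classes (length
#'   `spec$candidates_per_patch`); by default drawn from `spec$class_mix`.
#' @return object of class `phantom_patch` with elements `rgb` (HxWx3 array,
#'   0-255), `truth_maps` (binary lumen/cytoplasm/stroma/nuclei maps),
#'   `candidates` (list of `gland_candidate`), `patient_id`, `seed`.
#' @export
generate_patch <- function(spec, patient_id, seed, classes = NULL) {
  validate_phantom_spec(spec)
  eff <- .patient_effects(spec, patient_id)
  set.seed(as.integer(seed) %% 2147483647)
  n <- spec$patch_size
  ncand <- spec$candidates_per_patch
  if (is.null(classes)) {
    classes <- sample(names(spec$class_mix), ncand, replace = TRUE,
                      prob = spec$class_mix)
  }
  stopifnot(length(classes) == ncand)

  lumen_map <- matrix(FALSE, n, n)
  cyto_map <- matrix(FALSE, n, n)
  nuc_map <- matrix(FALSE, n, n)
  base <- array(0, c(n, n, 3))
  for (ch in 1:3) base[, , ch] <- eff$palette$stroma[ch]

  # sample geometry for every candidate first, then place the largest first
  # so that dense patches pack reliably
  sample_geom <- function(cl) {
    r0 <- runif(1, spec$lumen_radius_px[[cl]][1],
                spec$lumen_radius_px[[cl]][2]) * eff$geometry
    el <- runif(1, spec$elongation[[cl]][1], spec$elongation[[cl]][2])
    a <- r0 * sqrt(el)
    ring <- if (cl == "artefact") 0 else
      runif(1, spec$cytoplasm_ring_px[1], spec$cytoplasm_ring_px[2])
    nuc_r <- round(runif(1, spec$nuclei_radius_px[1], spec$nuclei_radius_px[2]))
    dens <- spec$nuclei_density[[cl]]
    band <- if (dens > 0) 2 * nuc_r + 2 else 0
    list(cl = cl, r0 = r0, a = a, b = r0 / sqrt(el),
         phi = runif(1, 0, pi), pert_amp = runif(3, 0, 0.06),
         pert_phase = runif(3, 0, 2 * pi), ring = ring, nuc_r = nuc_r,
         dens = dens, band = band, r_out = a * 1.2 + ring + band + 4)
  }
  geom <- lapply(classes, sample_geom)
  place_order <- order(vapply(geom, `[[`, 0, "r_out"), decreasing = TRUE)

  placed <- list()   # centres and outer radii for overlap rejection
  cands <- vector("list", ncand)
  for (ci in place_order) {
    g <- geom[[ci]]
    ok <- FALSE
    for (redraw in 1:50) {
      if (2 * g$r_out + 4 >= n) {       # cannot fit in the patch at all
        g <- sample_geom(classes[ci])
        next
      }
      for (try in 1:200) {
        cy <- runif(1, g$r_out + 2, n - g$r_out - 1)
        cx <- runif(1, g$r_out + 2, n - g$r_out - 1)
        clash <- FALSE
        for (p in placed) {
          if (sqrt((cy - p[1])^2 + (cx - p[2])^2) < g$r_out + p[3] + 3) {
            clash <- TRUE
            break
          }
        }
        if (!clash) {
          ok <- TRUE
          break
        }
      }
      if (ok) break
      g <- sample_geom(classes[ci])   # reject-and-resample the geometry
    }
    if (!ok) {
      stop("could not place candidate ", ci, " (class ", classes[ci],
           ") after bounded retries; reduce candidates_per_patch or lumen radii")
    }
    cl <- g$cl; a <- g$a; b <- g$b; phi <- g$phi
    pert_amp <- g$pert_amp; pert_phase <- g$pert_phase
    ring <- g$ring; nuc_r <- g$nuc_r; dens <- g$dens; band <- g$band
    placed[[length(placed) + 1]] <- c(cy, cx, g$r_out)

    # local window around the candidate; all fields evaluated there only
    wr <- max(1L, floor(cy - g$r_out)):min(n, ceiling(cy + g$r_out))
    wc <- max(1L, floor(cx - g$r_out)):min(n, ceiling(cx + g$r_out))

    # additive bands on the semi-axes: lumen, cytoplasm ring, nuclei band
    lum <- .rho_field(wr, wc, cy, cx, a, b, phi, pert_amp, pert_phase) <= 1
    cyto <- if (ring > 0) {
      .rho_field(wr, wc, cy, cx, a + ring, b + ring, phi,
                 pert_amp, pert_phase) <= 1 & !lum
    } else {
      lum & FALSE
    }
    # nuclei discs along the outer edge of the cytoplasm ring
    nucs <- matrix(FALSE, length(wr), length(wc))
    if (dens > 0) {
      layers <- if (dens >= 0.7) 2 else 1
      for (ly in seq_len(layers)) {
        off <- ring + nuc_r + (ly - 1) * (2 * nuc_r + 1)
        perim <- pi * (a + b + 2 * off)
        k <- max(1, floor(dens * perim / (2 * nuc_r + 1)))
        ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] +
          rnorm(k, 0, 0.04)
        # map ellipse-frame points back to image coordinates (inverse of the
        # rotation used by .rho_field)
        ex <- (a + off) * cos(ang)
        ey <- (b + off) * sin(ang)
        px <- cx + ex * cos(phi) + ey * sin(phi)
        py <- cy - ex * sin(phi) + ey * cos(phi)
        for (j in seq_len(k)) {
          rs <- round(py[j]); cs <- round(px[j])
          if (rs + nuc_r < wr[1] || rs - nuc_r > wr[length(wr)] ||
              cs + nuc_r < wc[1] || cs - nuc_r > wc[length(wc)]) next
          r1 <- max(wr[1], rs - nuc_r):min(wr[length(wr)], rs + nuc_r)
          c1 <- max(wc[1], cs - nuc_r):min(wc[length(wc)], cs + nuc_r)
          dd <- outer((r1 - py[j])^2, (c1 - px[j])^2, "+") <= nuc_r^2
          rl <- r1 - wr[1] + 1L; cll <- c1 - wc[1] + 1L
          nucs[rl, cll] <- nucs[rl, cll] | dd
        }
      }
      nucs <- nucs & !lum & !cyto
    }

    lumen_map[wr, wc] <- lumen_map[wr, wc] | lum
    cyto_map[wr, wc] <- cyto_map[wr, wc] | cyto
    nuc_map[wr, wc] <- nuc_map[wr, wc] | nucs

    # truth gland mask: filled outer boundary of the candidate
    gmask <- if (cl == "artefact") {
      dilate_disk(lum, 2)
    } else {
      .rho_field(wr, wc, cy, cx, a + ring + band, b + ring + band, phi,
                 pert_amp, pert_phase) <= 1
    }
    bb <- .tight_bbox(gmask, margin = 4L)
    cands[[ci]] <- list(
      bbox = c(bb[1] + wr[1] - 1L, bb[2] + wc[1] - 1L,
               bb[3] + wr[1] - 1L, bb[4] + wc[1] - 1L),
      class = cl,
      gland_mask = gmask[bb[1]:bb[3], bb[2]:bb[4]],
      lumen_mask = lum[bb[1]:bb[3], bb[2]:bb[4]])
  }

  # paint components over the stroma base
  for (ch in 1:3) {
    pl <- base[, , ch]
    pl[cyto_map] <- eff$palette$cytoplasm[ch]
    pl[lumen_map] <- eff$palette$lumen[ch]
    pl[nuc_map] <- eff$palette$nuclei[ch]
    base[, , ch] <- pl
  }
  rgb <- base + array(rnorm(length(base), 0, spec$noise_sd), dim(base))
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  storage.mode(rgb) <- "double"

  truth <- tissue_component_maps_new(
    lumen = lumen_map, cytoplasm = cyto_map,
    stroma = !(lumen_map | cyto_map | nuc_map), nuclei = nuc_map)

  candidates <- lapply(seq_along(cands), function(i) {
    cd <- cands[[i]]
    bb <- cd$bbox
    crop <- rgb[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE]
    masked <- crop
    for (ch in 1:3) masked[, , ch] <- crop[, , ch] * cd$gland_mask
    gland_candidate(rgb_bbox = crop, masked_rgb = masked,
                    bbox = bb, patient_id = patient_id, label = cd$class,
                    truth_gland_mask = cd$gland_mask,
                    truth_lumen_mask = cd$lumen_mask)
  })

  structure(list(rgb = rgb, truth_maps = truth, candidates = candidates,
                 patient_id = patient_id, seed = as.integer(seed)),
            class = "phantom_patch")
}

.tight_bbox <- function(mask, margin = 0L) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  c(max(1L, rr[1] - margin), max(1L, cc[1] - margin),
    min(nrow(mask), rr[2] + margin), min(ncol(mask), cc[2] + margin))
}

#' Gland candidate
#'
#' A segmented gland candidate: the RGB bounding-box crop, the same crop with
#' non-gland pixels zeroed (the segmentation output), and metadata. Phantom
#' candidates additionally carry ground-truth gland/lumen masks.
#'
#' @param rgb_bbox HxWx3 array, 0-255.
#' @param masked_rgb HxWx3 array with non-gland pixels set to 0.
#' @param bbox `c(row0, col0, row1, col1)`, 1-based inclusive patch coords.
#' @param patient_id character scalar.
#' @param label one of artefact/benign/grade3, or NA.
#' @param truth_gland_mask,truth_lumen_mask optional logical matrices.
#' @return object of class `gland_candidate`.
#' @export
gland_candidate <- function(rgb_bbox, masked_rgb, bbox, patient_id,
                            label = NA_character_,
                            truth_gland_mask = NULL, truth_lumen_mask = NULL) {
  stopifnot(length(dim(rgb_bbox)) == 3, all(dim(rgb_bbox) == dim(masked_rgb)))
  structure(list(rgb_bbox = rgb_bbox, masked_rgb = masked_rgb,
                 bbox = as.integer(bbox), patient_id = patient_id,
                 label = label, truth_gland_mask = truth_gland_mask,
                 truth_lumen_mask = truth_lumen_mask),
            class = "gland_candidate")
}

#' @export
print.gland_candidate <- function(x, ...) {
  d <- dim(x$rgb_bbox)
  cat(sprintf("<gland_candidate %dx%d patient=%s label=%s>\n",
              d[1], d[2], x$patient_id, x$label))
  invisible(x)
}

#' @export
print.phantom_patch <- function(x, ...) {
  cat(sprintf("<phantom_patch %dx%d patient=%s candidates=%d>\n",
              nrow(x$rgb), ncol(x$rgb), x$patient_id, length(x$candidates)))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Generates `n_patients x patches_per_patient` patches. Candidate classes
#' are allocated in exact proportion to `class_mix` (up to rounding) and
#' shuffled across the cohort, so per-class counts track the mix closely.
#'
#' @param spec a [phantom_spec()] with `n_patients >= 5`.
#' @return object of class `phantom_cohort`: list of patches plus a
#'   `candidates` index data frame (candidate_id, patient_id, patch, class).
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  if (spec$n_patients < 5) stop("n_patients must be >= 5 for patient-wise CV")
  n_patch <- spec$n_patients * spec$patches_per_patient
  total <- n_patch * spec$candidates_per_patch
  # exact-proportion class allocation, shuffled deterministically
  counts <- floor(spec$class_mix * total)
  rem <- total - sum(counts)
  if (rem > 0) {
    counts[order(spec$class_mix * total - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(spec$class_mix * total - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  all_classes <- rep(names(counts), counts)
  set.seed(spec$seed)
  all_classes <- sample(all_classes)

  patches <- vector("list", n_patch)
  idx <- 0L
  pos <- 0L
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", i)
    for (j in seq_len(spec$patches_per_patient)) {
      idx <- idx + 1L
      cls <- all_classes[pos + seq_len(spec$candidates_per_patch)]
      pos <- pos + spec$candidates_per_patch
      patches[[idx]] <- generate_patch(
        spec, pid, seed = (spec$seed + i * 1000L + j) %% 2147483647,
        classes = cls)
    }
  }
  tab <- do.call(rbind, lapply(seq_along(patches), function(k) {
    p <- patches[[k]]
    data.frame(candidate_id = sprintf("p%03d_c%02d", k,
                                      seq_along(p$candidates)),
               patient_id = p$patient_id, patch = k,
               class = vapply(p$candidates, `[[`, "", "label"),
               stringsAsFactors = FALSE)
  }))
  structure(list(patches = patches, candidates = tab, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort %d patients, %d patches, %d candidates>\n",
              x$spec$n_patients, length(x$patches), nrow(x$candidates)))
  print(table(x$candidates$class))
  invisible(x)
}

#' Synthesise a fractional-Gaussian-noise image
#'
#' Each row is an independent, zero-mean fractional Gaussian noise sample
#' with Hurst exponent `H`, generated by exact frequency-domain shaping: the
#' discrete spectrum is drawn as complex Gaussian noise with power
#' proportional to `f^(1-2H)`, so the log-log periodogram slope is `1-2H`.
#'
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param rows,cols image dimensions.
#' @param seed integer seed.
#' @return `rows x cols` numeric matrix; each row has mean zero.
#' @export
synthesize_fgn_image <- function(H, rows, cols, seed) {
  if (!is.numeric(H) || H <= 0 || H >= 1) {
    stop("H must lie strictly inside (0, 1)")
  }
  set.seed(as.integer(seed))
  n <- as.integer(cols)
  half <- n %/% 2L
  freq <- (1:half) / n
  amp <- freq^((1 - 2 * H) / 2)
  out <- matrix(0, rows, n)
  for (m in seq_len(rows)) {
    re <- rnorm(half)
    im <- rnorm(half)
    spec <- complex(real = re, imaginary = im) * amp
    if (n %% 2L == 0L) {
      spec[half] <- complex(real = re[half] * amp[half], imaginary = 0)
    }
    full <- complex(length.out = n)
    full[1] <- 0                      # zero mean
    full[2:(half + 1)] <- spec
    if (half > 1) {
      full[n:(n - half + 2)] <- Conj(spec[1:(half - 1)])
    }
    x <- Re(fft(full, inverse = TRUE)) / sqrt(n)
    out[m, ] <- x - mean(x)
  }
  out
}
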