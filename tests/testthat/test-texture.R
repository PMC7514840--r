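test_that("GLCMs are symmetric, normalised and match brute-force counts", {
  const <- matrix(0.5, 10, 10)
  g <- glcm(const, c(0, 2))
  expect_equal(sum(g), 1)
  expect_equal(sum(diag(g) > 0), 1)     # single diagonal cell
  # the worked toy example: hand-countable pairs at offset (0, 1)
  toy <- matrix(c(0, 1, 2, 3,
                  1, 1, 2, 3,
                  2, 2, 3, 3,
                  3, 3, 3, 3) / 8 + 0.01, 4, 4, byrow = TRUE)
  raw <- oracle_glcm_counts(toy, c(0, 1))
  sym <- raw + t(raw)
  expect_equal(glcm(toy, c(0, 1)), sym / sum(sym))
  # random crops vs the oracle, both offsets
  set.seed(10)
  for (i in 1:10) {
    m <- matrix(runif(12 * 14), 12, 14)
    for (off in list(c(0, 2), c(-2, 2))) {
      raw <- oracle_glcm_counts(m, off)
      sym <- raw + t(raw)
      expect_equal(glcm(m, off), sym / sum(sym))
    }
  }
  expect_error(glcm(matrix(0.5, 2, 2), c(0, 2)), "smaller")
  g2 <- glcm(matrix(runif(100), 10, 10), c(-2, 2))
  expect_equal(g2, t(g2))
})

test_that("GLCM statistics match closed forms", {
  one <- matrix(0, 8, 8); one[3, 3] <- 1
  f <- glcm_features(one)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["correlation"]), 0)  # zero marginal sd convention
  unif <- matrix(1 / 64, 8, 8)
  fu <- glcm_features(unif)
  expect_equal(unname(fu["energy"]), 1 / 64)
  expect_equal(unname(fu["entropy"]), log(64))
  expect_length(f, 21)
  expect_error(glcm_features(matrix(1, 8, 8)), "normalised")
})

test_that("LBP riu2 labels match the exhaustive oracle", {
  const <- matrix(0.3, 8, 8)
  expect_true(all(lbp_riu2(const) == 8))   # s(0) = 1 convention
  spot <- matrix(0, 5, 5); spot[3, 3] <- 1
  expect_equal(lbp_riu2(spot)[2, 2], 0L)   # bright pixel above all neighbours
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(16 * 16), 16, 16)
    o <- oracle_lbp_var(m)
    expect_equal(lbp_riu2(m), o$lab)
    expect_equal(var_map(m), o$var, tolerance = 1e-12)
  }
})

test_that("VAR follows its definition and symmetry", {
  const <- matrix(2, 9, 9)
  expect_true(all(var_map(const) == 0))
  # one bright neighbour among four integer-offset samples (P = 4):
  # neighbours {8, 0, 0, 0}, mean 2, variance (36 + 3*4)/4 = 12
  m <- matrix(0, 3, 3); m[1, 2] <- 8
  expect_equal(var_map(m, P = 4)[1, 1], 12)
  # rotation by 90 degrees permutes the map (up to transposition)
  set.seed(12)
  m2 <- matrix(runif(100), 10, 10)
  r90 <- t(m2)[, 10:1]
  v <- var_map(m2)
  vr <- var_map(r90)
  expect_equal(sort(as.vector(v)), sort(as.vector(vr)), tolerance = 1e-9)
})

test_that("LBPV accumulates variance per label", {
  const <- matrix(1, 8, 8)
  expect_true(all(lbpv_histogram(lbp_riu2(const), var_map(const)) == 0))
  set.seed(13)
  m <- matrix(runif(25), 5, 5)
  lab <- lbp_riu2(m); v <- var_map(m)
  h <- lbpv_histogram(lab, v)
  expect_equal(sum(h), sum(v))                     # partition identity
  expect_equal(h, oracle_lbpv(lab, v))
  expect_error(lbpv_histogram(lab, v[1:2, 1:2, drop = FALSE]), "shape")
})

test_that("the texture block has the published structure", {
  set.seed(14)
  chans <- list(cyan = matrix(runif(40 * 40), 40),
                hematoxylin = matrix(runif(40 * 40), 40),
                eosin = matrix(runif(40 * 40), 40))
  v <- texture_features(chans)
  expect_length(v, 186)
  expect_equal(sum(grepl("^glcm\\.", names(v))), 126)
  expect_equal(sum(grepl("^lbp\\.", names(v))), 60)
  expect_identical(v, texture_features(chans))
})
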