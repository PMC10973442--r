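test_that("quantization bins uniformly, monotonically, and validates input", {
  # constant image collapses to one level
  q <- quantize_image(matrix(128, 5, 5), 8)
  expect_length(unique(as.vector(q$pixels)), 1L)
  # extremes map to the extreme bins
  q2 <- quantize_image(matrix(c(0, 255, 0, 255), 2, 2), 2)
  expect_setequal(as.vector(q2$pixels), c(0L, 1L))
  # a full 0..255 ramp fills four bins with exactly 64 pixels each
  q3 <- quantize_image(matrix(0:255, 16, 16), 4)
  expect_equal(unname(table(q3$pixels)), rep(64L, 4L), ignore_attr = TRUE)
  # monotone in the raw intensities
  raw <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  q4 <- quantize_image(raw, 6)
  ord <- order(raw)
  expect_true(all(diff(q4$pixels[ord]) >= 0L))
  # unit-interval input uses the [0,1] scale
  q5 <- quantize_image(matrix(c(0, 0.49, 0.51, 1), 2, 2), 2)
  expect_equal(sort(as.vector(q5$pixels)), c(0L, 0L, 1L, 1L))
  expect_error(quantize_image(matrix(numeric(0), 0, 0), 8), "non-empty")
  expect_error(quantize_image(matrix(1, 2, 2), 1), ">= 2")
})

test_that("co-occurrence counts match hand-enumerated pairs", {
  img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), 2)
  # horizontal pairs: one (0,0) and one (1,1)
  g0 <- compute_glcm(img, glcm_params(angles = 0, n_levels = 2,
                                      symmetric = FALSE,
                                      average_angles = FALSE))
  expect_equal(g0$counts, rbind(c(1L, 0L), c(0L, 1L)))
  expect_equal(sum(g0$probs), 1)
  # vertical pairs: both pair level 0 with level 1 in one off-diagonal cell
  g90 <- compute_glcm(img, glcm_params(angles = 90, n_levels = 2,
                                       symmetric = FALSE,
                                       average_angles = FALSE))
  expect_equal(sort(as.vector(g90$counts)), c(0L, 0L, 0L, 2L))
  expect_equal(sum(g90$counts != 0), 1L)
  # constant MxN image: M*(N-1) identical horizontal pairs at (c,c)
  cimg <- gray_image(matrix(3L, 4, 7), 8)
  gc <- compute_glcm(cimg, glcm_params(angles = 0, n_levels = 8,
                                       symmetric = FALSE,
                                       average_angles = FALSE))
  expect_equal(gc$counts[4, 4], 4L * 6L)
  expect_equal(sum(gc$counts), 4L * 6L)
  # image too small for the offset
  tiny <- gray_image(matrix(0:1, 1, 2), 2)
  expect_error(compute_glcm(tiny, glcm_params(angles = 90, n_levels = 2,
                                              average_angles = FALSE)),
               "too small")
})

test_that("vectorized GLCM equals the brute-force pair counter", {
  set.seed(101)
  for (rep in 1:3) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1); ng <- sample(2:4, 1)
    img <- rand_gray(nr, nc, ng)
    for (ang in c(0, 45, 90, 135)) {
      for (sym in c(FALSE, TRUE)) {
        oracle <- bf_glcm_counts(img$pixels, ng, 1L, ang, sym)
        if (sum(oracle) == 0L) next
        g <- compute_glcm(img, glcm_params(angles = ang, n_levels = ng,
                                           symmetric = sym,
                                           average_angles = FALSE))
        expect_equal(g$counts, oracle)
        expect_equal(g$probs, oracle / sum(oracle))
      }
    }
  }
})

test_that("Haralick statistics reproduce their closed-form values", {
  # energy: point mass, uniform over K cells, two half cells
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  expect_equal(glcm_asm(one), 1.0)
  expect_equal(glcm_asm(matrix(1 / 9, 3, 3)), 1 / 9)
  diag2 <- probs_mat(c(0.5, 0), c(0, 0.5))
  expect_equal(glcm_asm(diag2), 0.5)
  # contrast: zero iff diagonal; single off-diagonal terms
  expect_equal(glcm_con(diag2), 0)
  expect_equal(glcm_con(probs_mat(c(0, 1), c(0, 0))), 1)
  off2 <- matrix(0, 3, 3); off2[1, 3] <- 0.5; off2[3, 1] <- 0.5
  expect_equal(glcm_con(off2), 4.0)
  # inverse difference moment
  expect_equal(glcm_idm(diag2), 1.0)
  expect_equal(glcm_idm(probs_mat(c(0, 1), c(0, 0))), 0.5)
  mix <- matrix(0, 3, 3); mix[1, 1] <- 0.5; mix[1, 3] <- 0.5
  expect_equal(glcm_idm(mix), 0.6)
  # correlation: perfectly correlated / anticorrelated marginals
  expect_equal(glcm_cor(diag2), 1.0)
  expect_equal(glcm_cor(probs_mat(c(0, 0.5), c(0.5, 0))), -1.0)
  const <- matrix(0, 2, 2); const[1, 1] <- 1
  expect_error(glcm_cor(const), class = "bcicm_degenerate_correlation")
  # entropy in bits
  expect_equal(glcm_ent(one), 0)
  expect_equal(glcm_ent(matrix(0.25, 2, 2)), 2.0)
  expect_equal(glcm_ent(probs_mat(c(0.5, 0.25), c(0.25, 0))), 1.5)
  # unnormalized input is rejected everywhere
  expect_error(glcm_asm(matrix(1, 2, 2)), "not normalized")
})

test_that("feature vector composes the statistics in canonical order", {
  img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), 2)
  p <- glcm_params(angles = 0, n_levels = 2, symmetric = FALSE,
                   average_angles = FALSE)
  expect_equal(extract_features(img, p),
               c(asm = 0.5, con = 0, idm = 1, cor = 1))
  # constant image: degenerate correlation falls back to 0 with a warning
  cimg <- gray_image(matrix(2L, 4, 4), 8)
  expect_warning(v <- extract_features(cimg, glcm_params()), "degenerate")
  expect_equal(v, c(asm = 1, con = 0, idm = 1, cor = 0))
  # optional statistics are appended after the mandatory four
  img2 <- rand_gray(8, 8, 4)
  v2 <- extract_features(img2, glcm_params(n_levels = 4),
                         include_optional = TRUE)
  expect_named(v2, c("asm", "con", "idm", "cor", "ent", "coarseness"))
})

test_that("feature ranges and diagonal equivalences hold on random images", {
  set.seed(202)
  for (rep in 1:50) {
    img <- rand_gray(sample(3:8, 1), sample(3:8, 1), sample(2:6, 1))
    g <- compute_glcm(img, glcm_params(n_levels = img$n_levels))
    expect_gt(glcm_asm(g), 0); expect_lte(glcm_asm(g), 1)
    expect_gte(glcm_con(g), 0)
    expect_gt(glcm_idm(g), 0); expect_lte(glcm_idm(g), 1)
    expect_gte(glcm_ent(g), 0)
    cc <- tryCatch(glcm_cor(g), bcicm_degenerate_correlation = function(e) 0)
    expect_gte(cc, -1); expect_lte(cc, 1)
    # CON = 0 <=> IDM = 1 <=> diagonal-only mass
    diag_only <- sum(g$probs) - sum(diag(g$probs)) < 1e-12
    expect_equal(glcm_con(g) < 1e-12, diag_only)
    expect_equal(glcm_idm(g) > 1 - 1e-12, diag_only)
  }
})

test_that("angle-averaged symmetric features are transpose-invariant", {
  set.seed(303)
  for (rep in 1:10) {
    img <- rand_gray(sample(4:7, 1), sample(4:7, 1), 4)
    timg <- gray_image(t(img$pixels), img$n_levels)
    p <- glcm_params(n_levels = 4)  # symmetric, all four angles, averaged
    expect_equal(suppressWarnings(extract_features(img, p)),
                 suppressWarnings(extract_features(timg, p)),
                 tolerance = 1e-12)
  }
})

test_that("symmetric counting makes each direction orientation-free", {
  # the symmetric table equals directional counts plus their transpose,
  # and the total equals twice the number of valid ordered pairs
  set.seed(404)
  img <- rand_gray(5, 6, 3)
  for (ang in c(0, 45, 90, 135)) {
    dir_ <- compute_glcm(img, glcm_params(angles = ang, n_levels = 3,
                                          symmetric = FALSE,
                                          average_angles = FALSE))
    sym <- compute_glcm(img, glcm_params(angles = ang, n_levels = 3,
                                         symmetric = TRUE,
                                         average_angles = FALSE))
    expect_equal(sym$counts, dir_$counts + t(dir_$counts))
    expect_equal(sum(sym$counts), 2L * sum(dir_$counts))
  }
})

test_that("coarseness distinguishes texture scale deterministically", {
  # constant image: every difference is zero, smallest window wins
  expect_equal(tamura_coarseness(matrix(5, 16, 16)), 1.0)
  # coarse checkerboard scores strictly above fine checkerboard
  board <- function(block, n = 32) {
    idx <- matrix(0L, n, n)
    ((row(idx) - 1L) %/% block + (col(idx) - 1L) %/% block) %% 2L
  }
  expect_gt(tamura_coarseness(board(4)), tamura_coarseness(board(1)))
  # nearest-neighbor 2x upscaling never decreases coarseness
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    m <- matrix(sample(0:7, n * n, replace = TRUE), n, n)
    up <- m[rep(seq_len(n), each = 2), rep(seq_len(n), each = 2)]
    expect_gte(tamura_coarseness(up), tamura_coarseness(m) - 1e-9)
  }
  expect_error(tamura_coarseness(matrix(1, 1, 1)), "too small")
})
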