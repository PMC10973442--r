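# Separable Gaussian convolution with reflected edges; kernel truncated at
# 3 sigma. sigma = 0 is the identity.
.gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  pad_reflect <- function(m, r) {
    # reflect up to nrow(m) rows; clamp to the edge beyond that
    idx_top <- rev(pmin(seq_len(r), nrow(m)))
    idx_bot <- pmax(nrow(m) - seq_len(r) + 1L, 1L)
    rbind(m[idx_top, , drop = FALSE], m, m[idx_bot, , drop = FALSE])
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (s in -r:r)
      out <- out + w[s + r + 1L] * p[(1L + r + s):(nrow(m) + r + s), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

#' Generator settings for the two-class synthetic texture fixture
#'
#' The fixture emulates two texture classes separable by GLCM statistics:
#' class "benign" images are heavily smoothed Gaussian noise fields (fine,
#' homogeneous texture: high inverse difference moment, low contrast) and
#' class "malignant" images are lightly smoothed fields (rough texture: high
#' contrast). After smoothing, each field is re-standardized to mean 128 and
#' standard deviation `noise_sd` before clipping to 8-bit, so coarseness
#' (kernel) and contrast (noise_sd) are controlled independently.
#'
#' @param n_per_class Images per class. Default 50.
#' @param resolution Square image side in pixels. Default 40.
#' @param smooth_kernel Blur sigma for the smooth class, pixels. Default 8.
#' @param rough_kernel Blur sigma for the rough class (< smooth_kernel).
#'   Default 0 (raw noise).
#' @param noise_sd Intensity standard deviation on the 0-255 scale.
#'   Default 40.
#' @param seed RNG seed. Default 1.
#' @return A `texture_gen_spec` list.
#' @export
texture_gen_spec <- function(n_per_class = 50L, resolution = 40L,
                             smooth_kernel = 8, rough_kernel = 0,
                             noise_sd = 40, seed = 1L) {
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1", call. = FALSE)
  if (resolution < 8L) stop("'resolution' must be >= 8", call. = FALSE)
  if (smooth_kernel < 0 || rough_kernel < 0 || rough_kernel >= smooth_kernel)
    stop("need 0 <= rough_kernel < smooth_kernel", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 resolution = as.integer(resolution),
                 smooth_kernel = smooth_kernel, rough_kernel = rough_kernel,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "texture_gen_spec")
}

#' Write a seeded two-class synthetic texture image set
#'
#' Generates `n_per_class` 8-bit grayscale PNGs per class under
#' `out_dir/benign/` (smooth texture) and `out_dir/malignant/` (rough
#' texture) — the folder layout [load_image_folder()] expects — plus a
#' `generator.json` recording the settings. Byte-identical across runs with
#' the same spec and seed.
#'
#' @param spec A [texture_gen_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the labeled image set (see [load_image_folder()]).
#' @export
make_texture_dataset <- function(spec = texture_gen_spec(), out_dir) {
  stopifnot(inherits(spec, "texture_gen_spec"))
  classes <- c(benign = spec$smooth_kernel, malignant = spec$rough_kernel)
  set.seed(spec$seed)
  for (cl in names(classes)) {
    dir.create(file.path(out_dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$n_per_class)) {
      f <- matrix(stats::rnorm(spec$resolution^2), spec$resolution)
      f <- .gaussian_blur(f, classes[[cl]])
      f <- (f - mean(f)) / stats::sd(f)          # fix contrast after blur
      pix <- pmin(pmax(128 + spec$noise_sd * f, 0), 255)
      png::writePNG(pix / 255,
                    file.path(out_dir, cl, sprintf("%s_%03d.png", cl, i)))
    }
  }
  jsonlite::write_json(unclass(spec), file.path(out_dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(load_image_folder(out_dir))
}

#' Generator settings for feature-space Gaussian blobs
#'
#' @param n_per_class Points per class. Default 100.
#' @param dim Feature dimension D. Default 4.
#' @param center_a,center_b True class centers (D-vectors). Defaults place
#'   them 10 standard deviations apart (`rep(0, dim)` and `rep(5, dim)` at
#'   `sd = 1`, `dim = 4`).
#' @param sd Isotropic standard deviation (> 0). Default 1.
#' @param seed RNG seed. Default 1.
#' @return A `blob_gen_spec` list with the recorded `separation`.
#' @export
blob_gen_spec <- function(n_per_class = 100L, dim = 4L,
                          center_a = rep(0, dim),
                          center_b = rep(10 / sqrt(dim), dim) * sd,
                          sd = 1, seed = 1L) {
  if (sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1", call. = FALSE)
  if (length(center_a) != dim || length(center_b) != dim)
    stop("centers must have length 'dim'", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class), dim = as.integer(dim),
                 center_a = as.numeric(center_a),
                 center_b = as.numeric(center_b), sd = sd,
                 separation = sqrt(sum((center_a - center_b)^2)),
                 seed = as.integer(seed)),
            class = "blob_gen_spec")
}

#' Sample a two-class isotropic Gaussian point cloud
#'
#' @param spec A [blob_gen_spec()].
#' @return List: `points` (2*n_per_class x dim matrix), `labels` (integer
#'   0 for class a, 1 for class b), `centers` (2 x dim matrix of the true
#'   centers) and `spec`.
#' @export
make_feature_blobs <- function(spec = blob_gen_spec()) {
  stopifnot(inherits(spec, "blob_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class; D <- spec$dim
  A <- matrix(stats::rnorm(n * D, sd = spec$sd), n, D, byrow = TRUE) +
    matrix(spec$center_a, n, D, byrow = TRUE)
  B <- matrix(stats::rnorm(n * D, sd = spec$sd), n, D, byrow = TRUE) +
    matrix(spec$center_b, n, D, byrow = TRUE)
  list(points = rbind(A, B), labels = rep(c(0L, 1L), each = n),
       centers = rbind(spec$center_a, spec$center_b), spec = spec)
}
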