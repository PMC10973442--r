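#' Quantize raw intensities to a fixed number of gray levels
#'
#' Uniformly bins intensities into `n_levels` gray levels, producing the
#' integer-valued image all texture computations operate on. Inputs may be
#' 8-bit integers in \[0, 255\] or unit-interval reals in \[0, 1\] (the scale
#' is detected from the data range); binning is monotone, so ordering of
#' pixel intensities is preserved.
#'
#' @param raw Numeric matrix of intensities (gray image, rows = image rows).
#' @param n_levels Number of gray levels N_g (>= 2). Default 8.
#' @return A `gray_image` object: list with `pixels` (integer matrix with
#'   values in `0:(n_levels-1)`) and `n_levels`.
#' @examples
#' img <- quantize_image(matrix(0:255, 16, 16), n_levels = 8)
#' range(img$pixels)
#' @export
quantize_image <- function(raw, n_levels = 8L) {
  if (!is.matrix(raw) || length(raw) == 0L)
    stop("'raw' must be a non-empty matrix", call. = FALSE)
  if (anyNA(raw)) stop("'raw' contains missing values", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("'n_levels' must be an integer >= 2", call. = FALSE)
  # scale detection: treat data in [0,1] as unit floats, otherwise 8-bit
  top <- if (max(raw) <= 1 && min(raw) >= 0) 1 else 255
  lev <- floor(raw / (top + ifelse(top == 1, 1e-9, 1)) * n_levels)
  lev <- pmin(pmax(lev, 0L), n_levels - 1L)
  gray_image(matrix(as.integer(lev), nrow(raw), ncol(raw)), n_levels)
}

#' Construct a gray image from already-quantized levels
#'
#' @param pixels Integer matrix with values in `0:(n_levels-1)`.
#' @param n_levels Number of gray levels N_g (>= 2).
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, n_levels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("'n_levels' must be an integer >= 2", call. = FALSE)
  px <- as.integer(pixels)
  if (anyNA(px) || any(px < 0L) || any(px >= n_levels))
    stop("pixel levels must be integers in [0, n_levels - 1]", call. = FALSE)
  structure(list(pixels = matrix(px, nrow(pixels), ncol(pixels)),
                 n_levels = n_levels),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels>\n",
              nrow(x$pixels), ncol(x$pixels), x$n_levels))
  invisible(x)
}

#' GLCM parameters
#'
#' Displacement and counting conventions for the gray-level co-occurrence
#' matrix: pixel-pair distance `d`, direction(s) `theta` among the four
#' canonical angles, whether counts are made symmetric (each pair counted in
#' both orders), and whether the normalized tables of the requested angles
#' are averaged into a single rotation-tolerant table.
#'
#' @param distance Pair distance d in pixels (>= 1). Default 1.
#' @param angles Angles in degrees, a subset of `c(0, 45, 90, 135)`.
#'   Default all four.
#' @param n_levels Gray levels N_g. Default 8.
#' @param symmetric Count each ordered pair in both orders. Default TRUE.
#' @param average_angles Average the per-angle normalized tables. Default TRUE.
#' @return A `glcm_params` list.
#' @export
glcm_params <- function(distance = 1L, angles = c(0, 45, 90, 135),
                        n_levels = 8L, symmetric = TRUE,
                        average_angles = TRUE) {
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L)
    stop("'distance' must be an integer >= 1", call. = FALSE)
  if (length(angles) < 1L || !all(angles %in% c(0, 45, 90, 135)))
    stop("'angles' must be drawn from {0, 45, 90, 135}", call. = FALSE)
  structure(list(distance = distance, angles = as.numeric(angles),
                 n_levels = as.integer(n_levels),
                 symmetric = isTRUE(symmetric),
                 average_angles = isTRUE(average_angles)),
            class = "glcm_params")
}

# Row/column offset of the displacement vector for one canonical angle.
# 0 deg looks right along a row; 45/90/135 move up the image (standard
# convention; with symmetric counting theta and theta+180 coincide).
.glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

# Raw directional pair counts for a single (d, theta) offset.
.glcm_counts_one <- function(px, n_levels, dr, dc) {
  M <- nrow(px); N <- ncol(px)
  r0 <- max(1L, 1L - dr); r1 <- min(M, M - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(N, N - dc)
  if (r0 > r1 || c0 > c1) return(matrix(0L, n_levels, n_levels))
  i <- px[r0:r1, c0:c1, drop = FALSE]
  j <- px[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  tab <- tabulate(as.vector(i) * n_levels + as.vector(j) + 1L,
                  nbins = n_levels * n_levels)
  matrix(tab, n_levels, n_levels, byrow = TRUE)
}

#' Compute the gray-level co-occurrence matrix of an image
#'
#' Counts, for a displacement of `distance` pixels in each requested
#' direction, how often gray level i co-occurs with gray level j, then
#' normalizes the counts to a probability table. With `symmetric = TRUE` the
#' transpose is added (each pair counted in both orders); with
#' `average_angles = TRUE` the normalized tables of the requested angles are
#' averaged.
#'
#' @param img A `gray_image` (see [quantize_image()]).
#' @param params A `glcm_params` object.
#' @return A `glcm` object: list with `counts` (summed integer pair counts),
#'   `probs` (normalized table summing to 1), and `params`.
#' @examples
#' img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), n_levels = 2)
#' g <- compute_glcm(img, glcm_params(angles = 0, n_levels = 2,
#'                                    symmetric = FALSE,
#'                                    average_angles = FALSE))
#' g$probs
#' @export
compute_glcm <- function(img, params = glcm_params()) {
  stopifnot(inherits(img, "gray_image"))
  if (!inherits(params, "glcm_params")) params <- do.call(glcm_params, params)
  if (params$n_levels < img$n_levels)
    stop("params$n_levels smaller than the image's level count", call. = FALSE)
  ng <- params$n_levels
  counts_total <- matrix(0L, ng, ng)
  prob_tabs <- list()
  for (a in params$angles) {
    off <- .glcm_offset(a, params$distance)
    cts <- .glcm_counts_one(img$pixels, ng, off[1L], off[2L])
    if (params$symmetric) cts <- cts + t(cts)
    tot <- sum(cts)
    if (tot == 0L)
      stop(sprintf("image too small for a %d-pixel pair at %g degrees",
                   params$distance, a), call. = FALSE)
    counts_total <- counts_total + cts
    prob_tabs[[length(prob_tabs) + 1L]] <- cts / tot
  }
  probs <- if (params$average_angles) {
    Reduce(`+`, prob_tabs) / length(prob_tabs)
  } else if (length(prob_tabs) == 1L) {
    prob_tabs[[1L]]
  } else {
    counts_total / sum(counts_total)
  }
  structure(list(counts = counts_total, probs = probs, params = params),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm %dx%d, d=%d, angles=%s%s%s>\n",
              nrow(x$probs), ncol(x$probs), x$params$distance,
              paste(x$params$angles, collapse = "/"),
              if (x$params$symmetric) ", symmetric" else "",
              if (x$params$average_angles) ", angle-averaged" else ""))
  invisible(x)
}

# Accepts a glcm object or a bare probability matrix; checks normalization.
.glcm_probs <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$probs else glcm
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("expected a glcm object or square probability matrix", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("GLCM is not normalized: probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  p
}

#' Haralick statistics of a normalized GLCM
#'
#' The four statistics of the core texture feature vector, plus entropy:
#' * `glcm_asm()`: energy / angular second moment, sum of squared
#'   probabilities. High for uniform, fine texture; in (0, 1].
#' * `glcm_con()`: contrast, the (i-j)^2-weighted sum. High for deep, sharp
#'   texture transitions; 0 iff all mass is on the diagonal.
#' * `glcm_idm()`: inverse difference moment (local homogeneity),
#'   sum of p/(1+(i-j)^2); in (0, 1], 1 iff diagonal-only.
#' * `glcm_cor()`: correlation of the row and column marginals; in \[-1, 1\].
#'   Undefined when a marginal standard deviation is zero (e.g. a constant
#'   image); this raises an error of class `bcicm_degenerate_correlation`.
#' * `glcm_ent()`: Shannon entropy in bits over the nonzero cells; >= 0.
#'
#' @param glcm A `glcm` object (or bare normalized probability matrix).
#' @return A single numeric value.
#' @name glcm_stats
NULL

#' @rdname glcm_stats
#' @export
glcm_asm <- function(glcm) {
  p <- .glcm_probs(glcm)
  sum(p * p)
}

#' @rdname glcm_stats
#' @export
glcm_con <- function(glcm) {
  p <- .glcm_probs(glcm)
  ij <- .level_grid(nrow(p))
  sum((ij$i - ij$j)^2 * p)
}

#' @rdname glcm_stats
#' @export
glcm_idm <- function(glcm) {
  p <- .glcm_probs(glcm)
  ij <- .level_grid(nrow(p))
  sum(p / (1 + (ij$i - ij$j)^2))
}

#' @rdname glcm_stats
#' @export
glcm_cor <- function(glcm) {
  p <- .glcm_probs(glcm)
  lev <- seq_len(nrow(p)) - 1
  px <- rowSums(p); py <- colSums(p)
  mu1 <- sum(lev * px); mu2 <- sum(lev * py)
  d1 <- sqrt(sum((lev - mu1)^2 * px))
  d2 <- sqrt(sum((lev - mu2)^2 * py))
  if (d1 < 1e-12 || d2 < 1e-12)
    stop(structure(class = c("bcicm_degenerate_correlation", "error",
                             "condition"),
                   list(message = paste("correlation undefined: a marginal",
                                        "standard deviation is zero"),
                        call = sys.call(-1))))
  ij <- .level_grid(nrow(p))
  sum((ij$i - mu1) * (ij$j - mu2) * p) / (d1 * d2)
}

#' @rdname glcm_stats
#' @export
glcm_ent <- function(glcm) {
  p <- .glcm_probs(glcm)
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

# i/j level grids (0-based) for an ng x ng table; i indexes rows.
.level_grid <- function(ng) {
  lev <- seq_len(ng) - 1
  list(i = matrix(lev, ng, ng), j = matrix(lev, ng, ng, byrow = TRUE))
}

#' Tamura coarseness of a gray image
#'
#' Perceptual texture-scale estimate. For each window exponent k in
#' `0:k_max`, box averages over 2^k x 2^k windows are compared between
#' neighboring non-overlapping windows (offset 2^k) horizontally and
#' vertically; each pixel (window anchor) selects the k with the largest
#' difference, ties broken toward the smallest k, and the coarseness is the
#' mean of 2^k_best over all anchors. Constant images give exactly 1.
#'
#' @param img A `gray_image` or numeric matrix.
#' @param k_max Largest window exponent to try (window 2^k_max); capped so
#'   both compared windows fit inside the image. Default 4.
#' @return Coarseness >= 1 (dimensionless).
#' @export
tamura_coarseness <- function(img, k_max = 4L) {
  px <- if (inherits(img, "gray_image")) img$pixels else img
  if (!is.matrix(px)) stop("'img' must be a gray_image or matrix",
                           call. = FALSE)
  M <- nrow(px); N <- ncol(px)
  if (M < 2L || N < 2L)
    stop("image too small for coarseness (need at least 2x2)", call. = FALSE)
  px <- px * 1.0
  # integral image with a leading zero row/column for O(1) box sums
  S <- matrix(0, M + 1L, N + 1L)
  S[-1L, -1L] <- apply(apply(px, 2L, cumsum), 1L, cumsum) |> t()
  box_mean <- function(k) {
    w <- 2L^k
    rmax <- M - w + 1L; cmax <- N - w + 1L
    if (rmax < 1L || cmax < 1L) return(NULL)
    r <- seq_len(rmax); cc <- seq_len(cmax)
    (S[r + w, cc + w, drop = FALSE] - S[r, cc + w, drop = FALSE] -
       S[r + w, cc, drop = FALSE] + S[r, cc, drop = FALSE]) / (w * w)
  }
  best_e <- matrix(-Inf, M, N)
  best_k <- matrix(NA_integer_, M, N)
  for (k in 0:k_max) {
    A <- box_mean(k)
    if (is.null(A)) break
    w <- 2L^k
    e <- matrix(-Inf, M, N)
    ra <- nrow(A); ca <- ncol(A)
    if (ca > w) {                       # horizontal neighbor at offset 2^k
      eh <- abs(A[, (w + 1L):ca, drop = FALSE] - A[, 1L:(ca - w), drop = FALSE])
      e[1:ra, 1:(ca - w)] <- pmax(e[1:ra, 1:(ca - w)], eh)
    }
    if (ra > w) {                       # vertical neighbor
      ev <- abs(A[(w + 1L):ra, , drop = FALSE] - A[1L:(ra - w), , drop = FALSE])
      e[1:(ra - w), 1:ca] <- pmax(e[1:(ra - w), 1:ca], ev)
    }
    upd <- e > best_e + 1e-12           # strict: ties keep the smaller k
    best_e[upd] <- e[upd]
    best_k[upd] <- k
  }
  valid <- is.finite(best_e) & !is.na(best_k)
  if (!any(valid))
    stop("image too small for coarseness at any window size", call. = FALSE)
  mean(2^best_k[valid])
}

#' Extract the texture feature vector of an image
#'
#' Computes the core four-component vector `[asm, con, idm, cor]` on the
#' image's (by default symmetric, angle-averaged) normalized GLCM, optionally
#' appending entropy and Tamura coarseness. A degenerate correlation (zero
#' marginal variance, e.g. a constant image) is replaced by `cor_fallback`
#' with a warning so batch runs are not aborted.
#'
#' @param img A `gray_image`.
#' @param params A `glcm_params` object.
#' @param include_optional Also compute `ent` (bits) and `coarseness`.
#' @param cor_fallback Value substituted for an undefined correlation.
#'   Default 0.
#' @return Named numeric vector `c(asm, con, idm, cor)` (+ `ent`,
#'   `coarseness` when requested).
#' @examples
#' img <- gray_image(rbind(c(0L, 0L), c(1L, 1L)), n_levels = 2)
#' extract_features(img, glcm_params(angles = 0, n_levels = 2,
#'                                   symmetric = FALSE, average_angles = FALSE))
#' @export
extract_features <- function(img, params = glcm_params(),
                             include_optional = FALSE, cor_fallback = 0) {
  g <- compute_glcm(img, params)
  cor_val <- tryCatch(glcm_cor(g), bcicm_degenerate_correlation = function(e) {
    warning("degenerate correlation (constant marginals); substituting ",
            cor_fallback, call. = FALSE)
    cor_fallback
  })
  out <- c(asm = glcm_asm(g), con = glcm_con(g), idm = glcm_idm(g),
           cor = cor_val)
  if (include_optional)
    out <- c(out, ent = glcm_ent(g), coarseness = tamura_coarseness(img))
  out
}
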