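# Independent oracles and fixture builders shared across tests.

# Brute-force GLCM pair counter: explicit double loop over every pixel,
# deliberately independent of the vectorized implementation.
bf_glcm_counts <- function(px, n_levels, d, angle, symmetric = FALSE) {
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0L, n_levels, n_levels)
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 >= 1L && r2 <= nrow(px) && c2 >= 1L && c2 <= ncol(px)) {
        i <- px[r, c] + 1L; j <- px[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

# Random quantized image
rand_gray <- function(nr, nc, n_levels) {
  gray_image(matrix(sample(0:(n_levels - 1L), nr * nc, replace = TRUE),
                    nr, nc), n_levels)
}

# Bare probability matrix -> glcm-like input accepted by the statistics
probs_mat <- function(...) {
  m <- rbind(...)
  m / sum(m)
}

# Tiny on-disk two-class image tree for folder-loading tests
make_image_tree <- function(root, with_subtypes = FALSE) {
  write_px <- function(path, val) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(matrix(val, 16, 16), path)
  }
  if (with_subtypes) {
    write_px(file.path(root, "benign", "adenosis", "a.png"), 0.2)
    write_px(file.path(root, "benign", "fibroadenoma", "b.png"), 0.4)
    write_px(file.path(root, "malignant", "ductal", "c.png"), 0.8)
  } else {
    write_px(file.path(root, "benign", "a.png"), 0.2)
    write_px(file.path(root, "malignant", "b.png"), 0.8)
  }
  root
}

# Small separable feature table: two tight clouds in the four feature
# dimensions, labeled, for pipeline/baseline tests that skip image IO.
make_separable_features <- function(n_per_class = 20, seed = 99) {
  set.seed(seed)
  a <- cbind(asm = rnorm(n_per_class, 0.8, 0.02),
             con = rnorm(n_per_class, 0.3, 0.05),
             idm = rnorm(n_per_class, 0.9, 0.02),
             cor = rnorm(n_per_class, 0.8, 0.05))
  b <- cbind(asm = rnorm(n_per_class, 0.1, 0.02),
             con = rnorm(n_per_class, 4.0, 0.3),
             idm = rnorm(n_per_class, 0.4, 0.02),
             cor = rnorm(n_per_class, 0.0, 0.05))
  df <- as.data.frame(rbind(a, b))
  df$image_id <- sprintf("img_%03d", seq_len(2 * n_per_class))
  df$label <- rep(c("benign", "malignant"), each = n_per_class)
  df
}
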