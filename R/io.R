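.config_schema <- list(
  top = c("resolution", "feature_scaling", "split_fraction", "split_seed",
          "include_optional", "glcm", "udlm"),
  glcm = c("n_levels", "distance", "angles", "symmetric", "average_angles"),
  udlm = c("pop_size", "max_iter", "seed")
)

.check_keys <- function(keys, allowed, where) {
  bad <- setdiff(keys, allowed)
  if (!length(bad)) return(invisible())
  hint <- vapply(bad, function(k) {
    m <- agrep(k, allowed, max.distance = 2, value = TRUE)
    if (length(m)) sprintf(" (did you mean '%s'?)", m[1L]) else ""
  }, "")
  stop(sprintf("unknown %s key(s): %s", where,
               paste0("'", bad, "'", hint, collapse = ", ")), call. = FALSE)
}

#' Parse a YAML experiment configuration file
#'
#' Reads the documented key schema (top level: `resolution`,
#' `feature_scaling`, `split_fraction`, `split_seed`, `include_optional`,
#' and the `glcm:` and `udlm:` sections), fills defaults for anything
#' omitted — an empty file yields the full default configuration — and
#' rejects unknown keys, naming the offender and suggesting the closest
#' valid key.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  .check_keys(names(raw), .config_schema$top, "config")
  .check_keys(names(raw$glcm), .config_schema$glcm, "glcm")
  .check_keys(names(raw$udlm), .config_schema$udlm, "udlm")
  glcm <- do.call(glcm_params, raw$glcm %||% list())
  udlm <- do.call(udlm_config, raw$udlm %||% list())
  args <- raw[setdiff(names(raw), c("glcm", "udlm"))]
  do.call(experiment_config, c(args, list(glcm = glcm, udlm = udlm)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an experiment configuration to YAML
#'
#' Round-trips with [parse_config()]: writing the defaults and re-parsing
#' yields an identical configuration.
#'
#' @param config An [experiment_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(resolution = config$resolution,
            feature_scaling = config$feature_scaling,
            split_fraction = config$split_fraction,
            split_seed = config$split_seed,
            include_optional = config$include_optional,
            glcm = unclass(config$glcm),
            udlm = unclass(config$udlm[c("pop_size", "max_iter", "seed")]))
  yaml::write_yaml(x, path)
  invisible(path)
}

# Atomic text write: temp file in the target directory, then rename.
.atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write ", path, call. = FALSE)
  invisible(path)
}

.write_csv <- function(df, path) {
  .atomic_write(function(p) utils::write.csv(df, p, row.names = FALSE),
                path)
}

.write_json <- function(x, path) {
  .atomic_write(function(p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE,
                                                 na = "null"),
                path)
}

#' Write the artifacts of a pipeline run
#'
#' Emits the stable file contracts into `out_dir`:
#' * `features.csv` — the per-image feature table;
#' * `assignments.csv` — `image_id, cluster, mapped_label, margin_score`;
#' * `metrics.json` — metrics, centers, objective, history, mapping, and the
#'   configuration/seeds (deterministic: no timestamps, so identical seeded
#'   runs are byte-identical);
#' * `manifest.json` — run manifest listing every artifact with its MD5
#'   content hash, plus package version, per-stage timings and warnings.
#'
#' All files are written atomically (temp file, then rename).
#'
#' @param run A `bcicm_run` (see [run_bcicm()]).
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_results <- function(run, out_dir) {
  stopifnot(inherits(run, "bcicm_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- run$features
  attr(feats, "errors") <- NULL
  .write_csv(feats, file.path(out_dir, "features.csv"))
  .write_csv(run$assignments, file.path(out_dir, "assignments.csv"))
  cfg <- run$config
  metrics <- list(
    metrics = if (is.null(run$metrics)) NULL else unclass(run$metrics),
    centers = lapply(seq_len(nrow(run$centers)),
                     function(i) unname(run$centers[i, ])),
    objective = run$objective,
    history = run$history,
    mapping = as.list(run$mapping),
    roc = if (is.null(run$roc)) NULL else
      run$roc[c("fpr", "tpr", "auc")],
    seed = cfg$udlm$seed,
    config = list(resolution = cfg$resolution,
                  feature_scaling = cfg$feature_scaling,
                  glcm = unclass(cfg$glcm),
                  udlm = unclass(cfg$udlm[c("pop_size", "max_iter",
                                            "seed")])))
  .write_json(metrics, file.path(out_dir, "metrics.json"))
  artifacts <- c("features.csv", "assignments.csv", "metrics.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
  names(hashes) <- artifacts
  manifest <- list(artifacts = hashes,
                   version = as.character(utils::packageVersion("bcicm")),
                   timings_sec = as.list(run$timings),
                   n_samples = nrow(run$assignments))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a feature table written by [write_results()] or the CLI
#'
#' @param path Path to a `features.csv`.
#' @return The feature data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.feature_cols, names(df))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
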