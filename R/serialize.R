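#' Serialize posterior draws to CSV
#'
#' Writes the stored draws in long format (`chain`, `iteration`, `parameter`,
#' `value`) together with the per-event pointwise log-likelihood matrix (one
#' row per posterior draw, one column per selection event, when stored) and a
#' JSON manifest recording the sampler configuration and seed.
#'
#' @param fit A `foraging_fit`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_fit_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "foraging_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- fit$draws
  pars <- dimnames(d)[[3]]
  long <- data.frame(
    chain = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), length(pars)),
    iteration = rep(seq_len(dim(d)[1]), dim(d)[2] * length(pars)),
    parameter = rep(pars, each = dim(d)[1] * dim(d)[2]),
    value = as.numeric(d)
  )
  dpath <- file.path(dir, "draws.csv")
  utils::write.csv(long, dpath, row.names = FALSE)
  paths <- dpath
  if (!is.null(fit$log_lik)) {
    lpath <- file.path(dir, "pointwise_loglik.csv")
    utils::write.csv(as.data.frame(fit$log_lik), lpath, row.names = FALSE)
    epath <- file.path(dir, "events.csv")
    utils::write.csv(fit$events, epath, row.names = FALSE)
    paths <- c(paths, lpath, epath)
  }
  write_run_manifest(
    file.path(dir, "manifest.json"), "fit",
    config = list(variant = fit$variant, half = fit$half,
                  chains = fit$meta$chains, warmup = fit$meta$warmup,
                  draws = fit$meta$draws),
    seed = if (is.null(fit$meta$seed)) NA else fit$meta$seed,
    outputs = basename(paths))
  invisible(c(paths, file.path(dir, "manifest.json")))
}

#' Serialize a model-comparison table
#'
#' Writes the ELPD comparison table as CSV and JSON.
#'
#' @param comparison A `foraging_comparison` (see
#'   [compare_foraging_models()]).
#' @param path_prefix Output path without extension; `.csv` and `.json` are
#'   appended.
#' @return Invisibly, the two file paths.
#' @export
write_comparison <- function(comparison, path_prefix) {
  stopifnot(inherits(comparison, "foraging_comparison"))
  cpath <- paste0(path_prefix, ".csv")
  jpath <- paste0(path_prefix, ".json")
  df <- as.data.frame(comparison)
  utils::write.csv(df, cpath, row.names = FALSE)
  jsonlite::write_json(df, jpath, digits = NA)
  invisible(c(cpath, jpath))
}

#' Read and write generator configuration files
#'
#' The session and colour-distribution settings round-trip through a nested
#' YAML file with a top-level `session` block and a nested `distribution`
#' block; omitted fields keep their defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return For `read_session_config()`, a [session_spec()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no config file at %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  sess <- cfg$session
  if (is.null(sess)) sess <- list()
  dist_args <- cfg$distribution
  if (is.null(dist_args)) dist_args <- list()
  dist <- do.call(distribution_spec, dist_args)
  if (!is.null(sess$quota_range)) sess$quota_range <- unlist(sess$quota_range)
  do.call(session_spec, c(sess, list(dist = dist)))
}

#' @param session A [session_spec()] to serialize.
#' @rdname read_session_config
#' @export
write_session_config <- function(session, path) {
  stopifnot(inherits(session, "session_spec"))
  dist <- session$dist
  yaml::write_yaml(list(
    session = list(n_trials = session$n_trials, shift = session$shift,
                   mu = session$mu, n_targets = session$n_targets,
                   n_distractors = session$n_distractors, grid = session$grid,
                   extent = session$extent, jitter = session$jitter,
                   disk_diameter = session$disk_diameter,
                   quota_range = as.integer(session$quota_range)),
    distribution = list(mu = dist$mu, sigma = dist$sigma,
                        half_span = dist$half_span, gap = dist$gap,
                        band_width = dist$band_width, n_hues = dist$n_hues)
  ), path)
  invisible(path)
}
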