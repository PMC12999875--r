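#' Construct a canonical foraging dataset
#'
#' The canonical container used throughout the package: per-item display
#' records, per-trial metadata, and the ordered selection (click) records.
#'
#' @param items Data frame: `participant`, `trial`, `item_id`, `hue`, `x`,
#'   `y`, `is_target`.
#' @param trials Data frame: `participant`, `trial`, `half`, `mu`, `quota`.
#' @param selections Data frame: `participant`, `trial`, `click_index`,
#'   `item_id`, optionally `rt` (seconds; carried through, never modelled).
#' @param n_hues Size of the circular colour space.
#' @param validate Run [validate_foraging_data()] on construction.
#' @return An object of class `foraging_data`.
#' @export
foraging_data <- function(items, trials, selections, n_hues = 48,
                          validate = TRUE) {
  obj <- structure(list(items = items, trials = trials,
                        selections = selections, n_hues = n_hues),
                   class = "foraging_data")
  if (validate) validate_foraging_data(obj)
  obj
}

#' Validate a foraging dataset
#'
#' Enforces the canonical-schema contracts: required columns present, hue and
#' position ranges, unique `(participant, trial, click_index)`, selected item
#' ids resolvable in their trial's display, and no repeated selection of an
#' item within a trial. All violations are collected and reported together.
#'
#' @param data A `foraging_data` object.
#' @return Invisibly, `data`; errors with an enumerated message otherwise.
#' @export
validate_foraging_data <- function(data) {
  stopifnot(inherits(data, "foraging_data"))
  errs <- character(0)
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      errs <<- c(errs, sprintf("%s is missing column(s): %s", name,
                               paste(miss, collapse = ", ")))
    length(miss) == 0L
  }
  it_ok <- need(data$items, c("participant", "trial", "item_id", "hue", "x", "y", "is_target"), "items")
  tr_ok <- need(data$trials, c("participant", "trial", "half", "mu", "quota"), "trials")
  se_ok <- need(data$selections, c("participant", "trial", "click_index", "item_id"), "selections")
  if (it_ok) {
    bad <- which(data$items$hue < 0 | data$items$hue >= data$n_hues)
    if (length(bad))
      errs <- c(errs, sprintf("items: hue out of [0, %d) in row(s) %s",
                              data$n_hues, paste(utils::head(bad, 10), collapse = ", ")))
    badp <- which(data$items$x < 0 | data$items$x > 1 | data$items$y < 0 | data$items$y > 1)
    if (length(badp))
      errs <- c(errs, sprintf("items: position outside the unit square in row(s) %s",
                              paste(utils::head(badp, 10), collapse = ", ")))
  }
  if (se_ok) {
    key <- paste(data$selections$participant, data$selections$trial,
                 data$selections$click_index)
    if (anyDuplicated(key))
      errs <- c(errs, sprintf("selections: duplicated (participant, trial, click_index): %s",
                              paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; ")))
    skey <- paste(data$selections$participant, data$selections$trial,
                  data$selections$item_id)
    if (anyDuplicated(skey))
      errs <- c(errs, sprintf(
        "selections: item selected twice within a trial (sampling is without replacement): %s",
        paste(utils::head(unique(skey[duplicated(skey)]), 5), collapse = "; ")))
  }
  if (se_ok && it_ok) {
    ikey <- paste(data$items$participant, data$items$trial, data$items$item_id)
    skey <- paste(data$selections$participant, data$selections$trial,
                  data$selections$item_id)
    bad <- which(!(skey %in% ikey))
    if (length(bad))
      errs <- c(errs, sprintf(
        "selections: item_id not present in its trial's display, row(s) %s",
        paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (se_ok && tr_ok) {
    tkey <- paste(data$trials$participant, data$trials$trial)
    stkey <- unique(paste(data$selections$participant, data$selections$trial))
    bad <- setdiff(stkey, tkey)
    if (length(bad))
      errs <- c(errs, sprintf("selections reference unknown trial(s): %s",
                              paste(utils::head(bad, 5), collapse = "; ")))
  }
  if (length(errs))
    stop(paste0("invalid foraging data:\n  - ", paste(errs, collapse = "\n  - ")),
         call. = FALSE)
  invisible(data)
}

# Rebuild a display object for one (participant, trial) from the dataset.
extract_display <- function(data, participant, trial) {
  it <- data$items[data$items$participant == participant &
                     data$items$trial == trial, , drop = FALSE]
  tr <- data$trials[data$trials$participant == participant &
                      data$trials$trial == trial, , drop = FALSE]
  if (nrow(it) == 0L || nrow(tr) != 1L)
    stop(sprintf("no display found for participant %s, trial %s", participant, trial),
         call. = FALSE)
  structure(list(items = it, mu = tr$mu, n_hues = data$n_hues, quota = tr$quota),
            class = "display")
}

#' Write a foraging dataset to canonical CSV files
#'
#' Writes `displays.csv` (one row per item, with the trial's half, quota and
#' designated hue joined on) and `selections.csv` into `dir`.
#'
#' @param data A `foraging_data` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_foraging_data <- function(data, dir) {
  stopifnot(inherits(data, "foraging_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  disp <- merge(data$items, data$trials, by = c("participant", "trial"), sort = FALSE)
  disp <- disp[order(disp$participant, disp$trial, disp$item_id),
               c("participant", "half", "trial", "item_id", "hue", "x", "y",
                 "is_target", "quota", "mu")]
  sel <- data$selections[order(data$selections$participant, data$selections$trial,
                               data$selections$click_index), , drop = FALSE]
  dpath <- file.path(dir, "displays.csv")
  spath <- file.path(dir, "selections.csv")
  utils::write.csv(disp, dpath, row.names = FALSE)
  utils::write.csv(sel, spath, row.names = FALSE)
  invisible(c(displays = dpath, selections = spath))
}

#' Read a foraging dataset from canonical CSV files
#'
#' @param dir Directory containing `displays.csv` and `selections.csv` (as
#'   written by [write_foraging_data()]).
#' @param n_hues Size of the circular colour space.
#' @return A validated `foraging_data` object.
#' @export
read_foraging_data <- function(dir, n_hues = 48) {
  dpath <- file.path(dir, "displays.csv")
  spath <- file.path(dir, "selections.csv")
  for (p in c(dpath, spath)) if (!file.exists(p))
    stop(sprintf("missing canonical file: %s", p), call. = FALSE)
  disp <- utils::read.csv(dpath)
  sel <- utils::read.csv(spath)
  items <- disp[, c("participant", "trial", "item_id", "hue", "x", "y", "is_target")]
  trials <- unique(disp[, c("participant", "trial", "half", "mu", "quota")])
  rownames(trials) <- NULL
  foraging_data(items, trials, sel, n_hues = n_hues)
}

#' Adapt externally formatted trial-level data to the canonical schema
#'
#' A thin adapter for datasets whose column names differ from the canonical
#' ones (for instance, externally deposited trial-level records). Columns are
#' renamed according to the mappings and the result is validated; a failed
#' adaptation therefore never yields a corrupt canonical object.
#'
#' @param items,trials,selections Data frames in the external layout.
#' @param item_map,trial_map,selection_map Named character vectors mapping
#'   canonical names to external names, e.g. `c(item_id = "object")`.
#'   Unmapped canonical columns are assumed to already be present.
#' @param n_hues Size of the circular colour space.
#' @return A validated `foraging_data` object.
#' @export
as_foraging_data <- function(items, trials, selections,
                             item_map = character(0), trial_map = character(0),
                             selection_map = character(0), n_hues = 48) {
  remap <- function(df, map) {
    for (canonical in names(map)) {
      ext <- map[[canonical]]
      if (!ext %in% names(df))
        stop(sprintf("mapped column '%s' not found", ext), call. = FALSE)
      names(df)[names(df) == ext] <- canonical
    }
    df
  }
  foraging_data(remap(items, item_map), remap(trials, trial_map),
                remap(selections, selection_map), n_hues = n_hues)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: the command, a config
#' snapshot, the seed, the package version and a timestamp. Every pipeline
#' stage that writes files writes exactly one manifest alongside them.
#'
#' @param path Output JSON path.
#' @param command Short name of the stage (e.g. "simulate").
#' @param config List snapshot of the configuration used.
#' @param seed The RNG seed driving the stage (or `NA`).
#' @param inputs,outputs Character vectors of file paths.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NA,
                               inputs = character(0), outputs = character(0)) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("hueforage")),
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.foraging_data <- function(x, ...) {
  cat(sprintf(
    "<foraging_data> %d participants, %d trials, %d items, %d selections (%d-hue space)\n",
    length(unique(data_participants(x))), nrow(x$trials), nrow(x$items),
    nrow(x$selections), x$n_hues))
  invisible(x)
}

data_participants <- function(data) sort(unique(data$trials$participant))
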