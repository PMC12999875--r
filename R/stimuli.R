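#' Specify a target/distractor colour distribution
#'
#' Targets are drawn from a truncated Gaussian on the hue circle: parent SD
#' `sigma` JND, truncated at `mu +/- half_span` JND (a 16-JND total span under
#' the defaults). Distractors come from two uniform bands of `band_width`
#' integer hue steps each, offset `gap` JND beyond the truncation bounds on
#' either side, so with the defaults distractor hues lie 11--18 JND from `mu`.
#'
#' @param mu Designated hue index: the centre of the target distribution.
#' @param sigma Parent SD of the target Gaussian, in JND.
#' @param half_span Truncation half-width, in JND.
#' @param gap Offset of each distractor band from the truncation bound, in JND.
#' @param band_width Width of each distractor band, in integer hue steps.
#' @param n_hues Number of hues on the circular colour space.
#' @return An object of class `distribution_spec`.
#' @export
distribution_spec <- function(mu = 24, sigma = 4, half_span = 8, gap = 3,
                              band_width = 8, n_hues = 48) {
  stopifnot(sigma > 0, half_span > 0, gap >= 0, band_width > 0, n_hues >= 2)
  if (mu < 0 || mu >= n_hues)
    stop("`mu` must lie in [0, n_hues)", call. = FALSE)
  occupied <- 2 * half_span + 2 * gap + 2 * band_width
  if (occupied > n_hues)
    stop(sprintf(
      "target span, gaps and distractor bands occupy %s JND but the circle only has %s hues",
      occupied, n_hues), call. = FALSE)
  structure(
    list(mu = mu, sigma = sigma, half_span = half_span, gap = gap,
         band_width = band_width, n_hues = n_hues),
    class = "distribution_spec"
  )
}

#' Specify a foraging session
#'
#' Defaults reproduce the study design: 48 trials split into two halves with
#' the colour distribution shifted by 24 JND (the opposite end of the 48-hue
#' circle) at the midpoint; 30 targets and 30 distractors per display, placed
#' on a jittered 8 x 8 grid spanning 11 x 11 degrees; each trial ends after a
#' randomised quota of 18--28 target selections.
#'
#' @param n_trials Total trials; must be even so halves split equally.
#' @param shift JND displacement of the second-half distribution.
#' @param mu First-half designated hue index.
#' @param n_targets,n_distractors Items per display.
#' @param grid Cells per side of the invisible placement grid.
#' @param extent Grid extent in degrees of visual angle (per side).
#' @param jitter Total positional jitter per axis, in degrees.
#' @param disk_diameter Item diameter in degrees (metadata only).
#' @param quota_range Inclusive integer range the per-trial target quota is
#'   drawn from, uniformly.
#' @param dist Optional `distribution_spec` giving the colour-space geometry;
#'   its `mu` is overridden per half.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_trials = 48, shift = 24, mu = 24,
                         n_targets = 30, n_distractors = 30,
                         grid = 8, extent = 11, jitter = 1,
                         disk_diameter = 0.5, quota_range = c(18L, 28L),
                         dist = distribution_spec(mu = mu)) {
  stopifnot(n_trials >= 2, n_trials %% 2 == 0,
            n_targets >= 1, n_distractors >= 0,
            grid >= 1, extent > 0, jitter >= 0,
            length(quota_range) == 2, quota_range[1] <= quota_range[2],
            quota_range[1] >= 1)
  if (shift < 0 || shift > dist$n_hues / 2)
    stop("`shift` must lie in [0, n_hues / 2]", call. = FALSE)
  if (n_targets + n_distractors > grid^2)
    stop("more items than grid cells", call. = FALSE)
  dist$mu <- mu
  structure(
    list(n_trials = n_trials, shift = shift, mu = mu,
         n_targets = n_targets, n_distractors = n_distractors,
         grid = grid, extent = extent, jitter = jitter,
         disk_diameter = disk_diameter,
         quota_range = as.integer(quota_range), dist = dist),
    class = "session_spec"
  )
}

#' Sample target hues from the truncated Gaussian
#'
#' Draws from Normal(`mu`, `sigma`) truncated to `mu +/- half_span` by inverse
#' CDF sampling, rounds to the nearest integer hue index, and wraps onto the
#' circle. Every returned hue is within circular distance `half_span` of `mu`.
#'
#' @param spec A [distribution_spec()].
#' @param n Number of draws.
#' @return Integer vector of hue indices.
#' @export
sample_target_hues <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  a <- stats::pnorm(-spec$half_span / spec$sigma)
  b <- stats::pnorm(spec$half_span / spec$sigma)
  dev <- spec$sigma * stats::qnorm(stats::runif(n, a, b))
  # qnorm at the exact bounds returns +/- half_span; rounding keeps |dev| <= half_span
  wrap_hue(as.integer(round(spec$mu + dev)), spec$n_hues)
}

#' Sample distractor hues from the two flanking uniform bands
#'
#' Each distractor offset is drawn uniformly from the `band_width` integer
#' steps `{half_span + gap, ..., half_span + gap + band_width - 1}` and placed
#' on a uniformly chosen side of `mu`, so the two bands are balanced in
#' expectation and no distractor lies within `half_span + gap` of `mu`.
#'
#' @inheritParams sample_target_hues
#' @return Integer vector of hue indices.
#' @export
sample_distractor_hues <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  lo <- spec$half_span + spec$gap
  offsets <- seq.int(lo, lo + spec$band_width - 1)
  if (max(offsets) > spec$n_hues / 2)
    stop("distractor bands overlap on the far side of the circle", call. = FALSE)
  d <- sample(offsets, n, replace = TRUE)
  side <- sample(c(-1L, 1L), n, replace = TRUE)
  wrap_hue(as.integer(round(spec$mu)) + side * d, spec$n_hues)
}

#' Place items on a jittered invisible grid
#'
#' Chooses `n_items` distinct cells of a `grid` x `grid` lattice spanning
#' `extent` degrees per side, jitters each cell centre uniformly by
#' `+/- jitter / 2` per axis, and maps degrees affinely to the unit square.
#' All model-side spatial computation uses these normalized coordinates.
#'
#' @param n_items Number of positions (must not exceed `grid^2`).
#' @param grid Cells per side.
#' @param extent Lattice extent in degrees.
#' @param jitter Total jitter per axis in degrees.
#' @return A data frame with columns `x` and `y` in `[0, 1]`.
#' @export
generate_layout <- function(n_items, grid = 8, extent = 11, jitter = 1) {
  stopifnot(n_items >= 1, grid >= 1, extent > 0, jitter >= 0)
  if (n_items > grid^2)
    stop(sprintf("n_items (%d) exceeds the %d available grid cells", n_items, grid^2),
         call. = FALSE)
  cell <- extent / grid
  cells <- sample.int(grid^2, n_items)  # without replacement
  cx <- ((cells - 1) %% grid + 0.5) * cell
  cy <- ((cells - 1) %/% grid + 0.5) * cell
  x <- cx + stats::runif(n_items, -jitter / 2, jitter / 2)
  y <- cy + stats::runif(n_items, -jitter / 2, jitter / 2)
  data.frame(x = x / extent, y = y / extent)
}

#' Generate a single foraging display
#'
#' Samples target and distractor hues, assigns them to jittered grid positions
#' uniformly at random, and draws the trial's target quota uniformly from the
#' session's quota range.
#'
#' @param spec A [distribution_spec()] (the half's colour distribution).
#' @param session A [session_spec()].
#' @return An object of class `display`: a list with `items` (data frame:
#'   `item_id`, `hue`, `x`, `y`, `is_target`), `mu`, `n_hues`, and `quota`.
#' @export
generate_display <- function(spec, session = session_spec()) {
  stopifnot(inherits(spec, "distribution_spec"), inherits(session, "session_spec"))
  nt <- session$n_targets
  nd <- session$n_distractors
  hues <- c(sample_target_hues(spec, nt),
            if (nd > 0) sample_distractor_hues(spec, nd) else integer(0))
  pos <- generate_layout(nt + nd, session$grid, session$extent, session$jitter)
  assign_order <- sample.int(nt + nd)  # random hue -> position assignment
  items <- data.frame(
    item_id = seq_len(nt + nd),
    hue = hues,
    x = pos$x[assign_order],
    y = pos$y[assign_order],
    is_target = rep(c(TRUE, FALSE), c(nt, nd))
  )
  quota <- sample(seq.int(session$quota_range[1], session$quota_range[2]), 1L)
  structure(list(items = items, mu = spec$mu, n_hues = spec$n_hues,
                 quota = quota, spec = spec),
            class = "display")
}

#' Generate a full session of displays
#'
#' The first `n_trials / 2` displays use the session's first-half distribution
#' centre; the remainder use the centre shifted by `shift` JND around the
#' circle. Hue samples are independent across trials.
#'
#' @param session A [session_spec()].
#' @return A list of length `n_trials`; each element has `half` (1 or 2),
#'   `trial`, and `display`.
#' @export
generate_session <- function(session = session_spec()) {
  stopifnot(inherits(session, "session_spec"))
  n <- session$n_trials
  mu2 <- wrap_hue(session$mu + session$shift, session$dist$n_hues)
  spec1 <- session$dist; spec1$mu <- session$mu
  spec2 <- session$dist; spec2$mu <- mu2
  lapply(seq_len(n), function(t) {
    half <- if (t <= n / 2) 1L else 2L
    list(half = half, trial = t,
         display = generate_display(if (half == 1L) spec1 else spec2, session))
  })
}
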