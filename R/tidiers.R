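#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a switching-segment fit
#'
#' @param x An `rt_switch_fit` from [rt_switch_test()].
#' @param ... Unused.
#' @return The per-segment call tibble.
#' @export
tidy.rt_switch_fit <- function(x, ...) x$calls

#' One-row summary of a switching-segment fit
#'
#' @inheritParams tidy.rt_switch_fit
#' @return One-row tibble: segment counts by class, `pi0`, `q_cutoff`,
#'   `null_size`.
#' @export
glance.rt_switch_fit <- function(x, ...) {
  cls <- x$calls$class
  tibble::tibble(
    n_segments = nrow(x$calls),
    n_masked = sum(cls == "masked"),
    n_etol = sum(cls == "EtoL"),
    n_ltoe = sum(cls == "LtoE"),
    n_etoe = sum(cls == "EtoE"),
    n_ltol = sum(cls == "LtoL"),
    pi0 = x$pi0,
    q_cutoff = x$q_cutoff,
    null_size = length(x$null_pool)
  )
}

#' Tidy a fiber analysis
#'
#' @param x A `fiber_analysis` from [analyze_fibers()].
#' @param ... Unused.
#' @return Per-track fork speeds.
#' @export
tidy.fiber_analysis <- function(x, ...) x$speeds

#' One-row summary of a fiber analysis
#'
#' @inheritParams tidy.fiber_analysis
#' @return One-row tibble with the calibrated stretch factor, fork-speed and
#'   inter-origin-distance summaries.
#' @export
glance.fiber_analysis <- function(x, ...) {
  tibble::tibble(
    stretch_kb_per_um = x$stretch$stretch_kb_per_um,
    stretch_sd = x$stretch$sd,
    fork_speed_mean = if (nrow(x$speeds)) mean(x$speeds$speed_kb_per_min) else NA_real_,
    fork_speed_median = if (nrow(x$speeds)) stats::median(x$speeds$speed_kb_per_min) else NA_real_,
    n_forks = nrow(x$speeds),
    interorigin_mean_kb = if (nrow(x$distances)) mean(x$distances$distance_kb) else NA_real_,
    interorigin_median_kb = if (nrow(x$distances)) stats::median(x$distances$distance_kb) else NA_real_,
    n_distances = nrow(x$distances),
    n_origins = nrow(x$origins)
  )
}
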