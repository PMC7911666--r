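#' Calibrate the combing stretch factor from lambda-DNA molecules
#'
#' Combed lambda-phage genomes (48.5 kb) of measured length give the
#' kb-per-micrometer stretch factor as `48.5 / mean(lengths)`. The factor's
#' standard deviation is propagated from the length standard deviation by the
#' delta method (`sd_factor = 48.5 * sd(L) / mean(L)^2`), and the standard
#' error of the calibrated mean is `sd_factor / sqrt(n)`.
#'
#' @param lambda_lengths Measured lambda molecule lengths in micrometers.
#' @param genome_kb Reference genome length (48.5 kb for lambda).
#' @return One-row tibble: `stretch_kb_per_um`, `sd`, `se`, `n`.
#' @examples
#' calibrate_stretch(c(24.25, 24.25)) # exactly 2 kb/um
#' @export
calibrate_stretch <- function(lambda_lengths, genome_kb = 48.5) {
  x <- lambda_lengths[!is.na(lambda_lengths)]
  if (length(x) == 0 || any(x <= 0)) {
    stop("lambda lengths must be positive and non-empty")
  }
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  sd_f <- genome_kb * s / m^2
  tibble::tibble(stretch_kb_per_um = genome_kb / m, sd = sd_f,
                 se = sd_f / sqrt(length(x)), n = length(x))
}

#' Replication fork speed from a labeled track
#'
#' `speed = length_um * stretch / label_minutes` in kb/min: a second-label
#' track laid down by a single fork over the full pulse measures that fork's
#' speed directly.
#'
#' @param track_length_um Track length(s) in micrometers.
#' @param stretch_kb_per_um Stretch factor from [calibrate_stretch()].
#' @param label_minutes Pulse duration in minutes.
#' @return Fork speed(s) in kb/min.
#' @export
fork_speed <- function(track_length_um, stretch_kb_per_um, label_minutes = 20) {
  if (any(track_length_um <= 0) || stretch_kb_per_um <= 0 || label_minutes <= 0) {
    stop("track length, stretch factor and label time must be positive")
  }
  track_length_um * stretch_kb_per_um / label_minutes
}

# Per-molecule neighbour bookkeeping: gaps to the previous/next track and
# whether each side has an adjacent (gap < tol) track of a given label.
fiber_neighbours <- function(fibers, adjacency_tol_um = 1) {
  stopifnot(all(c("molecule_id", "label", "start_um", "length_um",
                  "molecule_length_um") %in% names(fibers)))
  fb <- dplyr::arrange(fibers, .data$molecule_id, .data$start_um)
  fb <- dplyr::group_by(fb, .data$molecule_id)
  fb <- dplyr::mutate(
    fb,
    end_um = .data$start_um + .data$length_um,
    gap_prev = .data$start_um - dplyr::lag(.data$end_um),
    gap_next = dplyr::lead(.data$start_um) - .data$end_um,
    prev_label = dplyr::lag(.data$label),
    next_label = dplyr::lead(.data$label),
    adj_prev = !is.na(.data$gap_prev) & .data$gap_prev < adjacency_tol_um,
    adj_next = !is.na(.data$gap_next) & .data$gap_next < adjacency_tol_um
  )
  dplyr::ungroup(fb)
}

#' Fork speeds from a fiber track table
#'
#' Selects the second-label tracks that measure one fork over the full second
#' pulse: adjacent to a first-label track on exactly one side, open
#' (unlabeled DNA or no track within the adjacency tolerance) on the other
#' side, and not touching a molecule end. Tracks bounded by first-label on
#' both sides are fused converging forks and tracks at molecule ends are
#' censored; both would bias the speed downward or upward, so they are
#' excluded.
#'
#' @param fibers Fiber track tibble (`molecule_id`, `track_index`, `label`,
#'   `start_um`, `length_um`, `molecule_length_um`).
#' @param stretch_kb_per_um Stretch factor.
#' @param label_minutes Second-pulse duration in minutes.
#' @param adjacency_tol_um Maximum gap for two tracks to count as adjacent.
#' @param edge_tol_um Distance to a molecule end below which a track counts
#'   as touching it.
#' @return Tibble `molecule_id`, `track_index`, `length_um`,
#'   `speed_kb_per_min`.
#' @export
measure_fork_speeds <- function(fibers, stretch_kb_per_um, label_minutes = 20,
                                adjacency_tol_um = 1, edge_tol_um = 0.5) {
  fb <- fiber_neighbours(fibers, adjacency_tol_um)
  first_prev <- fb$adj_prev & fb$prev_label == "first"
  first_next <- fb$adj_next & fb$next_label == "first"
  open_prev <- !fb$adj_prev
  open_next <- !fb$adj_next
  interior <- fb$start_um > edge_tol_um &
    fb$end_um < fb$molecule_length_um - edge_tol_um
  keep <- fb$label == "second" & interior &
    ((first_prev & open_next) | (first_next & open_prev))
  out <- fb[keep, c("molecule_id", "track_index", "length_um")]
  out$speed_kb_per_min <- fork_speed(out$length_um, stretch_kb_per_um,
                                     label_minutes)
  tibble::as_tibble(out)
}

#' Locate replication origins on fiber molecules
#'
#' Under first-then-second pulse labeling, a bidirectional origin that fired
#' during the first pulse leaves a first-label track flanked by second-label
#' tracks on both sides; the origin sits at the midpoint of the first-label
#' track. First-label tracks touching a molecule end are excluded (their
#' midpoint is censored). Molecules without the signature yield no origins.
#'
#' @inheritParams measure_fork_speeds
#' @return Tibble `molecule_id`, `position_um`.
#' @export
find_origins <- function(fibers, adjacency_tol_um = 1, edge_tol_um = 0.5) {
  fb <- fiber_neighbours(fibers, adjacency_tol_um)
  keep <- fb$label == "first" &
    fb$adj_prev & fb$prev_label == "second" &
    fb$adj_next & fb$next_label == "second" &
    fb$start_um > edge_tol_um &
    fb$end_um < fb$molecule_length_um - edge_tol_um
  tibble::tibble(molecule_id = fb$molecule_id[keep],
                 position_um = fb$start_um[keep] + fb$length_um[keep] / 2)
}

#' Inter-origin distances
#'
#' Center-to-center distances between adjacent origins on the same molecule,
#' converted to kb. Molecules with fewer than two origins contribute nothing.
#'
#' @param origins Tibble from [find_origins()].
#' @param stretch_kb_per_um Stretch factor.
#' @return Tibble `molecule_id`, `distance_kb`.
#' @export
interorigin_distances <- function(origins, stretch_kb_per_um) {
  if (stretch_kb_per_um <= 0) stop("stretch factor must be positive")
  purrr::map_dfr(split(origins, origins$molecule_id), function(df) {
    if (nrow(df) < 2) return(NULL)
    pos <- sort(df$position_um)
    tibble::tibble(molecule_id = df$molecule_id[1],
                   distance_kb = diff(pos) * stretch_kb_per_um)
  })
}

#' Complete DNA-combing analysis
#'
#' Calibrates the stretch factor from lambda molecules, measures fork speeds
#' on qualifying second-label tracks, locates origins and computes
#' inter-origin distances.
#'
#' @param fibers Fiber track tibble (see [measure_fork_speeds()]).
#' @param lambda_lengths Lambda molecule lengths in micrometers.
#' @param label_minutes Second-pulse duration in minutes.
#' @param adjacency_tol_um,edge_tol_um See [measure_fork_speeds()].
#' @return An object of class `fiber_analysis`: list with `stretch` (tibble
#'   from [calibrate_stretch()]), `speeds`, `origins`, `distances`.
#'   [generics::tidy()] returns per-track speeds, [generics::glance()] the
#'   one-row summary.
#' @export
analyze_fibers <- function(fibers, lambda_lengths, label_minutes = 20,
                           adjacency_tol_um = 1, edge_tol_um = 0.5) {
  stretch <- calibrate_stretch(lambda_lengths)
  f <- stretch$stretch_kb_per_um
  speeds <- measure_fork_speeds(fibers, f, label_minutes,
                                adjacency_tol_um, edge_tol_um)
  origins <- find_origins(fibers, adjacency_tol_um, edge_tol_um)
  distances <- interorigin_distances(origins, f)
  structure(list(stretch = stretch, speeds = speeds, origins = origins,
                 distances = distances, label_minutes = label_minutes),
            class = "fiber_analysis")
}

#' @export
print.fiber_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fiber_analysis> stretch %.3f kb/um (sd %.3f, n = %d lambda)\n",
              g$stretch_kb_per_um, g$stretch_sd, x$stretch$n))
  cat(sprintf("  fork speed: mean %.3f kb/min (n = %d tracks)\n",
              g$fork_speed_mean, g$n_forks))
  cat(sprintf("  inter-origin distance: mean %.1f kb, median %.1f kb (n = %d)\n",
              g$interorigin_mean_kb, g$interorigin_median_kb, g$n_distances))
  invisible(x)
}
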