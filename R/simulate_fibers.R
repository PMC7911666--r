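#' Simulate combed DNA fibers with IdU/CldU replication tracks
#'
#' Emulates a two-pulse fiber-labeling experiment on combed DNA. Origins are
#' placed along each molecule by a renewal process with gamma-distributed
#' spacings (quasi-regular origin spacing), all firing at the start of the
#' first pulse. Both forks of each origin progress outward at the fork speed;
#' converging forks of adjacent origins stop where they meet. DNA replicated
#' during the first `label_minutes[1]` minutes carries the first label (IdU),
#' DNA replicated during the next `label_minutes[2]` minutes the second label
#' (CldU); DNA not replicated within the pulses is unlabeled. An isolated
#' origin therefore yields a central first-label track of length
#' `2 * v * t1` flanked by two second-label tracks of `v * t2` each. Track
#' coordinates are converted to micrometers with the stretch factor and the
#' measured lengths are jittered. Lambda-phage calibration molecules (48.5 kb)
#' are drawn as `Normal(48.5 / stretch, lambda_len_sd_um)`.
#'
#' @param fork_speed_kb_min True fork speed in kb/min.
#' @param ori_spacing_kb Mean inter-origin spacing in kb.
#' @param spacing_shape Gamma shape of the spacing distribution (larger =
#'   more regular spacing).
#' @param label_minutes Length-2 vector: first and second pulse duration.
#' @param stretch_kb_per_um True combing stretch factor (kb per micrometer).
#' @param n_molecules Number of fiber molecules.
#' @param molecule_kb Molecule length in kb. Keep this large relative to the
#'   origin spacing (the default is 10x): on short molecules, long
#'   inter-origin gaps are preferentially censored at the ends, biasing the
#'   observed spacing downward (fiber length bias).
#' @param jitter_um_sd Measurement noise SD added to track lengths (um).
#' @param n_lambda Number of lambda calibration molecules.
#' @param lambda_len_sd_um SD of measured lambda molecule lengths (um).
#' @param seed Integer seed.
#' @return List with `fibers` (tibble `molecule_id`, `track_index`, `label`,
#'   `start_um`, `length_um`, `molecule_length_um`), `lambda` (tibble
#'   `molecule_id`, `length_um`) and `truth` (the generating parameters).
#' @export
simulate_fibers <- function(fork_speed_kb_min = 1.5, ori_spacing_kb = 150,
                            spacing_shape = 10, label_minutes = c(20, 20),
                            stretch_kb_per_um = 2.32, n_molecules = 200,
                            molecule_kb = 1500, jitter_um_sd = 0.3,
                            n_lambda = 100, lambda_len_sd_um = 1, seed = 1L) {
  if (fork_speed_kb_min <= 0 || ori_spacing_kb <= 0 || any(label_minutes <= 0) ||
      stretch_kb_per_um <= 0 || molecule_kb <= 0) {
    stop("rates, spacings, lengths and pulse times must be positive")
  }
  v <- fork_speed_kb_min
  t1 <- label_minutes[1]
  t2 <- label_minutes[2]
  reach <- v * (t1 + t2)

  withr::with_seed(seed, {
    fibers <- purrr::map_dfr(seq_len(n_molecules), function(m) {
      # renewal origin process covering the molecule plus one fork reach
      gaps <- stats::rgamma(ceiling(3 * (molecule_kb + 4 * reach) / ori_spacing_kb) + 8,
                            shape = spacing_shape,
                            scale = ori_spacing_kb / spacing_shape)
      ori <- cumsum(gaps) - reach - stats::runif(1, 0, ori_spacing_kb)
      ori <- ori[ori > -reach & ori < molecule_kb + reach]
      if (length(ori) == 0) return(NULL)
      tr <- fiber_tracks_kb(ori, molecule_kb, v, t1, t2)
      if (nrow(tr) == 0) return(NULL)
      len_um <- pmax((tr$end - tr$start) / stretch_kb_per_um +
                       stats::rnorm(nrow(tr), 0, jitter_um_sd), 0.05)
      tibble::tibble(
        molecule_id = sprintf("mol%04d", m),
        track_index = seq_len(nrow(tr)),
        label = tr$label,
        start_um = tr$start / stretch_kb_per_um,
        length_um = len_um,
        molecule_length_um = molecule_kb / stretch_kb_per_um
      )
    })
    lambda <- tibble::tibble(
      molecule_id = sprintf("lambda%04d", seq_len(n_lambda)),
      length_um = stats::rnorm(n_lambda, 48.5 / stretch_kb_per_um, lambda_len_sd_um)
    )
    list(fibers = fibers, lambda = lambda,
         truth = list(fork_speed_kb_min = v, ori_spacing_kb = ori_spacing_kb,
                      stretch_kb_per_um = stretch_kb_per_um,
                      label_minutes = label_minutes))
  })
}

# Labeled track intervals (kb coordinates on [0, L]) for origins `ori` firing
# synchronously at t = 0, forks at speed v, pulses t1 then t2. The time a
# position is replicated is dist-to-nearest-flanking-origin / v (converging
# forks meet at the midpoint between adjacent origins).
fiber_tracks_kb <- function(ori, L, v, t1, t2) {
  ori <- sort(ori)
  mids <- if (length(ori) > 1) (ori[-1] + ori[-length(ori)]) / 2 else numeric()
  cuts <- sort(unique(pmin(pmax(c(
    0, L, ori, mids,
    ori - v * t1, ori + v * t1,
    ori - v * (t1 + t2), ori + v * (t1 + t2)
  ), 0), L)))
  cuts <- cuts[!duplicated(signif(cuts, 12))]
  if (length(cuts) < 2) return(tibble::tibble(label = character(),
                                              start = numeric(), end = numeric()))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  mid <- (lo + hi) / 2
  # replication time at each probe position
  idx <- findInterval(mid, ori)
  d_left <- ifelse(idx >= 1, mid - ori[pmax(idx, 1)], Inf)
  d_right <- ifelse(idx < length(ori), ori[pmin(idx + 1, length(ori))] - mid, Inf)
  tau <- pmin(d_left, d_right) / v
  label <- ifelse(tau <= t1, "first", ifelse(tau <= t1 + t2, "second", NA))
  keep <- !is.na(label) & (hi - lo) > 1e-9
  out <- tibble::tibble(label = label[keep], start = lo[keep], end = hi[keep])
  if (nrow(out) <= 1) return(out)
  # merge touching intervals with the same label
  run <- cumsum(c(TRUE, out$label[-1] != out$label[-nrow(out)] |
                    abs(out$start[-1] - out$end[-nrow(out)]) > 1e-9))
  dplyr::summarise(dplyr::group_by(out, run = run),
                   label = .data$label[1], start = min(.data$start),
                   end = max(.data$end), .groups = "drop")[, c("label", "start", "end")]
}
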