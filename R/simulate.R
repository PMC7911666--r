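#' Simulate a domain-structured replication-timing landscape
#'
#' Generates a ground-truth replication timing (RT) landscape on the log2
#' early/late scale: replication-domain boundaries are placed by a Poisson
#' process along each chromosome, and each domain draws a timing level from a
#' two-component mixture (early and late domains), giving the periodic
#' alternation of Mb-sized early and late replication domains seen in
#' mammalian genomes. The truth is piecewise constant across bins.
#'
#' @param layout A [genome_layout()].
#' @param mean_domain_kb Mean domain length in kb (Poisson boundary process).
#'   Must be at least twice the segment size.
#' @param rt_levels Numeric vector of mixture component centres on the
#'   log2(early/late) scale; a component is drawn uniformly per domain.
#'   A single value gives a degenerate (constant-level) landscape.
#' @param rt_sd Standard deviation of per-domain timing around its component
#'   centre.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `rt_truth`: list with `bins` (tibble `chrom`,
#'   `start`, `end`, `bin`, `domain`, `rt`), `domains` (tibble of domain
#'   intervals with their timing level) and `layout`.
#' @examples
#' layout <- genome_layout(c(chr1 = 10e6))
#' truth <- simulate_rt_landscape(layout, seed = 7)
#' head(truth$bins)
#' @export
simulate_rt_landscape <- function(layout, mean_domain_kb = 1500,
                                  rt_levels = c(1.5, -1.5), rt_sd = 0.5,
                                  seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (mean_domain_kb * 1000 < 2 * layout$segment_size) {
    stop("mean_domain_kb too small: must be at least twice the segment size")
  }
  withr::with_seed(seed, {
    bins <- layout_bins(layout)
    domains <- purrr::map2_dfr(layout$chroms$chrom, layout$chroms$length, function(ch, len) {
      n_b <- stats::rpois(1, len / (mean_domain_kb * 1000))
      bounds <- sort(stats::runif(n_b, 0, len))
      starts <- c(0, bounds)
      tibble::tibble(chrom = ch, start = starts, end = c(bounds, len))
    })
    domains$domain <- seq_len(nrow(domains))
    centre <- rt_levels[sample.int(length(rt_levels), nrow(domains), replace = TRUE)]
    domains$rt <- stats::rnorm(nrow(domains), centre, rt_sd)

    # assign each bin the domain containing its start
    bins$domain <- NA_integer_
    for (ch in layout$chroms$chrom) {
      i <- bins$chrom == ch
      d <- domains[domains$chrom == ch, ]
      bins$domain[i] <- d$domain[findInterval(bins$start[i], d$start)]
    }
    bins$rt <- domains$rt[bins$domain]
    structure(list(bins = bins, domains = domains, layout = layout),
              class = "rt_truth")
  })
}

#' @export
print.rt_truth <- function(x, ...) {
  cat(sprintf("<rt_truth> %d bins, %d domains, rt range [%.2f, %.2f]\n",
              nrow(x$bins), nrow(x$domains), min(x$bins$rt), max(x$bins$rt)))
  invisible(x)
}

#' Plant replication-timing switches into a second condition
#'
#' Takes a ground-truth landscape (condition A) and produces condition B by
#' shifting whole 200-kb segments: early segments shifted by `-delta`
#' (early-to-late, EtoL) and late segments by `+delta` (late-to-early, LtoE).
#' Eligible segments are those whose true mean timing is clearly early or
#' late (`|mean rt| >= rt_margin`), since a switch is only well defined when
#' it crosses the early/late boundary. All other bins are untouched, and the
#' returned switch table records exactly the edits made.
#'
#' @param truth An `rt_truth` (condition A).
#' @param n_switch Number of segments to switch (drawn from the eligible
#'   pool; direction follows each segment's sign).
#' @param delta_magnitude Absolute timing shift applied to switched segments.
#' @param rt_margin Minimum |segment mean rt| for eligibility.
#' @param seed Integer seed.
#' @return List with `truth` (condition B as an `rt_truth`) and `switches`
#'   (tibble `segment`, `chrom`, `start`, `end`, `direction`, `delta`).
#' @export
plant_switches <- function(truth, n_switch, delta_magnitude = 1.5,
                           rt_margin = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "rt_truth"))
  layout <- truth$layout
  segs <- layout_segments(layout)
  bins <- add_segment_index(truth$bins, layout)
  seg_mean <- dplyr::summarise(dplyr::group_by(bins, .data$segment),
                               rt = mean(.data$rt), .groups = "drop")
  eligible <- seg_mean[abs(seg_mean$rt) >= rt_margin, ]
  if (n_switch > nrow(eligible)) {
    stop(sprintf("n_switch (%d) exceeds eligible segments (%d)",
                 n_switch, nrow(eligible)))
  }
  withr::with_seed(seed, {
    pick <- eligible[sample.int(nrow(eligible), n_switch), ]
  })
  pick$direction <- ifelse(pick$rt > 0, "EtoL", "LtoE")
  pick$delta <- ifelse(pick$direction == "EtoL", -delta_magnitude, delta_magnitude)

  bins_b <- bins
  hit <- match(bins_b$segment, pick$segment)
  shift <- ifelse(is.na(hit), 0, pick$delta[hit])
  bins_b$rt <- bins_b$rt + shift
  bins_b$segment <- NULL

  switches <- dplyr::left_join(pick[, c("segment", "direction", "delta")],
                               segs[, c("segment", "chrom", "start", "end")],
                               by = "segment")
  switches <- switches[order(switches$segment),
                       c("segment", "chrom", "start", "end", "direction", "delta")]
  truth_b <- structure(list(bins = bins_b, domains = truth$domains, layout = layout),
                       class = "rt_truth")
  list(truth = truth_b, switches = tibble::as_tibble(switches))
}

#' Simulate early/late Repli-seq count tracks
#'
#' For each replicate, a bin-level latent timing `rt + N(0, replicate_noise_sd)`
#' is mapped through the logit link `p = 1 / (1 + 2^-rt)` to an early-read
#' weight (so `rt = log2(p / (1-p))`, keeping the simulator on the same scale
#' the pipeline estimates). Early and late counts are Poisson with bin rates
#' proportional to `p` and `1 - p` respectively, scaled to library sizes drawn
#' uniformly within +/-20% of the nominal depth. Replicate noise enters the
#' latent timing, not the counts, mimicking biological replicate variation.
#'
#' @param truth An `rt_truth`.
#' @param depth_per_fraction Expected mean reads per bin in each fraction
#'   (total library size is this times the number of bins, before the +/-20%
#'   library-size draw).
#' @param replicate_noise_sd SD of per-bin latent timing noise per replicate.
#' @param n_replicates Number of replicates to simulate.
#' @param sample_prefix Prefix for the `sample` column (`<prefix>_rep<i>`).
#' @param seed Integer seed.
#' @return A long tibble: `chrom`, `start`, `end`, `bin`, `sample`,
#'   `fraction` (`"early"`/`"late"`), `count`.
#' @export
simulate_counts <- function(truth, depth_per_fraction = 20,
                            replicate_noise_sd = 0.3, n_replicates = 2,
                            sample_prefix = "s", seed = 1L) {
  stopifnot(inherits(truth, "rt_truth"))
  if (depth_per_fraction <= 0) stop("depth_per_fraction must be positive")
  bins <- truth$bins
  n <- nrow(bins)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      latent <- bins$rt + stats::rnorm(n, 0, replicate_noise_sd)
      p <- 1 / (1 + 2^(-latent))
      d_e <- stats::runif(1, 0.8, 1.2) * depth_per_fraction * n
      d_l <- stats::runif(1, 0.8, 1.2) * depth_per_fraction * n
      early <- stats::rpois(n, d_e * p / sum(p))
      late <- stats::rpois(n, d_l * (1 - p) / sum(1 - p))
      tibble::tibble(
        chrom = rep(bins$chrom, 2),
        start = rep(bins$start, 2),
        end = rep(bins$end, 2),
        bin = rep(bins$bin, 2),
        sample = paste0(sample_prefix, "_rep", r),
        fraction = rep(c("early", "late"), each = n),
        count = c(early, late)
      )
    })
  })
}

#' Simulate per-segment ChIP deltas and a coupled gene-expression table
#'
#' Produces the two integration inputs with known ground truth: a per-segment
#' ChIP enrichment change constructed as
#' `coupling_r * z + sqrt(1 - coupling_r^2) * noise` where `z` is the
#' standardized RT delta (so the population correlation with the RT delta is
#' exactly `coupling_r`), and a gene table with TSS placed uniformly along
#' the genome whose log2 fold changes carry the same coupling to their
#' segment's RT delta, scaled by `fc_sd`.
#'
#' @param rt_delta Tibble with `segment`, `chrom`, `start`, `end`, `delta`
#'   (per-segment RT change, mutant minus control). Rows with `NA` delta are
#'   carried through with `NA` ChIP delta.
#' @param layout The [genome_layout()] the segments belong to.
#' @param coupling_r Target correlation in `[-1, 1]`.
#' @param n_genes Number of genes to place.
#' @param fc_sd Overall SD of simulated log2 fold changes.
#' @param seed Integer seed.
#' @return List with `chip` (tibble `segment`, `chrom`, `start`, `end`,
#'   `chip_delta`) and `genes` (tibble `gene_id`, `chrom`, `tss`, `expr_a`,
#'   `expr_b`, `log2_fc`).
#' @export
simulate_omics <- function(rt_delta, layout, coupling_r = 0.6, n_genes = 2000,
                           fc_sd = 1, seed = 1L) {
  if (abs(coupling_r) > 1) stop("coupling_r must lie in [-1, 1]")
  stopifnot(all(c("segment", "chrom", "start", "end", "delta") %in% names(rt_delta)))
  ok <- !is.na(rt_delta$delta)
  z <- rep(NA_real_, nrow(rt_delta))
  z[ok] <- as.numeric(scale(rt_delta$delta[ok]))
  withr::with_seed(seed, {
    chip <- rt_delta[, c("segment", "chrom", "start", "end")]
    chip$chip_delta <- coupling_r * z +
      sqrt(1 - coupling_r^2) * stats::rnorm(nrow(rt_delta))
    chip$chip_delta[!ok] <- NA_real_

    ch <- sample(layout$chroms$chrom, n_genes, replace = TRUE,
                 prob = layout$chroms$length)
    tss <- floor(stats::runif(n_genes) *
                   layout$chroms$length[match(ch, layout$chroms$chrom)])
    seg <- segment_index(layout, ch, tss)
    z_seg <- z[match(seg, rt_delta$segment)]
    z_seg[is.na(z_seg)] <- 0
    log2_fc <- fc_sd * (coupling_r * z_seg +
                          sqrt(1 - coupling_r^2) * stats::rnorm(n_genes))
    expr_a <- stats::rnorm(n_genes, 6, 2)
    genes <- tibble::tibble(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      chrom = ch, tss = tss,
      expr_a = expr_a, expr_b = expr_a + log2_fc,
      log2_fc = log2_fc
    )
    list(chip = tibble::as_tibble(chip), genes = genes)
  })
}
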