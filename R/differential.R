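#' Between-group distances and the replicate null pool
#'
#' The switching statistic: for every segment, the distance between the two
#' group means of replicate RT values, `d = |mean(B reps) - mean(A reps)|`.
#' The empirical null is built from the replicates themselves: the absolute
#' difference of every within-group replicate pair, pooled over all segments
#' and both groups, measures how far two measurements of the *same* biology
#' drift apart.
#'
#' A within-pair difference has variance `2 * sigma^2` while the
#' between-group mean difference has variance `sigma^2 * (1/nA + 1/nB)`;
#' with `scale_null = TRUE` (default) the pooled pair differences are scaled
#' by `sqrt((1/nA + 1/nB) / 2)` so the null pool is variance-matched to the
#' statistic and the resulting p-values are calibrated. `scale_null = FALSE`
#' keeps the raw pair differences (a conservative null).
#'
#' Segments masked (`NA`) in any replicate are excluded from both the
#' statistics and the null pool.
#'
#' @param seg_wide Wide per-segment tibble from [segment_rt()]: `segment`,
#'   `chrom`, `start`, `end` plus one numeric column per replicate sample.
#' @param group_a Column names of the control-group replicates.
#' @param group_b Column names of the mutant-group replicates.
#' @param scale_null Variance-match the null pool (see Details).
#' @return List with `stats` (tibble `segment`, `chrom`, `start`, `end`,
#'   `ctrl_mean`, `mut_mean`, `delta`, `d`; masked segments carry `NA`) and
#'   `null_pool` (numeric vector).
#' @export
segment_distances <- function(seg_wide, group_a, group_b, scale_null = TRUE) {
  stopifnot(all(group_a %in% names(seg_wide)), all(group_b %in% names(seg_wide)))
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 && n_b < 2) {
    stop("no within-group replicate pair available; the null is undefined")
  }
  a <- as.matrix(seg_wide[, group_a, drop = FALSE])
  b <- as.matrix(seg_wide[, group_b, drop = FALSE])
  ok <- stats::complete.cases(a) & stats::complete.cases(b)

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  stats_tbl <- tibble::tibble(
    segment = seg_wide$segment,
    chrom = seg_wide$chrom, start = seg_wide$start, end = seg_wide$end,
    ctrl_mean = ifelse(ok, mean_a, NA_real_),
    mut_mean = ifelse(ok, mean_b, NA_real_),
    delta = ifelse(ok, mean_b - mean_a, NA_real_),
    d = ifelse(ok, abs(mean_b - mean_a), NA_real_)
  )

  pair_diffs <- function(m) {
    if (ncol(m) < 2) return(numeric())
    pairs <- utils::combn(ncol(m), 2)
    unlist(lapply(seq_len(ncol(pairs)), function(j) {
      abs(m[ok, pairs[1, j]] - m[ok, pairs[2, j]])
    }), use.names = FALSE)
  }
  null_pool <- c(pair_diffs(a), pair_diffs(b))
  if (scale_null) null_pool <- null_pool * sqrt((1 / n_a + 1 / n_b) / 2)
  list(stats = stats_tbl, null_pool = null_pool)
}

#' Empirical p-values against a null pool
#'
#' `p_i = (1 + #\{null >= d_i\}) / (1 + N)` (the add-one permutation
#' convention, so p is never 0 and lies in (0, 1]).
#'
#' @param d Numeric vector of observed statistics (`NA` passes through).
#' @param null_pool Numeric vector of null statistics.
#' @return Numeric vector of p-values.
#' @export
empirical_pvalues <- function(d, null_pool) {
  if (length(null_pool) == 0) stop("null pool is empty")
  ns <- sort(null_pool)
  n <- length(ns)
  # #{null >= d} = N - #{null < d}
  ge <- n - findInterval(d, ns, left.open = TRUE)
  p <- (1 + ge) / (1 + n)
  p[is.na(d)] <- NA_real_
  p
}

#' Storey q-values
#'
#' Converts p-values to q-values, the estimated false discovery rate incurred
#' by calling everything at or below each p. The proportion of true nulls is
#' estimated as `pi0 = #\{p > lambda\} / ((1 - lambda) * m)` capped at 1
#' (`pi0_method = "fixed_lambda"`, default `lambda = 0.5`), or fixed at 1
#' (`pi0_method = "bh"`), which makes the q-values identical to
#' Benjamini-Hochberg adjusted p-values. `q_(i) = min_(j >= i)
#' (pi0 * m * p_(j) / j)` on the sorted p-values; q is monotone in p and
#' invariant to input order.
#'
#' @param p Numeric vector of p-values in (0, 1] (`NA` passes through).
#' @param pi0_method `"fixed_lambda"` or `"bh"`.
#' @param lambda Threshold for the fixed-lambda pi0 estimate.
#' @return Numeric vector of q-values.
#' @export
storey_qvalues <- function(p, pi0_method = c("fixed_lambda", "bh"), lambda = 0.5) {
  pi0_method <- match.arg(pi0_method)
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pv)
  if (m == 0) return(p)
  pi0 <- if (pi0_method == "bh") 1 else
    min(1, max(sum(pv > lambda) / ((1 - lambda) * m), 1 / m))
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- rep(NA_real_, length(p))
  q[ok][o] <- q_sorted
  q
}

#' Classify segments into switching classes
#'
#' A segment significant at the q cutoff whose control timing is early
#' (`ctrl_mean > 0` on the log2 early/late scale) and that moved later
#' (`delta < 0`) is an EtoL switch; significant, late control timing and a
#' move earlier is LtoE. Everything else keeps its non-switching endpoint
#' class: EtoE if the control mean is early, LtoL otherwise (significant
#' same-direction shifts, e.g. early-to-earlier, stay EtoE/LtoL but keep
#' their significance flag). Masked segments are classed `"masked"`.
#'
#' @param stats Tibble with `ctrl_mean`, `mut_mean`, `delta`, `q` (as built
#'   by [segment_distances()] + [empirical_pvalues()] + [storey_qvalues()]).
#' @param q_cutoff Significance cutoff on q (conventionally 0.01 for
#'   high-confidence and 0.05 for lower-confidence switch sets).
#' @return `stats` with added logical `significant` and character `class`.
#' @export
call_switches <- function(stats, q_cutoff = 0.01) {
  stopifnot(all(c("ctrl_mean", "mut_mean", "delta", "q") %in% names(stats)))
  sig <- !is.na(stats$q) & stats$q <= q_cutoff
  cls <- ifelse(is.na(stats$ctrl_mean), "masked",
          ifelse(sig & stats$ctrl_mean > 0 & stats$delta < 0, "EtoL",
           ifelse(sig & stats$ctrl_mean < 0 & stats$delta > 0, "LtoE",
            ifelse(stats$ctrl_mean > 0, "EtoE", "LtoL"))))
  stats$significant <- sig & !is.na(stats$ctrl_mean)
  stats$class <- cls
  stats
}

#' Merge adjacent same-class segments into domains
#'
#' Runs of genomically adjacent segments sharing class and significance
#' become one domain; the domain q is the minimum member q. Masked segments
#' break runs and are dropped.
#'
#' @param calls Output of [call_switches()] (must be coordinate-sorted, as
#'   the package produces it).
#' @return Tibble `chrom`, `start`, `end`, `class`, `significant`, `q`,
#'   `n_segments`.
#' @export
merge_to_domains <- function(calls) {
  keep <- calls$class != "masked"
  x <- calls[keep, ]
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          class = character(), significant = logical(),
                          q = numeric(), n_segments = integer()))
  }
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$start[-1] != x$end[-nrow(x)] |
                 x$class[-1] != x$class[-nrow(x)] |
                 x$significant[-1] != x$significant[-nrow(x)])
  x$run <- cumsum(new_run)
  dplyr::summarise(
    dplyr::group_by(x, .data$run),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    class = .data$class[1], significant = .data$significant[1],
    q = suppressWarnings(min(.data$q, na.rm = TRUE)),
    n_segments = dplyr::n(), .groups = "drop"
  )[, c("chrom", "start", "end", "class", "significant", "q", "n_segments")]
}

#' Hypergeometric overlap test between two segment sets
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two sets drawn from a common universe of segments, plus
#' the expected overlap under independence (`|A| * |B| / universe`).
#'
#' @param set_a,set_b Vectors of segment identifiers.
#' @param universe_size Number of segments in the universe.
#' @return One-row tibble: `n_a`, `n_b`, `universe`, `overlap`, `expected`,
#'   `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop("sets cannot exceed the universe")
  }
  ov <- length(intersect(set_a, set_b))
  tibble::tibble(
    n_a = length(set_a), n_b = length(set_b), universe = universe_size,
    overlap = ov,
    expected = length(set_a) * length(set_b) / universe_size,
    p_value = stats::phyper(ov - 1, length(set_a),
                            universe_size - length(set_a), length(set_b),
                            lower.tail = FALSE)
  )
}

#' Replication-timing switching-segment test
#'
#' The full differential stage in one call: between-group distances and the
#' replicate-calibrated null ([segment_distances()]), empirical p-values,
#' Storey q-values, and switch classification.
#'
#' @inheritParams segment_distances
#' @inheritParams call_switches
#' @inheritParams storey_qvalues
#' @return An object of class `rt_switch_fit` with elements `calls` (the
#'   per-segment tibble: coordinates, group means, `delta`, `d`, `p`, `q`,
#'   `significant`, `class`), `null_pool`, `pi0`, `q_cutoff`, `groups`.
#'   [generics::tidy()] returns the calls, [generics::glance()] a one-row
#'   summary, and [ggplot2::autoplot()] a genome-wide delta plot.
#' @examples
#' layout <- genome_layout(c(chr1 = 20e6))
#' truth <- simulate_rt_landscape(layout, seed = 1)
#' planted <- plant_switches(truth, n_switch = 5, seed = 2)
#' counts <- dplyr::bind_rows(
#'   simulate_counts(truth, sample_prefix = "wt", seed = 3),
#'   simulate_counts(planted$truth, sample_prefix = "tko", seed = 4)
#' )
#' seg <- segment_rt(counts, layout)
#' fit <- rt_switch_test(seg, c("wt_rep1", "wt_rep2"), c("tko_rep1", "tko_rep2"))
#' glance(fit)
#' @export
rt_switch_test <- function(seg_wide, group_a, group_b, q_cutoff = 0.01,
                           pi0_method = "fixed_lambda", scale_null = TRUE) {
  sd_res <- segment_distances(seg_wide, group_a, group_b, scale_null = scale_null)
  calls <- sd_res$stats
  calls$p <- empirical_pvalues(calls$d, sd_res$null_pool)
  calls$q <- storey_qvalues(calls$p, pi0_method = pi0_method)
  calls <- call_switches(calls, q_cutoff = q_cutoff)
  pv <- calls$p[!is.na(calls$p)]
  pi0 <- if (identical(pi0_method, "bh")) 1 else
    min(1, max(sum(pv > 0.5) / (0.5 * length(pv)), 1 / length(pv)))
  structure(list(calls = calls, null_pool = sd_res$null_pool, pi0 = pi0,
                 q_cutoff = q_cutoff,
                 groups = list(a = group_a, b = group_b)),
            class = "rt_switch_fit")
}

#' @export
print.rt_switch_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<rt_switch_fit> %d segments (%d masked), q <= %g\n",
              g$n_segments, g$n_masked, x$q_cutoff))
  cat(sprintf("  EtoL: %d, LtoE: %d switching segments; pi0 = %.3f\n",
              g$n_etol, g$n_ltoe, g$pi0))
  invisible(x)
}
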