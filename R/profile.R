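#' Scale a count track to counts per million
#'
#' Each bin is scaled by `1e6 / total`, so the scaled track sums to one
#' million. The raw counts are kept alongside (the minimum-coverage mask in
#' [log2_ratio()] is defined on raw reads).
#'
#' @param track Tibble with a raw count column.
#' @param count Name of the count column.
#' @return `track` with an added `cpm` column.
#' @export
normalize_per_million <- function(track, count = "count") {
  stopifnot(count %in% names(track))
  total <- sum(track[[count]], na.rm = TRUE)
  if (total <= 0) stop("cannot normalize a track with zero total count")
  track$cpm <- 1e6 * track[[count]] / total
  track
}

#' Per-bin log2 early/late ratio
#'
#' Computes `log2((early + c) / (late + c))` on per-million-scaled tracks.
#' Bins whose summed raw coverage (early + late reads) falls below
#' `min_reads` are masked (`NA`): a ratio of a handful of reads is noise, and
#' the pseudocount `c` (in per-million units) keeps zero-count bins finite.
#'
#' @param early,late Tibbles from [normalize_per_million()] (must carry both
#'   `count` and `cpm`), on the same layout.
#' @param pseudocount Pseudocount `c` in per-million units.
#' @param min_reads Minimum raw early+late reads for an unmasked bin.
#' @return A ratio track tibble: `chrom`, `start`, `end`, `bin`, `value`.
#' @export
log2_ratio <- function(early, late, pseudocount = 1, min_reads = 10) {
  stopifnot(all(c("chrom", "start", "cpm", "count") %in% names(early)),
            all(c("chrom", "start", "cpm", "count") %in% names(late)))
  if (nrow(early) != nrow(late) ||
      !all(early$chrom == late$chrom) || !all(early$start == late$start)) {
    stop("early and late tracks are on different layouts")
  }
  value <- log2((early$cpm + pseudocount) / (late$cpm + pseudocount))
  value[early$count + late$count < min_reads] <- NA_real_
  out <- early[, intersect(c("chrom", "start", "end", "bin"), names(early))]
  out$value <- value
  out
}

tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)

# Σ_k g_k x_{i+k} for k = -K..K, zero-padded at the edges.
roll_sum <- function(x, g) {
  k <- (length(g) - 1) / 2
  xp <- c(rep(0, k), x, rep(0, k))
  out <- stats::filter(xp, rev(g), method = "convolution", sides = 2)
  as.numeric(out[(k + 1):(length(xp) - k)])
}

#' Smooth a ratio track by fixed-span local linear regression
#'
#' At every bin, a degree-1 weighted least-squares line is fitted to the
#' unmasked bins within the `span_kb` genomic window centred on it, with
#' tricube weights in genomic distance; the fitted value at the centre is the
#' smoothed value (LOESS with a fixed genomic span rather than a global point
#' fraction). Chromosomes are smoothed independently. Masked bins are
#' excluded from every fit and stay masked in the output; a bin whose window
#' contains fewer than two unmasked bins is masked too, since no line is
#' determined there.
#'
#' @param track A ratio track (`chrom`, `start`, `value`), bins in genome
#'   order as produced by the package.
#' @param layout The [genome_layout()].
#' @param span_kb Full window width in kb (default 300).
#' @param value Name of the value column.
#' @return `track` with `value` replaced by the smoothed values.
#' @export
loess_smooth <- function(track, layout, span_kb = 300, value = "value") {
  stopifnot(value %in% names(track), inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  h <- span_kb * 1000 / 2
  K <- floor(h / bs)
  off <- (-K:K) * bs
  w <- tricube(off / h)

  out <- track
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    y <- track[[value]][i]
    m <- as.numeric(!is.na(y))
    if (sum(m) < 2) {
      warning("chromosome ", ch, " has fewer than 2 unmasked bins; output masked")
      out[[value]][i] <- NA_real_
      next
    }
    ym <- ifelse(is.na(y), 0, y) * m
    s0 <- roll_sum(m, w)
    s1 <- roll_sum(m, w * off)
    s2 <- roll_sum(m, w * off^2)
    t0 <- roll_sum(ym, w)
    t1 <- roll_sum(ym, w * off)
    npts <- roll_sum(m, as.numeric(w > 0))
    den <- s0 * s2 - s1^2
    fit <- (s2 * t0 - s1 * t1) / den
    fit[npts < 2 | abs(den) < 1e-12 * pmax(s0 * s2, 1e-300)] <- NA_real_
    fit[m == 0] <- NA_real_
    out[[value]][i] <- fit
  }
  out
}

#' Average a bin-level track into fixed 200-kb segments
#'
#' Each segment's value is the mean of its unmasked constituent bins. A
#' segment with fewer than `min_valid_fraction` of its bins unmasked is
#' masked (`NA`), so sparse coverage cannot masquerade as a timing estimate.
#'
#' @param track Bin-level tibble (`chrom`, `start`, value column).
#' @param layout The [genome_layout()].
#' @param min_valid_fraction Minimum fraction of unmasked bins per segment.
#' @param value Name of the value column.
#' @return Tibble with one row per layout segment: `segment`, `chrom`,
#'   `start`, `end`, `value`, `valid_fraction`.
#' @export
average_into_segments <- function(track, layout, min_valid_fraction = 0.5,
                                  value = "value") {
  stopifnot(value %in% names(track))
  tr <- add_segment_index(track, layout)
  per <- dplyr::summarise(
    dplyr::group_by(tr, .data$segment),
    mean_value = mean(.data[[value]][!is.na(.data[[value]])]),
    valid_fraction = mean(!is.na(.data[[value]])),
    .groups = "drop"
  )
  per$mean_value[per$valid_fraction < min_valid_fraction] <- NA_real_
  per$mean_value[is.nan(per$mean_value)] <- NA_real_
  segs <- layout_segments(layout)[, c("segment", "chrom", "start", "end")]
  out <- dplyr::left_join(segs, per, by = "segment")
  out$valid_fraction[is.na(out$valid_fraction)] <- 0
  names(out)[names(out) == "mean_value"] <- value
  out
}

#' Replication timing differential between two segment tables
#'
#' `delta = mut - ctrl` per segment (the mutant-minus-control convention), on
#' replicate-averaged segment values. A segment masked on either side is
#' masked in the differential.
#'
#' @param seg_mut,seg_ctrl Segment tibbles from [average_into_segments()]
#'   (or any tibble with `segment`, `chrom`, `start`, `end` and a value
#'   column), on the same layout.
#' @param value Name of the value column.
#' @return Tibble `segment`, `chrom`, `start`, `end`, `ctrl`, `mut`, `delta`.
#' @export
rt_differential <- function(seg_mut, seg_ctrl, value = "value") {
  if (nrow(seg_mut) != nrow(seg_ctrl) ||
      !all(seg_mut$chrom == seg_ctrl$chrom) ||
      !all(seg_mut$start == seg_ctrl$start)) {
    stop("segment tables are on different layouts")
  }
  tibble::tibble(
    segment = seg_mut$segment,
    chrom = seg_mut$chrom, start = seg_mut$start, end = seg_mut$end,
    ctrl = seg_ctrl[[value]], mut = seg_mut[[value]],
    delta = seg_mut[[value]] - seg_ctrl[[value]]
  )
}

#' Bin-level log2 ratio tracks for one or more samples
#'
#' Convenience wrapper running per-million normalization and [log2_ratio()]
#' for every sample in a long count tibble (as produced by
#' [simulate_counts()] or assembled from [read_bedgraph()] tracks).
#'
#' @param counts Long tibble: `chrom`, `start`, `end`, `bin`, `sample`,
#'   `fraction` (`"early"`/`"late"`), `count`.
#' @param layout The [genome_layout()].
#' @param pseudocount,min_reads Passed to [log2_ratio()].
#' @param span_kb If non-`NULL`, smooth each sample's ratio track with
#'   [loess_smooth()] at this span.
#' @return Long tibble `chrom`, `start`, `end`, `bin`, `sample`, `value`.
#' @export
bin_ratio_tracks <- function(counts, layout, pseudocount = 1, min_reads = 10,
                             span_kb = NULL) {
  purrr::map_dfr(split(counts, counts$sample), function(df) {
    early <- normalize_per_million(df[df$fraction == "early", ])
    late <- normalize_per_million(df[df$fraction == "late", ])
    ratio <- log2_ratio(early, late, pseudocount, min_reads)
    if (!is.null(span_kb)) ratio <- loess_smooth(ratio, layout, span_kb)
    ratio$sample <- df$sample[1]
    ratio
  })
}

#' Per-segment replication timing matrix across samples
#'
#' Runs the count-to-segment pipeline for every sample and returns the wide
#' per-segment table consumed by [rt_switch_test()]: one column of mean
#' log2(early/late) per sample. Segment averaging operates on the unsmoothed
#' 5-kb ratios; smoothing is a display/profile operation.
#'
#' @inheritParams bin_ratio_tracks
#' @param min_valid_fraction Passed to [average_into_segments()].
#' @return Wide tibble: `segment`, `chrom`, `start`, `end`, one numeric
#'   column per sample.
#' @export
segment_rt <- function(counts, layout, pseudocount = 1, min_reads = 10,
                       min_valid_fraction = 0.5) {
  ratios <- bin_ratio_tracks(counts, layout, pseudocount, min_reads)
  long <- purrr::map_dfr(split(ratios, ratios$sample), function(df) {
    seg <- average_into_segments(df, layout, min_valid_fraction)
    seg$sample <- df$sample[1]
    seg
  })
  tidyr::pivot_wider(long[, c("segment", "chrom", "start", "end", "sample", "value")],
                     names_from = "sample", values_from = "value")
}
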