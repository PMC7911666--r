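# Shared fixture builders. Everything is generated in code; no binary files.

# small single-chromosome layout: n_bins bins of 5 kb, 200-kb segments
toy_layout <- function(n_bins = 40, bin_size = 5000, segment_size = 200000,
                       chrom = "chr1") {
  sizes <- stats::setNames(n_bins * bin_size, chrom)
  genome_layout(sizes, bin_size = bin_size, segment_size = segment_size)
}

# a bin-level value track on a layout
toy_track <- function(layout, value) {
  bins <- layout_bins(layout)
  bins$partial <- NULL
  bins$value <- value
  bins
}

# count-track pair carrying cpm + count, as normalize_per_million() produces
toy_scaled_pair <- function(layout, early_cpm, late_cpm,
                            early_count = NULL, late_count = NULL) {
  bins <- layout_bins(layout)
  bins$partial <- NULL
  e <- bins
  e$count <- if (is.null(early_count)) rep(100, nrow(bins)) else early_count
  e$cpm <- early_cpm
  l <- bins
  l$count <- if (is.null(late_count)) rep(100, nrow(bins)) else late_count
  l$cpm <- late_cpm
  list(early = e, late = l)
}

# hand-built rt_truth with an explicit rt vector
toy_truth <- function(layout, rt) {
  bins <- layout_bins(layout)
  bins$partial <- NULL
  bins$domain <- 1L
  bins$rt <- rt
  structure(list(bins = bins,
                 domains = tibble::tibble(chrom = layout$chroms$chrom[1],
                                          start = 0, end = layout$chroms$length[1],
                                          domain = 1L, rt = NA_real_),
                 layout = layout),
            class = "rt_truth")
}

# a fiber molecule assembled from (label, start_um, length_um) triples
toy_molecule <- function(..., molecule_id = "m1", molecule_length_um = 100) {
  tr <- list(...)
  tibble::tibble(
    molecule_id = molecule_id,
    track_index = seq_along(tr),
    label = vapply(tr, `[[`, "", 1),
    start_um = vapply(tr, function(x) as.numeric(x[[2]]), 0),
    length_um = vapply(tr, function(x) as.numeric(x[[3]]), 0),
    molecule_length_um = molecule_length_um
  )
}

# brute-force local-linear tricube smoother: independent oracle for
# loess_smooth(), one explicit weighted least-squares fit per bin
wls_smooth_oracle <- function(x, y, h) {
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- x - x[i]
    w <- ifelse(abs(d) < h, (1 - abs(d / h)^3)^3, 0)
    w[is.na(y)] <- 0
    use <- w > 0
    if (sum(use) < 2 || is.na(y[i])) next
    X <- cbind(1, d[use])
    W <- diag(w[use], nrow = sum(use))
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[use])
    out[i] <- beta[1]
  }
  out
}
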