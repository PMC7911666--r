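#' Pearson correlation between per-segment deltas
#'
#' Correlates a replication-timing delta with an omics delta (e.g. per-segment
#' H3K27me3 enrichment change) over the jointly unmasked segments.
#'
#' @param data Tibble holding both delta columns.
#' @param x,y Column names (strings) of the two deltas.
#' @return One-row tibble: `r`, `n`.
#' @export
correlate_deltas <- function(data, x, y) {
  stopifnot(x %in% names(data), y %in% names(data))
  ok <- !is.na(data[[x]]) & !is.na(data[[y]])
  if (sum(ok) < 3) stop("fewer than 3 jointly unmasked observations")
  tibble::tibble(r = stats::cor(data[[x]][ok], data[[y]][ok]), n = sum(ok))
}

#' Five-number summaries per switching class
#'
#' Box-plot style summaries (median, quartiles, 1.5*IQR whiskers) and counts
#' of a per-segment or per-gene quantity within each replication-timing
#' class. Classes with no observations are reported with `n = 0` and `NA`
#' summaries rather than dropped.
#'
#' @param data Tibble with the value and class columns.
#' @param value,class Column names (strings).
#' @param classes Class levels to report (default the four switch classes).
#' @return Tibble: `class`, `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`.
#' @export
summarize_by_class <- function(data, value, class = "class",
                               classes = c("EtoL", "LtoE", "EtoE", "LtoL")) {
  stopifnot(value %in% names(data), class %in% names(data))
  purrr::map_dfr(classes, function(cl) {
    v <- data[[value]][data[[class]] == cl & !is.na(data[[value]])]
    if (length(v) == 0) {
      return(tibble::tibble(class = cl, n = 0L, median = NA_real_,
                            q1 = NA_real_, q3 = NA_real_,
                            whisker_lo = NA_real_, whisker_hi = NA_real_))
    }
    q1 <- unname(stats::quantile(v, 0.25))
    q3 <- unname(stats::quantile(v, 0.75))
    iqr <- q3 - q1
    tibble::tibble(
      class = cl, n = length(v), median = stats::median(v), q1 = q1, q3 = q3,
      whisker_lo = min(v[v >= q1 - 1.5 * iqr]),
      whisker_hi = max(v[v <= q3 + 1.5 * iqr])
    )
  })
}

#' Most extreme segments by delta percentile
#'
#' The `ceiling(percent/100 * n)` segments with the largest (`"gain"`) or
#' smallest (`"loss"`) finite deltas. Ties are broken by coordinate order so
#' the selection is deterministic.
#'
#' @param data Tibble with the delta and `chrom`/`start` columns.
#' @param delta Column name (string) of the delta.
#' @param percent Percentile in (0, 100); typical analyses use 1, 5 and 10.
#' @param direction `"gain"` or `"loss"`.
#' @return The selected rows of `data`.
#' @export
top_percentile_segments <- function(data, delta, percent,
                                    direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (percent <= 0 || percent >= 100) stop("percent must lie in (0, 100)")
  stopifnot(delta %in% names(data))
  x <- data[is.finite(data[[delta]]), ]
  n <- nrow(x)
  if (n == 0) return(x)
  k <- ceiling(percent / 100 * n)
  key <- if (direction == "gain") -x[[delta]] else x[[delta]]
  ord <- order(key, match(x$chrom, unique(x$chrom)), x$start)
  x[sort(ord[seq_len(k)]), ]
}

#' Assign genes to segments by TSS
#'
#' Each gene is assigned to the fixed segment whose half-open interval
#' contains its transcription start site.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`.
#' @param layout The [genome_layout()].
#' @return `genes` with an added `segment` column.
#' @export
assign_genes_to_segments <- function(genes, layout) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  len <- layout$chroms$length[match(genes$chrom, layout$chroms$chrom)]
  bad <- which(is.na(len) | genes$tss < 0 | genes$tss >= len)
  if (length(bad) > 0) {
    stop("TSS of gene ", genes$gene_id[bad[1]], " is off-chromosome")
  }
  genes$segment <- segment_index(layout, genes$chrom, genes$tss)
  genes
}

#' Fisher enrichment test of a gene set in a region class
#'
#' Two-sided Fisher exact test on the 2x2 table of gene-set membership (e.g.
#' fold change > 2) against region-class membership (e.g. the gene's segment
#' is an LtoE switching segment). The odds ratio is the cross-product ratio,
#' with a Haldane 0.5 correction when a cell is empty.
#'
#' @param in_set Logical vector: gene satisfies the set predicate.
#' @param in_class Logical vector: gene lies in the region class.
#' @return One-row tibble: the four cell counts (`set_class`, `set_other`,
#'   `other_class`, `other_other`), `odds_ratio`, `p_value`.
#' @export
fold_enrichment_test <- function(in_set, in_class) {
  if (length(in_set) == 0) stop("empty gene list")
  stopifnot(length(in_set) == length(in_class))
  ok <- !is.na(in_set) & !is.na(in_class)
  in_set <- in_set[ok]
  in_class <- in_class[ok]
  a <- sum(in_set & in_class)
  b <- sum(in_set & !in_class)
  c <- sum(!in_set & in_class)
  d <- sum(!in_set & !in_class)
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  tibble::tibble(set_class = a, set_other = b, other_class = c, other_other = d,
                 odds_ratio = or, p_value = p)
}
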