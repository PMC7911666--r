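#' Define a binned genome layout
#'
#' A genome layout fixes the coordinate system used throughout the package:
#' an ordered set of chromosomes tiled by fixed-position bins (default 5 kb)
#' and coarser fixed-position segments (default 200 kb). All intervals are
#' 0-based half-open `[k*size, (k+1)*size)`; the final bin/segment of a
#' chromosome may be partial and is retained (flagged, not dropped) so that
#' genome coverage accounting stays exact.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length` (bp), or
#'   a named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp. Must divide `segment_size`.
#' @param segment_size Segment width in bp.
#'
#' @return An object of class `genome_layout`: a list with `chroms` (tibble
#'   of `chrom`, `length`), `bin_size` and `segment_size`.
#' @examples
#' layout <- genome_layout(c(chr1 = 10e6, chr2 = 5e6))
#' layout_bins(layout)
#' @export
genome_layout <- function(chrom_sizes, bin_size = 5000L, segment_size = 200000L) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble::tibble(chrom = names(chrom_sizes),
                                  length = unname(chrom_sizes))
  }
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  chroms <- tibble::as_tibble(chrom_sizes[, c("chrom", "length")])
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$chrom)) stop("duplicated chromosome names")
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  bin_size <- as.numeric(bin_size)
  segment_size <- as.numeric(segment_size)
  if (bin_size <= 0 || segment_size <= 0) stop("bin_size and segment_size must be positive")
  if (segment_size %% bin_size != 0) stop("bin_size must divide segment_size")
  structure(list(chroms = chroms, bin_size = bin_size, segment_size = segment_size),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %s bp total\n",
              nrow(x$chroms), format(sum(x$chroms$length), big.mark = ",")))
  cat(sprintf("  bin size: %g bp (%d bins); segment size: %g bp (%d segments)\n",
              x$bin_size, n_bins(x), x$segment_size, n_segments(x)))
  invisible(x)
}

tile_chrom <- function(chrom, len, size) {
  n <- ceiling(len / size)
  start <- (seq_len(n) - 1) * size
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + size, len))
}

#' Bin and segment tilings of a layout
#'
#' `layout_bins()` and `layout_segments()` materialise the fixed tilings as
#' tibbles in genome order. `bin` and `segment` are 1-based global indices;
#' `partial` flags a final interval shorter than the nominal width.
#'
#' @param layout A [genome_layout()].
#' @return A tibble with columns `chrom`, `start`, `end`, the index column,
#'   and `partial`.
#' @export
layout_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  out <- purrr::map2_dfr(layout$chroms$chrom, layout$chroms$length,
                         tile_chrom, size = layout$bin_size)
  out$bin <- seq_len(nrow(out))
  out$partial <- (out$end - out$start) < layout$bin_size
  out
}

#' @rdname layout_bins
#' @export
layout_segments <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  out <- purrr::map2_dfr(layout$chroms$chrom, layout$chroms$length,
                         tile_chrom, size = layout$segment_size)
  out$segment <- seq_len(nrow(out))
  out$partial <- (out$end - out$start) < layout$segment_size
  out
}

n_bins <- function(layout) sum(ceiling(layout$chroms$length / layout$bin_size))
n_segments <- function(layout) sum(ceiling(layout$chroms$length / layout$segment_size))

# 1-based global segment index for (chrom, pos); pos 0-based, half-open rule.
segment_index <- function(layout, chrom, pos) {
  segs <- layout$chroms
  n_per <- ceiling(segs$length / layout$segment_size)
  offset <- c(0, cumsum(n_per))[match(chrom, segs$chrom)]
  if (anyNA(offset)) {
    bad <- unique(chrom[is.na(offset)])
    stop("unknown chromosome ", bad[1])
  }
  len <- segs$length[match(chrom, segs$chrom)]
  if (any(pos < 0) || any(pos >= len)) {
    stop("position outside chromosome bounds")
  }
  as.integer(offset + floor(pos / layout$segment_size) + 1)
}

# Attach the global segment index to a bin-level tibble.
add_segment_index <- function(track, layout) {
  dplyr::mutate(track, segment = segment_index(layout, .data$chrom, .data$start))
}
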