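#' Read a chrom.sizes file
#'
#' Two-column headerless TSV of chromosome name and length in bp, the UCSC
#' `chrom.sizes` convention.
#'
#' @param path File path.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = readr::cols(chrom = "c", length = "d"),
                  progress = FALSE)
}

# Read a bedGraph-style file, dropping track/browser/comment lines.
read_bedgraph_raw <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  readr::read_tsv(I(lines[keep]), col_names = c("chrom", "start", "end", "value"),
                  col_types = readr::cols("c", "d", "d", "d"), progress = FALSE)
}

#' Read a bedGraph onto the bins of a layout
#'
#' Intervals are 0-based half-open. Values of intervals aligned to the bin
#' grid are assigned directly; an interval spanning several bins is
#' length-weighted onto the bins it overlaps (each bin receives
#' `value * overlap / interval_length`). Bins not covered by any interval get
#' value 0.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value). `track`,
#'   `browser` and `#` lines are skipped.
#' @param layout A [genome_layout()].
#' @param value_name Name for the value column of the result.
#' @param missing Value assigned to bins no interval covers: 0 for count
#'   tracks (default), `NA` for masked value tracks written by
#'   [write_bedgraph()] (which omits masked bins).
#' @return A tibble with one row per layout bin: `chrom`, `start`, `end`,
#'   `bin`, and the value column.
#' @examples
#' layout <- genome_layout(c(chr1 = 10000), bin_size = 5000, segment_size = 10000)
#' f <- tempfile(fileext = ".bedgraph")
#' writeLines("chr1\t0\t10000\t4", f)
#' read_bedgraph(f, layout) # 4 split evenly across the two bins
#' @export
read_bedgraph <- function(path, layout, value_name = "value", missing = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  iv <- read_bedgraph_raw(path)
  bins <- layout_bins(layout)
  bins[[value_name]] <- missing
  bins$partial <- NULL
  if (nrow(iv) == 0) return(bins)

  if (any(iv$start < 0)) stop("negative coordinates in ", path)
  unknown <- setdiff(unique(iv$chrom), layout$chroms$chrom)
  if (length(unknown) > 0) stop("unknown chromosome ", unknown[1])
  len <- layout$chroms$length[match(iv$chrom, layout$chroms$chrom)]
  if (any(iv$end > len)) stop("interval beyond chromosome end in ", path)
  if (any(iv$end <= iv$start)) stop("empty or inverted interval in ", path)

  # overlapping intervals are ambiguous for a value track
  ord <- order(match(iv$chrom, layout$chroms$chrom), iv$start)
  iv <- iv[ord, ]
  same <- iv$chrom == dplyr::lag(iv$chrom, default = "")
  if (any(same & iv$start < dplyr::lag(iv$end, default = -Inf))) {
    stop("overlapping intervals in ", path)
  }

  bs <- layout$bin_size
  lo <- floor(iv$start / bs)
  hi <- floor((iv$end - 1) / bs)
  k <- hi - lo + 1
  row <- rep.int(seq_len(nrow(iv)), k)
  bin_in_chrom <- sequence(k) - 1 + rep.int(lo, k)
  b_start <- bin_in_chrom * bs
  overlap <- pmin(iv$end[row], b_start + bs) - pmax(iv$start[row], b_start)
  contrib <- iv$value[row] * overlap / (iv$end[row] - iv$start[row])

  n_per <- ceiling(layout$chroms$length / bs)
  offset <- c(0, cumsum(n_per))[match(iv$chrom[row], layout$chroms$chrom)]
  idx <- offset + bin_in_chrom + 1
  acc <- rep(as.numeric(missing), nrow(bins))
  agg <- rowsum(contrib, idx)
  acc[as.numeric(rownames(agg))] <- agg[, 1]
  bins[[value_name]] <- acc
  bins
}

#' Write a bin-level track as bedGraph
#'
#' One line per unmasked bin (masked bins, i.e. `NA` values, are omitted).
#' A single `track type=bedGraph` header line is written so an empty track
#' still produces a parseable file. `read_bedgraph(write_bedgraph(x))` is the
#' identity for grid-aligned data.
#'
#' @param track Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "value") {
  stopifnot(all(c("chrom", "start", "end", value) %in% names(track)))
  keep <- !is.na(track[[value]])
  out <- track[keep, c("chrom", "start", "end", value)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (nrow(out) > 0) {
    writeLines(paste(out$chrom, format(out$start, scientific = FALSE, trim = TRUE),
                     format(out$end, scientific = FALSE, trim = TRUE),
                     format(out[[value]], digits = 15, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a tab-separated table with a checked schema
#'
#' Reads a TSV with a header, verifies required columns are present, and
#' converts declared numeric columns with an informative error (naming the
#' line) on unparseable values. Literal `NA` / empty fields become missing
#' values rather than being dropped. Extra columns are kept as character.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric Character vector of columns that must parse as numeric.
#' @return A tibble.
#' @export
read_genomic_table <- function(path, required = character(), numeric = character()) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) stop("missing column ", missing[1])
  for (col in intersect(numeric, names(df))) {
    x <- df[[col]]
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("unparseable numeric in column '%s' at line %d: '%s'",
                   col, bad[1] + 1L, x[bad[1]]))
    }
    df[[col]] <- parsed
  }
  df
}

#' Write called domains as BED6
#'
#' The BED name field is the switch class and the score is
#' `round(1000 * (1 - q))`, so higher-confidence domains score closer to 1000.
#'
#' @param domains Tibble with `chrom`, `start`, `end`, `class`, `q`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  stopifnot(all(c("chrom", "start", "end", "class", "q") %in% names(domains)))
  out <- tibble::tibble(
    chrom = domains$chrom,
    start = format(domains$start, scientific = FALSE, trim = TRUE),
    end = format(domains$end, scientific = FALSE, trim = TRUE),
    name = domains$class,
    score = round(1000 * (1 - domains$q)),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
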