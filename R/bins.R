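#' Read a two-column chromosome sizes file
#'
#' @param path Path to a whitespace-separated file with columns
#'   `chrom` and `size` (bp), as distributed with genome assemblies.
#' @return A tibble with columns `chrom` (character) and `size` (integer bp).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Read a BED file of intervals
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used; extra columns are kept verbatim as `name`, `score`, `strand` when
#' present.
#'
#' @param path Path to a BED file.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  extra <- c("name", "score", "strand")
  names(df) <- c(c("chrom", "start", "end"), extra)[seq_len(min(ncol(df), 6))]
  if (any(df$end < df$start)) stop("BED interval with end < start in ", path)
  tibble::as_tibble(df)
}

#' Tile chromosomes into fixed-size bins
#'
#' Builds the binned-genome coordinate model shared by every analysis step.
#' Bins tile each chromosome contiguously from coordinate 0 (0-based,
#' half-open); the last bin of a chromosome may be shorter. Bins overlapping
#' an assembly gap are flagged and excluded from all downstream scores.
#'
#' @param chrom_sizes A tibble as returned by [read_chrom_sizes()], or a
#'   named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp (e.g. 50000). Must be positive.
#' @param gaps Optional tibble of assembly-gap intervals (`chrom`, `start`,
#'   `end`) or a path to a BED file of gaps.
#' @return A tibble with columns `chrom`, `bin` (0-based index within the
#'   chromosome), `start`, `end`, `gap` (logical), carrying the bin size in
#'   attribute `bin_size`.
#' @examples
#' genome_bins(c(chr1 = 250000), bin_size = 100000)
#' @export
genome_bins <- function(chrom_sizes, bin_size, gaps = NULL) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0 ||
      bin_size != as.integer(bin_size)) {
    stop("`bin_size` must be a single positive integer (bp)")
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble::tibble(chrom = names(chrom_sizes),
                                  size = unname(chrom_sizes))
  }
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  if (is.character(gaps)) gaps <- read_bed(gaps)

  bins <- purrr::map2_dfr(chrom_sizes$chrom, chrom_sizes$size, function(ch, sz) {
    n <- ceiling(sz / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    tibble::tibble(chrom = ch, bin = seq_len(n) - 1L,
                   start = start, end = pmin(start + bin_size, sz))
  })
  bins$gap <- FALSE
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (k in seq_len(nrow(gaps))) {
      hit <- bins$chrom == gaps$chrom[k] &
        bins$start < gaps$end[k] & bins$end > gaps$start[k]
      bins$gap <- bins$gap | hit
    }
  }
  attr(bins, "bin_size") <- as.integer(bin_size)
  bins
}

#' Bin size of a binned table
#'
#' @param x A tibble produced by [genome_bins()] or any per-bin table derived
#'   from it (the `bin_size` attribute is propagated by daric functions).
#' @return The bin width in bp.
#' @export
bin_size <- function(x) {
  bs <- attr(x, "bin_size")
  if (is.null(bs)) {
    # fall back to the modal bin width
    w <- x$end - x$start
    bs <- as.integer(stats::median(w))
  }
  bs
}

# carry the grid attribute through dplyr verbs that drop it
.keep_grid <- function(new, old) {
  attr(new, "bin_size") <- bin_size(old)
  new
}

# n bins per chromosome as a named vector
.n_bins <- function(bins) {
  tapply(bins$bin, bins$chrom, function(b) max(b) + 1L)
}
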