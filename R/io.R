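#' Read a sparse observed/expected contact dump for one chromosome
#'
#' Parses the whitespace-separated triplet text produced by
#' `juicer_tools dump oe KR` (`start_i start_j value`, positions being bin
#' start coordinates). The matrix is symmetric; entries are stored once with
#' `i <= j` and queried either way.
#'
#' Non-finite values (NaN/Inf, produced by balancing on sparse rows) are
#' dropped with a message; duplicated (i, j) pairs are a format error.
#'
#' @param path Path to the triplet text file.
#' @param chrom Chromosome name the dump belongs to.
#' @param bin_size Bin width in bp; positions must be multiples of it.
#' @return A tibble with columns `i`, `j` (0-based bin indices, `i <= j`) and
#'   `oe` (positive obs/exp ratio), with attributes `chrom` and `bin_size`.
#' @export
read_contact_matrix <- function(path, chrom, bin_size) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE,
                      col.names = c("pos_i", "pos_j", "oe"),
                      colClasses = "numeric"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(pos_i = numeric(0), pos_j = numeric(0), oe = numeric(0))
      } else {
        stop("malformed contact dump ", path, ": ", conditionMessage(e))
      }
    })
  bad <- which(df$pos_i %% bin_size != 0 | df$pos_j %% bin_size != 0)
  if (length(bad) > 0) {
    stop("contact dump ", path, " line ", bad[1],
         ": position not a multiple of bin_size ", bin_size)
  }
  i <- as.integer(df$pos_i %/% bin_size)
  j <- as.integer(df$pos_j %/% bin_size)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("contact dump ", path, " line ", dup[1],
         ": duplicate entry for bin pair (", i[dup[1]], ", ", j[dup[1]], ")")
  }
  keep <- is.finite(df$oe)
  if (any(!keep)) {
    message("read_contact_matrix: dropped ", sum(!keep),
            " non-finite values from ", basename(path))
  }
  out <- tibble::tibble(i = i[keep], j = j[keep], oe = df$oe[keep])
  attr(out, "chrom") <- chrom
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

#' Query a symmetric contact matrix
#'
#' @param contacts A tibble from [read_contact_matrix()] or
#'   [simulate_contact_matrix()].
#' @param i,j 0-based bin indices (either order).
#' @return The stored obs/exp value, or 0 when the pair is absent.
#' @export
contact_at <- function(contacts, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  idx <- match(paste(lo, hi), paste(contacts$i, contacts$j))
  ifelse(is.na(idx), 0, contacts$oe[idx])
}

#' Read a bedGraph signal onto a bin grid
#'
#' Intervals must be aligned to the bin grid or coarser; a coarser interval
#' is broadcast to every bin it covers. Bins with no covering interval are
#' missing (`NA`). Overlapping intervals, intervals extending past the
#' chromosome end, and intervals not aligned to the grid are errors.
#'
#' @param path Path to a bedGraph file (`chrom start end value`).
#' @param bins Bin grid from [genome_bins()].
#' @return A per-bin track tibble: `chrom`, `bin`, `start`, `end`, `value`.
#' @export
read_bedgraph_track <- function(path, bins) {
  bs <- bin_size(bins)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  df <- df[!grepl("^track|^browser", df[[1]]), , drop = FALSE]
  if (ncol(df) < 4) stop("bedGraph ", path, " needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "value")

  track <- bins[, c("chrom", "bin", "start", "end")]
  track$value <- NA_real_
  sizes <- tapply(bins$end, bins$chrom, max)
  for (k in seq_len(nrow(df))) {
    ch <- df$chrom[k]
    if (!ch %in% names(sizes)) next   # chromosome absent from grid: skip
    s <- df$start[k]; e <- df$end[k]
    if (e > sizes[[ch]]) {
      stop("bedGraph ", path, " line ", k, ": interval [", s, ", ", e,
           ") crosses the end of ", ch)
    }
    if (s %% bs != 0 || (e %% bs != 0 && e != sizes[[ch]])) {
      stop("bedGraph ", path, " line ", k,
           ": interval not aligned to the ", bs, " bp bin grid")
    }
    covered <- track$chrom == ch & track$start >= s & track$start < e
    if (any(!is.na(track$value[covered]))) {
      stop("bedGraph ", path, " line ", k, ": overlapping intervals on ", ch)
    }
    track$value[covered] <- df$value[k]
  }
  .keep_grid(track, bins)
}

#' Call A/B compartments from a PC1 track
#'
#' The sign of the first principal component of the Hi-C correlation matrix
#' defines the two compartments; the input track must already be oriented so
#' that positive PC1 means the active (A) compartment (use `flip` for
#' chromosomes whose eigenvector came out inverted). Bins with PC1 exactly 0,
#' missing PC1, or overlapping an assembly gap are unassigned.
#'
#' @param pc1 Per-bin PC1 track (from [read_bedgraph_track()]).
#' @param bins Bin grid; supplies the gap mask.
#' @param flip Character vector of chromosome names whose PC1 sign is
#'   inverted before calling.
#' @return A tibble `chrom`, `bin`, `start`, `end`, `compartment`
#'   (`"A"`, `"B"`, or `NA`).
#' @export
call_compartments <- function(pc1, bins = NULL, flip = character(0)) {
  v <- pc1$value
  if (length(flip) > 0) {
    v[pc1$chrom %in% flip] <- -v[pc1$chrom %in% flip]
  }
  comp <- ifelse(is.na(v) | v == 0, NA_character_,
                 ifelse(v > 0, "A", "B"))
  if (!is.null(bins)) {
    gap <- bins$gap[match(paste(pc1$chrom, pc1$bin),
                          paste(bins$chrom, bins$bin))]
    comp[which(gap)] <- NA_character_
  }
  for (ch in unique(pc1$chrom)) {
    lab <- comp[pc1$chrom == ch]
    lab <- lab[!is.na(lab)]
    if (length(lab) > 0 && length(unique(lab)) == 1) {
      warning("all assigned bins on ", ch, " are compartment ", lab[1],
              "; check the PC1 sign orientation", call. = FALSE)
    }
  }
  out <- pc1[, c("chrom", "bin", "start", "end")]
  out$compartment <- comp
  .keep_grid(out, pc1)
}

#' Write a per-bin track as bedGraph
#'
#' Consecutive bins with bit-identical values are merged into one interval
#' (run-length merging); missing bins are omitted.
#'
#' @param track A per-bin track tibble with a `value` column (or a column
#'   named by `column`).
#' @param path Output path.
#' @param column Name of the value column to write.
#' @return Invisibly, the number of lines written.
#' @export
write_track <- function(track, path, column = "value") {
  v <- track[[column]]
  keep <- !is.na(v)
  tr <- track[keep, ]
  v <- v[keep]
  if (nrow(tr) == 0) {
    file.create(path)
    return(invisible(0L))
  }
  # runs of equal value over contiguous bins of one chromosome
  new_run <- c(TRUE, tr$chrom[-1] != tr$chrom[-nrow(tr)] |
                 tr$bin[-1] != tr$bin[-nrow(tr)] + 1L |
                 v[-1] != v[-length(v)])
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(tr$chrom, run, `[`, 1),
    start = tapply(tr$start, run, min),
    end = tapply(tr$end, run, max),
    # %.17g keeps doubles bit-exact through the text round trip
    value = sprintf("%.17g", tapply(v, run, `[`, 1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(out))
}

#' Write domains as BED6+
#'
#' Columns: chrom, start, end, state label, score (mean residual or mean
#' significance score), strand (`"."`), then any remaining columns.
#'
#' @param domains A domain tibble (from [merge_domains()] or
#'   [call_significant_domains()]).
#' @param path Output path.
#' @param score_column Which column to place in the BED score field.
#' @return Invisibly, the number of lines written.
#' @export
write_domains <- function(domains, path, score_column = "mean_delta") {
  if (nrow(domains) == 0) {
    file.create(path)
    return(invisible(0L))
  }
  out <- data.frame(
    chrom = domains$chrom,
    start = domains$start,
    end = domains$end,
    name = domains$label,
    score = round(domains[[score_column]], 6),
    strand = "."
  )
  extra <- setdiff(names(domains),
                   c("chrom", "start", "end", "label", score_column,
                     "comparison"))
  for (nm in extra) out[[nm]] <- domains[[nm]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(out))
}
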