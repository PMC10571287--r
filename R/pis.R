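#' Preferential Interaction Score (PIS) for one chromosome
#'
#' For every usable bin b, PIS(b) is the log2 ratio of the bin's average
#' obs/exp interaction with A-compartment bins to its average interaction
#' with B-compartment bins on the same chromosome:
#' \deqn{PIS(b) = \log_2 \frac{\mathrm{mean}_{a \in A, a \ne b}\, oe(b,a)}
#'                           {\mathrm{mean}_{k \in B, k \ne b}\, oe(b,k)}}
#' Positive PIS means the bin preferentially contacts the active compartment.
#'
#' Averages run over all usable A (resp. B) bins of the chromosome, counting
#' pairs absent from the sparse dump as zero contact (obs/exp dumps omit
#' zero-observed pairs; ignoring them would inflate PIS for sparse bins).
#' Set `mean_over = "nonzero"` to average over stored pairs only. The
#' self-pair is excluded from both averages. PIS is missing for gap bins,
#' bins without a compartment call, and bins whose A- or B-average is zero
#' or undefined.
#'
#' @param contacts Sparse obs/exp triplets for one chromosome
#'   ([read_contact_matrix()] / [simulate_contact_matrix()]).
#' @param compartments Per-bin compartment calls ([call_compartments()]);
#'   only rows for the contact matrix's chromosome are used. Gap-masked bins
#'   must already be `NA` here.
#' @param mean_over `"all"` (default; absent pairs count as zero) or
#'   `"nonzero"` (average over stored pairs only).
#' @param exclude_diag Drop the self-interaction from both averages
#'   (default TRUE; the diagonal's obs/exp is an outlier).
#' @return A per-bin track tibble (`chrom`, `bin`, `start`, `end`, `value`)
#'   for that chromosome.
#' @export
compute_pis <- function(contacts, compartments,
                        mean_over = c("all", "nonzero"),
                        exclude_diag = TRUE) {
  mean_over <- match.arg(mean_over)
  ch <- attr(contacts, "chrom")
  comp <- compartments[compartments$chrom == ch, ]
  if (nrow(comp) == 0) stop("no compartment calls for chromosome ", ch)
  n <- max(comp$bin) + 1L
  lab <- rep(NA_character_, n)
  lab[comp$bin + 1L] <- comp$compartment

  out <- comp[, c("chrom", "bin", "start", "end")]
  out$value <- NA_real_

  a_idx <- which(lab == "A")
  b_idx <- which(lab == "B")
  if (length(a_idx) == 0 || length(b_idx) == 0) {
    warning("chromosome ", ch, " has no ",
            if (length(a_idx) == 0) "A" else "B",
            " bins; PIS is undefined there", call. = FALSE)
    return(.keep_grid(out, compartments))
  }

  keep <- contacts$i < n & contacts$j < n
  M <- Matrix::sparseMatrix(i = contacts$i[keep] + 1L,
                            j = contacts$j[keep] + 1L,
                            x = contacts$oe[keep], dims = c(n, n))
  M <- M + Matrix::t(M)
  Matrix::diag(M) <- if (exclude_diag) 0 else Matrix::diag(M) / 2

  a_ind <- as.numeric(seq_len(n) %in% a_idx)
  b_ind <- as.numeric(seq_len(n) %in% b_idx)
  sum_a <- as.vector(M %*% a_ind)
  sum_b <- as.vector(M %*% b_ind)
  if (mean_over == "all") {
    den_a <- length(a_idx) - (seq_len(n) %in% a_idx) * exclude_diag
    den_b <- length(b_idx) - (seq_len(n) %in% b_idx) * exclude_diag
  } else {
    NZ <- M != 0
    den_a <- as.vector(NZ %*% a_ind)
    den_b <- as.vector(NZ %*% b_ind)
  }
  mean_a <- ifelse(den_a > 0, sum_a / den_a, NA_real_)
  mean_b <- ifelse(den_b > 0, sum_b / den_b, NA_real_)
  pis <- ifelse(!is.na(mean_a) & !is.na(mean_b) & mean_a > 0 & mean_b > 0,
                log2(mean_a) - log2(mean_b), NA_real_)
  pis[is.na(lab)] <- NA_real_
  out$value <- pis[out$bin + 1L]
  .keep_grid(out, compartments)
}

#' Gaussian smoothing of a binned track with missing-value masking
#'
#' One-dimensional Gaussian convolution per chromosome. Missing bins carry
#' no weight: the kernel is renormalized over the non-missing neighbours
#' (masked convolution), so values near gaps are not dragged toward zero.
#' Missing bins stay missing. The same renormalization handles chromosome
#' ends (truncated kernel). `sigma = 0` returns the input unchanged.
#'
#' @param track A per-bin track tibble.
#' @param sigma Kernel standard deviation in bins (default 1); the kernel is
#'   truncated at 4 sigma.
#' @param column Value column to smooth.
#' @return The track with the smoothed values.
#' @export
smooth_track <- function(track, sigma = 1, column = "value") {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("`sigma` must be a single non-negative number (bins)")
  }
  if (sigma == 0) return(track)
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)

  out <- track
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    v <- track[[column]][sel]
    w <- as.numeric(!is.na(v))
    v0 <- ifelse(is.na(v), 0, v)
    num <- .conv_same(v0 * w, kern, r)
    den <- .conv_same(w, kern, r)
    sm <- ifelse(w > 0 & den > 0, num / den, NA_real_)
    out[[column]][sel] <- sm
  }
  out
}

# 'same'-length convolution with zero padding outside the vector
.conv_same <- function(x, kern, r) {
  n <- length(x)
  padded <- c(rep(0, r), x, rep(0, r))
  full <- stats::filter(padded, kern, method = "convolution", sides = 2)
  as.numeric(full[(r + 1):(r + n)])
}
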