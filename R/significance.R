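#' Empirical null of PIS differences from biological replicates
#'
#' Builds the null vector of residual-PIS values expected from technical and
#' biological replicate variation alone. With two replicates per condition,
#' let `d1 = PIS(cell1, rep1) - PIS(cell1, rep2)` and
#' `d2 = PIS(cell2, rep1) - PIS(cell2, rep2)` at each jointly defined bin;
#' the null vector collects the averaged replicate differences in all
#' possible orderings, i.e. the four values `(±d1 ± d2) / 2` per bin, giving
#' a vector of length 4N for N bins. Its mean is exactly 0 by construction
#' (every value appears with both signs), and it is well approximated by a
#' Gaussian, fitted here with the mean pinned at 0 (sd = root mean square).
#'
#' @param cell1,cell2 Lists of exactly two replicate PIS tracks per
#'   condition, normalized to the same reference as the residual they will
#'   be compared against.
#' @return A `daric_null` object: `sd`, `n_bins` (N), and `values` (the
#'   length-4N null vector).
#' @export
build_null <- function(cell1, cell2) {
  if (is.data.frame(cell1) || is.data.frame(cell2) ||
      length(cell1) != 2 || length(cell2) != 2) {
    stop("the replicate null requires exactly 2 replicates per condition")
  }
  v11 <- cell1[[1]]$value; v12 <- cell1[[2]]$value
  v21 <- cell2[[1]]$value; v22 <- cell2[[2]]$value
  ok <- !is.na(v11) & !is.na(v12) & !is.na(v21) & !is.na(v22)
  if (!any(ok)) stop("no bin is defined in all four replicate tracks")
  d1 <- v11[ok] - v12[ok]
  d2 <- v21[ok] - v22[ok]
  values <- c((d1 + d2) / 2, (-d1 + d2) / 2, (d1 - d2) / 2, (-d1 - d2) / 2)
  s <- sqrt(mean(values^2))
  if (s == 0) stop("replicates are identical; the null is degenerate")
  structure(list(sd = s, n_bins = sum(ok), values = values),
            class = "daric_null")
}

#' @export
print.daric_null <- function(x, ...) {
  cat("Replicate-derived empirical null\n")
  cat(sprintf("  N = %d bins, |null vector| = %d, sd = %.6g\n",
              x$n_bins, length(x$values), x$sd))
  invisible(x)
}

#' Per-bin significance of residual PIS
#'
#' One-sided p-value of each bin's residual under the replicate null, taken
#' in the direction of the observed sign: `p(b) = P(X > |dPIS(b)|)` for
#' `X ~ N(0, sd)` (so a residual of exactly 0 has p = 0.5). P-values more
#' significant than 1e-20 are set to 1e-20, and the significance score is
#' `-log10(p)`, hence capped at 20. `mode = "empirical"` uses the upper tail
#' of the null vector itself instead of the fitted Gaussian (diagnostic; it
#' cannot resolve p below 1/|null|).
#'
#' No multiple-testing correction is applied: domains are called on raw
#' scores, as the mean-score threshold operates on the score scale directly.
#'
#' @param residual Residual track from [compute_residual()].
#' @param null A `daric_null` object from [build_null()].
#' @param mode `"gaussian"` (default) or `"empirical"`.
#' @param cap Score cap (default 20, i.e. p floored at 1e-20).
#' @return A tibble `chrom`, `bin`, `start`, `end`, `delta`, `p`, `score`.
#' @export
score_bins <- function(residual, null, mode = c("gaussian", "empirical"),
                       cap = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(null, "daric_null"))
  v <- residual$value
  p <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  if (mode == "gaussian") {
    p[ok] <- stats::pnorm(abs(v[ok]), mean = 0, sd = null$sd,
                          lower.tail = FALSE)
  } else {
    nv <- null$values
    p[ok] <- vapply(abs(v[ok]), function(x) mean(nv > x), numeric(1))
    p[ok] <- pmax(p[ok], 1 / (length(nv) + 1))
  }
  p[ok] <- pmax(p[ok], 10^(-cap))
  out <- residual[, c("chrom", "bin", "start", "end")]
  out$delta <- v
  out$p <- p
  out$score <- -log10(p)
  .keep_grid(out, residual)
}

#' Call significant differential domains
#'
#' Only the extreme states (`Strong-` / `Strong+`, i.e. the lowest- and
#' highest-mean HMM states) are candidates; a candidate domain is kept when
#' the mean significance score over its bins is strictly greater than
#' `threshold` (default 2, i.e. mean p below 0.01).
#'
#' @param domains Domain tibble from [merge_domains()].
#' @param scores Significance tibble from [score_bins()].
#' @param threshold Minimum mean score, exclusive (default 2).
#' @return The significant domains with a `mean_score` column.
#' @export
call_significant_domains <- function(domains, scores, threshold = 2) {
  if (nrow(domains) == 0) {
    domains$mean_score <- numeric(0)
    return(domains)
  }
  k <- attr(domains, "k")
  if (is.null(k)) k <- max(domains$state)
  strong_states <- c(1L, k)
  if (!is.data.frame(scores)) {
    score_for <- function(cmp) scores[[cmp]]
  } else {
    score_for <- function(cmp) scores
  }
  mean_score <- vapply(seq_len(nrow(domains)), function(r) {
    sc <- score_for(domains$comparison[r])
    sel <- sc$chrom == domains$chrom[r] &
      sc$start >= domains$start[r] & sc$end <= domains$end[r] &
      !is.na(sc$score)
    if (!any(sel)) return(NA_real_)
    mean(sc$score[sel])
  }, numeric(1))
  domains$mean_score <- mean_score
  keep <- domains$state %in% strong_states &
    !is.na(mean_score) & mean_score > threshold
  domains[keep, ]
}
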