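#' MA coordinates of two PIS tracks
#'
#' For each bin where both tracks are defined, `M = PIS_ref - PIS_other`
#' (the residual) and `A = (PIS_ref + PIS_other) / 2` (the average level).
#' These are the coordinates on which between-sample normalization is
#' fitted. The reconstruction `PIS_ref = A + M/2`, `PIS_other = A - M/2`
#' holds exactly.
#'
#' @param pis_ref Reference PIS track (per-bin tibble).
#' @param pis_other Other sample's PIS track on the same bin grid.
#' @return A tibble `chrom`, `bin`, `start`, `end`, `M`, `A` (rows for all
#'   bins; `M`/`A` are `NA` where either input is missing).
#' @export
compute_ma <- function(pis_ref, pis_other) {
  if (nrow(pis_ref) != nrow(pis_other) ||
      !all(pis_ref$chrom == pis_other$chrom & pis_ref$bin == pis_other$bin)) {
    stop("the two PIS tracks are not on the same bin grid")
  }
  out <- pis_ref[, c("chrom", "bin", "start", "end")]
  out$M <- pis_ref$value - pis_other$value
  out$A <- (pis_ref$value + pis_other$value) / 2
  if (!any(!is.na(out$M))) stop("no bin is defined in both PIS tracks")
  .keep_grid(out, pis_ref)
}

#' Fit the MA normalization model on background bins
#'
#' Most of the genome does not change compartmentalization between two
#' samples; systematic scale/offset differences (enzyme, cell-cycle
#' composition, depth) therefore show up as a linear trend of M against A
#' over the background. Background bins are those whose residual M value
#' lies between the `low`-th and `high`-th percentile (default 15–85). A
#' robust line `M ~ a + b A` is fitted on them by iteratively reweighted
#' least squares with Tukey's bisquare loss, so bins with genuine large
#' changes that leak into the background window carry no weight.
#'
#' The background selection is itself iterated: the first pass selects on
#' raw M, later passes reselect on the residual from the current line and
#' refit. Selecting on the residual rather than on raw M avoids the slope
#' attenuation that one-shot response truncation induces when M carries a
#' real A-trend (see the methods vignette); three passes are ample for
#' convergence.
#'
#' @param ma MA table from [compute_ma()].
#' @param low,high Background percentile bounds, in \[0, 100\].
#' @param iterations Background reselection passes (default 3; 1 reproduces
#'   the one-shot selection on raw M).
#' @return A `daric_norm` object: intercept `a`, slope `b`, the bounds, and
#'   the number of background bins from the final pass.
#' @export
fit_normalization <- function(ma, low = 15, high = 85, iterations = 3) {
  if (!(low < high) || low < 0 || high > 100) {
    stop("background percentile bounds must satisfy 0 <= low < high <= 100")
  }
  ok <- !is.na(ma$M)
  m_all <- ma$M[ok]; a_all <- ma$A[ok]
  resid <- m_all
  coefs <- c(0, 0); n_bg <- 0L
  warned_const_a <- FALSE
  for (pass in seq_len(max(1, iterations))) {
    qs <- stats::quantile(resid, c(low, high) / 100, names = FALSE)
    bg <- resid >= qs[1] & resid <= qs[2]
    n_bg <- sum(bg)
    if (n_bg < 30) {
      stop("only ", n_bg, " background bins (< 30); cannot fit normalization")
    }
    m <- m_all[bg]; a <- a_all[bg]
    if (stats::sd(a) == 0 || all(m == m[1])) {
      if (stats::sd(a) == 0 && !warned_const_a) {
        warning("A values are constant on the background; ",
                "fitting an intercept-only model", call. = FALSE)
        warned_const_a <- TRUE
      }
      coefs <- c(stats::median(m), 0)
    } else {
      ols <- stats::lm(m ~ a)
      if (max(abs(stats::resid(ols))) < 1e-10 * max(1, stats::sd(m))) {
        # exact linear relation: IRLS scale is 0, OLS already is the answer
        coefs <- unname(stats::coef(ols))
      } else {
        fit <- MASS::rlm(m ~ a, psi = MASS::psi.bisquare, maxit = 50,
                         acc = 1e-8)
        coefs <- unname(stats::coef(fit))
      }
    }
    resid <- m_all - (coefs[1] + coefs[2] * a_all)
  }
  structure(
    list(intercept = coefs[1], slope = coefs[2],
         low = low, high = high, n_background = n_bg),
    class = "daric_norm")
}

#' @export
print.daric_norm <- function(x, ...) {
  cat("MA normalization model (robust bisquare fit)\n")
  cat(sprintf("  M = %.6g %+.6g * A\n", x$intercept, x$slope))
  cat(sprintf("  background: M in [%g, %g] percentile, %d bins\n",
              x$low, x$high, x$n_background))
  invisible(x)
}

#' Apply a normalization model
#'
#' The fitted line is extrapolated to every bin: the normalized residual is
#' `M_norm(b) = M(b) - (a + b A(b))`, and the normalized track for the
#' non-reference sample is `PIS_ref(b) - M_norm(b)`. The reference track is
#' never modified.
#'
#' @param pis_ref The reference PIS track (same grid as `ma`).
#' @param ma MA table from [compute_ma()] with the same orientation
#'   (`M = ref - other`) the model was fitted on.
#' @param model A `daric_norm` object from [fit_normalization()].
#' @return A tibble `chrom`, `bin`, `start`, `end`, `value` (the normalized
#'   non-reference track) and `m_norm` (the normalized residual).
#' @export
apply_normalization <- function(pis_ref, ma, model) {
  stopifnot(inherits(model, "daric_norm"))
  out <- ma[, c("chrom", "bin", "start", "end")]
  m_norm <- ma$M - (model$intercept + model$slope * ma$A)
  out$value <- pis_ref$value - m_norm
  out$m_norm <- m_norm
  .keep_grid(out, ma)
}

#' Normalize one PIS track against a reference
#'
#' Convenience wrapper: computes MA coordinates, fits the background robust
#' regression, and returns the normalized non-reference track.
#'
#' @inheritParams compute_ma
#' @inheritParams fit_normalization
#' @return A list with `track` (normalized `pis_other`, per-bin tibble with
#'   `value` and `m_norm`) and `model` (the `daric_norm` fit).
#' @export
normalize_to_reference <- function(pis_ref, pis_other, low = 15, high = 85) {
  ma <- compute_ma(pis_ref, pis_other)
  model <- fit_normalization(ma, low = low, high = high)
  list(track = apply_normalization(pis_ref, ma, model), model = model)
}
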