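#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normalization model
#'
#' @param x A `daric_norm` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy daric_norm
#' @export
tidy.daric_norm <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "A"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.daric_norm
#' @method glance daric_norm
#' @export
glance.daric_norm <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 bg_low = x$low, bg_high = x$high,
                 n_background = x$n_background)
}

#' Tidy an HMM segmentation
#'
#' `tidy()` returns the per-state emission table; `glance()` the fit
#' summary.
#'
#' @param x A `daric_hmm` object.
#' @param ... Unused.
#' @method tidy daric_hmm
#' @export
tidy.daric_hmm <- function(x, ...) {
  tibble::tibble(state = seq_len(x$k), label = x$labels,
                 mean = x$means, sd = x$sds,
                 stationary_weight = x$init)
}

#' @rdname tidy.daric_hmm
#' @method glance daric_hmm
#' @export
glance.daric_hmm <- function(x, ...) {
  tibble::tibble(k = x$k, log_likelihood = x$loglik,
                 n_obs = x$n_obs, n_iter = x$n_iter)
}

#' Tidy a replicate null model
#'
#' @param x A `daric_null` object.
#' @param ... Unused.
#' @method tidy daric_null
#' @export
tidy.daric_null <- function(x, ...) {
  tibble::tibble(sd = x$sd, n_bins = x$n_bins,
                 null_length = length(x$values))
}

#' @rdname tidy.daric_null
#' @method glance daric_null
#' @export
glance.daric_null <- function(x, ...) tidy.daric_null(x)

#' Tidy a variability segmentation
#'
#' @param x A `daric_varhmm` object.
#' @param ... Unused.
#' @return The per-state emission table on the original (mean, sd) scale.
#' @method tidy daric_varhmm
#' @export
tidy.daric_varhmm <- function(x, ...) x$emissions

#' @rdname tidy.daric_varhmm
#' @method glance daric_varhmm
#' @export
glance.daric_varhmm <- function(x, ...) {
  tibble::tibble(k = 5, log_likelihood = x$loglik,
                 n_obs = nrow(x$states))
}
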