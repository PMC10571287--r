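# Gaussian-emission hidden Markov machinery.
#
# The segmentation of residual PIS into differential-compartmentalization
# states is a K-state HMM with (diagonal) Gaussian emissions, trained by
# EM (Baum-Welch with per-step scaling) from a deterministic quantile-based
# initialization, decoded by Viterbi. Missing bins split chromosomes into
# independent observation sequences; no transition is modelled across a gap.

# log emission densities: T x K, diagonal Gaussian over d features
.hmm_logdens <- function(obs, means, sds) {
  T_ <- nrow(obs); K <- nrow(means)
  out <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    lp <- 0
    for (dd in seq_len(ncol(obs))) {
      lp <- lp + stats::dnorm(obs[, dd], means[k, dd], sds[k, dd], log = TRUE)
    }
    out[, k] <- lp
  }
  out
}

# scaled forward-backward for one sequence; returns loglik, gamma (T x K),
# xi_sum (K x K) and gamma1
.hmm_fb <- function(logB, trans, init) {
  T_ <- nrow(logB); K <- ncol(logB)
  mx <- apply(logB, 1, max)
  B <- exp(logB - mx)
  alpha <- matrix(0, T_, K)
  cvec <- numeric(T_)
  a <- init * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- as.vector(alpha[t - 1, ] %*% trans) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  xi_sum <- matrix(0, K, K)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      bb <- B[t + 1, ] * beta[t + 1, ]
      xi_sum <- xi_sum +
        (alpha[t, ] %o% bb) * trans / cvec[t + 1]
      beta[t, ] <- as.vector(trans %*% bb) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = sum(log(cvec) + mx), gamma = gamma, xi_sum = xi_sum,
       gamma1 = gamma[1, ])
}

# EM over a list of observation matrices (each T_s x d)
.hmm_em <- function(obs_list, means, sds, trans, init,
                    max_iter = 100, tol = 1e-6, sd_floor = NULL) {
  K <- nrow(means); d <- ncol(means)
  all_obs <- do.call(rbind, obs_list)
  if (is.null(sd_floor)) {
    sd_floor <- pmax(1e-6, apply(all_obs, 2, stats::sd) * 1e-3)
  }
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g_sum <- matrix(0, K, d)        # sum gamma * x
    g2_sum <- matrix(0, K, d)       # sum gamma * x^2
    g_tot <- numeric(K)
    xi_tot <- matrix(0, K, K)
    init_acc <- numeric(K)
    gammas <- vector("list", length(obs_list))
    for (s in seq_along(obs_list)) {
      obs <- obs_list[[s]]
      fb <- .hmm_fb(.hmm_logdens(obs, means, sds), trans, init)
      ll <- ll + fb$loglik
      gammas[[s]] <- fb$gamma
      g_tot <- g_tot + colSums(fb$gamma)
      g_sum <- g_sum + t(fb$gamma) %*% obs
      g2_sum <- g2_sum + t(fb$gamma) %*% (obs^2)
      xi_tot <- xi_tot + fb$xi_sum
      init_acc <- init_acc + fb$gamma1
    }
    # M step
    means_new <- g_sum / g_tot
    vars_new <- g2_sum / g_tot - means_new^2
    sds_new <- sqrt(pmax(vars_new, 0))
    sds_new <- pmax(sds_new, matrix(sd_floor, K, d, byrow = TRUE))
    rs <- rowSums(xi_tot)
    trans_new <- trans
    ok <- rs > 0
    trans_new[ok, ] <- xi_tot[ok, , drop = FALSE] / rs[ok]
    init_new <- init_acc / sum(init_acc)

    converged <- is.finite(ll) && (ll - ll_old) < tol * (1 + abs(ll))
    means <- means_new; sds <- sds_new; trans <- trans_new; init <- init_new
    if (converged && iter > 1) break
    ll_old <- ll
  }
  list(means = means, sds = sds, trans = trans, init = init,
       loglik = ll, n_iter = iter)
}

# Viterbi decoding of one sequence; returns integer state path
.hmm_viterbi <- function(obs, means, sds, trans, init) {
  logB <- .hmm_logdens(obs, means, sds)
  T_ <- nrow(logB); K <- ncol(logB)
  lt <- log(trans)
  delta <- log(init) + logB[1, ]
  psi <- matrix(0L, T_, K)
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- delta + lt           # K x K: cand[i, j] = delta_i + log t_ij
      psi[t, ] <- apply(cand, 2, which.max)
      delta <- apply(cand, 2, max) + logB[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1) {
    for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

#' Residual PIS between two conditions
#'
#' The observation sequence for differential segmentation: the per-bin
#' difference of replicate-averaged PIS, `mean(cell1 reps) - mean(cell2
#' reps)`, computed after all tracks have been normalized to a common
#' reference. A bin is missing whenever any required input is missing there.
#'
#' @param cell1,cell2 A single per-bin PIS track or a list of replicate
#'   tracks per condition (all on one bin grid).
#' @return A per-bin track tibble of the residual.
#' @export
compute_residual <- function(cell1, cell2) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  cell1 <- as_list(cell1); cell2 <- as_list(cell2)
  tracks <- c(cell1, cell2)
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (nrow(tr) != nrow(ref) ||
        !all(tr$chrom == ref$chrom & tr$bin == ref$bin)) {
      stop("replicate tracks are not on the same bin grid")
    }
  }
  m1 <- rowMeans(do.call(cbind, lapply(cell1, `[[`, "value")))
  m2 <- rowMeans(do.call(cbind, lapply(cell2, `[[`, "value")))
  out <- ref[, c("chrom", "bin", "start", "end")]
  out$value <- m1 - m2
  .keep_grid(out, ref)
}

# split one or more residual tracks into gap-free observation segments
.hmm_segments <- function(residuals, columns) {
  segs <- list()
  for (cmp in names(residuals)) {
    tr <- residuals[[cmp]]
    vals <- as.matrix(tr[, columns, drop = FALSE])
    ok <- stats::complete.cases(vals)
    for (ch in unique(tr$chrom)) {
      sel <- which(tr$chrom == ch & ok)
      if (length(sel) == 0) next
      brk <- cumsum(c(TRUE, diff(tr$bin[sel]) != 1L))
      for (g in split(sel, brk)) {
        segs[[length(segs) + 1L]] <-
          list(comparison = cmp, rows = g,
               obs = vals[g, , drop = FALSE])
      }
    }
  }
  segs
}

#' Segment residual PIS with a Gaussian-emission HMM
#'
#' Fits a K-state hidden Markov model to one or more residual PIS tracks and
#' decodes the per-bin state by Viterbi. When several comparisons are given
#' (e.g. consecutive time points of a differentiation course) one unified
#' model is trained on all of them — chromosomes and comparisons enter as
#' independent observation sequences — and each comparison is decoded under
#' that shared model, so states are comparable across comparisons.
#'
#' States are relabelled in ascending order of emission mean; for the default
#' `k = 4` they are named `Strong-`, `Weak-`, `Weak+`, `Strong+`, matching
#' the four qualitative classes of conventional compartment-switching
#' analysis. Training is deterministic (quantile-based initialization) unless
#' `restarts > 0`, in which case seeded random restarts are run and the fit
#' with the highest log-likelihood kept.
#'
#' @param residuals A residual track tibble (from [compute_residual()]) or a
#'   named list of them, one per comparison.
#' @param k Number of states (default 4).
#' @param seed Integer seed controlling the random restarts.
#' @param restarts Number of additional randomized EM starts (default 0:
#'   fully deterministic).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `daric_hmm` object with elements `k`, `means`, `sds`,
#'   `transitions`, `init`, `labels`, `loglik`, and `states` — a tibble
#'   (`comparison`, `chrom`, `bin`, `start`, `end`, `delta`, `state`,
#'   `label`) of the decoded path.
#' @export
fit_hmm <- function(residuals, k = 4, seed = NULL, restarts = 0,
                    max_iter = 100, tol = 1e-6) {
  if (k < 2) stop("`k` must be at least 2")
  if (is.data.frame(residuals)) residuals <- list(comparison = residuals)
  if (is.null(names(residuals)) || any(names(residuals) == "")) {
    names(residuals) <- paste0("comparison", seq_along(residuals))
  }
  segs <- .hmm_segments(residuals, "value")
  obs_list <- lapply(segs, `[[`, "obs")
  all_obs <- unlist(obs_list)
  if (length(all_obs) < 10 * k) {
    stop("only ", length(all_obs), " non-missing bins; need at least ", 10 * k)
  }
  s0 <- stats::sd(all_obs)
  if (s0 == 0) stop("degenerate residual track: zero variance")

  # deterministic initialization: quantile archetypes refined by k-means
  # (multi-start under a fixed internal seed, so the default fit is still
  # a pure function of the data)
  q <- stats::quantile(all_obs, probs = (2 * seq_len(k) - 1) / (2 * k),
                       names = FALSE)
  km <- suppressWarnings(stats::kmeans(all_obs, centers = unique(q),
                                       iter.max = 50))
  if (length(unique(q)) == k) {
    old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    set.seed(104729L)
    km2 <- tryCatch(
      suppressWarnings(stats::kmeans(all_obs, centers = k, nstart = 25,
                                     iter.max = 50)),
      error = function(e) km)
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
    if (km2$tot.withinss < km$tot.withinss) km <- km2
  }
  kk <- nrow(km$centers)
  mu0 <- as.vector(km$centers)
  sd0 <- vapply(seq_len(kk), function(g) {
    v <- all_obs[km$cluster == g]
    if (length(v) > 1) max(stats::sd(v), s0 / 100) else s0
  }, numeric(1))
  ord0 <- order(mu0)
  mu0 <- mu0[ord0]; sd0 <- sd0[ord0]
  if (kk < k) {   # k-means collapsed levels; fall back to quantile spread
    mu0 <- q; sd0 <- rep(s0, k)
  }
  trans0 <- matrix(0.1 / (k - 1), k, k); diag(trans0) <- 0.9
  init0 <- rep(1 / k, k)
  obs_mats <- lapply(obs_list, function(x) matrix(x, ncol = 1))

  fit <- .hmm_em(obs_mats, matrix(mu0, ncol = 1),
                 matrix(sd0, k, 1), trans0, init0,
                 max_iter = max_iter, tol = tol)
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      q_r <- sort(q + stats::rnorm(k, 0, s0 / 2))
      cand <- .hmm_em(obs_mats, matrix(q_r, ncol = 1),
                      matrix(s0, k, 1), trans0, init0,
                      max_iter = max_iter, tol = tol)
      if (cand$loglik > fit$loglik) fit <- cand
    }
  }

  # relabel ascending by emission mean; ties broken by smaller sd
  mu <- fit$means[, 1]; sg <- fit$sds[, 1]
  if (anyDuplicated(paste(mu, sg))) {
    stop("degenerate fit: two states share identical emission parameters")
  }
  ord <- order(mu, sg)
  perm <- match(seq_len(k), ord)          # old state -> new index
  model <- list(
    means = mu[ord], sds = sg[ord],
    transitions = fit$trans[ord, ord, drop = FALSE],
    init = fit$init[ord])
  labels <- if (k == 4) {
    c("Strong-", "Weak-", "Weak+", "Strong+")
  } else {
    paste0("S", seq_len(k))
  }

  states <- purrr::map_dfr(seq_along(segs), function(s) {
    seg <- segs[[s]]
    path <- .hmm_viterbi(matrix(seg$obs, ncol = 1),
                         matrix(model$means, ncol = 1),
                         matrix(model$sds, ncol = 1),
                         model$transitions, model$init)
    tr <- residuals[[seg$comparison]][seg$rows, ]
    tibble::tibble(comparison = seg$comparison,
                   chrom = tr$chrom, bin = tr$bin,
                   start = tr$start, end = tr$end,
                   delta = tr$value, state = path,
                   label = labels[path])
  })
  structure(
    list(k = k, means = model$means, sds = model$sds,
         transitions = model$transitions, init = model$init,
         labels = labels, loglik = fit$loglik, n_iter = fit$n_iter,
         n_obs = length(all_obs), states = states,
         bin_size = bin_size(residuals[[1]])),
    class = "daric_hmm")
}

#' @export
print.daric_hmm <- function(x, ...) {
  cat("Gaussian-emission HMM segmentation (", x$k, " states)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), "on", x$n_obs, "bins\n")
  em <- data.frame(label = x$labels, mean = x$means, sd = x$sds)
  print(em, row.names = FALSE)
  invisible(x)
}

#' Merge decoded states into domains
#'
#' Maximal runs of consecutive bins sharing one state become domains;
#' missing bins break runs (a domain never spans a gap). Runs shorter than
#' `min_bins` are absorbed into the flanking state whose emission mean is
#' closer to their own state's emission mean, and merging is repeated until
#' stable.
#'
#' @param fit A `daric_hmm` object.
#' @param min_bins Minimum domain length in bins (default 1: no absorption).
#' @return A tibble `comparison`, `chrom`, `start`, `end`, `state`, `label`,
#'   `n_bins`, `mean_delta`.
#' @export
merge_domains <- function(fit, min_bins = 1) {
  stopifnot(inherits(fit, "daric_hmm"))
  st <- fit$states
  if (nrow(st) == 0) {
    empty <- tibble::tibble(comparison = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            state = integer(0), label = character(0),
                            n_bins = integer(0), mean_delta = numeric(0))
    attr(empty, "k") <- fit$k
    attr(empty, "labels") <- fit$labels
    return(empty)
  }
  out <- purrr::map_dfr(split(st, paste(st$comparison, st$chrom)), function(tr) {
    tr <- tr[order(tr$bin), ]
    seg_id <- cumsum(c(TRUE, diff(tr$bin) != 1L))
    purrr::map_dfr(split(tr, seg_id), function(seg) {
      state <- seg$state
      repeat {
        run <- cumsum(c(TRUE, diff(state) != 0))
        len <- tapply(run, run, length)
        short <- which(len < min_bins)
        if (length(short) == 0 || length(len) == 1) break
        changed <- FALSE
        for (rr in short) {
          idx <- which(run == rr)
          left <- if (rr > 1) state[max(which(run == rr - 1))] else NA
          right <- if (rr < length(len)) state[min(which(run == rr + 1))] else NA
          target <- if (is.na(left)) right else if (is.na(right)) left else {
            dl <- abs(fit$means[left] - fit$means[state[idx[1]]])
            dr <- abs(fit$means[right] - fit$means[state[idx[1]]])
            if (dl <= dr) left else right
          }
          if (!is.na(target) && target != state[idx[1]]) {
            state[idx] <- target
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      run <- cumsum(c(TRUE, diff(state) != 0))
      run_state <- as.integer(tapply(state, run, `[`, 1))
      tibble::tibble(
        comparison = seg$comparison[1],
        chrom = seg$chrom[1],
        start = as.numeric(tapply(seg$start, run, min)),
        end = as.numeric(tapply(seg$end, run, max)),
        state = run_state,
        label = fit$labels[run_state],
        n_bins = as.integer(tapply(run, run, length)),
        mean_delta = as.numeric(tapply(seg$delta, run, mean)))
    })
  })
  out <- out[order(out$comparison, out$chrom, out$start), ]
  attr(out, "k") <- fit$k
  attr(out, "labels") <- fit$labels
  out
}
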