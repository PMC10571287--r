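#' Per-bin mean and standard deviation across a panel of PIS tracks
#'
#' Summarizes compartmentalization across a panel of samples that have all
#' been normalized to one common reference. Bins with fewer than two
#' contributing samples are missing.
#'
#' @param tracks A list of at least two normalized PIS tracks on one grid.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @return A tibble `chrom`, `bin`, `start`, `end`, `mean`, `sd`, `n`.
#' @export
summarize_panel <- function(tracks, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.data.frame(tracks) || length(tracks) < 2) {
    stop("a panel summary needs at least 2 tracks")
  }
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (nrow(tr) != nrow(ref) ||
        !all(tr$chrom == ref$chrom & tr$bin == ref$bin)) {
      stop("panel tracks are not on the same bin grid")
    }
  }
  V <- do.call(cbind, lapply(tracks, `[[`, "value"))
  n <- rowSums(!is.na(V))
  mu <- rowMeans(V, na.rm = TRUE)
  ss <- rowSums((V - mu)^2, na.rm = TRUE)
  denom <- if (sd_type == "population") n else n - 1
  sdv <- sqrt(ifelse(denom > 0, ss / denom, NA_real_))
  miss <- n < 2
  out <- ref[, c("chrom", "bin", "start", "end")]
  out$mean <- ifelse(miss, NA_real_, mu)
  out$sd <- ifelse(miss, NA_real_, sdv)
  out$n <- as.integer(n)
  .keep_grid(out, ref)
}

#' Segment compartmentalization variability into five states
#'
#' Fits a 5-state HMM with diagonal 2-D Gaussian emissions to the per-bin
#' (mean, sd) of PIS across the panel, then names the states by their
#' emission parameters: the state with the largest sd emission is
#' `variable`; of the remaining four, the two with the smallest sd are the
#' conserved compartments — `conA` (higher mean) and `conB` (lower mean) —
#' and the other two are `varA` / `varB` by the same mean ordering. Both
#' features are standardized before fitting (they live on different scales)
#' and emissions are reported back on the original scale.
#'
#' @param summary Panel summary from [summarize_panel()].
#' @param seed Integer seed for the optional randomized restarts.
#' @param restarts Number of additional randomized EM starts (default 0:
#'   deterministic archetype initialization).
#' @param max_iter,tol EM controls.
#' @return A `daric_varhmm` object with `states` (per-bin tibble `chrom`,
#'   `bin`, `start`, `end`, `mean`, `sd`, `state`, `label`), `emissions`
#'   (per-state 2-D means/sds on the original scale), `transitions`.
#' @export
segment_variability <- function(summary, seed = NULL, restarts = 0,
                                max_iter = 100, tol = 1e-6) {
  ok <- !is.na(summary$mean) & !is.na(summary$sd)
  if (sum(ok) < 50) stop("need at least 50 defined bins to segment")
  mu_c <- mean(summary$mean[ok]); mu_s <- stats::sd(summary$mean[ok])
  sd_c <- mean(summary$sd[ok]); sd_s <- stats::sd(summary$sd[ok])
  if (mu_s == 0 || sd_s == 0) {
    stop("degenerate panel summary: constant mean or sd feature")
  }
  std <- summary
  std$z_mean <- (summary$mean - mu_c) / mu_s
  std$z_sd <- (summary$sd - sd_c) / sd_s

  segs <- .hmm_segments(list(panel = std), c("z_mean", "z_sd"))
  obs_list <- lapply(segs, `[[`, "obs")
  all_obs <- do.call(rbind, obs_list)

  qm <- stats::quantile(all_obs[, 1], c(.10, .30, .50, .70, .90), names = FALSE)
  qs <- stats::quantile(all_obs[, 2], c(.25, .75, .95), names = FALSE)
  # archetypes: conB, varB, variable, varA, conA in standardized space,
  # refined by (deterministic, archetype-seeded) k-means before EM
  means0 <- rbind(c(qm[1], qs[1]), c(qm[2], qs[2]), c(qm[3], qs[3]),
                  c(qm[4], qs[2]), c(qm[5], qs[1]))
  km <- suppressWarnings(stats::kmeans(all_obs, centers = means0,
                                       iter.max = 50))
  # multi-start refinement under a fixed internal seed keeps the whole
  # initialization deterministic while escaping bad archetype placements
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  set.seed(104729L)
  km2 <- suppressWarnings(stats::kmeans(all_obs, centers = 5, nstart = 25,
                                        iter.max = 50))
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }
  if (km2$tot.withinss < km$tot.withinss) km <- km2
  means0 <- unname(km$centers)
  sds0 <- matrix(0, 5, 2)
  for (k in 1:5) {
    members <- all_obs[km$cluster == k, , drop = FALSE]
    sds0[k, ] <- if (nrow(members) > 1) {
      pmax(apply(members, 2, stats::sd), 0.05)
    } else c(0.5, 0.5)
  }
  trans0 <- matrix(0.1 / 4, 5, 5); diag(trans0) <- 0.9
  init0 <- rep(0.2, 5)

  fit <- .hmm_em(obs_list, means0, sds0, trans0, init0,
                 max_iter = max_iter, tol = tol)
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      jit <- means0 + matrix(stats::rnorm(10, 0, 0.5), 5, 2)
      cand <- .hmm_em(obs_list, jit, sds0, trans0, init0,
                      max_iter = max_iter, tol = tol)
      if (cand$loglik > fit$loglik) fit <- cand
    }
  }

  # label assignment from emission parameters
  sd_em <- fit$means[, 2]
  mean_em <- fit$means[, 1]
  labels <- character(5)
  variable <- which.max(sd_em)
  labels[variable] <- "variable"
  rest <- setdiff(1:5, variable)
  con <- rest[order(sd_em[rest])][1:2]
  var <- setdiff(rest, con)
  labels[con[which.max(mean_em[con])]] <- "conA"
  labels[con[which.min(mean_em[con])]] <- "conB"
  labels[var[which.max(mean_em[var])]] <- "varA"
  labels[var[which.min(mean_em[var])]] <- "varB"

  states <- purrr::map_dfr(seq_along(segs), function(s) {
    seg <- segs[[s]]
    path <- .hmm_viterbi(seg$obs, fit$means, fit$sds,
                         fit$trans, fit$init)
    rows <- std[seg$rows, ]
    tibble::tibble(chrom = rows$chrom, bin = rows$bin,
                   start = rows$start, end = rows$end,
                   mean = rows$mean, sd = rows$sd,
                   state = path, label = labels[path])
  })
  emissions <- tibble::tibble(
    state = 1:5, label = labels,
    mean_pis = fit$means[, 1] * mu_s + mu_c,
    sd_pis = fit$means[, 2] * sd_s + sd_c,
    mean_pis_sd = fit$sds[, 1] * mu_s,
    sd_pis_sd = fit$sds[, 2] * sd_s)
  structure(
    list(states = states, emissions = emissions,
         transitions = fit$trans, loglik = fit$loglik,
         labels = labels, bin_size = bin_size(summary)),
    class = "daric_varhmm")
}

#' @export
print.daric_varhmm <- function(x, ...) {
  cat("Compartment variability segmentation (5 states)\n")
  print(as.data.frame(x$emissions), row.names = FALSE)
  invisible(x)
}

#' Variability states as domains
#'
#' Merges consecutive bins sharing a variability state into intervals.
#'
#' @param fit A `daric_varhmm` object.
#' @return A tibble `chrom`, `start`, `end`, `label`, `n_bins`,
#'   `mean_delta` (mean of the panel mean-PIS over the domain).
#' @export
variability_domains <- function(fit) {
  stopifnot(inherits(fit, "daric_varhmm"))
  st <- fit$states
  purrr::map_dfr(split(st, st$chrom), function(tr) {
    tr <- tr[order(tr$bin), ]
    run <- cumsum(c(TRUE, diff(tr$bin) != 1L | diff(tr$state) != 0))
    tibble::tibble(chrom = tr$chrom[1],
                   start = tapply(tr$start, run, min),
                   end = tapply(tr$end, run, max),
                   label = tr$label[match(unique(run), run)],
                   n_bins = as.integer(tapply(run, run, length)),
                   mean_delta = as.numeric(tapply(tr$mean, run, mean)))
  })
}

#' Observed/expected enrichment of features in domains
#'
#' For each domain state, compares the observed number of subset features
#' (e.g. differentially expressed genes) falling in that state's domains
#' with the number expected from the state's share of the whole universe
#' (e.g. all genes):
#' `expected_i = N_subset * N_universe_in_i / N_universe`, and the reported
#' enrichment is `log2(observed_i / expected_i)`. Features are assigned to
#' domains by midpoint containment (or any overlap with `by = "any"`, using
#' the domain with the largest overlap).
#'
#' @param domains Domain tibble with `chrom`, `start`, `end`, `label`.
#' @param universe Tibble of all features (`chrom`, `start`, `end`, and an
#'   id column `name` if available).
#' @param subset Tibble of the features of interest; every row must also be
#'   present in `universe` (matched on chrom/start/end).
#' @param by `"midpoint"` (default) or `"any"`.
#' @return A tibble `label`, `n_universe`, `n_subset`, `expected`,
#'   `log2_enrichment` (NA where expected is 0, flagged by `undefined`).
#' @export
enrich_features <- function(domains, universe, subset,
                            by = c("midpoint", "any")) {
  by <- match.arg(by)
  key <- function(x) paste(x$chrom, x$start, x$end)
  if (!all(key(subset) %in% key(universe))) {
    stop("`subset` contains features absent from `universe`")
  }
  assign_state <- function(feat) {
    vapply(seq_len(nrow(feat)), function(r) {
      dd <- domains[domains$chrom == feat$chrom[r], ]
      if (nrow(dd) == 0) return(NA_character_)
      if (by == "midpoint") {
        mid <- (feat$start[r] + feat$end[r]) / 2
        hit <- which(dd$start <= mid & mid < dd$end)
        if (length(hit) == 0) return(NA_character_)
        dd$label[hit[1]]
      } else {
        ov <- pmin(dd$end, feat$end[r]) - pmax(dd$start, feat$start[r])
        if (max(ov) <= 0) return(NA_character_)
        dd$label[which.max(ov)]
      }
    }, character(1))
  }
  u_state <- assign_state(universe)
  s_state <- u_state[match(key(subset), key(universe))]
  states <- unique(domains$label)
  n_u_tot <- nrow(universe)
  n_s_tot <- nrow(subset)
  purrr::map_dfr(states, function(st) {
    n_u <- sum(u_state == st, na.rm = TRUE)
    n_s <- sum(s_state == st, na.rm = TRUE)
    expected <- n_s_tot * n_u / n_u_tot
    tibble::tibble(
      label = st, n_universe = n_u, n_subset = n_s, expected = expected,
      log2_enrichment = ifelse(expected > 0, log2(n_s / expected), NA_real_),
      undefined = expected == 0)
  })
}
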