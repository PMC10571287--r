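#' Configuration for synthetic Hi-C compartment data
#'
#' Collects the generative parameters for the synthetic checkerboard model:
#' chromosomes are tiled with alternating A/B compartment runs; obs/exp
#' contact values are `w` for same-compartment pairs and `c` for
#' cross-compartment pairs (`w > c > 0`), modulated by per-bin strength
#' multipliers and multiplicative lognormal noise. PIS-level experiments add
#' replicate Gaussian noise `tau` and between-sample offset/scale
#' distortions `alpha` / `beta` (emulating enzyme and protocol differences).
#'
#' Defaults describe a 400-bin chromosome at 50 kb (a 20 Mb arm), mean
#' compartment run of 15 bins (~750 kb domains), within/cross obs/exp levels
#' 1.5 / 0.5 (checkerboard contrast of 3), and replicate noise sd 0.1 on the
#' PIS scale.
#'
#' @param n_bins Number of bins on the simulated chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name.
#' @param mean_run_bins Mean length (bins) of an A or B compartment run.
#' @param w,c Within- and cross-compartment obs/exp levels; `w > c > 0`.
#' @param tau Replicate noise sd (PIS scale) or lognormal log-sd (matrix).
#' @param alpha,beta Between-sample offset and scale distortion applied to
#'   the second sample (`cell2 = beta * truth + alpha`).
#' @param strength Optional tibble (`from_bin`, `to_bin`, `multiplier`) of
#'   per-domain contact strength multipliers planted into the matrix.
#' @param seed Integer seed; every simulated object is reproducible from it.
#' @return A `daric_sim_config` list.
#' @export
simulation_config <- function(n_bins = 400, bin_size = 50000, chrom = "chrS",
                              mean_run_bins = 15, w = 1.5, c = 0.5,
                              tau = 0.1, alpha = 0, beta = 1,
                              strength = NULL, seed = 1) {
  if (!(w > c && c > 0)) stop("need w > c > 0")
  if (tau < 0) stop("`tau` must be non-negative")
  if (mean_run_bins < 1) stop("`mean_run_bins` must be >= 1")
  structure(list(n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
                 chrom = chrom, mean_run_bins = mean_run_bins,
                 w = w, c = c, tau = tau, alpha = alpha, beta = beta,
                 strength = strength, seed = as.integer(seed)),
            class = "daric_sim_config")
}

# bins grid for a config
.sim_bins <- function(config) {
  sizes <- stats::setNames(config$n_bins * config$bin_size, config$chrom)
  genome_bins(sizes, config$bin_size)
}

# alternating A/B run layout; geometric run lengths, seeded
.sim_layout <- function(config) {
  set.seed(config$seed)
  lab <- character(0)
  cur <- "A"
  while (length(lab) < config$n_bins) {
    len <- 1L + stats::rgeom(1, 1 / config$mean_run_bins)
    lab <- c(lab, rep(cur, len))
    cur <- if (cur == "A") "B" else "A"
  }
  lab[seq_len(config$n_bins)]
}

#' Simulate an obs/exp contact matrix with planted compartments
#'
#' Builds the dense checkerboard obs/exp matrix: `oe(i, j) = w` when bins i
#' and j share the planted compartment and `c` otherwise, multiplied by the
#' two bins' strength multipliers and by lognormal noise
#' `exp(N(0, tau^2))`. Returned in the same sparse-triplet form the readers
#' produce, together with the planted compartment truth.
#'
#' @param config A [simulation_config()].
#' @return A list: `contacts` (triplet tibble with `chrom`/`bin_size`
#'   attributes), `compartments` (truth calls on the grid), `bins`,
#'   `strength` (per-bin multiplier vector).
#' @export
simulate_contact_matrix <- function(config) {
  stopifnot(inherits(config, "daric_sim_config"))
  lab <- .sim_layout(config)
  bins <- .sim_bins(config)
  n <- config$n_bins
  s <- rep(1, n)
  if (!is.null(config$strength)) {
    for (r in seq_len(nrow(config$strength))) {
      sel <- (config$strength$from_bin[r]:config$strength$to_bin[r]) + 1L
      s[sel] <- s[sel] * config$strength$multiplier[r]
    }
  }
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- idx[, 1] - 1L; j <- idx[, 2] - 1L
  same <- lab[i + 1L] == lab[j + 1L]
  base <- ifelse(same, config$w, config$c)
  # strength = compartmentalization strength: same-type contacts are
  # enriched and cross-type contacts depleted by the bins' multipliers
  strength_factor <- (s[i + 1L] * s[j + 1L])^ifelse(same, 1, -1)
  set.seed(config$seed + 1L)
  noise <- if (config$tau > 0) {
    exp(stats::rnorm(length(base), 0, config$tau))
  } else 1
  contacts <- tibble::tibble(i = i, j = j,
                             oe = base * strength_factor * noise)
  attr(contacts, "chrom") <- config$chrom
  attr(contacts, "bin_size") <- config$bin_size
  comp <- bins[, c("chrom", "bin", "start", "end")]
  comp$compartment <- lab
  list(contacts = contacts, compartments = .keep_grid(comp, bins),
       bins = bins, strength = s)
}

#' Simulate a two-condition replicated PIS experiment
#'
#' Generates the inputs of the differential pipeline with known truth. A
#' shared base PIS track follows the planted compartment layout
#' (`+log2(w/c)` on A runs, `-log2(w/c)` on B runs, with per-run level
#' jitter and smooth bin-level variation so the MA regression sees a
#' realistic spread). Condition 1 equals the base plus any planted
#' differential effects; condition 2 is the distorted base
#' `beta * base + alpha` (no biological change). Each replicate adds
#' independent Gaussian noise of sd `tau`. The residual after perfect
#' normalization is therefore the planted effect itself.
#'
#' @param config A [simulation_config()].
#' @param planted Optional tibble (`from_bin`, `to_bin`, `delta`) of
#'   differential-PIS effects added to condition 1.
#' @param n_reps Replicates per condition (default 2).
#' @return A list: `bins`, `cell1`, `cell2` (lists of replicate tracks),
#'   `base` (the undistorted truth track), and `truth` (planted domains with
#'   coordinates and expected labels).
#' @export
simulate_two_cell_experiment <- function(config, planted = NULL, n_reps = 2) {
  stopifnot(inherits(config, "daric_sim_config"))
  lab <- .sim_layout(config)
  bins <- .sim_bins(config)
  n <- config$n_bins
  amp <- log2(config$w / config$c)

  set.seed(config$seed + 2L)
  run <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  run_jit <- stats::rnorm(max(run), 0, 0.25)
  wiggle <- stats::filter(stats::rnorm(n + 20, 0, 0.35), rep(1 / 5, 5),
                          sides = 2, method = "convolution")
  wiggle <- as.numeric(wiggle[11:(10 + n)])
  base <- ifelse(lab == "A", amp, -amp) + run_jit[run] + wiggle

  truth1 <- base
  if (!is.null(planted) && nrow(planted) > 0) {
    for (r in seq_len(nrow(planted))) {
      sel <- (planted$from_bin[r]:planted$to_bin[r]) + 1L
      truth1[sel] <- truth1[sel] + planted$delta[r]
    }
  }
  truth2 <- config$beta * base + config$alpha

  mk_track <- function(values) {
    tr <- bins[, c("chrom", "bin", "start", "end")]
    tr$value <- values
    .keep_grid(tr, bins)
  }
  set.seed(config$seed + 3L)
  cell1 <- lapply(seq_len(n_reps), function(r) {
    mk_track(truth1 + stats::rnorm(n, 0, config$tau))
  })
  cell2 <- lapply(seq_len(n_reps), function(r) {
    mk_track(truth2 + stats::rnorm(n, 0, config$tau))
  })

  truth <- if (is.null(planted) || nrow(planted) == 0) {
    tibble::tibble(chrom = character(0), start = numeric(0),
                   end = numeric(0), from_bin = integer(0),
                   to_bin = integer(0), delta = numeric(0),
                   label = character(0))
  } else {
    tibble::tibble(chrom = config$chrom,
                   start = planted$from_bin * config$bin_size,
                   end = (planted$to_bin + 1) * config$bin_size,
                   from_bin = as.integer(planted$from_bin),
                   to_bin = as.integer(planted$to_bin),
                   delta = planted$delta,
                   label = ifelse(planted$delta > 0, "Strong+", "Strong-"))
  }
  list(bins = bins, cell1 = cell1, cell2 = cell2,
       base = mk_track(base), truth = truth)
}

#' Simulate a normalized multi-sample PIS panel
#'
#' Produces a panel of PIS tracks sharing the compartment backbone, with a
#' planted set of variable regions: within `variable_bins` each sample gets
#' an independent perturbation of sd `variable_sd`, elsewhere samples differ
#' only by replicate-level noise `tau`. Feeds [summarize_panel()] and
#' [segment_variability()].
#'
#' @param config A [simulation_config()].
#' @param n_samples Number of samples in the panel.
#' @param variable_bins Integer vector of 0-based bins made variable.
#' @param variable_sd Cross-sample sd planted in the variable bins.
#' @return A list: `bins`, `tracks` (list of per-sample tracks), `base`,
#'   `variable_bins`.
#' @export
simulate_panel <- function(config, n_samples = 8, variable_bins = integer(0),
                           variable_sd = 0.8) {
  stopifnot(inherits(config, "daric_sim_config"))
  lab <- .sim_layout(config)
  bins <- .sim_bins(config)
  n <- config$n_bins
  amp <- log2(config$w / config$c)
  set.seed(config$seed + 4L)
  base <- ifelse(lab == "A", amp, -amp) + stats::rnorm(n, 0, 0.2)
  tracks <- lapply(seq_len(n_samples), function(s) {
    v <- base + stats::rnorm(n, 0, config$tau)
    if (length(variable_bins) > 0) {
      v[variable_bins + 1L] <- base[variable_bins + 1L] +
        stats::rnorm(length(variable_bins), 0, variable_sd)
    }
    tr <- bins[, c("chrom", "bin", "start", "end")]
    tr$value <- v
    .keep_grid(tr, bins)
  })
  list(bins = bins, tracks = tracks, base = base,
       variable_bins = as.integer(variable_bins))
}

#' Write a simulated contact matrix in juicer-dump triplet form
#'
#' @param sim Result of [simulate_contact_matrix()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_contact_matrix <- function(sim, path) {
  bs <- attr(sim$contacts, "bin_size")
  out <- data.frame(pos_i = sim$contacts$i * bs,
                    pos_j = sim$contacts$j * bs,
                    oe = sprintf("%.17g", sim$contacts$oe))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
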