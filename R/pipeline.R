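#' Full differential-compartmentalization comparison
#'
#' Runs the complete pipeline on replicate PIS tracks of two conditions:
#' Gaussian smoothing, MA normalization of the non-reference condition's
#' replicates against the reference (the replicate-mean track of condition
#' 1), residual computation, K-state HMM segmentation, replicate-null
#' significance scoring, and the final significant Strong± domain calls.
#'
#' Significance requires exactly two replicates per condition (the
#' replicate-null construction is defined for the 2+2 design); with other
#' designs the segmentation still runs and the significance outputs are
#' `NULL`.
#'
#' @param cell1,cell2 Lists of replicate PIS tracks (condition 1 is the
#'   reference).
#' @param sigma Smoothing sd in bins (default 1).
#' @param k HMM state number (default 4).
#' @param bg Background percentile bounds for normalization.
#' @param threshold Minimum mean significance score for a Strong± domain.
#' @param seed Seed for HMM restarts.
#' @param restarts Randomized EM restarts (default 0, deterministic).
#' @param min_bins Minimum domain length in bins.
#' @param comparison Name recorded on the residual.
#' @param out_dir Optional directory; when given, all tracks and domain
#'   calls are written there as bedGraph/BED/TSV plus a run manifest.
#' @return A list: `residual`, `hmm`, `domains`, `null`, `scores`,
#'   `significant`, `norm_models`, `reference`.
#' @export
daric_compare <- function(cell1, cell2, sigma = 1, k = 4, bg = c(15, 85),
                          threshold = 2, seed = 0, restarts = 0,
                          min_bins = 1, comparison = "cell1_vs_cell2",
                          out_dir = NULL) {
  if (is.data.frame(cell1)) cell1 <- list(cell1)
  if (is.data.frame(cell2)) cell2 <- list(cell2)

  cell1_sm <- lapply(cell1, smooth_track, sigma = sigma)
  cell2_sm <- lapply(cell2, smooth_track, sigma = sigma)

  # reference: replicate-mean of condition 1 (never modified)
  ref <- cell1_sm[[1]]
  V <- do.call(cbind, lapply(cell1_sm, `[[`, "value"))
  ref$value <- rowMeans(V)

  norm <- lapply(cell2_sm, function(tr) {
    normalize_to_reference(ref, tr, low = bg[1], high = bg[2])
  })
  cell2_norm <- lapply(norm, function(x) {
    tr <- x$track[, c("chrom", "bin", "start", "end", "value")]
    .keep_grid(tr, x$track)
  })

  residual <- compute_residual(cell1_sm, cell2_norm)
  residuals <- stats::setNames(list(residual), comparison)
  hmm <- fit_hmm(residuals, k = k, seed = seed, restarts = restarts)
  domains <- merge_domains(hmm, min_bins = min_bins)

  null <- scores <- significant <- NULL
  if (length(cell1_sm) == 2 && length(cell2_norm) == 2) {
    null <- build_null(cell1_sm, cell2_norm)
    scores <- score_bins(residual, null)
    significant <- call_significant_domains(domains, scores,
                                            threshold = threshold)
  } else {
    message("significance skipped: requires exactly 2 replicates per condition")
  }

  result <- list(residual = residual, hmm = hmm, domains = domains,
                 null = null, scores = scores, significant = significant,
                 norm_models = lapply(norm, `[[`, "model"),
                 reference = ref)
  if (!is.null(out_dir)) {
    write_compare_outputs(result, out_dir,
                          params = list(sigma = sigma, k = k,
                                        bg_low = bg[1], bg_high = bg[2],
                                        threshold = threshold, seed = seed,
                                        restarts = restarts,
                                        min_bins = min_bins,
                                        comparison = comparison))
  }
  result
}

#' Write the outputs of a comparison run
#'
#' Emits residual and significance bedGraphs, the 4-state segmentation BED,
#' the significant-domain BED, a model TSV (emission means/sds and the
#' transition matrix), a null TSV, and a plain-text run manifest with the
#' package version and all parameters.
#'
#' @param result A list as returned by [daric_compare()].
#' @param out_dir Output directory (created if needed).
#' @param params Named list of run parameters recorded in the manifest.
#' @return Invisibly, `out_dir`.
#' @export
write_compare_outputs <- function(result, out_dir, params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_track(result$residual, fp("residual.bedgraph"))
  st <- result$hmm$states
  st_track <- st[, c("chrom", "bin", "start", "end")]
  st_track$value <- st$state
  write_track(st_track, fp("states.bedgraph"))
  write_domains(result$domains, fp("domains.bed"))
  if (!is.null(result$scores)) {
    sc <- result$scores
    sc$value <- sc$score
    write_track(sc, fp("significance.bedgraph"))
    write_domains(result$significant, fp("significant_domains.bed"),
                  score_column = "mean_score")
    null_tab <- data.frame(sd = result$null$sd, n_bins = result$null$n_bins,
                           null_length = length(result$null$values))
    utils::write.table(null_tab, fp("null_model.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  em <- data.frame(state = seq_len(result$hmm$k),
                   label = result$hmm$labels,
                   mean = result$hmm$means, sd = result$hmm$sds)
  utils::write.table(em, fp("hmm_emissions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$hmm$transitions, fp("hmm_transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  manifest <- c(
    paste0("daric_version: ", as.character(utils::packageVersion("daric"))),
    paste0("r_version: ", R.version.string),
    vapply(names(params), function(nm) {
      paste0(nm, ": ", paste(params[[nm]], collapse = ","))
    }, character(1)))
  writeLines(manifest, fp("manifest.txt"))
  invisible(out_dir)
}
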