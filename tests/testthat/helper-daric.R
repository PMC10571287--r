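# shared builders and independent oracles

toy_bins <- function(n, chrom = "chr1", bs = 50000, gaps = NULL) {
  sizes <- stats::setNames(n * bs, chrom)
  genome_bins(sizes, bs, gaps = gaps)
}

mk_track <- function(values, chrom = "chr1", bs = 50000) {
  bins <- toy_bins(length(values), chrom, bs)
  tr <- bins[, c("chrom", "bin", "start", "end")]
  tr$value <- values
  attr(tr, "bin_size") <- bs
  tr
}

# dense symmetric matrix -> sparse triplet tibble (upper triangle)
dense_to_contacts <- function(mat, chrom = "chr1", bs = 50000,
                              drop_zero = TRUE) {
  n <- nrow(mat)
  idx <- which(upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  oe <- mat[idx]
  keep <- if (drop_zero) oe != 0 else rep(TRUE, length(oe))
  out <- tibble::tibble(i = idx[keep, 1] - 1L, j = idx[keep, 2] - 1L,
                        oe = oe[keep])
  attr(out, "chrom") <- chrom
  attr(out, "bin_size") <- as.integer(bs)
  out
}

mk_compartments <- function(labels, chrom = "chr1", bs = 50000) {
  bins <- toy_bins(length(labels), chrom, bs)
  comp <- bins[, c("chrom", "bin", "start", "end")]
  comp$compartment <- labels
  attr(comp, "bin_size") <- bs
  comp
}

# brute-force PIS oracle on a dense matrix: per-bin loops, no sparse algebra
dense_pis_oracle <- function(mat, labels, exclude_diag = TRUE) {
  n <- nrow(mat)
  a_idx <- which(labels == "A")
  b_idx <- which(labels == "B")
  vapply(seq_len(n), function(b) {
    if (is.na(labels[b])) return(NA_real_)
    aa <- setdiff(a_idx, if (exclude_diag) b else integer(0))
    bb <- setdiff(b_idx, if (exclude_diag) b else integer(0))
    if (length(aa) == 0 || length(bb) == 0) return(NA_real_)
    ma <- mean(mat[b, aa])
    mb <- mean(mat[b, bb])
    if (is.na(ma) || is.na(mb) || ma <= 0 || mb <= 0) return(NA_real_)
    log2(ma / mb)
  }, numeric(1))
}

# random dense positive symmetric obs/exp matrix plus labels
random_dense_case <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * n, rate = 1), n, n)
  m <- (m + t(m)) / 2
  labels <- sample(c("A", "B"), n, replace = TRUE)
  # guarantee both compartments exist
  labels[1] <- "A"; labels[2] <- "B"
  list(mat = m, labels = labels)
}

# piecewise-constant residual track with known state truth
planted_track <- function(seed, level_means = c(-1.5, -0.3, 0.3, 1.5),
                          n_segments = 30, seg_len = c(20, 40),
                          noise_sd = 0.2) {
  set.seed(seed)
  states <- integer(0)
  while (length(states) == 0 ||
         length(unique(states)) < length(level_means)) {
    states <- sample(seq_along(level_means), n_segments, replace = TRUE)
  }
  lens <- sample(seg_len[1]:seg_len[2], n_segments, replace = TRUE)
  truth <- rep(states, lens)
  values <- level_means[truth] + rnorm(length(truth), 0, noise_sd)
  list(track = mk_track(values), truth = truth)
}

# bin-level F1 of significant Strong+ calls against a planted window
strong_plus_f1 <- function(result, truth_bins, bin_size = 50000) {
  pred <- integer(0)
  sig <- result$significant
  if (!is.null(sig) && nrow(sig) > 0) {
    sig <- sig[sig$label == "Strong+", ]
    for (r in seq_len(nrow(sig))) {
      pred <- c(pred, (sig$start[r] / bin_size):(sig$end[r] / bin_size - 1))
    }
  }
  tp <- length(intersect(pred, truth_bins))
  if (length(pred) == 0 || tp == 0) return(0)
  prec <- tp / length(pred)
  rec <- tp / length(truth_bins)
  2 * prec * rec / (prec + rec)
}

expect_same_grid <- function(a, b) {
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$bin, b$bin)
}
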