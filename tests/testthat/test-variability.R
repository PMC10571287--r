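# a panel summary with five planted (mean, sd) clusters in long runs
planted_summary <- function(seed, run_len = 40, n_runs = 25) {
  set.seed(seed)
  centers <- list(conA = c(1.2, 0.10), varA = c(0.7, 0.45),
                  variable = c(0.0, 0.90), varB = c(-0.7, 0.45),
                  conB = c(-1.2, 0.10))
  truth <- sample(names(centers), n_runs, replace = TRUE)
  while (length(unique(truth)) < 5) {
    truth <- sample(names(centers), n_runs, replace = TRUE)
  }
  lab <- rep(truth, each = run_len)
  n <- length(lab)
  mu <- vapply(lab, function(l) centers[[l]][1], numeric(1)) +
    rnorm(n, 0, 0.06)
  sd_ <- pmax(0.01, vapply(lab, function(l) centers[[l]][2], numeric(1)) +
                rnorm(n, 0, 0.04))
  bins <- toy_bins(n)
  out <- bins[, c("chrom", "bin", "start", "end")]
  out$mean <- mu; out$sd <- sd_; out$n <- 8L
  attr(out, "bin_size") <- 50000L
  list(summary = out, truth = unname(lab))
}

test_that("panel summaries are exact and order-invariant", {
  t1 <- mk_track(c(1, 0, NA)); t2 <- mk_track(c(-1, 0, 2))
  t3 <- mk_track(c(0, 0, 1))
  s <- summarize_panel(list(t1, t2, t3))
  expect_equal(s$mean[1], 0)
  expect_equal(s$sd[1], sqrt(2 / 3))   # population sd of (1, -1, 0)
  expect_equal(s$n[3], 2L)             # one sample missing -> n = 2
  expect_equal(s$mean[3], 1.5)

  # two-value bin: mean 0, population sd 1
  s2 <- summarize_panel(list(mk_track(1), mk_track(-1)))
  expect_equal(s2$mean, 0); expect_equal(s2$sd, 1)

  # sample-sd option and permutation invariance
  s3 <- summarize_panel(list(t3, t1, t2))
  expect_identical(s3$mean, s$mean)
  expect_identical(s3$sd, s$sd)
  s4 <- summarize_panel(list(mk_track(1), mk_track(-1)), sd_type = "sample")
  expect_equal(s4$sd, sqrt(2))

  expect_error(summarize_panel(list(t1)), "at least 2")

  # identical tracks: sd identically zero
  s5 <- summarize_panel(list(t3, t3))
  expect_true(all(s5$sd[!is.na(s5$sd)] == 0))
})

test_that("five planted variability clusters are recovered with correct labels", {
  case <- planted_summary(5)
  seg <- segment_variability(case$summary)
  acc <- mean(seg$states$label == case$truth)
  expect_gt(acc, 0.95)
  em <- tidy(seg)
  expect_gt(em$mean_pis[em$label == "conA"], em$mean_pis[em$label == "conB"])
  expect_equal(em$label[which.max(em$sd_pis)], "variable")
})

test_that("variability segmentation is deterministic and rejects degenerate input", {
  case <- planted_summary(9)
  a <- segment_variability(case$summary, seed = 2, restarts = 2)
  b <- segment_variability(case$summary, seed = 2, restarts = 2)
  expect_identical(a$states$label, b$states$label)

  flat <- case$summary
  flat$sd <- 0.2    # constant feature
  expect_error(segment_variability(flat), "degenerate")
  expect_error(segment_variability(case$summary[1:30, ]), "at least 50")
})

test_that("obs/exp enrichment reproduces the gene-count formula", {
  # universe of 100 genes: 20 in stateX, 80 in stateY; subset of 10
  mkgenes <- function(n, offset) {
    tibble::tibble(chrom = "chr1",
                   start = offset + (seq_len(n) - 1) * 1000 + 400,
                   end = offset + (seq_len(n) - 1) * 1000 + 600)
  }
  universe <- rbind(mkgenes(20, 0), mkgenes(80, 100000))
  domains <- tibble::tibble(chrom = "chr1", start = c(0, 100000),
                            end = c(100000, 200000),
                            label = c("stateX", "stateY"))
  # 2 subset genes in stateX -> expected 10 * 20/100 = 2 -> log2(1) = 0
  subset2 <- rbind(universe[1:2, ], universe[21:28, ])
  e2 <- enrich_features(domains, universe, subset2)
  ex <- e2[e2$label == "stateX", ]
  expect_equal(ex$expected, 2)
  expect_equal(ex$log2_enrichment, 0)
  # 6 subset genes in stateX -> log2(6/2) = log2 3
  subset6 <- rbind(universe[1:6, ], universe[21:24, ])
  e6 <- enrich_features(domains, universe, subset6)
  expect_equal(e6$log2_enrichment[e6$label == "stateX"], log2(3))

  # conservation: expected counts sum to the subset size
  expect_equal(sum(e6$expected), 10)

  # state with no universe genes is undefined, flagged
  domains3 <- rbind(domains, tibble::tibble(chrom = "chr1", start = 300000,
                                            end = 400000, label = "stateZ"))
  e3 <- enrich_features(domains3, universe, subset2)
  expect_true(e3$undefined[e3$label == "stateZ"])
  expect_true(is.na(e3$log2_enrichment[e3$label == "stateZ"]))

  # subset must be inside the universe
  rogue <- tibble::tibble(chrom = "chr1", start = 999000, end = 999100)
  expect_error(enrich_features(domains, universe, rogue), "absent")
})

test_that("enrichment is stable under joint subsampling of universe and subset", {
  set.seed(21)
  universe <- tibble::tibble(chrom = "chr1",
                             start = sort(sample.int(4e6, 600)),
                             end = 0)
  universe$end <- universe$start + 200
  domains <- tibble::tibble(chrom = "chr1",
                            start = c(0, 2e6), end = c(2e6, 4.1e6),
                            label = c("s1", "s2"))
  in_s1 <- (universe$start + 100) < 2e6
  # enrich subset toward s1
  sub_idx <- c(sample(which(in_s1), 80), sample(which(!in_s1), 20))
  subset <- universe[sub_idx, ]
  full <- enrich_features(domains, universe, subset)

  reps <- replicate(30, {
    keep_u <- sort(sample(nrow(universe), 300))
    u2 <- universe[keep_u, ]
    s2 <- subset[paste(subset$chrom, subset$start) %in%
                   paste(u2$chrom, u2$start), ]
    e <- enrich_features(domains, u2, s2)
    e$log2_enrichment[e$label == "s1"]
  })
  expect_equal(mean(reps), full$log2_enrichment[full$label == "s1"],
               tolerance = 0.1)
})
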