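test_that("residuals are replicate means of condition differences", {
  r1 <- mk_track(c(1.0, 2, NA)); r2 <- mk_track(c(1.2, 2, 1))
  s1 <- mk_track(c(0.5, 2, 1)); s2 <- mk_track(c(0.7, 2, 1))
  res <- compute_residual(list(r1, r2), list(s1, s2))
  expect_equal(res$value[1], 1.1 - 0.6)
  expect_equal(res$value[2], 0)        # identical conditions
  expect_true(is.na(res$value[3]))     # any missing input -> missing

  # single replicate each: plain difference
  res2 <- compute_residual(r1, s1)
  expect_equal(res2$value[1], 0.5)

  bad <- mk_track(c(1, 2), chrom = "chr2")
  expect_error(compute_residual(list(r1, bad), list(s1, s2)), "grid")
})

test_that("the HMM recovers planted four-level segments", {
  case <- planted_track(101)
  fit <- fit_hmm(case$track, k = 4)
  acc <- mean(fit$states$state == case$truth)
  expect_gt(acc, 0.95)
  # emission means recover the planted levels after label sorting
  expect_equal(fit$means, c(-1.5, -0.3, 0.3, 1.5), tolerance = 0.1)
  expect_equal(fit$labels, c("Strong-", "Weak-", "Weak+", "Strong+"))
})

test_that("decoding is deterministic and label order follows emission means", {
  case <- planted_track(7)
  f1 <- fit_hmm(case$track, k = 4, seed = 3, restarts = 2)
  f2 <- fit_hmm(case$track, k = 4, seed = 3, restarts = 2)
  expect_identical(f1$states$state, f2$states$state)
  expect_identical(f1$means, f2$means)
  # labels are a function of sorted emission means regardless of restarts
  f3 <- fit_hmm(case$track, k = 4, seed = 99, restarts = 4)
  expect_true(!is.unsorted(f3$means))
  expect_equal(f3$labels, c("Strong-", "Weak-", "Weak+", "Strong+"))
})

test_that("symmetric input yields approximately antisymmetric emission means", {
  case <- planted_track(19, level_means = c(-1.2, -0.4, 0.4, 1.2))
  fit <- fit_hmm(case$track, k = 4)
  expect_lt(abs(mean(fit$means)), 0.1)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_hmm(mk_track(rnorm(15)), k = 4), "non-missing")
  expect_error(fit_hmm(mk_track(rep(1, 100)), k = 4), "degenerate")
})

test_that("missing bins break observation sequences and domains never span them", {
  case <- planted_track(23)
  v <- case$track$value
  v[101:110] <- NA
  tr <- mk_track(v)
  fit <- fit_hmm(tr, k = 4)
  expect_false(any(fit$states$bin %in% 100:109))
  d <- merge_domains(fit)
  expect_false(any(d$start < 100 * 50000 & d$end > 110 * 50000))
})

test_that("runs of equal state merge into domains; short runs are absorbed", {
  case <- planted_track(31)
  fit <- fit_hmm(case$track, k = 4)
  st <- fit$states

  d <- merge_domains(fit)
  # coverage conservation: domain bins sum to non-missing bins
  expect_equal(sum(d$n_bins), nrow(st))
  expect_equal(sum(d$end - d$start), nrow(st) * 50000)
  # every domain is a maximal run: neighbours differ in state
  expect_true(all(diff(d$start) > 0))
  expect_true(all(d$state[-1] != d$state[-nrow(d)]))

  # hand-built path [4,4,4,1,1] -> two domains
  fake <- fit
  fake$states <- fit$states[1:5, ]
  fake$states$state <- c(4L, 4L, 4L, 1L, 1L)
  fake$states$label <- fake$labels[fake$states$state]
  d2 <- merge_domains(fake)
  expect_equal(d2$n_bins, c(3L, 2L))

  # singleton between two Strong+ runs is absorbed with min_bins = 2
  fake$states$state <- c(4L, 4L, 3L, 4L, 4L)
  fake$states$label <- fake$labels[fake$states$state]
  d3 <- merge_domains(fake, min_bins = 2)
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$state, 4L)
  expect_equal(d3$n_bins, 5L)
})

test_that("Strong labels are sign-coherent with the residual", {
  case <- planted_track(43)
  fit <- fit_hmm(case$track, k = 4)
  st <- fit$states
  med <- median(st$delta)
  strong_pos <- st$delta[st$label == "Strong+"]
  strong_neg <- st$delta[st$label == "Strong-"]
  expect_gt(mean(strong_pos > med), 0.99)
  expect_gt(mean(strong_neg < med), 0.99)
})

test_that("strong regions are stable between model orders K=4 and K=5", {
  case <- planted_track(57)
  f4 <- fit_hmm(case$track, k = 4)
  f5 <- fit_hmm(case$track, k = 5)
  strong4 <- f4$states$bin[f4$states$state %in% c(1, 4)]
  strong5 <- f5$states$bin[f5$states$state %in% c(1, 5)]
  jac <- length(intersect(strong4, strong5)) /
    length(union(strong4, strong5))
  expect_gte(jac, 0.8)
})

test_that("a unified model is trained across comparisons and decoded on each", {
  c1 <- planted_track(61)
  c2 <- planted_track(62)
  fit <- fit_hmm(list(day02 = c1$track, day15 = c2$track), k = 4)
  expect_setequal(unique(fit$states$comparison), c("day02", "day15"))
  # same shared emission model governs both decodes
  acc1 <- mean(fit$states$state[fit$states$comparison == "day02"] == c1$truth)
  acc2 <- mean(fit$states$state[fit$states$comparison == "day15"] == c2$truth)
  expect_gt(acc1, 0.9)
  expect_gt(acc2, 0.9)
})

test_that("Viterbi matches brute-force best-path enumeration on tiny cases", {
  set.seed(5)
  obs <- matrix(rnorm(8), ncol = 1)
  means <- matrix(c(-1, 1), ncol = 1)
  sds <- matrix(c(0.8, 0.8), ncol = 1)
  trans <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)
  path <- daric:::.hmm_viterbi(obs, means, sds, trans, init)

  # enumerate all 2^8 paths
  grid <- as.matrix(expand.grid(rep(list(1:2), 8)))
  logp <- apply(grid, 1, function(st) {
    lp <- log(init[st[1]]) +
      dnorm(obs[1], means[st[1]], sds[st[1]], log = TRUE)
    for (t in 2:8) {
      lp <- lp + log(trans[st[t - 1], st[t]]) +
        dnorm(obs[t], means[st[t]], sds[st[t]], log = TRUE)
    }
    lp
  })
  expect_equal(unname(path), unname(grid[which.max(logp), ]))
})
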