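test_that("PIS matches the closed form on uniform interaction patterns", {
  # bin 0 (an A bin) contacts every other A bin at 2.0 and every B bin at 1.0
  labels <- c("A", "A", "A", "B", "B", "B")
  m <- matrix(1.0, 6, 6)
  m[1, 2:3] <- m[2:3, 1] <- 2.0
  m[1, 4:6] <- m[4:6, 1] <- 1.0
  pis <- compute_pis(dense_to_contacts(m), mk_compartments(labels))
  expect_equal(pis$value[1], 1.0)   # log2(2/1)

  # equal mean interaction with A and B -> PIS 0
  m2 <- matrix(1.3, 6, 6)
  pis2 <- compute_pis(dense_to_contacts(m2), mk_compartments(labels))
  expect_equal(pis2$value, rep(0, 6))
})

test_that("block checkerboard gives +/- log2(contrast), against the dense oracle", {
  labels <- c("A", "A", "A", "B", "B", "B")
  m <- matrix(0.5, 6, 6)
  same <- outer(labels, labels, "==")
  m[same] <- 1.5
  pis <- compute_pis(dense_to_contacts(m), mk_compartments(labels))
  expect_equal(pis$value, dense_pis_oracle(m, labels), tolerance = 1e-12)
  expect_equal(pis$value, ifelse(labels == "A", log2(3), -log2(3)),
               tolerance = 1e-12)
})

test_that("sparse PIS equals dense brute force on random matrices", {
  for (seed in 1:5) {
    case <- random_dense_case(60, seed)
    pis <- compute_pis(dense_to_contacts(case$mat),
                       mk_compartments(case$labels))
    expect_equal(pis$value, dense_pis_oracle(case$mat, case$labels),
                 tolerance = 1e-9)
  }
})

test_that("PIS is antisymmetric under label swap and invariant to global scaling", {
  case <- random_dense_case(50, 11)
  comp <- mk_compartments(case$labels)
  contacts <- dense_to_contacts(case$mat)
  pis <- compute_pis(contacts, comp)

  swapped <- comp
  swapped$compartment <- chartr("AB", "BA", comp$compartment)
  pis_sw <- compute_pis(contacts, swapped)
  expect_identical(pis_sw$value, -pis$value)

  scaled <- contacts
  scaled$oe <- contacts$oe * 7.3
  attr(scaled, "chrom") <- "chr1"
  pis_sc <- compute_pis(scaled, comp)
  expect_equal(pis_sc$value, pis$value, tolerance = 1e-12)
})

test_that("scaling one bin's A-interactions shifts its PIS by exactly log2(c)", {
  case <- random_dense_case(40, 13)
  comp <- mk_compartments(case$labels)
  pis <- compute_pis(dense_to_contacts(case$mat), comp)

  b <- 5  # 1-based row; any bin works
  a_cols <- which(case$labels == "A" & seq_along(case$labels) != b)
  m2 <- case$mat
  m2[b, a_cols] <- m2[b, a_cols] * 3
  m2[a_cols, b] <- m2[a_cols, b] * 3
  pis2 <- compute_pis(dense_to_contacts(m2), comp)
  expect_equal(pis2$value[b] - pis$value[b], log2(3), tolerance = 1e-9)
})

test_that("chromosomes without both compartment types give all-missing PIS", {
  labels <- rep("A", 6)
  m <- matrix(1, 6, 6)
  expect_warning(
    pis <- compute_pis(dense_to_contacts(m), mk_compartments(labels)),
    "no B bins")
  expect_true(all(is.na(pis$value)))
})

test_that("absent sparse entries count as zero contact by default", {
  labels <- c("A", "A", "B", "B")
  # bin 0 contacts only one of the two other... one A bin (bin 1) at 2.0,
  # and one B bin (bin 2) at 2.0; pairs (0,3) and others absent
  contacts <- tibble::tibble(i = c(0L, 0L), j = c(1L, 2L), oe = c(2, 2))
  attr(contacts, "chrom") <- "chr1"
  comp <- mk_compartments(labels)
  pis_all <- compute_pis(contacts, comp, mean_over = "all")
  # A-mean = 2/1, B-mean = (2+0)/2 -> log2(2/1) = 1
  expect_equal(pis_all$value[1], 1)
  pis_nz <- compute_pis(contacts, comp, mean_over = "nonzero")
  # over stored pairs only: A-mean 2, B-mean 2 -> 0
  expect_equal(pis_nz$value[1], 0)
})

test_that("gaussian smoothing is mass-preserving, masked, and exact at sigma 0", {
  const <- mk_track(rep(2.5, 40))
  expect_equal(smooth_track(const, sigma = 3)$value, rep(2.5, 40))

  tr <- mk_track(rnorm(30))
  expect_identical(smooth_track(tr, sigma = 0), tr)
  expect_error(smooth_track(tr, sigma = -1), "non-negative")

  # unit impulse reproduces the normalized discrete kernel
  imp <- mk_track(c(rep(0, 10), 1, rep(0, 39)))
  sm <- smooth_track(imp, sigma = 1)
  kern <- dnorm(-4:4, sd = 1); kern <- kern / sum(kern)
  expect_equal(sm$value[7:15], kern, tolerance = 1e-9)
  expect_equal(sum(sm$value), 1, tolerance = 1e-9)

  # missing bins stay missing and carry no weight
  vals <- rep(1, 20); vals[10] <- NA
  sm2 <- smooth_track(mk_track(vals), sigma = 1)
  expect_true(is.na(sm2$value[10]))
  expect_equal(sm2$value[-10], rep(1, 19))  # renormalized mask: constants kept

  # interior mean preservation on a fully defined track
  set.seed(1)
  x <- rnorm(200)
  sm3 <- smooth_track(mk_track(x), sigma = 2)
  r <- 8  # kernel radius at sigma 2
  expect_equal(mean(sm3$value[(r + 1):(200 - r)]),
               mean(stats::filter(x, dnorm(-r:r, sd = 2) /
                                    sum(dnorm(-r:r, sd = 2)),
                                  sides = 2)[(r + 1):(200 - r)]),
               tolerance = 1e-9)
})
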