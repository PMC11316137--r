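test_that("indicator values follow the specificity-times-fidelity
           definition", {
  # equal abundance everywhere: both groups get 0.5
  iv <- indval(rep(2, 8), rep(c(FALSE, TRUE), each = 4))
  expect_equal(unname(iv), c(0.5, 0.5))

  # perfect upper-group indicator
  iv <- indval(c(0, 0, 0, 3, 3, 3), rep(c(FALSE, TRUE), each = 3))
  expect_equal(unname(iv), c(0, 1))

  # hand enumeration on the 6-sample toy (0,0,1,2,2,3) split 3/3
  x <- c(0, 0, 1, 2, 2, 3)
  hi <- rep(c(FALSE, TRUE), each = 3)
  m_lo <- mean(x[1:3]); m_hi <- mean(x[4:6])
  expected <- c(m_lo / (m_lo + m_hi) * (1 / 3),
                m_hi / (m_lo + m_hi) * (3 / 3))
  expect_equal(unname(indval(x, hi)), expected, tolerance = 1e-12)

  # random tables against the brute-force definition
  set.seed(31)
  for (i in 1:20) {
    x <- rpois(12, 1.5); if (all(x == 0)) x[1] <- 1
    hi <- sample(rep(c(TRUE, FALSE), 6))
    iv <- indval(x, hi)
    expect_true(all(iv >= 0 & iv <= 1))
    a_hi <- mean(x[hi]) / (mean(x[hi]) + mean(x[!hi]))
    expect_equal(unname(iv["indval_high"]), a_hi * mean(x[hi] > 0),
                 tolerance = 1e-12)
  }
  expect_error(indval(rep(0, 6), rep(c(FALSE, TRUE), each = 3)),
               "absent")
  expect_error(indval(x, rep(TRUE, 12)), "non-empty")
})

test_that("change-point scan finds a planted step and respects
           symmetry under gradient reversal", {
  set.seed(77)
  n <- 40
  grad <- sort(runif(n, 0, 10))
  med <- median(grad)
  x <- ifelse(grad > med, 1, 0)
  cfg <- titan_config(n_permutations = 100, seed = 5)
  set.seed(1)
  res <- scan_changepoints(x, grad, cfg)
  gaps <- sort(grad)
  k <- max(which(gaps <= med))
  expect_lte(abs(res$cp - med), gaps[k + 2] - gaps[max(k - 1, 1)])
  expect_equal(res$direction, 1L)
  expect_gt(res$z, 3)

  # reversal: same permutations -> direction flips, |z| preserved,
  # change point negated
  set.seed(1)
  rev <- scan_changepoints(x, -grad, cfg)
  expect_equal(rev$direction, -1L)
  expect_equal(rev$z, res$z, tolerance = 1e-9)
  expect_equal(rev$cp, -res$cp, tolerance = 1e-9)
})

test_that("pure-noise taxa stay in the null range of the
           best-candidate z", {
  # the reported z is a maximum over candidate change points, so its
  # null distribution sits above a single-split z; what matters is that
  # noise rarely reaches the extreme values planted steps attain
  cfg <- titan_config(n_permutations = 100, seed = 5)
  hits <- 0; n_ok <- 0
  for (sd in 1:10) {
    set.seed(sd)
    grad <- runif(30, 0, 10)
    x <- rpois(30, 1)
    if (sum(x > 0) < cfg$min_occurrences) next
    res <- scan_changepoints(x, grad, cfg)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    if (res$z >= 4.5) hits <- hits + 1
  }
  expect_gte(n_ok, 8)
  expect_lte(hits, 2)

  # and a planted step on the same layout clears that bar every time
  for (sd in 1:3) {
    set.seed(sd)
    grad <- runif(30, 0, 10)
    x <- ifelse(grad > median(grad), 2, 0)
    expect_gt(scan_changepoints(x, grad, cfg)$z, 4.5)
  }
})

test_that("bootstrap metrics: a deterministic perfect increaser is pure,
           reliable and significant", {
  grad <- seq(1, 10, length.out = 30)
  x <- ifelse(grad > 5.5, 2, 0)
  cfg <- titan_config(n_permutations = 100, n_bootstrap = 100, seed = 9)
  r <- bootstrap_taxon(x, grad, cfg)
  expect_equal(r$purity, 1)
  expect_equal(r$reliability, 1)
  expect_true(r$significant)
  expect_equal(r$direction, 1L)

  # determinism: identical seed, identical response
  r2 <- bootstrap_taxon(x, grad, cfg)
  expect_identical(r, r2)
})

test_that("community classification recovers directions at VT level and
           handles an empty taxon set", {
  grad <- seq(1, 10, length.out = 30)
  base <- ifelse(grad > 5.5, 3, 0)
  counts <- cbind(ASV1 = base + rpois(30, 1) * (grad > 5.5),
                  ASV2 = 2 * base, ASV3 = rev(base) + 1)
  rownames(counts) <- paste0("s", 1:30)
  tax <- data.frame(asv_id = c("ASV1", "ASV2", "ASV3"),
                    vt_id = c("VT1", "VT1", "VT2"))
  cfg <- titan_config(n_permutations = 100, n_bootstrap = 60, seed = 4)
  res <- classify_community(counts, grad, cfg, taxonomy = tax)
  vt1 <- res$responses[res$responses$taxon == "VT1", ]
  expect_equal(vt1$direction, 1L)  # all-increaser members aggregate up

  # empty after the occurrence filter: clean empty result
  sparse <- cbind(ASVx = c(1, rep(0, 29)))
  rownames(sparse) <- paste0("s", 1:30)
  res0 <- suppressWarnings(classify_community(sparse, grad, cfg))
  expect_equal(res0$n_tested, 0)
  expect_equal(nrow(res0$responses), 0)
  expect_equal(res0$n_increasers + res0$n_decreasers, 0)
})

test_that("purity and reliability are invariant to sample order", {
  set.seed(12)
  grad <- runif(30, 0, 10)
  x <- ifelse(grad > 5, 2, 0) + rpois(30, 0.3)
  cfg <- titan_config(n_permutations = 100, n_bootstrap = 80, seed = 6)
  r1 <- bootstrap_taxon(x, grad, cfg)
  perm <- sample(30)
  r2 <- bootstrap_taxon(x[perm], grad[perm], cfg)
  expect_equal(r2$purity, r1$purity, tolerance = 0.1)
  expect_equal(r2$reliability, r1$reliability, tolerance = 0.1)
  expect_equal(r2$cp, r1$cp, tolerance = 1e-9)
})
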