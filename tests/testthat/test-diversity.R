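test_that("shared-community filter applies the two-species and
           multi-tree rules", {
  counts <- rbind(
    s1 = c(shared = 5, rubrum_only = 3, single_tree = 0),
    s2 = c(2, 1, 0),
    s3 = c(4, 0, 7),
    s4 = c(1, 0, 0))
  species <- c("A. rubrum", "A. rubrum", "A. saccharum", "A. saccharum")
  out <- filter_shared(counts, species, min_trees = 2)
  expect_equal(colnames(out), "shared")
  expect_equal(attr(out, "retention")$n_out, 1)

  # single_tree occurs once, on a saccharum tree only -> both rules drop
  # it; with min_trees = 1 the species rule alone still drops it
  out1 <- filter_shared(counts, species, min_trees = 1)
  expect_equal(colnames(out1), "shared")

  # idempotence
  again <- filter_shared(out, species, min_trees = 2)
  expect_equal(unclass(again)[, , drop = FALSE], unclass(out)[, ,
                                                              drop = FALSE])
  expect_error(filter_shared(counts, rep("A. rubrum", 4)), "both")
})

test_that("Chao1 matches its closed forms and a brute-force oracle", {
  expect_equal(chao1(c(1, 1, 2), bias_corrected = FALSE), 5)
  expect_equal(chao1(c(1, 1, 2), bias_corrected = TRUE), 3.5)
  # no singletons -> S_obs under bias correction
  expect_equal(chao1(c(3, 4, 2)), 3)
  expect_error(chao1(c(0.5, 1)), "integer")

  set.seed(5)
  for (i in 1:100) {
    v <- rpois(sample(5:40, 1), lambda = sample(1:3, 1))
    expect_equal(chao1(v, TRUE), oracle_chao1(v, TRUE))
    expect_equal(chao1(v, FALSE), oracle_chao1(v, FALSE))
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("Hellinger rows are unit-norm square roots of relative
           abundance", {
  m <- rbind(a = c(1, 1, 2), b = c(0, 4, 0))
  h <- hellinger(m)
  expect_equal(h["a", ], c(0.5, 0.5, 0.70711), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(rowSums(h^2), c(a = 1, b = 1))
  expect_warning(h0 <- hellinger(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_equal(h0[2, ], c(0, 0))
  expect_error(hellinger(rbind(c(-1, 2))), "non-negative")

  set.seed(9)
  for (i in 1:25) {
    m <- matrix(rpois(60, 2), 6)
    h <- hellinger(m)
    nz <- rowSums(m) > 0
    expect_equal(rowSums(h[nz, , drop = FALSE]^2), rep(1, sum(nz)),
                 tolerance = 1e-12)
  }
})

test_that("richness regression matches a closed-form least-squares
           oracle and the df bookkeeping", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.7, 12.3)
  r <- regress_diversity(y, x)
  # independent normal-equation computation
  n <- 6
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - bx * mean(x)
  resid <- y - b0 - bx * x
  ss_res <- sum(resid^2); ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  Fst <- (ss_tot - ss_res) / (ss_res / (n - 2))
  expect_equal(r$slope, bx, tolerance = 1e-9)
  expect_equal(r$F, Fst, tolerance = 1e-9)
  expect_equal(r$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 2),
               tolerance = 1e-9)
  expect_equal(c(r$df1, r$df2), c(1, 4))

  # exact line
  rl <- suppressWarnings(regress_diversity(2 * (1:10) + 1, 1:10))
  expect_equal(rl$r2, 1, tolerance = 1e-12)
  expect_equal(rl$adj_r2, 1, tolerance = 1e-12)
  expect_lt(rl$p, 1e-12)

  # df = (1, n-2) at the sample sizes where the field reports F(1,62)
  # and F(1,68)
  set.seed(2)
  r64 <- regress_diversity(rnorm(64), rnorm(64))
  expect_equal(c(r64$df1, r64$df2), c(1, 62))
  r70 <- regress_diversity(rnorm(70), rnorm(70))
  expect_equal(c(r70$df1, r70$df2), c(1, 68))

  expect_error(regress_diversity(1:5, rep(2, 5)), "variance")
  expect_error(regress_diversity(1:2, 1:2), "three")
})

test_that("transformations agree with the community-ecology reference
           implementations", {
  set.seed(21)
  m <- matrix(rpois(80, 3), 8)
  expect_equal(unname(hellinger(m)),
               unname(as.matrix(vegan::decostand(m, "hellinger"))),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (i in 1:8) {
    ref <- suppressWarnings(vegan::estimateR(m[i, ]))  # NaN SEs possible
    expect_equal(chao1(m[i, ], bias_corrected = TRUE),
                 unname(ref["S.chao1"]), tolerance = 1e-9)
  }
})

test_that("VT aggregation sums member ASVs and drops unmapped ones", {
  counts <- cbind(ASV1 = c(1, 2), ASV2 = c(3, 0), ASV3 = c(5, 5))
  rownames(counts) <- c("s1", "s2")
  tax <- data.frame(asv_id = c("ASV1", "ASV2", "ASV3"),
                    vt_id = c("VT1", "VT1", NA))
  expect_message(v <- aggregate_vt(counts, tax), "unmapped")
  expect_equal(dim(v), c(2, 1))
  expect_equal(unname(v[, "VT1"]), c(4, 2))
})
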