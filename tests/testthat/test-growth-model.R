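test_that("design assembly: lag bookkeeping, standardization, species
           filter", {
  st <- small_study(seed = 4)
  des <- build_design(st$growth$bai, st$growth$diameters, st$trees,
                      st$growth$temps)
  # 15 simulated years -> 14 usable rows per tree
  expect_equal(nrow(des), nrow(st$trees) * 14)
  for (cn in c("nmin", "bai_lag", "ln_dbh", "may_min_temp")) {
    expect_equal(mean(des[[cn]]), 0, tolerance = 1e-9)
    expect_equal(sd(des[[cn]]), 1, tolerance = 1e-9)
  }
  sc <- attr(des, "scaling")
  expect_true(all(c("nmin", "bai_lag", "ln_dbh", "may_min_temp") %in%
                    names(sc)))

  des_r <- build_design(st$growth$bai, st$growth$diameters, st$trees,
                        st$growth$temps, species = "A. rubrum")
  expect_true(all(des_r$species == "A. rubrum"))
  expect_lt(nrow(des_r), nrow(des))

  # missing temperature year is named
  temps_bad <- st$growth$temps[-3, ]
  expect_error(build_design(st$growth$bai, st$growth$diameters,
                            st$trees, temps_bad),
               "May minimum temperature")
})

test_that("spatial covariance kernel: zero distance, decay, site
           blocking", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 0))
  sites <- c("A", "A", "B")
  S <- build_sere_cov(coords, phi = log(2), sigma2_sere = 2,
                      site_ids = sites)
  expect_equal(S[1, 1], 2)
  expect_equal(S[1, 2], 2 / 2, tolerance = 1e-12)  # d=1, phi=ln2
  expect_equal(S[1, 3], 0)                          # cross-site
  expect_true(isSymmetric(unclass(S)[, , drop = FALSE]))
  expect_error(build_sere_cov(coords, -1, 1, sites), "phi")
})

test_that("log-posterior matches an independently coded density on tiny
           datasets", {
  d <- tiny_design()
  params <- list(alpha = 1.5, beta = c(0.3, -0.2, 0.1, 0.05),
                 a = 0.3, b = 0.02, theta = -0.5, sigma2_sere = 1.5,
                 sere = c(0.1, -0.2))
  expect_equal(log_posterior(params, d),
               oracle_log_posterior(params, d), tolerance = 1e-8)

  # single row, b = 0, sere = 0: plain log-normal density plus priors
  d1 <- tiny_design(bai = 5, nmin = 0.5, bai_lag = 4, ln_dbh = 3,
                    temp = 4, tree_id = "A")
  p1 <- list(alpha = 2, beta = rep(0, 4), a = 0.25, b = 0,
             theta = 0, sigma2_sere = 1, sere = 0)
  expect_equal(log_posterior(p1, d1), oracle_log_posterior(p1, d1),
               tolerance = 1e-8)

  # variance support violated -> -Inf, no exception
  p_bad <- params; p_bad$b <- -1
  expect_identical(log_posterior(p_bad, d), -Inf)
  p_bad2 <- params; p_bad2$alpha <- 7
  expect_identical(log_posterior(p_bad2, d), -Inf)

  # finite-difference agreement in beta1
  f <- function(b1) {
    p <- params; p$beta[1] <- b1
    log_posterior(p, d)
  }
  h <- 1e-6
  num <- (f(0.3 + h) - f(0.3 - h)) / (2 * h)
  ctx_X <- as.matrix(d[c("nmin", "bai_lag", "ln_dbh", "may_min_temp")])
  s2 <- params$a + params$b * d$ln_dbh
  trees <- attr(d, "trees")
  D <- params$alpha + drop(ctx_X %*% params$beta) +
    params$sere[match(d$tree_id, trees$tree_id)]
  analytic <- sum((log(d$bai) - D) / s2 * d$nmin) - params$beta[1]
  expect_equal(num, analytic, tolerance = 1e-4)
})

test_that("MCMC is deterministic given a seed and summaries match the
           pooled draws", {
  des <- small_design(seed = 3)
  s1 <- run_mcmc(des, n_chains = 2, n_iter = 300, seed = 5)
  s2 <- run_mcmc(des, n_chains = 2, n_iter = 300, seed = 5)
  expect_identical(s1$chains, s2$chains)
  s3 <- run_mcmc(des, n_chains = 2, n_iter = 300, seed = 6)
  expect_false(identical(s1$chains, s3$chains))

  fit <- suppressWarnings(summarize_fit(s1, des,
                                        allow_unconverged = TRUE))
  pooled <- pool_draws(s1)
  expect_equal(fit$summary$mean,
               unname(colMeans(pooled[, s1$scalar_names])),
               tolerance = 1e-12)
  expect_true(all(fit$summary$q2.5 <= fit$summary$mean + 1e-12))
  expect_true(all(fit$summary$mean <= fit$summary$q97.5 + 1e-12))
})

test_that("split R-hat separates mixed from disagreeing chains and
           flags constant ones", {
  fake <- function(chains) {
    structure(list(chains = chains, n_chains = length(chains),
                   scalar_names = colnames(chains[[1]]),
                   param_names = colnames(chains[[1]]),
                   sere = "none", n_trees = 0),
              class = "growth_mcmc")
  }
  set.seed(17)
  iid <- fake(lapply(1:2, function(i) {
    matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  }))
  r <- gelman_rubin(iid, params = "x")
  expect_gte(r[["x"]], 0.99)
  expect_lte(r[["x"]], 1.05)

  apart <- fake(list(
    matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "x")),
    matrix(rnorm(500, 10), ncol = 1, dimnames = list(NULL, "x"))))
  expect_gt(gelman_rubin(apart, params = "x")[["x"]], 1.5)

  const <- fake(lapply(1:2, function(i) {
    matrix(1, 100, 1, dimnames = list(NULL, "x"))
  }))
  rc <- gelman_rubin(const, params = "x")
  expect_equal(rc[["x"]], 1)
  expect_equal(attr(rc, "zero_variance"), "x")

  one <- fake(list(matrix(rnorm(100), ncol = 1,
                          dimnames = list(NULL, "x"))))
  expect_error(gelman_rubin(one), "two chains")
})

test_that("a degenerate posterior has pD exactly zero", {
  des <- small_design(seed = 5)
  s <- run_mcmc(des, n_chains = 2, n_iter = 300, seed = 2)
  # freeze every draw, in every chain, at one common value
  frozen <- s$chains[[1]][1, , drop = FALSE]
  s$chains <- lapply(s$chains, function(m) {
    frozen[rep(1, 60), , drop = FALSE]
  })
  dic <- compute_dic(s, des)
  expect_equal(dic$pD, 0, tolerance = 1e-9)
  expect_equal(dic$DIC, dic$Dhat, tolerance = 1e-9)
})

test_that("posterior prediction is monotone for a positive nitrogen
           effect and guards its grid", {
  des <- small_design(seed = 3)
  s <- run_mcmc(des, n_chains = 2, n_iter = 400, seed = 11)
  rng <- range(des$nmin * attr(des, "scaling")$nmin$scale +
                 attr(des, "scaling")$nmin$center)
  grid <- seq(rng[1], rng[2], length.out = 5)
  pr <- predict_response(s, des, grid)
  expect_true(all(diff(pr$bai_mean) > 0))
  expect_true(all(pr$bai_lo <= pr$bai_mean & pr$bai_mean <= pr$bai_hi))
  expect_error(predict_response(s, des, rng[2] * 3), "range")
})
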