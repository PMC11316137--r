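test_that("DBH reconstruction anchors at the measured diameter and
           averages cores", {
  # constant 1 mm rings on two cores: 0.1 cm radial increment per year,
  # so five years back the diameter is 20 - 2 * 0.5 = 19 cm
  rings <- data.frame(
    tree_id = "T1",
    core_id = rep(c("N", "S"), each = 5),
    year = rep(2018:2022, 2),
    width_mm = 1)
  d <- reconstruct_dbh(rings, measured_dbh_cm = 20, final_year = 2022)
  expect_equal(d$dbh_cm[d$year == 2022], 20)
  expect_equal(d$dbh_cm[d$year == 2017], 19, tolerance = 1e-12)

  # zero widths leave the diameter constant
  rings0 <- transform(rings, width_mm = 0)
  d0 <- reconstruct_dbh(rings0, 20, 2022)
  expect_true(all(d0$dbh_cm == 20))

  # one core with width w, the other 0 -> increment w/2
  r2 <- data.frame(tree_id = "T1", core_id = c("N", "S"),
                   year = 2022, width_mm = c(2, 0))
  d2 <- reconstruct_dbh(r2, 20, 2022)
  expect_equal(diff(d2$dbh_cm), 2 * (1 / 10) / 1, tolerance = 1e-12)

  # widths inconsistent with the measured diameter
  rbad <- data.frame(tree_id = "T1", core_id = "N", year = 2020:2022,
                     width_mm = 40)
  expect_error(reconstruct_dbh(rbad, 10, 2022), "non-positive")
})

test_that("BAI matches the annulus area and telescopes", {
  d <- data.frame(year = 2020:2021, dbh_cm = c(10, 10.2))
  b <- compute_bai(d)
  expect_equal(b$bai_cm2, pi * ((10.2 / 2)^2 - (10 / 2)^2),
               tolerance = 1e-12)
  expect_equal(b$bai_cm2, 3.173, tolerance = 1e-3)

  # constant diameters -> zero BAI; non-monotone -> error
  expect_true(all(compute_bai(data.frame(year = 1:3,
                                         dbh_cm = 15))$bai_cm2 == 0))
  expect_error(compute_bai(data.frame(year = 1:3,
                                      dbh_cm = c(10, 9, 11))),
               "non-decreasing")

  # telescoping and split/concat invariance on random series
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    dbh <- cumsum(c(runif(1, 8, 20), runif(n - 1, 0, 1)))
    ds <- data.frame(year = seq_len(n) + 1980, dbh_cm = dbh)
    b <- compute_bai(ds)
    expect_equal(sum(b$bai_cm2),
                 (pi / 4) * (dbh[n]^2 - dbh[1]^2), tolerance = 1e-9)
    k <- sample(2:(n - 1), 1)
    b_split <- rbind(compute_bai(ds[1:k, ]), compute_bai(ds[k:n, ]))
    expect_equal(b_split$bai_cm2, b$bai_cm2, tolerance = 1e-12)
  }
})

test_that("ring widths from a diameter series round-trip through
           reconstruction", {
  set.seed(11)
  dbh <- cumsum(c(15, runif(24, 0.05, 0.8)))
  years <- 1998:2022
  width_mm <- diff(dbh) / 2 * 10
  rings <- data.frame(tree_id = "T1", core_id = "N",
                      year = years[-1], width_mm = width_mm)
  rec <- reconstruct_dbh(rings, measured_dbh_cm = dbh[25],
                         final_year = 2022)
  expect_equal(rec$dbh_cm, dbh, tolerance = 1e-9)
})

test_that("mean BAI averages over the window actually present", {
  b <- data.frame(year = 1990:2021, bai_cm2 = 3)
  expect_equal(mean_bai(b, 1981, 2021)$mean_bai, 3)
  expect_equal(mean_bai(b, 1981, 2021)$n_years, 32)  # missing early years
  w <- mean_bai(b, 2000, 2009)
  expect_equal(w$n_years, 10)
  expect_error(mean_bai(b, 1900, 1950), "overlap")
})

test_that("EPS follows the closed form", {
  mk <- function(w) data.frame(year = 2000:2019, width_mm = w)
  set.seed(3)
  w <- runif(20, 0.2, 2)
  ident <- list(mk(w), mk(w), mk(w))
  expect_equal(compute_eps(ident)$eps, 1, tolerance = 1e-12)

  # five noisy copies of one signal: rbar derived independently with
  # cor(), then eps must equal n*rbar / (1 + (n-1)*rbar); with rbar
  # tuned near 0.3 that is about 0.6818
  set.seed(42)
  sig <- runif(20, 0.2, 2)
  series <- lapply(1:5, function(i) mk(sig + rnorm(20, 0, 0.75)))
  m <- sapply(series, `[[`, "width_mm")
  cm <- cor(m)
  rbar <- mean(cm[lower.tri(cm)])
  got <- compute_eps(series)
  expect_equal(got$rbar, rbar, tolerance = 1e-12)
  expect_equal(got$eps, 5 * rbar / (1 + 4 * rbar), tolerance = 1e-12)
  expect_equal(5 * 0.3 / (1 + 4 * 0.3), 0.6818, tolerance = 1e-4)

  # uncorrelated-ish series: eps clamps at 0 when rbar <= 0
  s1 <- mk(c(rep(c(1, 2), 10)))
  s2 <- mk(c(rep(c(2, 1), 10)))
  expect_equal(compute_eps(list(s1, s2))$eps, 0)
  expect_error(compute_eps(list(mk(w))), "two series")
  expect_error(compute_eps(list(mk(w)[1:5, ], mk(w)[1:5, ])), "overlap")
})

test_that("pith offset follows the arc geometry", {
  # semicircular arc: L = 2h -> r = h
  expect_equal(estimate_pith_offset(10, 5), 5, tolerance = 1e-12)
  expect_equal(estimate_pith_offset(10, 2), 100 / 16 + 1,
               tolerance = 1e-12)
  expect_error(estimate_pith_offset(10, 1e-9), "tolerance")
  expect_error(estimate_pith_offset(-1, 2), "positive")
  expect_error(estimate_pith_offset(10, 0), "positive")
})

test_that("rwl decadal reader recovers series in mm", {
  tmp <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c(
    "TREE1A  1990   100   200   300   150   999",
    "TREE2A  1991    50    60    70 -9999"), tmp)
  x <- read_rwl(tmp)
  s1 <- x[x$series_id == "TREE1A", ]
  expect_equal(s1$year, 1990:1993)
  expect_equal(s1$width_mm, c(1, 2, 3, 1.5))
  s2 <- x[x$series_id == "TREE2A", ]
  expect_equal(s2$width_mm, c(0.05, 0.06, 0.07))
})
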