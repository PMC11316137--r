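# Synthetic study generator: a multi-site soil nitrogen gradient, tree
# growth series drawn forward from the hierarchical growth model, and
# ASV community tables with a planted richness trend and planted
# threshold responders.  Everything is deterministic given the seed.

#' Generative growth-model parameters
#'
#' Parameters of the forward simulation: intercept and slopes on
#' standardized covariates, the diameter-dependent variance model, and
#' the spatial random-effect kernel.  The dynamic covariates (lag BAI and
#' log DBH) are standardized with the fixed reference constants given
#' here, since their distribution is not known before simulation; N
#' mineralization and May temperature are z-scored empirically.
#'
#' @param alpha log-BAI intercept (mean ln cm^2 at covariate means).
#' @param beta slopes for (Nmin, lag BAI, lnDBH, May min temp), on
#'   standardized covariates.
#' @param a,b variance model `sigma^2 = a + b * z(lnDBH)`; must stay
#'   positive over the simulated range.
#' @param phi spatial decay rate per metre (> 0).
#' @param sigma2_sere spatial random-effect variance (>= 0).
#' @param initial_dbh_range uniform range (cm) for starting diameters.
#' @param lag_center,lag_scale,lndbh_center,lndbh_scale standardization
#'   constants for the dynamic covariates.
#' @return list of class `growth_params`.
#' @export
growth_params <- function(alpha = 1.8, beta = c(0.6, 0.2, 0.15, 0.1),
                          a = 0.04, b = 0.01, phi = 0.1,
                          sigma2_sere = 0.03,
                          initial_dbh_range = c(12, 25),
                          lag_center = 12, lag_scale = 20,
                          lndbh_center = 3.0, lndbh_scale = 0.4) {
  stopifnot(length(beta) == 4, phi > 0, sigma2_sere >= 0, a > 0,
            initial_dbh_range[1] > 0,
            initial_dbh_range[1] < initial_dbh_range[2])
  structure(list(alpha = alpha, beta = beta, a = a, b = b, phi = phi,
                 sigma2_sere = sigma2_sere,
                 initial_dbh_range = initial_dbh_range,
                 lag_center = lag_center, lag_scale = lag_scale,
                 lndbh_center = lndbh_center, lndbh_scale = lndbh_scale),
            class = "growth_params")
}

#' Configuration of a full synthetic study
#'
#' Defaults emulate the study design the package targets: 12 even-aged
#' stands spanning a net N mineralization gradient of roughly 0.2-1.9
#' micrograms N per gram per day, five trees per stand, 40 years of
#' growth, and an AMF community whose richness rises along the gradient
#' and that contains taxa with abrupt (threshold) occurrence responses.
#'
#' @param n_sites,trees_per_site,years study layout.
#' @param nmin_range (min, max) net N mineralization across sites.
#' @param growth_params see [growth_params()].
#' @param richness_intercept,richness_slope expected per-tree realized
#'   richness `intercept + slope * Nmin` (taxa; slope per unit Nmin).
#' @param richness_noise_sd sd of the per-tree richness noise (taxa).
#' @param n_taxa_pool,n_threshold_increasers,n_threshold_decreasers,n_noise_taxa
#'   taxon pool composition; any remainder are baseline taxa with
#'   gradient-independent occurrence weight.
#' @param sequencing_depth reads per sample (multinomial total).
#' @param dominant_genus_frac fraction of virtual taxa assigned to the
#'   dominant genus (Glomus).
#' @param seed master seed for the study.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 12, trees_per_site = 5, years = 40,
                       nmin_range = c(0.22, 1.87),
                       growth_params = mycogrowth::growth_params(),
                       richness_intercept = 8, richness_slope = 6,
                       richness_noise_sd = 1.5,
                       n_taxa_pool = 40, n_threshold_increasers = 12,
                       n_threshold_decreasers = 3, n_noise_taxa = 25,
                       sequencing_depth = 5000,
                       dominant_genus_frac = 0.6, seed = 1) {
  stopifnot(n_sites > 0, trees_per_site > 0, years > 0,
            nmin_range[1] < nmin_range[2], n_taxa_pool > 0,
            sequencing_depth > 0,
            n_threshold_increasers + n_threshold_decreasers +
              n_noise_taxa <= n_taxa_pool)
  structure(list(n_sites = n_sites, trees_per_site = trees_per_site,
                 years = years, nmin_range = nmin_range,
                 growth_params = growth_params,
                 richness_intercept = richness_intercept,
                 richness_slope = richness_slope,
                 richness_noise_sd = richness_noise_sd,
                 n_taxa_pool = n_taxa_pool,
                 n_threshold_increasers = n_threshold_increasers,
                 n_threshold_decreasers = n_threshold_decreasers,
                 n_noise_taxa = n_noise_taxa,
                 sequencing_depth = sequencing_depth,
                 dominant_genus_frac = dominant_genus_frac,
                 seed = seed),
            class = "sim_config")
}

#' Generate the site/tree layout of a synthetic study
#'
#' Sites receive evenly spaced N mineralization levels spanning
#' `nmin_range`; per-tree values add a small jitter and are clamped to
#' the range.  Trees sit uniformly in a 100 m x 100 m box per site, and
#' sites are 10 km apart so spatial dependence is effectively
#' within-site.  Host species alternate between the two maples.
#'
#' @param config `sim_config`.
#' @return data.frame with `tree_id`, `site_id`, `x`, `y`, `nmin`,
#'   `species`.
#' @export
generate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites * config$trees_per_site
  if (n <= 0) stop("zero trees requested")
  set.seed(config$seed %% .Machine$integer.max)
  site_nmin <- seq(config$nmin_range[1], config$nmin_range[2],
                   length.out = config$n_sites)
  jit_sd <- if (config$n_sites > 1) diff(site_nmin[1:2]) * 0.15 else
    diff(config$nmin_range) * 0.05
  site <- rep(seq_len(config$n_sites), each = config$trees_per_site)
  nmin <- pmin(pmax(site_nmin[site] + stats::rnorm(n, 0, jit_sd),
                    config$nmin_range[1]), config$nmin_range[2])
  data.frame(
    tree_id = sprintf("T%03d", seq_len(n)),
    site_id = sprintf("S%02d", site),
    x = (site - 1) * 10000 + stats::runif(n, 0, 100),
    y = stats::runif(n, 0, 100),
    nmin = nmin,
    species = rep_len(c("A. rubrum", "A. saccharum"), n),
    stringsAsFactors = FALSE)
}

#' Simulate tree growth forward from the hierarchical model
#'
#' Draws one spatial random effect per tree from the blocked exponential
#' kernel, then iterates years: the linear predictor on standardized
#' covariates gives the log-normal location, BAI is sampled with variance
#' `a + b * z(lnDBH)`, and the diameter is updated by inverting the
#' basal-area identity.  Ring widths are emitted as two cores (north and
#' south) whose mean equals the true radial increment.
#'
#' @param trees layout from [generate_layout()].
#' @param params `growth_params`.
#' @param years number of growth years.
#' @param seed RNG seed.
#' @param final_year calendar year of the last ring (default 2021).
#' @return list with `rings` (tree_id, core_id, year, width_mm),
#'   `diameters` (tree_id, year, dbh_cm; includes the pre-growth year),
#'   `bai` (tree_id, year, bai_cm2), `temps` (year, may_min_temp),
#'   `measured_dbh` (tree_id, dbh_cm at final_year), `sere` (per-tree
#'   effects).
#' @export
simulate_growth <- function(trees, params, years, seed,
                            final_year = 2021) {
  stopifnot(inherits(params, "growth_params"),
            all(c("tree_id", "site_id", "x", "y", "nmin") %in%
                  names(trees)))
  if (anyNA(trees$nmin) || anyNA(trees$x) || anyNA(trees$y)) {
    stop("Nmin and coordinates must be present for all trees")
  }
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(trees)
  z_nmin <- if (n > 1 && stats::sd(trees$nmin) > 0) {
    (trees$nmin - mean(trees$nmin)) / stats::sd(trees$nmin)
  } else rep(0, n)

  yrs <- (final_year - years + 1):final_year
  temps <- data.frame(year = yrs,
                      may_min_temp = stats::rnorm(years, 5, 1.5))
  z_temp <- if (years > 1 && stats::sd(temps$may_min_temp) > 0) {
    as.vector(scale(temps$may_min_temp))
  } else rep(0, years)

  sere <- rep(0, n)
  if (params$sigma2_sere > 0) {
    S <- build_sere_cov(trees[, c("x", "y")], params$phi,
                        params$sigma2_sere, trees$site_id)
    sere <- drop(crossprod(chol(S), stats::rnorm(n)))
  }

  dbh <- stats::runif(n, params$initial_dbh_range[1],
                      params$initial_dbh_range[2])
  prev_bai <- rep(params$lag_center, n)  # z = 0 in the first year
  dbh_mat <- matrix(NA_real_, n, years + 1)
  dbh_mat[, 1] <- dbh
  bai_mat <- matrix(NA_real_, n, years)
  for (t in seq_len(years)) {
    z_lag <- (prev_bai - params$lag_center) / params$lag_scale
    z_dbh <- (log(dbh) - params$lndbh_center) / params$lndbh_scale
    s2 <- params$a + params$b * z_dbh
    if (any(s2 <= 0)) {
      i <- which(s2 <= 0)[1]
      stop("variance model non-positive for tree ", trees$tree_id[i],
           " in year ", yrs[t], " (a + b*z(lnDBH) = ", signif(s2[i], 3),
           ")")
    }
    D <- params$alpha + params$beta[1] * z_nmin +
      params$beta[2] * z_lag + params$beta[3] * z_dbh +
      params$beta[4] * z_temp[t] + sere
    bai <- stats::rlnorm(n, D, sqrt(s2))
    if (any(!is.finite(bai))) {
      i <- which(!is.finite(bai))[1]
      stop("growth diverged for tree ", trees$tree_id[i], " in year ",
           yrs[t], "; the lag-feedback parameters are unstable")
    }
    dbh_new <- sqrt(dbh^2 + 4 * bai / pi)
    bai_mat[, t] <- bai
    dbh_mat[, t + 1] <- dbh_new
    prev_bai <- bai
    dbh <- dbh_new
  }

  width_mm <- (dbh_mat[, -1] - dbh_mat[, -(years + 1)]) / 2 * 10
  split_e <- matrix(stats::runif(n * years, 0, 0.1), n) * width_mm
  long <- function(m, value_name, years_vec) {
    data.frame(tree_id = rep(trees$tree_id, times = length(years_vec)),
               year = rep(years_vec, each = n),
               v = as.vector(m), stringsAsFactors = FALSE,
               check.names = FALSE) |>
      stats::setNames(c("tree_id", "year", value_name))
  }
  rings <- rbind(
    cbind(long(width_mm + split_e, "width_mm", yrs), core_id = "N"),
    cbind(long(width_mm - split_e, "width_mm", yrs), core_id = "S"))
  rings <- rings[order(rings$tree_id, rings$core_id, rings$year),
                 c("tree_id", "core_id", "year", "width_mm")]
  rownames(rings) <- NULL
  diam <- long(dbh_mat, "dbh_cm", c(yrs[1] - 1L, yrs))
  diam <- diam[order(diam$tree_id, diam$year), ]
  rownames(diam) <- NULL
  bai_df <- long(bai_mat, "bai_cm2", yrs)
  bai_df <- bai_df[order(bai_df$tree_id, bai_df$year), ]
  rownames(bai_df) <- NULL
  list(rings = rings, diameters = diam, bai = bai_df, temps = temps,
       measured_dbh = data.frame(tree_id = trees$tree_id,
                                 dbh_cm = dbh_mat[, years + 1]),
       sere = sere)
}

#' Simulate an ASV community along the gradient
#'
#' Per tree, realized richness is `round(intercept + slope * Nmin +
#' noise)` truncated to [1, pool size].  Which taxa are present is a
#' weighted draw without replacement: threshold increasers carry a
#' logistic occurrence weight jumping from 0.1 to 0.9 above their planted
#' change point on the Nmin axis (decreasers mirrored), noise and
#' baseline taxa a constant weight.  Present taxa receive log-normal
#' abundance weights (threshold taxa doubled on their favoured side) and
#' counts are drawn multinomially at the sequencing depth.  The taxonomy
#' map groups ASVs of a common response type into virtual taxa, a
#' configurable majority of which belong to the dominant genus.
#'
#' @param trees layout from [generate_layout()] (must carry `nmin`).
#' @param config `sim_config`.
#' @param seed RNG seed.
#' @return list with `counts` (tree-by-ASV integer matrix), `taxonomy`
#'   (asv_id, vt_id, genus), `truth` (per-taxon role and change point).
#' @export
simulate_community <- function(trees, config, seed) {
  stopifnot(inherits(config, "sim_config"), "nmin" %in% names(trees))
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(trees)
  pool <- config$n_taxa_pool
  nI <- config$n_threshold_increasers
  nD <- config$n_threshold_decreasers
  nN <- config$n_noise_taxa
  roles <- c(rep("increaser", nI), rep("decreaser", nD),
             rep("noise", nN), rep("baseline", pool - nI - nD - nN))
  asv_ids <- sprintf("ASV%03d", seq_len(pool))

  exp_rich <- config$richness_intercept +
    config$richness_slope * trees$nmin
  if (any(exp_rich <= 0)) {
    stop("richness_slope makes expected richness non-positive at Nmin = ",
         signif(trees$nmin[which.min(exp_rich)], 3))
  }
  rich <- pmin(pmax(round(exp_rich +
                            stats::rnorm(n, 0, config$richness_noise_sd)),
                    1), pool)

  # planted change points on the inner part of the gradient
  inner <- config$nmin_range[1] + diff(config$nmin_range) * c(0.25, 0.75)
  cps <- rep(NA_real_, pool)
  if (nI > 0) cps[roles == "increaser"] <- seq(inner[1], inner[2],
                                               length.out = nI)
  if (nD > 0) cps[roles == "decreaser"] <- seq(inner[1], inner[2],
                                               length.out = nD)
  steep <- 12 / diff(config$nmin_range)  # logistic steepness per unit Nmin
  occ_weight <- function(nmin) {
    w <- rep(0.5, pool)
    jump <- function(cp, sgn) {
      0.1 + 0.8 * stats::plogis(sgn * 4 * steep * (nmin - cp))
    }
    w[roles == "increaser"] <- jump(cps[roles == "increaser"], 1)
    w[roles == "decreaser"] <- jump(cps[roles == "decreaser"], -1)
    w
  }

  counts <- matrix(0L, n, pool,
                   dimnames = list(trees$tree_id, asv_ids))
  for (i in seq_len(n)) {
    w <- occ_weight(trees$nmin[i])
    present <- sample.int(pool, rich[i], prob = w)
    aw <- stats::rlnorm(length(present), 0, 1)
    boost <- rep(1, length(present))
    r <- roles[present]
    above <- trees$nmin[i] > cps[present]
    boost[r == "increaser" & above] <- 2
    boost[r == "decreaser" & !above] <- 2
    cnt <- stats::rmultinom(1, config$sequencing_depth, aw * boost)
    counts[i, present] <- cnt
  }

  # taxonomy: VTs group ASVs of a common response type (about 3 per VT)
  vt_of <- integer(pool)
  nxt <- 0
  for (r in unique(roles)) {
    ix <- which(roles == r)
    vt_of[ix] <- nxt + ceiling(seq_along(ix) / 3)
    nxt <- max(vt_of)
  }
  n_vt <- max(vt_of)
  genera <- c("Glomus", "Paraglomus", "Acaulospora", "Diversispora",
              "Claroideospora", "Archaeospora")
  n_dom <- round(config$dominant_genus_frac * n_vt)
  vt_genus <- c(rep(genera[1], n_dom),
                sample(genera[-1], n_vt - n_dom, replace = TRUE))
  vt_genus <- sample(vt_genus)  # shuffle which VTs are dominant-genus
  taxonomy <- data.frame(asv_id = asv_ids,
                         vt_id = sprintf("VT%04d", vt_of),
                         genus = vt_genus[vt_of],
                         stringsAsFactors = FALSE)
  truth <- data.frame(asv_id = asv_ids, role = roles, change_point = cps,
                      stringsAsFactors = FALSE)
  list(counts = counts, taxonomy = taxonomy, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: layout, growth series and community in one call,
#' with sub-seeds derived deterministically from the config seed.
#'
#' @param config `sim_config`.
#' @return list with `trees`, `growth` (see [simulate_growth()]), and
#'   `community` (see [simulate_community()]).
#' @export
simulate_study <- function(config) {
  trees <- generate_layout(config)
  growth <- simulate_growth(trees, config$growth_params, config$years,
                            seed = config$seed + 1)
  community <- simulate_community(trees, config, seed = config$seed + 2)
  list(trees = trees, growth = growth, community = community)
}
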