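# Assembly of the per-tree-per-year design table consumed by the
# hierarchical growth model.

#' Assemble the growth-model design table
#'
#' Joins basal area increments with their one-year lag, (lagged) log
#' diameter, per-tree net N mineralization and coordinates, and per-year
#' May minimum temperature.  The first year of each tree is dropped
#' (undefined lag).  Log diameter entering both the mean and the variance
#' model is the diameter at the start of the growth year, i.e. the
#' previous year's DBH.
#'
#' @param bai data.frame `tree_id`, `year`, `bai_cm2`.
#' @param diameters data.frame `tree_id`, `year`, `dbh_cm`.
#' @param trees data.frame `tree_id`, `site_id`, `x`, `y`, `nmin`,
#'   `species`.
#' @param temps data.frame `year`, `may_min_temp`.
#' @param species optional species label; keep only that species' trees.
#' @param standardize z-score the four covariates (default TRUE); the
#'   centering/scaling constants are stored in the `"scaling"` attribute
#'   for back-transformation.
#' @return data.frame of class `growth_design` with columns `tree_id`,
#'   `year`, `bai`, `nmin`, `bai_lag`, `ln_dbh`, `may_min_temp`,
#'   `site_id`, `x`, `y`, `species`; attributes `scaling`, `trees`,
#'   `standardized`.
#' @export
build_design <- function(bai, diameters, trees, temps, species = NULL,
                         standardize = TRUE) {
  stopifnot(all(c("tree_id", "year", "bai_cm2") %in% names(bai)),
            all(c("tree_id", "year", "dbh_cm") %in% names(diameters)),
            all(c("tree_id", "site_id", "x", "y", "nmin", "species")
                %in% names(trees)),
            all(c("year", "may_min_temp") %in% names(temps)))
  if (!is.null(species)) trees <- trees[trees$species == species, ]
  if (nrow(trees) == 0) stop("no trees after species filter")
  bai <- bai[bai$tree_id %in% trees$tree_id, ]
  bai <- bai[order(bai$tree_id, bai$year), ]
  if (any(bai$bai_cm2 <= 0)) {
    stop("BAI must be positive (log-normal response); offending rows: ",
         paste(utils::head(which(bai$bai_cm2 <= 0), 5), collapse = ", "))
  }

  # lag BAI within tree
  lag1 <- function(v) c(NA, v[-length(v)])
  bai$bai_lag <- stats::ave(bai$bai_cm2, bai$tree_id, FUN = lag1)
  keep <- !is.na(bai$bai_lag)
  d <- bai[keep, c("tree_id", "year", "bai_cm2", "bai_lag")]
  names(d)[names(d) == "bai_cm2"] <- "bai"

  # previous-year DBH (size entering the growth year)
  key_d <- paste(diameters$tree_id, diameters$year)
  prev <- match(paste(d$tree_id, d$year - 1), key_d)
  if (anyNA(prev)) {
    bad <- which(is.na(prev))
    stop("missing previous-year DBH for rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  d$ln_dbh <- log(diameters$dbh_cm[prev])

  ti <- match(d$tree_id, trees$tree_id)
  d$nmin <- trees$nmin[ti]
  d$site_id <- trees$site_id[ti]
  d$x <- trees$x[ti]
  d$y <- trees$y[ti]
  d$species <- trees$species[ti]
  yt <- match(d$year, temps$year)
  if (anyNA(yt)) {
    stop("missing May minimum temperature for year(s): ",
         paste(unique(d$year[is.na(yt)]), collapse = ", "))
  }
  d$may_min_temp <- temps$may_min_temp[yt]
  bad <- !stats::complete.cases(
    d[c("bai", "bai_lag", "ln_dbh", "nmin", "may_min_temp")])
  if (any(bad)) {
    stop("missing covariates in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }

  covs <- c("nmin", "bai_lag", "ln_dbh", "may_min_temp")
  scaling <- lapply(covs, function(cn) {
    list(center = mean(d[[cn]]), scale = stats::sd(d[[cn]]))
  })
  names(scaling) <- covs
  if (standardize) {
    for (cn in covs) {
      s <- scaling[[cn]]
      if (s$scale == 0) stop("covariate '", cn, "' has zero variance")
      d[[cn]] <- (d[[cn]] - s$center) / s$scale
    }
  }
  d <- d[order(d$tree_id, d$year), ]
  rownames(d) <- NULL
  tr <- trees[trees$tree_id %in% d$tree_id,
              c("tree_id", "site_id", "x", "y", "species")]
  tr <- tr[order(tr$tree_id), ]
  rownames(tr) <- NULL
  structure(d, scaling = scaling, trees = tr, standardized = standardize,
            class = c("growth_design", "data.frame"))
}

#' Spatial random-effect covariance over trees
#'
#' Exponential distance-decay kernel blocked by site:
#' `Sigma_ij = sigma2_sere * exp(-phi * d_ij)` for trees i, j in the same
#' site, 0 across sites, `sigma2_sere` on the diagonal.  A small jitter is
#' added to the diagonal if the matrix is not numerically positive
#' definite, and recorded in the `"jitter"` attribute.
#'
#' @param coords two-column matrix (x, y) in metres, one row per tree.
#' @param phi decay rate per metre, > 0.
#' @param sigma2_sere marginal variance, >= 0.
#' @param site_ids site membership vector, length nrow(coords).
#' @return covariance matrix (trees x trees).
#' @export
build_sere_cov <- function(coords, phi, sigma2_sere, site_ids) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, length(site_ids) == nrow(coords))
  if (!is.finite(phi) || phi <= 0) stop("phi must be > 0")
  if (sigma2_sere < 0) stop("sigma2_sere must be >= 0")
  n <- nrow(coords)
  dmat <- as.matrix(stats::dist(coords))
  if (any(dmat < 0)) stop("negative distances")
  same_site <- outer(site_ids, site_ids, "==")
  sig <- sigma2_sere * exp(-phi * dmat) * same_site
  diag(sig) <- sigma2_sere
  jitter <- 0
  if (sigma2_sere > 0 && n > 0) {
    ok <- FALSE
    for (k in 0:6) {
      jitter <- if (k == 0) 0 else 10^(k - 9) * sigma2_sere
      test <- sig + diag(jitter, n)
      ev <- tryCatch(chol(test), error = function(e) NULL)
      if (!is.null(ev)) { sig <- test; ok <- TRUE; break }
    }
    if (!ok) stop("covariance not positive definite even after jitter")
  }
  structure(sig, jitter = jitter)
}
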