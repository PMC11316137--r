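# Convergence diagnostics, DIC, posterior summaries and prediction.

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed over the resulting 2 * n_chains sequences, per
#' scalar parameter.  Parameters with zero variance everywhere get R-hat
#' 1 and are listed in the `"zero_variance"` attribute.
#'
#' @param samples `growth_mcmc` object (>= 2 chains of equal length).
#' @param params parameters to assess (default: all scalar parameters).
#' @return named vector of R-hat values.
#' @export
gelman_rubin <- function(samples, params = samples$scalar_names) {
  if (samples$n_chains < 2) stop("need at least two chains for R-hat")
  lens <- vapply(samples$chains, nrow, integer(1))
  if (length(unique(lens)) != 1) stop("chains have unequal lengths")
  half <- floor(lens[1] / 2)
  if (half < 2) stop("chains too short to split")
  out <- stats::setNames(rep(NA_real_, length(params)), params)
  zerovar <- character(0)
  for (p in params) {
    segs <- list()
    for (ch in samples$chains) {
      v <- ch[, p]
      segs <- c(segs, list(v[seq_len(half)]),
                list(v[(half + 1):(2 * half)]))
    }
    m <- length(segs); n <- half
    means <- vapply(segs, mean, numeric(1))
    vars <- vapply(segs, stats::var, numeric(1))
    W <- mean(vars)
    B_n <- stats::var(means)            # = B / n
    if (W == 0 && B_n == 0) {
      out[p] <- 1; zerovar <- c(zerovar, p); next
    }
    if (W == 0) { out[p] <- Inf; next }
    var_plus <- (n - 1) / n * W + B_n
    out[p] <- sqrt(var_plus / W)
  }
  attr(out, "zero_variance") <- zerovar
  out
}

#' Effective sample size of pooled draws
#'
#' Autocorrelation-based ESS using the initial positive sequence
#' estimator on the within-chain autocovariances.
#'
#' @param samples `growth_mcmc` object.
#' @param params parameters (default scalars).
#' @return named vector of effective sample sizes.
#' @export
effective_size <- function(samples, params = samples$scalar_names) {
  out <- stats::setNames(rep(NA_real_, length(params)), params)
  for (p in params) {
    total <- 0
    for (ch in samples$chains) {
      v <- ch[, p]
      n <- length(v)
      if (stats::var(v) == 0) { total <- total + n; next }
      ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE,
                       demean = TRUE)$acf[-1]
      # initial positive sequence: stop at first non-positive paired sum
      s <- 0; k <- 1
      while (k + 1 <= length(ac)) {
        pair <- ac[k] + ac[k + 1]
        if (pair <= 0) break
        s <- s + pair; k <- k + 2
      }
      total <- total + n / (1 + 2 * s)
    }
    out[p] <- total
  }
  out
}

# Per-draw deviance evaluations shared by DIC and summaries.
draw_params <- function(draw, n_trees) {
  list(alpha = draw[["alpha"]],
       beta = c(draw[["beta1"]], draw[["beta2"]], draw[["beta3"]],
                draw[["beta4"]]),
       a = draw[["a"]], b = draw[["b"]], theta = draw[["theta"]],
       sigma2_sere = draw[["sigma2_sere"]],
       sere = if (n_trees > 0) {
         unname(draw[-(1:9)])
       } else numeric(0))
}

#' Deviance information criterion
#'
#' `D(theta) = -2 log L`; `DIC = Dbar + pD` with
#' `pD = Dbar - D(theta_bar)`, `theta_bar` the posterior mean of all
#' parameters (SERE averaged elementwise).  The deviance focuses on the
#' data likelihood conditional on the random effects.
#'
#' @param samples `growth_mcmc` object with >= 100 kept draws.
#' @param data the `growth_design` the model was fitted to.
#' @return list with `DIC`, `pD`, `Dbar`, `Dhat`.
#' @export
compute_dic <- function(samples, data) {
  pooled <- pool_draws(samples)
  if (nrow(pooled) < 100) stop("need at least 100 kept draws for DIC")
  ctx <- model_context(data)
  use_sere <- samples$sere == "kernel" && ctx$n_trees > 0
  dev <- apply(pooled, 1, function(dr) {
    p <- draw_params(dr, samples$n_trees)
    if (!use_sere) p$sere <- rep(0, ctx$n_trees)
    -2 * growth_loglik(p$alpha, p$beta, p$a, p$b, p$sere, ctx)
  })
  bad <- !is.finite(dev)
  if (mean(bad) > 0.01) {
    stop("non-finite deviance in ", round(100 * mean(bad), 1),
         "% of draws")
  }
  dev <- dev[!bad]
  pooled_ok <- pooled[!bad, , drop = FALSE]
  Dbar <- mean(dev)
  pm <- colMeans(pooled_ok)
  pbar <- draw_params(pm, samples$n_trees)
  if (!use_sere) pbar$sere <- rep(0, ctx$n_trees)
  Dhat <- -2 * growth_loglik(pbar$alpha, pbar$beta, pbar$a, pbar$b,
                             pbar$sere, ctx)
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior summary, convergence check and goodness of fit
#'
#' Produces the posterior mean, sd and central 95% interval per scalar
#' parameter, split-chain R-hat, a significance flag for the slope
#' coefficients (95% interval excluding zero), DIC, and goodness-of-fit
#' R-squared: the squared Pearson correlation between observed ln BAI and
#' the posterior-mean linear predictor (also reported on the natural BAI
#' scale using the log-normal median `exp(D)`).
#'
#' @param samples `growth_mcmc` object.
#' @param data the fitted `growth_design`.
#' @param rhat_threshold convergence threshold (default 1.1).
#' @param allow_unconverged proceed with a warning instead of an error
#'   when some R-hat exceeds the threshold.
#' @return object of class `growth_fit`: list with `summary` (data.frame),
#'   `r2_log`, `r2_natural`, `dic`, `rhat`, `n_obs`, `n_trees`.
#' @export
summarize_fit <- function(samples, data, rhat_threshold = 1.1,
                          allow_unconverged = FALSE) {
  rhat <- tryCatch(gelman_rubin(samples), error = function(e) NULL)
  if (!is.null(rhat) && any(rhat > rhat_threshold, na.rm = TRUE)) {
    msg <- paste0("R-hat above ", rhat_threshold, " for: ",
                  paste(names(rhat)[rhat > rhat_threshold], collapse = ", "))
    if (allow_unconverged) warning(msg) else stop(msg)
  }
  pooled <- pool_draws(samples)
  sc <- samples$scalar_names
  qs <- t(apply(pooled[, sc, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975)))
  summ <- data.frame(
    parameter = sc,
    mean = colMeans(pooled[, sc, drop = FALSE]),
    sd = apply(pooled[, sc, drop = FALSE], 2, stats::sd),
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    rhat = if (is.null(rhat)) NA_real_ else unname(rhat[sc]),
    row.names = NULL)
  slope_pars <- c("beta1", "beta2", "beta3", "beta4", "b")
  summ$significant <- summ$parameter %in% slope_pars &
    (summ$q2.5 > 0 | summ$q97.5 < 0)

  ctx <- model_context(data)
  r2_log <- r2_nat <- NA_real_
  dic <- NULL
  if (ctx$n > 0) {
    pm <- colMeans(pooled)
    p <- draw_params(pm, samples$n_trees)
    use_sere <- samples$sere == "kernel" && ctx$n_trees > 0
    D <- p$alpha + drop(ctx$X %*% p$beta)
    if (use_sere) D <- D + p$sere[ctx$tree_index]
    r2_log <- stats::cor(ctx$y, D)^2
    r2_nat <- stats::cor(exp(ctx$y), exp(D))^2
    dic <- tryCatch(compute_dic(samples, data), error = function(e) NULL)
  }
  structure(list(summary = summ, r2_log = r2_log, r2_natural = r2_nat,
                 dic = dic, rhat = rhat, n_obs = ctx$n,
                 n_trees = ctx$n_trees),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Hierarchical growth model fit:", x$n_obs, "tree-years,",
      x$n_trees, "trees\n")
  print(x$summary, digits = 3)
  cat(sprintf("R2 (log scale) = %.3f, R2 (natural scale) = %.3f\n",
              x$r2_log, x$r2_natural))
  if (!is.null(x$dic)) {
    cat(sprintf("DIC = %.1f (pD = %.1f)\n", x$dic$DIC, x$dic$pD))
  }
  invisible(x)
}

#' Posterior predicted growth along the N mineralization gradient
#'
#' For each grid point, the posterior distribution of median BAI
#' `exp(D)` with all other covariates held at reference values (default:
#' their observed means) and the spatial effect at zero.
#'
#' @param samples `growth_mcmc` object.
#' @param data the fitted `growth_design` (provides the covariate scaling
#'   and the admissible grid range).
#' @param nmin_grid N mineralization values (raw units); must lie within
#'   10% of the observed range.
#' @param reference named list of raw-scale reference values for
#'   `bai_lag`, `ln_dbh`, `may_min_temp` (default: observed means).
#' @return data.frame with `nmin`, `bai_mean`, `bai_lo`, `bai_hi`.
#' @export
predict_response <- function(samples, data, nmin_grid, reference = NULL) {
  scaling <- attr(data, "scaling")
  standardized <- isTRUE(attr(data, "standardized"))
  raw_nmin <- if (standardized) {
    data$nmin * scaling$nmin$scale + scaling$nmin$center
  } else data$nmin
  rng <- range(raw_nmin)
  slack <- 0.1 * diff(rng)
  if (any(nmin_grid < rng[1] - slack | nmin_grid > rng[2] + slack)) {
    stop("nmin_grid extends beyond 10% outside the observed range [",
         signif(rng[1], 3), ", ", signif(rng[2], 3), "]")
  }
  zval <- function(name, raw) {
    if (!standardized) return(raw)
    (raw - scaling[[name]]$center) / scaling[[name]]$scale
  }
  ref <- list(bai_lag = mean(data$bai_lag), ln_dbh = mean(data$ln_dbh),
              may_min_temp = mean(data$may_min_temp))
  if (!is.null(reference)) {
    for (nm in names(reference)) ref[[nm]] <- zval(nm, reference[[nm]])
  }
  pooled <- pool_draws(samples)
  zg <- zval("nmin", nmin_grid)
  out <- data.frame(nmin = nmin_grid, bai_mean = NA_real_,
                    bai_lo = NA_real_, bai_hi = NA_real_)
  for (i in seq_along(zg)) {
    D <- pooled[, "alpha"] + pooled[, "beta1"] * zg[i] +
      pooled[, "beta2"] * ref$bai_lag + pooled[, "beta3"] * ref$ln_dbh +
      pooled[, "beta4"] * ref$may_min_temp
    bai <- exp(D)
    out$bai_mean[i] <- mean(bai)
    out$bai_lo[i] <- stats::quantile(bai, 0.025)
    out$bai_hi[i] <- stats::quantile(bai, 0.975)
  }
  out
}
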