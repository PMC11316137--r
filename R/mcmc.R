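# Adaptive Metropolis-within-Gibbs sampler for the growth model.  Scalar
# parameters get random-walk updates with Roberts-Rosenthal step-size
# adaptation during burn-in; the spatial random-effect vector is updated
# jointly by elliptical slice sampling under its multivariate-normal
# prior, so it needs no tuning.

# Cholesky factors of the per-site prior blocks for given (theta, s2).
sere_chols <- function(theta, sigma2, ctx) {
  phi <- exp(theta)
  lapply(ctx$dist_blocks, function(D) {
    S <- sigma2 * exp(-phi * D)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(S + diag(1e-8 * sigma2, nrow(D)))
    ch
  })
}

# MVN(0, Sigma) draw / log density from cached Cholesky blocks.
sere_draw <- function(chols, ctx) {
  out <- numeric(ctx$n_trees)
  for (k in seq_along(ctx$site_blocks)) {
    ix <- ctx$site_blocks[[k]]
    out[ix] <- drop(crossprod(chols[[k]], stats::rnorm(length(ix))))
  }
  out
}

sere_logdens <- function(sere, chols, ctx) {
  total <- 0
  for (k in seq_along(ctx$site_blocks)) {
    ix <- ctx$site_blocks[[k]]
    ch <- chols[[k]]
    z <- backsolve(ch, sere[ix], transpose = TRUE)
    total <- total - sum(log(diag(ch))) - 0.5 * sum(z^2) -
      0.5 * length(ix) * log(2 * pi)
  }
  total
}

#' Sample the growth-model posterior by MCMC
#'
#' Adaptive Metropolis-within-Gibbs over (alpha, beta, a, b, theta,
#' sigma2_sere) with the spatial random-effect (SERE) vector updated
#' jointly by elliptical slice sampling.  Proposal scales adapt during
#' burn-in only.  With a zero-row design the sampler explores the prior
#' (useful for prior-recovery checks).
#'
#' @param data `growth_design` from [build_design()]; may have zero rows.
#' @param priors prior list, see [default_priors()].
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations per chain (default half).
#' @param n_keep_total cap on total kept draws pooled over chains;
#'   post-burn-in draws are thinned to respect it.
#' @param seed integer seed; the run is deterministic given it.
#' @param sere `"kernel"` (spatial random effects on) or `"none"`
#'   (ablation without SERE; theta and sigma2_sere are then sampled from
#'   their priors and do not enter the likelihood).
#' @return object of class `growth_mcmc`: list with `chains` (list of
#'   draw matrices, iterations x parameters), `param_names`, `accept`
#'   (acceptance rates), and metadata.
#' @export
run_mcmc <- function(data, priors = default_priors(), n_chains = 3,
                     n_iter = 10000, n_burnin = floor(n_iter / 2),
                     n_keep_total = 50000, seed = 1,
                     sere = c("kernel", "none")) {
  sere <- match.arg(sere)
  if (n_chains < 1) stop("need at least one chain")
  ctx <- model_context(data)
  use_sere <- sere == "kernel" && ctx$n_trees > 0

  scalar_names <- c("alpha", "beta1", "beta2", "beta3", "beta4",
                    "a", "b", "theta", "sigma2_sere")
  # per-tree covariate means, for joint moves along the soft direction
  # where a slope shift is absorbed by the tree-level random effects
  tree_means <- if (ctx$n_trees > 0 && ctx$n > 0) {
    apply(ctx$X, 2, function(col) {
      vapply(split(col, ctx$tree_index), mean, numeric(1))
    })
  } else matrix(0, 0, 4)
  sere_names <- if (ctx$n_trees > 0) {
    paste0("sere_", attr(data, "trees")$tree_id)
  } else character(0)
  par_names <- c(scalar_names, sere_names)

  set.seed(seed %% .Machine$integer.max)
  chain_seeds <- sample.int(2^30, n_chains)

  n_post <- n_iter - n_burnin
  keep_per_chain <- min(n_post, max(1, ceiling(n_keep_total / n_chains)))
  thin <- max(1L, floor(n_post / keep_per_chain))
  keep_iters <- seq(n_burnin + thin, n_iter, by = thin)

  # starting values: crude least-squares fit when data are present
  base_init <- function() {
    st <- list(alpha = 2.5, beta = rep(0, 4), a = 0.5, b = 0,
               theta = 0, sigma2_sere = if (use_sere) 1 else 5,
               sere = rep(0, ctx$n_trees))
    if (ctx$n > 0) {
      fit <- stats::lm.fit(cbind(1, ctx$X), ctx$y)
      cf <- fit$coefficients
      st$alpha <- min(max(cf[1], 0.05), 4.95)
      st$beta <- pmin(pmax(cf[-1], -3), 3)
      st$a <- max(stats::var(fit$residuals), 1e-4)
    }
    if (st$a + st$b * min(c(ctx$ln_dbh, 0)) <= 0) {
      stop("cannot initialize with positive variance; ",
           "check the BAI and DBH inputs")
    }
    st
  }

  run_chain <- function(cseed) {
    set.seed(cseed)
    st <- base_init()
    st$alpha <- min(max(st$alpha + stats::rnorm(1, 0, 0.1), 0.05), 4.95)
    st$beta <- st$beta + stats::rnorm(4, 0, 0.1)
    st$a <- st$a * exp(stats::rnorm(1, 0, 0.1))
    st$theta <- stats::rnorm(1, 0, 0.5)
    st$sigma2_sere <- stats::runif(1, 0.2, 5)

    log_step <- stats::setNames(rep(log(0.2), length(scalar_names)),
                                scalar_names)
    if (ctx$n > 0) log_step[c("a", "b")] <- log(0.05)
    acc <- bat <- stats::setNames(rep(0, length(scalar_names)),
                                  scalar_names)
    batch_no <- 0

    D <- if (ctx$n > 0) st$alpha + drop(ctx$X %*% st$beta) else numeric(0)
    if (ctx$n > 0 && use_sere) D <- D + st$sere[ctx$tree_index]
    s2 <- if (ctx$n > 0) st$a + st$b * ctx$ln_dbh else numeric(0)
    ll_data <- function(D, s2) {
      if (ctx$n == 0) return(0)
      if (any(s2 <= 0)) return(-Inf)
      sum(stats::dnorm(ctx$y, D, sqrt(s2), log = TRUE)) - ctx$sum_log_y
    }
    cur_ll <- ll_data(D, s2)
    chols <- if (use_sere) sere_chols(st$theta, st$sigma2_sere, ctx) else NULL
    cur_sp <- if (use_sere) sere_logdens(st$sere, chols, ctx) else 0

    pri <- function(name, val) {
      switch(name,
        alpha = stats::dunif(val, priors$alpha_min, priors$alpha_max,
                             log = TRUE),
        a = if (val <= 0) -Inf else
          stats::dlnorm(val, priors$a_meanlog, priors$a_sdlog, log = TRUE),
        b = stats::dnorm(val, priors$b_mean, priors$b_sd, log = TRUE),
        theta = stats::dnorm(val, priors$theta_mean, priors$theta_sd,
                             log = TRUE),
        sigma2_sere = stats::dunif(val, priors$sigma2_sere_min,
                                   priors$sigma2_sere_max, log = TRUE),
        stats::dnorm(val, priors$beta_mean, priors$beta_sd, log = TRUE))
    }

    draws <- matrix(NA_real_, length(keep_iters), length(par_names),
                    dimnames = list(NULL, par_names))
    krow <- 0

    for (it in seq_len(n_iter)) {
      # --- location / variance scalars (data likelihood changes) ---
      for (nm in c("alpha", "beta1", "beta2", "beta3", "beta4", "a", "b")) {
        old <- switch(nm, alpha = st$alpha, a = st$a, b = st$b,
                      st$beta[as.integer(substring(nm, 5))])
        prop <- old + stats::rnorm(1, 0, exp(log_step[nm]))
        lp_old <- pri(nm, old); lp_new <- pri(nm, prop)
        if (is.finite(lp_new)) {
          if (nm == "alpha") {
            D_new <- D + (prop - old); s2_new <- s2
          } else if (nm == "a" || nm == "b") {
            D_new <- D
            s2_new <- if (nm == "a") s2 + (prop - old) else
              s2 + (prop - old) * ctx$ln_dbh
          } else {
            k <- as.integer(substring(nm, 5))
            D_new <- D + (prop - old) * ctx$X[, k]; s2_new <- s2
          }
          ll_new <- ll_data(D_new, s2_new)
          if (log(stats::runif(1)) < (ll_new + lp_new) - (cur_ll + lp_old)) {
            if (nm == "alpha") st$alpha <- prop
            else if (nm == "a") st$a <- prop
            else if (nm == "b") st$b <- prop
            else st$beta[as.integer(substring(nm, 5))] <- prop
            D <- D_new; s2 <- s2_new; cur_ll <- ll_new
            acc[nm] <- acc[nm] + 1
          }
        }
        bat[nm] <- bat[nm] + 1
      }

      # --- spatial hyperparameters (SERE prior changes) ---
      for (nm in c("theta", "sigma2_sere")) {
        old <- if (nm == "theta") st$theta else st$sigma2_sere
        prop <- old + stats::rnorm(1, 0, exp(log_step[nm]))
        lp_old <- pri(nm, old); lp_new <- pri(nm, prop)
        if (is.finite(lp_new)) {
          if (use_sere) {
            ch_new <- if (nm == "theta") {
              sere_chols(prop, st$sigma2_sere, ctx)
            } else sere_chols(st$theta, prop, ctx)
            sp_new <- sere_logdens(st$sere, ch_new, ctx)
          } else {
            ch_new <- NULL; sp_new <- 0
          }
          if (log(stats::runif(1)) < (sp_new + lp_new) - (cur_sp + lp_old)) {
            if (nm == "theta") st$theta <- prop else st$sigma2_sere <- prop
            chols <- ch_new; cur_sp <- sp_new
            acc[nm] <- acc[nm] + 1
          }
        }
        bat[nm] <- bat[nm] + 1
      }

      # --- SERE vector: elliptical slice sample under its MVN prior ---
      if (use_sere) {
        nu <- sere_draw(chols, ctx)
        logy <- cur_ll + log(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        amin <- ang - 2 * pi; amax <- ang
        base_D <- D - st$sere[ctx$tree_index]
        repeat {
          sere_new <- st$sere * cos(ang) + nu * sin(ang)
          D_new <- base_D + sere_new[ctx$tree_index]
          ll_new <- ll_data(D_new, s2)
          if (ll_new > logy) {
            st$sere <- sere_new; D <- D_new; cur_ll <- ll_new
            cur_sp <- sere_logdens(st$sere, chols, ctx)
            break
          }
          if (ang < 0) amin <- ang else amax <- ang
          ang <- stats::runif(1, amin, amax)
          if (amax - amin < 1e-12) break  # degenerate bracket; keep state
        }
      }

      # --- joint moves breaking the ridge between the intercept /
      #     slopes and the SERE vector: shift the parameter and absorb
      #     its tree-level component into the random effects.  For the
      #     intercept and tree-level covariates the likelihood is exactly
      #     invariant; for time-varying covariates only the within-tree
      #     residual changes. ---
      if (use_sere && ctx$n > 0) {
        for (mv in c("jalpha", "jbeta1", "jbeta2", "jbeta3")) {
          if (!mv %in% names(log_step)) {
            log_step[mv] <- log(0.2); acc[mv] <- 0; bat[mv] <- 0
          }
          dlt <- stats::rnorm(1, 0, exp(log_step[mv]))
          if (mv == "jalpha") {
            sere_new <- st$sere - dlt
            lp_old <- pri("alpha", st$alpha)
            lp_new <- pri("alpha", st$alpha + dlt)
            D_new <- D; ll_new <- cur_ll
          } else {
            k <- as.integer(substring(mv, 6))
            sere_new <- st$sere - dlt * tree_means[, k]
            lp_old <- pri(paste0("beta", k), st$beta[k])
            lp_new <- pri(paste0("beta", k), st$beta[k] + dlt)
            resid <- ctx$X[, k] - tree_means[ctx$tree_index, k]
            if (all(abs(resid) < 1e-12)) {
              D_new <- D; ll_new <- cur_ll
            } else {
              D_new <- D + dlt * resid
              ll_new <- ll_data(D_new, s2)
            }
          }
          if (is.finite(lp_new)) {
            sp_new <- sere_logdens(sere_new, chols, ctx)
            if (log(stats::runif(1)) <
                (ll_new + sp_new + lp_new) - (cur_ll + cur_sp + lp_old)) {
              if (mv == "jalpha") st$alpha <- st$alpha + dlt else
                st$beta[k] <- st$beta[k] + dlt
              st$sere <- sere_new
              D <- D_new; cur_ll <- ll_new; cur_sp <- sp_new
              acc[mv] <- acc[mv] + 1
            }
          }
          bat[mv] <- bat[mv] + 1
        }
      }

      # --- step-size adaptation, burn-in only ---
      if (it <= n_burnin && it %% 50 == 0) {
        batch_no <- batch_no + 1
        delta <- min(0.25, 1 / sqrt(batch_no))
        rate <- acc / pmax(bat, 1)
        log_step <- log_step + ifelse(rate > 0.44, delta, -delta)
        acc[] <- 0; bat[] <- 0
      }

      if (it > n_burnin && (it - n_burnin) %% thin == 0) {
        krow <- krow + 1
        if (krow <= nrow(draws)) {
          draws[krow, ] <- c(st$alpha, st$beta, st$a, st$b, st$theta,
                             st$sigma2_sere, st$sere)
        }
      }
    }
    list(draws = draws[seq_len(krow), , drop = FALSE],
         accept = acc / pmax(bat, 1))
  }

  chains <- lapply(chain_seeds, run_chain)
  structure(list(
    chains = lapply(chains, `[[`, "draws"),
    accept = lapply(chains, `[[`, "accept"),
    param_names = par_names,
    scalar_names = scalar_names,
    n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
    thin = thin, seed = seed, sere = sere,
    n_trees = ctx$n_trees
  ), class = "growth_mcmc")
}

#' Pool kept draws across chains
#' @param samples a `growth_mcmc` object.
#' @return matrix of pooled draws.
#' @export
pool_draws <- function(samples) {
  do.call(rbind, samples$chains)
}
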