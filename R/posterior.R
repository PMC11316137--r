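# Log-posterior of the hierarchical log-normal growth model:
#   ln BAI_{i,y} ~ N(D_{i,y}, a + b * lnDBH_{i,y-1})
#   D_{i,y} = alpha + b1*Nmin_i + b2*BAI_{i,y-1} + b3*lnDBH_{i,y-1}
#             + b4*MayMinTemp_y + SERE_i
#   SERE ~ MVN(0, Sigma), Sigma_ij = sigma2_sere * exp(-phi d_ij) within
#   site, phi = exp(theta).

#' Default prior specification
#'
#' Second parameters of the normal/log-normal priors follow the JAGS
#' precision convention: `beta ~ N(0, precision 1)`,
#' `a ~ logN(meanlog 1, precision 0.001)`, `b ~ N(0, precision 0.001)`,
#' `theta ~ N(0, 1)` with `phi = exp(theta)`, `alpha ~ U(0, 5)`,
#' `sigma2_sere ~ U(0, 10)`.
#'
#' @return list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(
    alpha_min = 0, alpha_max = 5,
    beta_mean = 0, beta_sd = 1,
    a_meanlog = 1, a_sdlog = sqrt(1 / 0.001),
    b_mean = 0, b_sd = sqrt(1 / 0.001),
    theta_mean = 0, theta_sd = 1,
    sigma2_sere_min = 0, sigma2_sere_max = 10
  )
}

# Precomputed quantities shared by the density and the sampler.
model_context <- function(data) {
  if (nrow(data) == 0) {
    return(list(n = 0L, y = numeric(0), X = matrix(0, 0, 4),
                tree_index = integer(0), n_trees = 0L,
                site_blocks = list(), dist_blocks = list(),
                sum_log_y = 0, ln_dbh = numeric(0)))
  }
  trees <- attr(data, "trees")
  if (is.null(trees)) {
    trees <- unique(data[c("tree_id", "site_id", "x", "y")])
    trees <- trees[order(trees$tree_id), ]
  }
  y <- log(data$bai)
  X <- as.matrix(data[c("nmin", "bai_lag", "ln_dbh", "may_min_temp")])
  tree_index <- match(data$tree_id, trees$tree_id)
  sites <- split(seq_len(nrow(trees)), trees$site_id)
  dist_blocks <- lapply(sites, function(ix) {
    as.matrix(stats::dist(trees[ix, c("x", "y")]))
  })
  list(n = nrow(data), y = y, X = X, tree_index = tree_index,
       n_trees = nrow(trees), site_blocks = sites,
       dist_blocks = dist_blocks, sum_log_y = sum(y),
       ln_dbh = data$ln_dbh)
}

# Data log-likelihood given parameters; -Inf when the variance model goes
# non-positive on any row.
growth_loglik <- function(alpha, beta, a, b, sere, ctx) {
  if (ctx$n == 0) return(0)
  s2 <- a + b * ctx$ln_dbh
  if (any(s2 <= 0)) return(-Inf)
  D <- alpha + drop(ctx$X %*% beta)
  if (length(sere)) D <- D + sere[ctx$tree_index]
  sum(stats::dnorm(ctx$y, D, sqrt(s2), log = TRUE)) - ctx$sum_log_y
}

# Zero-mean MVN log density of the SERE vector under the blocked
# exponential kernel; returns the density and caches nothing.
sere_logprior <- function(sere, theta, sigma2_sere, ctx) {
  if (ctx$n_trees == 0) return(0)
  if (sigma2_sere <= 0) return(-Inf)
  phi <- exp(theta)
  total <- 0
  for (k in seq_along(ctx$site_blocks)) {
    ix <- ctx$site_blocks[[k]]
    S <- sigma2_sere * exp(-phi * ctx$dist_blocks[[k]])
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      S <- S + diag(1e-8 * sigma2_sere, length(ix))
      ch <- chol(S)
    }
    z <- backsolve(ch, sere[ix], transpose = TRUE)
    total <- total - sum(log(diag(ch))) - 0.5 * sum(z^2) -
      0.5 * length(ix) * log(2 * pi)
  }
  total
}

#' Log-posterior density of the growth model
#'
#' Sum of the log-normal data likelihood, the multivariate-normal density
#' of the spatial random effects under the blocked exponential kernel, and
#' the log priors.  Returns `-Inf` (no exception) when any parameter is
#' outside its prior support or the variance model `a + b * lnDBH` is
#' non-positive on any row.
#'
#' @param params list with elements `alpha`, `beta` (length 4), `a`, `b`,
#'   `theta`, `sigma2_sere`, `sere` (length = number of trees; may be
#'   omitted/NULL when the design is empty).
#' @param data a `growth_design` (see [build_design()]); may have zero
#'   rows for a prior-only evaluation.
#' @param priors list as returned by [default_priors()].
#' @return scalar log density.
#' @export
log_posterior <- function(params, data, priors = default_priors()) {
  p <- params
  if (is.null(p$sere)) p$sere <- numeric(0)
  vals <- c(p$alpha, p$beta, p$a, p$b, p$theta, p$sigma2_sere, p$sere)
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  ctx <- model_context(data)
  if (ctx$n_trees > 0 && length(p$sere) != ctx$n_trees) {
    stop("sere must have one entry per tree (", ctx$n_trees, ")")
  }
  if (p$alpha <= priors$alpha_min || p$alpha >= priors$alpha_max ||
      p$a <= 0 ||
      p$sigma2_sere <= priors$sigma2_sere_min ||
      p$sigma2_sere >= priors$sigma2_sere_max) {
    return(-Inf)
  }
  ll <- growth_loglik(p$alpha, p$beta, p$a, p$b, p$sere, ctx)
  if (!is.finite(ll)) return(-Inf)
  lp <- ll +
    sere_logprior(p$sere, p$theta, p$sigma2_sere, ctx) +
    stats::dunif(p$alpha, priors$alpha_min, priors$alpha_max, log = TRUE) +
    sum(stats::dnorm(p$beta, priors$beta_mean, priors$beta_sd, log = TRUE)) +
    stats::dlnorm(p$a, priors$a_meanlog, priors$a_sdlog, log = TRUE) +
    stats::dnorm(p$b, priors$b_mean, priors$b_sd, log = TRUE) +
    stats::dnorm(p$theta, priors$theta_mean, priors$theta_sd, log = TRUE) +
    stats::dunif(p$sigma2_sere, priors$sigma2_sere_min,
                 priors$sigma2_sere_max, log = TRUE)
  lp
}
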