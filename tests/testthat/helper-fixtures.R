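# Shared fixtures: all built in code at test time.

# A small complete synthetic study (6 sites x 3 trees, 15 years).
small_study <- function(seed = 1, ...) {
  cfg <- sim_config(n_sites = 6, trees_per_site = 3, years = 15,
                    n_taxa_pool = 20, n_threshold_increasers = 5,
                    n_threshold_decreasers = 2, n_noise_taxa = 10,
                    sequencing_depth = 1000, seed = seed, ...)
  simulate_study(cfg)
}

# Design table for a small study (all trees).
small_design <- function(seed = 1, ...) {
  st <- small_study(seed, ...)
  build_design(st$growth$bai, st$growth$diameters, st$trees,
               st$growth$temps)
}

# An empty design with the right structure, for prior-only MCMC.
empty_design <- function() {
  d <- data.frame(tree_id = character(0), year = integer(0),
                  bai = numeric(0), bai_lag = numeric(0),
                  ln_dbh = numeric(0), nmin = numeric(0),
                  may_min_temp = numeric(0), site_id = character(0),
                  x = numeric(0), y = numeric(0),
                  species = character(0))
  structure(d, scaling = NULL, trees = NULL, standardized = FALSE,
            class = c("growth_design", "data.frame"))
}

# Hand-built tiny design table with explicit values (unstandardized).
tiny_design <- function(bai = c(5, 6, 4, 7), nmin = c(0.5, 0.5, 1.2, 1.2),
                        bai_lag = c(4, 5, 5, 6),
                        ln_dbh = c(2.9, 3.0, 3.1, 3.2),
                        temp = c(4, 6, 4, 6),
                        tree_id = c("A", "A", "B", "B")) {
  n <- length(bai)
  d <- data.frame(tree_id = tree_id, year = seq_len(n) + 2000,
                  bai = bai, bai_lag = bai_lag, ln_dbh = ln_dbh,
                  nmin = nmin, may_min_temp = temp,
                  site_id = "S01", x = c(0, 0, 10, 10)[seq_len(n)],
                  y = 0, species = "A. rubrum")
  trees <- unique(d[c("tree_id", "site_id", "x", "y")])
  trees <- trees[order(trees$tree_id), ]
  structure(d, scaling = NULL, trees = trees, standardized = FALSE,
            class = c("growth_design", "data.frame"))
}

# Independent log-posterior oracle, coded from the model definition with
# no shared helpers: log-normal rows + blocked MVN + hand-coded priors.
oracle_log_posterior <- function(params, data) {
  p <- params
  if (p$alpha <= 0 || p$alpha >= 5 || p$a <= 0 ||
      p$sigma2_sere <= 0 || p$sigma2_sere >= 10) return(-Inf)
  s2 <- p$a + p$b * data$ln_dbh
  if (any(s2 <= 0)) return(-Inf)
  X <- as.matrix(data[c("nmin", "bai_lag", "ln_dbh", "may_min_temp")])
  trees <- attr(data, "trees")
  D <- p$alpha + drop(X %*% p$beta) +
    p$sere[match(data$tree_id, trees$tree_id)]
  ll <- sum(-log(data$bai) - 0.5 * log(2 * pi * s2) -
              (log(data$bai) - D)^2 / (2 * s2))
  # blocked MVN over trees
  phi <- exp(p$theta)
  mvn <- 0
  for (s in unique(trees$site_id)) {
    ix <- which(trees$site_id == s)
    dm <- as.matrix(stats::dist(trees[ix, c("x", "y")]))
    S <- p$sigma2_sere * exp(-phi * dm)
    v <- p$sere[ix]
    mvn <- mvn - 0.5 * (length(ix) * log(2 * pi) +
                          determinant(S, logarithm = TRUE)$modulus +
                          drop(t(v) %*% solve(S, v)))
  }
  pri <- -log(5) +
    sum(-0.5 * log(2 * pi) - p$beta^2 / 2) +
    (-log(p$a) - 0.5 * log(2 * pi * 1000) - (log(p$a) - 1)^2 / 2000) +
    (-0.5 * log(2 * pi * 1000) - p$b^2 / 2000) +
    (-0.5 * log(2 * pi) - p$theta^2 / 2) +
    -log(10)
  as.numeric(ll + mvn + pri)
}

# Brute-force Chao1 from frequency-of-frequencies, independent of the
# package implementation.
oracle_chao1 <- function(counts, bias_corrected = TRUE) {
  tab <- table(counts[counts > 0])
  sobs <- sum(tab)
  f1 <- if ("1" %in% names(tab)) unname(tab[["1"]]) else 0
  f2 <- if ("2" %in% names(tab)) unname(tab[["2"]]) else 0
  if (bias_corrected || f2 == 0) {
    sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    sobs + f1^2 / (2 * f2)
  }
}
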