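# Threshold indicator taxa analysis: per-taxon change-point detection on
# a continuous gradient via indicator-value permutation z-scores, with
# bootstrap purity and reliability and increaser/decreaser
# classification.

#' Configuration for threshold indicator taxa analysis
#'
#' @param n_permutations permutation-null size per candidate change point.
#' @param n_bootstrap bootstrap replicates for purity/reliability.
#' @param purity_threshold,reliability_threshold significance thresholds
#'   (both default 0.95; a taxon is significant when both are met).
#' @param reliability_p per-replicate permutation p-value counted as a
#'   "reliable" detection (default 0.05).
#' @param min_occurrences minimum samples a taxon must occur in.
#' @param min_split minimum samples on each side of a candidate change
#'   point.
#' @param seed RNG seed; all permutations and bootstraps derive from it.
#' @return list of class `titan_config`.
#' @export
titan_config <- function(n_permutations = 250, n_bootstrap = 1000,
                         purity_threshold = 0.95,
                         reliability_threshold = 0.95,
                         reliability_p = 0.05, min_occurrences = 3,
                         min_split = 5, seed = 1) {
  stopifnot(n_permutations >= 50, n_bootstrap >= 50,
            purity_threshold > 0, purity_threshold <= 1,
            reliability_threshold > 0, reliability_threshold <= 1,
            min_split >= 1)
  structure(list(n_permutations = n_permutations,
                 n_bootstrap = n_bootstrap,
                 purity_threshold = purity_threshold,
                 reliability_threshold = reliability_threshold,
                 reliability_p = reliability_p,
                 min_occurrences = min_occurrences,
                 min_split = min_split, seed = seed),
            class = "titan_config")
}

#' Dufrene-Legendre indicator values for a binary split
#'
#' For each group g: specificity `A_g = mean abundance in g / (mean in
#' low + mean in high)`, fidelity `B_g` = fraction of g's samples with
#' abundance > 0, and `IndVal_g = A_g * B_g` on the 0-1 scale.
#'
#' @param abundance per-sample abundance vector.
#' @param high logical vector, TRUE for samples above the split.
#' @return named vector `c(indval_low, indval_high)`.
#' @export
indval <- function(abundance, high) {
  stopifnot(length(abundance) == length(high))
  if (all(abundance == 0)) stop("taxon absent from every sample")
  if (!any(high) || all(high)) stop("both groups must be non-empty")
  m_lo <- mean(abundance[!high]); m_hi <- mean(abundance[high])
  a_lo <- m_lo / (m_lo + m_hi); a_hi <- m_hi / (m_lo + m_hi)
  b_lo <- mean(abundance[!high] > 0); b_hi <- mean(abundance[high] > 0)
  c(indval_low = a_lo * b_lo, indval_high = a_hi * b_hi)
}

# IndVal of the larger group at every candidate split of sorted data,
# vectorised over permutation columns.  xs: matrix (n x ncol) of
# abundances already ordered along the gradient; ks: candidate split
# positions (group low = 1..k).  Returns max-group IndVal matrix
# (length(ks) x ncol).
indval_at_splits <- function(xs, ks) {
  n <- nrow(xs)
  Lk <- matrix(0, length(ks), n)
  for (i in seq_along(ks)) Lk[i, seq_len(ks[i])] <- 1
  cs <- Lk %*% xs                 # low-group sums
  co <- Lk %*% (xs > 0)           # low-group occurrences
  tot <- matrix(colSums(xs), length(ks), ncol(xs), byrow = TRUE)
  toc <- matrix(colSums(xs > 0), length(ks), ncol(xs), byrow = TRUE)
  k <- ks; nk <- n - ks
  m_lo <- cs / k
  m_hi <- (tot - cs) / nk
  denom <- m_lo + m_hi
  a_lo <- ifelse(denom > 0, m_lo / denom, 0)
  a_hi <- ifelse(denom > 0, m_hi / denom, 0)
  iv_lo <- a_lo * (co / k)
  iv_hi <- a_hi * ((toc - co) / nk)
  list(iv = pmax(iv_lo, iv_hi), high_side = iv_hi >= iv_lo)
}

#' Scan candidate change points for one taxon
#'
#' Candidate change points are midpoints between consecutive distinct
#' sorted gradient values leaving at least `min_split` samples on each
#' side.  At each candidate the larger-group indicator value is compared
#' to its permutation null (abundances shuffled across samples
#' `n_permutations` times); `z = (IndVal_obs - mean_perm) / sd_perm`.
#' The best change point maximises z, ties broken toward the candidate
#' nearer the gradient median.  Uses the current RNG state (seed it for
#' reproducibility).
#'
#' @param abundance per-sample abundance (e.g. Hellinger-transformed).
#' @param gradient per-sample continuous gradient values.
#' @param config `titan_config`.
#' @return list with `cp`, `direction` (+1 increaser / -1 decreaser),
#'   `indval`, `z`, `p`, `n_candidates`, `n_skipped`; or `NULL` when no
#'   candidate is scorable.
#' @export
scan_changepoints <- function(abundance, gradient, config = titan_config()) {
  n <- length(abundance)
  stopifnot(length(gradient) == n)
  if (sum(abundance > 0) < config$min_occurrences) {
    stop("taxon occurs in fewer than min_occurrences = ",
         config$min_occurrences, " samples")
  }
  if (length(unique(gradient)) < 2) stop("gradient must vary")
  ord <- order(gradient)
  g <- gradient[ord]
  xo <- abundance[ord]
  ks <- which(diff(g) != 0)
  ks <- ks[ks >= config$min_split & (n - ks) >= config$min_split]
  if (!length(ks)) return(NULL)
  cps <- (g[ks] + g[ks + 1]) / 2

  obs <- indval_at_splits(matrix(xo, ncol = 1), ks)
  # permutations are shuffles of the sample->abundance assignment,
  # independent of the gradient ordering
  P <- vapply(seq_len(config$n_permutations),
              function(i) abundance[sample.int(n)][ord], numeric(n))
  perm <- indval_at_splits(P, ks)
  mu <- rowMeans(perm$iv)
  sdv <- sqrt(pmax(rowMeans(perm$iv^2) - mu^2, 0) *
                config$n_permutations / (config$n_permutations - 1))
  ok <- sdv > 0
  n_skipped <- sum(!ok)
  if (!any(ok)) return(NULL)
  z <- rep(-Inf, length(ks))
  z[ok] <- (obs$iv[ok, 1] - mu[ok]) / sdv[ok]
  zmax <- max(z)
  best <- which(z >= zmax - 1e-12)
  if (length(best) > 1) {
    best <- best[which.min(abs(cps[best] - stats::median(gradient)))]
  }
  p <- (1 + sum(perm$iv[best, ] >= obs$iv[best, 1])) /
    (1 + config$n_permutations)
  list(cp = cps[best],
       direction = if (obs$high_side[best, 1]) 1L else -1L,
       indval = obs$iv[best, 1], z = z[best], p = p,
       n_candidates = length(ks), n_skipped = n_skipped)
}

#' Bootstrap purity and reliability for one taxon
#'
#' Resamples samples with replacement `n_bootstrap` times and reruns the
#' change-point scan on each replicate.  Purity is the fraction of
#' replicates agreeing with the observed response direction; reliability
#' is the fraction whose permutation p-value is at most `reliability_p`.
#' Replicates in which the taxon is absent are redrawn up to 10 times and
#' then counted as failures (against both metrics).  Deterministic given
#' `seed`.
#'
#' @param abundance,gradient as in [scan_changepoints()].
#' @param config `titan_config`.
#' @param seed RNG seed (default `config$seed`).
#' @return one-row data.frame: `cp`, `direction`, `z`, `z_median`,
#'   `purity`, `reliability`, `significant`, `cp_lo`, `cp_hi`,
#'   `n_failed`.
#' @export
bootstrap_taxon <- function(abundance, gradient, config = titan_config(),
                            seed = config$seed) {
  set.seed(seed %% .Machine$integer.max)
  obs <- scan_changepoints(abundance, gradient, config)
  if (is.null(obs)) stop("taxon is unscorable on the observed data")
  n <- length(abundance)
  agree <- reliable <- logical(config$n_bootstrap)
  zb <- cpb <- rep(NA_real_, config$n_bootstrap)
  n_failed <- 0
  for (b in seq_len(config$n_bootstrap)) {
    res <- NULL
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(abundance[idx] == 0) ||
          sum(abundance[idx] > 0) < config$min_occurrences ||
          length(unique(gradient[idx])) < 2) next
      res <- tryCatch(
        scan_changepoints(abundance[idx], gradient[idx], config),
        error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) { n_failed <- n_failed + 1; next }
    agree[b] <- res$direction == obs$direction
    reliable[b] <- res$p <= config$reliability_p
    zb[b] <- res$z; cpb[b] <- res$cp
  }
  purity <- mean(agree)
  reliability <- mean(reliable)
  okb <- !is.na(zb)
  data.frame(
    cp = obs$cp, direction = obs$direction, z = obs$z,
    z_median = if (any(okb)) stats::median(zb[okb]) else NA_real_,
    purity = purity, reliability = reliability,
    significant = purity >= config$purity_threshold &
      reliability >= config$reliability_threshold,
    cp_lo = if (any(okb)) stats::quantile(cpb[okb], 0.05) else NA_real_,
    cp_hi = if (any(okb)) stats::quantile(cpb[okb], 0.95) else NA_real_,
    n_failed = n_failed, row.names = NULL)
}

#' Threshold indicator taxa analysis of a community table
#'
#' Runs the per-taxon change-point scan and bootstrap over every taxon
#' occurring in at least `min_occurrences` samples, on
#' Hellinger-transformed relative abundances (applied internally by
#' default).  For virtual-taxon level analysis supply a taxonomy map:
#' ASV counts are summed within VT before transformation.
#'
#' @param counts sample-by-taxon count matrix.
#' @param gradient per-sample gradient vector aligned to rows.
#' @param config `titan_config`.
#' @param taxonomy optional data.frame (`asv_id`, `vt_id`) triggering
#'   VT-level aggregation.
#' @param transform Hellinger-transform the counts first (default TRUE).
#' @return list of class `titan_result`: `responses` (data.frame with one
#'   row per scored taxon), `n_increasers`, `n_decreasers` (significant
#'   taxa only), `n_tested`, `n_unscorable`.
#' @export
classify_community <- function(counts, gradient, config = titan_config(),
                               taxonomy = NULL, transform = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(length(gradient) == nrow(counts))
  if (!is.null(taxonomy)) counts <- aggregate_vt(counts, taxonomy)
  mat <- if (transform) hellinger(counts) else counts
  occ <- colSums(mat > 0)
  taxa <- colnames(mat)[occ >= config$min_occurrences]
  rows <- list()
  n_unscorable <- 0
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    res <- tryCatch(
      bootstrap_taxon(mat[, tx], gradient, config,
                      seed = config$seed + i),
      error = function(e) NULL)
    if (is.null(res)) { n_unscorable <- n_unscorable + 1; next }
    rows[[length(rows) + 1]] <- cbind(taxon = tx, res)
  }
  responses <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), cp = numeric(0),
               direction = integer(0), z = numeric(0),
               z_median = numeric(0), purity = numeric(0),
               reliability = numeric(0), significant = logical(0),
               cp_lo = numeric(0), cp_hi = numeric(0),
               n_failed = integer(0))
  structure(list(
    responses = responses,
    n_increasers = sum(responses$significant & responses$direction == 1),
    n_decreasers = sum(responses$significant & responses$direction == -1),
    n_tested = length(taxa),
    n_unscorable = n_unscorable
  ), class = "titan_result")
}

#' @export
print.titan_result <- function(x, ...) {
  cat("Threshold indicator taxa analysis:", x$n_tested, "taxa tested\n")
  cat("  significant increasers:", x$n_increasers, "\n")
  cat("  significant decreasers:", x$n_decreasers, "\n")
  if (x$n_unscorable) cat("  unscorable:", x$n_unscorable, "\n")
  invisible(x)
}

#' Write per-taxon responses as TSV
#' @param result `titan_result`.
#' @param path output TSV path.
#' @export
write_titan_tsv <- function(result, path) {
  utils::write.table(result$responses, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
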