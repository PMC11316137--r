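# Shared-ASV community construction, Chao1 richness, Hellinger
# transformation, and richness regressions.

#' Restrict a count table to the ASVs shared between host species
#'
#' Retains taxa with a nonzero count in at least one sample of EACH host
#' species and present on at least `min_trees` trees overall.  With
#' `min_trees = 1` the species-sharing rule alone governs.
#'
#' @param counts sample-by-taxon matrix (rownames = sample/tree ids).
#' @param species character vector of host-species labels, one per
#'   sample; exactly two species must be present.
#' @param min_trees minimum number of trees a taxon must occur on
#'   (default 2).
#' @return filtered count matrix with a `"retention"` attribute logging
#'   taxa in/out.
#' @export
filter_shared <- function(counts, species, min_trees = 2) {
  counts <- as.matrix(counts)
  stopifnot(length(species) == nrow(counts))
  sp <- unique(species)
  if (length(sp) < 2) {
    stop("both host species must be present (found only: ",
         paste(sp, collapse = ", "), ")")
  }
  present <- counts > 0
  in_each_sp <- Reduce(`&`, lapply(sp, function(s) {
    colSums(present[species == s, , drop = FALSE]) > 0
  }))
  n_trees_per_taxon <- colSums(present)
  keep <- in_each_sp & n_trees_per_taxon >= min_trees
  out <- counts[, keep, drop = FALSE]
  attr(out, "retention") <- list(
    n_in = ncol(counts), n_out = sum(keep),
    dropped_species_rule = sum(!in_each_sp),
    dropped_min_trees = sum(in_each_sp & n_trees_per_taxon < min_trees))
  out
}

#' Chao1 richness estimate of one sample
#'
#' `S_obs + F1^2 / (2 F2)` (classic) or the bias-corrected
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (default), where F1 and F2 are
#' the numbers of singleton and doubleton taxa.  The classic form falls
#' back to the bias-corrected one when F2 = 0.
#'
#' @param counts non-negative integer vector of taxon counts.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("Chao1 requires integer counts, not relative abundances")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Chao1 per sample of a count table
#'
#' Samples with total reads below `min_depth` are dropped (with a
#' message) before estimation, since Chao1 is depth-sensitive.
#'
#' @param counts sample-by-taxon matrix.
#' @param bias_corrected passed to [chao1()].
#' @param min_depth minimum total reads per retained sample (default 1).
#' @return named numeric vector of estimates, one per retained sample.
#' @export
chao1_per_sample <- function(counts, bias_corrected = TRUE,
                             min_depth = 1) {
  counts <- as.matrix(counts)
  depth <- rowSums(counts)
  drop <- depth < min_depth
  if (any(drop)) {
    message(sum(drop), " sample(s) below min_depth = ", min_depth,
            " dropped: ", paste(rownames(counts)[drop], collapse = ", "))
  }
  apply(counts[!drop, , drop = FALSE], 1, chao1,
        bias_corrected = bias_corrected)
}

#' Hellinger transformation of a count table
#'
#' Each entry becomes the square root of its sample relative abundance,
#' `sqrt(count / sample total)`.  All-zero samples map to zeros with a
#' warning.
#'
#' @param counts sample-by-taxon matrix with non-negative entries.
#' @return transformed matrix of the same shape.
#' @export
hellinger <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- rowSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left as zeros")
    tot[zero] <- 1
  }
  sqrt(counts / tot)
}

#' Ordinary least-squares regression of richness on a gradient
#'
#' Fits `response ~ covariate`, reporting the slope test F statistic with
#' (1, n-2) degrees of freedom and the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - 2)`.
#'
#' @param response per-sample richness (e.g. Chao1).
#' @param covariate per-sample gradient value (mean BAI or Nmin).
#' @return list with `slope`, `intercept`, `F`, `df1`, `df2`, `p`,
#'   `r2`, `adj_r2`, `n`.
#' @export
regress_diversity <- function(response, covariate) {
  ok <- is.finite(response) & is.finite(covariate)
  response <- response[ok]; covariate <- covariate[ok]
  n <- length(response)
  if (n < 3) stop("need at least three paired observations")
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  fit <- stats::lm(response ~ covariate)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = unname(sm$fstatistic[1]),
       df1 = unname(sm$fstatistic[2]),
       df2 = unname(sm$fstatistic[3]),
       p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                            sm$fstatistic[3], lower.tail = FALSE)),
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       n = n)
}

#' Aggregate ASV counts to virtual taxa
#'
#' Sums counts of ASVs mapped to the same virtual taxon; unmapped ASVs
#' (NA `vt_id`) are dropped with a message.
#'
#' @param counts sample-by-ASV matrix.
#' @param taxonomy data.frame with `asv_id`, `vt_id`.
#' @return sample-by-VT matrix.
#' @export
aggregate_vt <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  vt <- taxonomy$vt_id[match(colnames(counts), taxonomy$asv_id)]
  unmapped <- is.na(vt)
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped ASV(s) dropped from VT aggregation")
  }
  m <- counts[, !unmapped, drop = FALSE]
  vt <- vt[!unmapped]
  out <- t(rowsum(t(m), group = vt))
  out[, order(colnames(out)), drop = FALSE]
}
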