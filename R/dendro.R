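# Ring-width series -> reconstructed diameters -> basal area increments,
# plus chronology quality (EPS) and pith-offset estimation.

#' Reconstruct historical diameter at breast height from ring widths
#'
#' Works backwards from a field-measured DBH in a known final year.  Each
#' year's radial increment is the mean width across the available cores of
#' the tree (typically a north and a south core, each measuring one
#' radius), so diameter shrinks by twice the increment per year going back
#' in time.
#'
#' @param series data.frame with columns `core_id`, `year`, `width_mm`
#'   holding every core of one tree.  Years within a core must be strictly
#'   consecutive and widths non-negative; at most two cores per tree.
#' @param measured_dbh_cm field-measured DBH (cm) in `final_year`.
#' @param final_year calendar year of the DBH measurement; must be the
#'   last ring year.
#' @param pith_offset_mm optional missing radius to the pith (mm), e.g.
#'   from [estimate_pith_offset()]; subtracted (x2) from the first
#'   reconstructed diameter check only, i.e. used to validate that the
#'   innermost diameter remains positive after accounting for it.
#' @return data.frame with columns `year` and `dbh_cm`, one row per year
#'   from the year before the first ring (initial stem) through
#'   `final_year`.  The first row is the diameter before the earliest
#'   measured ring formed.
#' @export
reconstruct_dbh <- function(series, measured_dbh_cm, final_year,
                            pith_offset_mm = 0) {
  stopifnot(is.data.frame(series),
            all(c("core_id", "year", "width_mm") %in% names(series)))
  if (!is.numeric(measured_dbh_cm) || length(measured_dbh_cm) != 1 ||
      measured_dbh_cm <= 0) {
    stop("measured_dbh_cm must be a single positive number")
  }
  if (any(series$width_mm < 0)) stop("ring widths must be >= 0")
  cores <- split(series, series$core_id)
  if (length(cores) > 2) stop("at most two cores per tree are supported")
  for (co in cores) {
    yr <- sort(co$year)
    if (length(yr) > 1 && any(diff(yr) != 1)) {
      stop("years within core '", co$core_id[1],
           "' must be strictly consecutive")
    }
  }
  years <- sort(unique(series$year))
  if (max(years) != final_year) {
    stop("final_year (", final_year, ") must match the last ring year (",
         max(years), ")")
  }
  # mean width across cores that have a ring for that year, mm -> cm radius
  incr_cm <- vapply(years, function(y) {
    w <- series$width_mm[series$year == y]
    mean(w) / 10
  }, numeric(1))

  n <- length(years)
  dbh <- numeric(n + 1)
  dbh[n + 1] <- measured_dbh_cm          # after final_year's growth
  for (k in n:1) dbh[k] <- dbh[k + 1] - 2 * incr_cm[k]
  if (any(dbh <= 0)) {
    bad <- years[which(dbh[-(n + 1)] <= 0)][1]
    stop("reconstructed DBH non-positive at year ", bad,
         "; ring widths are inconsistent with the measured diameter")
  }
  if (dbh[1] - 2 * pith_offset_mm / 10 < -1e-9) {
    stop("pith offset exceeds the innermost reconstructed radius")
  }
  out <- data.frame(year = c(years[1] - 1L, years), dbh_cm = dbh)
  rownames(out) <- NULL
  out
}

#' Basal area increment from a diameter series
#'
#' BAI for year y is the annulus area between consecutive diameters,
#' `pi * ((D_y / 2)^2 - (D_{y-1} / 2)^2)`, in cm^2.
#'
#' @param d data.frame with columns `year`, `dbh_cm`; years consecutive
#'   and diameters non-decreasing.
#' @return data.frame with columns `year`, `bai_cm2`, one row per year
#'   after the first.
#' @export
compute_bai <- function(d) {
  stopifnot(is.data.frame(d), all(c("year", "dbh_cm") %in% names(d)))
  d <- d[order(d$year), ]
  if (nrow(d) < 2) stop("need at least two years of diameters")
  if (any(diff(d$dbh_cm) < 0)) stop("DBH must be non-decreasing in year")
  r2 <- (d$dbh_cm / 2)^2
  data.frame(year = d$year[-1], bai_cm2 = pi * diff(r2))
}

#' Mean basal area increment over a year window
#'
#' @param b data.frame with columns `year`, `bai_cm2`.
#' @param start_year,end_year inclusive window; only years present in the
#'   series contribute.
#' @return list with `mean_bai` (cm^2 yr^-1) and `n_years` contributing.
#' @export
mean_bai <- function(b, start_year, end_year) {
  stopifnot(is.data.frame(b), all(c("year", "bai_cm2") %in% names(b)))
  sel <- b$year >= start_year & b$year <= end_year
  if (!any(sel)) stop("window [", start_year, ", ", end_year,
                      "] does not overlap the series")
  list(mean_bai = mean(b$bai_cm2[sel]), n_years = sum(sel))
}

#' Expressed population signal of a set of ring-width series
#'
#' EPS = n * rbar / (1 + (n - 1) * rbar), where rbar is the mean pairwise
#' Pearson correlation of the series over their common years and n the
#' number of series.  Raw widths are used (no detrending).
#'
#' @param series_list list of data.frames, each with columns `year`,
#'   `width_mm` (one series per core or per tree).
#' @param min_overlap minimum number of shared years required for each
#'   pairwise correlation (default 10).
#' @return list with `eps`, `rbar`, `n_series`.
#' @export
compute_eps <- function(series_list, min_overlap = 10) {
  n <- length(series_list)
  if (n < 2) stop("need at least two series")
  rs <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- series_list[[i]]; b <- series_list[[j]]
      common <- intersect(a$year, b$year)
      if (length(common) < min_overlap) {
        stop("series ", i, " and ", j, " overlap in only ",
             length(common), " years (need >= ", min_overlap, ")")
      }
      wa <- a$width_mm[match(common, a$year)]
      wb <- b$width_mm[match(common, b$year)]
      if (stats::sd(wa) == 0 && stats::sd(wb) == 0 && all(wa == wb)) {
        r <- 1  # identical constant series: perfect agreement
      } else if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
        r <- 0
      } else {
        r <- stats::cor(wa, wb)
      }
      rs <- c(rs, r)
    }
  }
  rbar <- mean(rs)
  eps <- if (rbar <= 0) 0 else n * rbar / (1 + (n - 1) * rbar)
  list(eps = eps, rbar = rbar, n_series = n)
}

#' Missing radius to the pith by the geometric (arc) method
#'
#' From the innermost visible ring arc with chord length L and arc height
#' h, the radius of curvature is `r = L^2 / (8 h) + h / 2`, taken as the
#' distance from the innermost ring to the pith.
#'
#' @param chord_mm chord length L (mm), > 0.
#' @param arc_height_mm arc height h (mm), > 0.
#' @param tol minimum arc height; below this the arc is effectively flat
#'   and the estimate diverges, so an error is raised.
#' @return estimated missing radius in mm.
#' @export
estimate_pith_offset <- function(chord_mm, arc_height_mm, tol = 1e-6) {
  if (!is.finite(chord_mm) || chord_mm <= 0) {
    stop("chord_mm must be a positive number")
  }
  if (!is.finite(arc_height_mm) || arc_height_mm <= 0) {
    stop("arc_height_mm must be a positive number")
  }
  if (arc_height_mm < tol) {
    stop("arc height below tolerance (", tol,
         " mm): arc too flat to estimate a radius")
  }
  chord_mm^2 / (8 * arc_height_mm) + arc_height_mm / 2
}
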