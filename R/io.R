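# Readers and writers for the plain-text formats the pipeline exchanges:
# long-format ring widths, Tucson/rwl decadal ring widths, dense ASV count
# tables (CSV or BIOM), and taxonomy maps.

#' Read a long-format ring-width table
#'
#' Expected columns: `tree_id`, `core_id`, `year`, `width_mm`.
#' @param path CSV file path.
#' @return data.frame with the four columns, year coerced to integer.
#' @export
read_ring_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "core_id", "year", "width_mm")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("ring-width CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x$year <- as.integer(x$year)
  x$width_mm <- as.numeric(x$width_mm)
  x[need]
}

#' Write a long-format ring-width table
#' @param rings data.frame as returned by [read_ring_csv()].
#' @param path output CSV path.
#' @export
write_ring_csv <- function(rings, path) {
  utils::write.csv(rings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Tucson (rwl) decadal ring-width file
#'
#' Minimal reader for the classic dendrochronology exchange format: each
#' line holds a series id, the decade-start year, and up to ten ring
#' widths; 999 (units of 0.01 mm) or -9999 (units of 0.001 mm) terminates
#' a series.
#'
#' @param path rwl file path.
#' @param divisor measurement units per mm; 100 for 0.01 mm files
#'   (terminator 999), 1000 for 0.001 mm files (terminator -9999).
#'   Guessed from the terminator when `NULL`.
#' @return data.frame with columns `series_id`, `year`, `width_mm`.
#' @export
read_rwl <- function(path, divisor = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 3) next
    id <- toks[1]
    yr0 <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(yr0) || anyNA(vals)) next
    term <- vals %in% c(999, -9999)
    div <- divisor
    if (is.null(div)) div <- if (any(vals == -9999)) 1000 else 100
    keep <- !term
    if (any(term)) keep[which(term)[1]:length(vals)] <- FALSE
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      series_id = id,
      year = yr0 + seq_along(vals)[keep] - 1L,
      width_mm = vals[keep] / div,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no ring-width data found in ", path)
  do.call(rbind, out)
}

#' Read a dense sample-by-taxon count table
#'
#' CSV with samples in rows (first column `sample_id`) and taxa in
#' columns, or a BIOM file (requires the biomformat package).
#'
#' @param path CSV or BIOM file path.
#' @return integer matrix, samples in rows, taxa in columns.
#' @export
read_counts <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(t(m))  # biom stores taxa x samples
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "sample_id") stop("first column must be sample_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write a dense count table as CSV
#' @param counts matrix, samples in rows.
#' @param path output CSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy map
#'
#' Tab-separated with columns `asv_id`, `vt_id`, `genus`; `vt_id` may be
#' NA for unmapped ASVs.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("asv_id", "vt_id", "genus")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("taxonomy TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- x$asv_id[duplicated(x$asv_id)]
  if (length(dup)) stop("ASVs mapped more than once: ",
                        paste(unique(dup), collapse = ", "))
  x[need]
}

#' Write an ASV taxonomy map as TSV
#' @param tax data.frame with columns `asv_id`, `vt_id`, `genus`.
#' @param path output TSV path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
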