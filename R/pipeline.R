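# End-to-end orchestration: synthetic or user data in, BAI tables, growth
# model fits, richness regressions and threshold-taxa tables out, with a
# manifest of hashes for reproducibility.

#' Build a pipeline configuration
#'
#' Exactly one of `synthetic` (a [sim_config()]) or `paths` (named list
#' of input files: `rings`, `measured_dbh`, `trees`, `temps`, `counts`,
#' `taxonomy`) must be supplied.  The global seed propagates
#' deterministically to every stage.
#'
#' Stage settings default to values that complete a full synthetic run in
#' minutes; production settings (e.g. `growth = list(n_iter = 10000)`,
#' `titan = list(n_bootstrap = 1000)`) are a config away.
#'
#' @param synthetic optional `sim_config`.
#' @param paths optional named list of input file paths.
#' @param growth list overriding growth-model settings
#'   (`n_chains`, `n_iter`, `sere`).
#' @param diversity list overriding diversity settings (`min_trees`,
#'   `bias_corrected`, `min_depth`).
#' @param titan list overriding [titan_config()] arguments.
#' @param out_dir output directory (created if absent).
#' @param seed global seed.
#' @param bai_window_years window length for per-tree mean BAI
#'   (default 41, the last 41 ring years).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            growth = list(), diversity = list(),
                            titan = list(), out_dir, seed = 1,
                            bai_window_years = 41) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("supply exactly one of 'synthetic' or 'paths'")
  }
  g <- utils::modifyList(list(n_chains = 3, n_iter = 2000,
                              sere = "kernel"), growth)
  dv <- utils::modifyList(list(min_trees = 2, bias_corrected = TRUE,
                               min_depth = 1), diversity)
  tt <- utils::modifyList(list(n_permutations = 250, n_bootstrap = 250),
                          titan)
  structure(list(synthetic = synthetic, paths = paths, growth = g,
                 diversity = dv, titan = tt, out_dir = out_dir,
                 seed = seed, bai_window_years = bai_window_years),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of [pipeline_config()]; a `synthetic`
#' block is passed to [sim_config()] (with a nested `growth_params`
#' block passed to [growth_params()]).
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$growth_params)) {
      s$growth_params <- do.call(growth_params, s$growth_params)
    }
    if (!is.null(s$nmin_range)) s$nmin_range <- as.numeric(s$nmin_range)
    syn <- do.call(sim_config, s)
  }
  pipeline_config(
    synthetic = syn, paths = y$paths,
    growth = if (is.null(y$growth)) list() else y$growth,
    diversity = if (is.null(y$diversity)) list() else y$diversity,
    titan = if (is.null(y$titan)) list() else y$titan,
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    seed = if (is.null(y$seed)) 1 else y$seed,
    bai_window_years = if (is.null(y$bai_window_years)) 41 else
      y$bai_window_years)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data generation or loading; ring widths to
#' reconstructed DBH and BAI; hierarchical growth model per species;
#' shared-community Chao1 and its regressions on mean BAI and N
#' mineralization; threshold indicator taxa analysis against both
#' gradients at ASV and VT level.  Every output lands under
#' `config$out_dir`; `manifest.json` records seeds, stage counts and an
#' MD5 hash per output file.  On a stage error a `failure.json` naming
#' the stage is written before the error propagates.
#'
#' @param config `pipeline_config`.
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    write_json_file(list(failed_stage = stage,
                         message = conditionMessage(e)),
                    file.path(out, "failure.json"))
    stop("pipeline failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    # --- stage: inputs ---------------------------------------------------
    stage <- "inputs"
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      study <- simulate_study(cfg)
      trees <- study$trees
      rings <- study$growth$rings
      temps <- study$growth$temps
      measured <- study$growth$measured_dbh
      counts <- study$community$counts
      taxonomy <- study$community$taxonomy
      utils::write.csv(trees, file.path(out, "trees.csv"),
                       row.names = FALSE, quote = FALSE)
      write_ring_csv(rings, file.path(out, "ring_widths.csv"))
      utils::write.csv(temps, file.path(out, "may_min_temp.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(measured, file.path(out, "measured_dbh.csv"),
                       row.names = FALSE, quote = FALSE)
      write_counts(counts, file.path(out, "asv_counts.csv"))
      write_taxonomy(taxonomy, file.path(out, "taxonomy.tsv"))
    } else {
      p <- config$paths
      trees <- utils::read.csv(p$trees, stringsAsFactors = FALSE)
      rings <- read_ring_csv(p$rings)
      temps <- utils::read.csv(p$temps, stringsAsFactors = FALSE)
      measured <- utils::read.csv(p$measured_dbh,
                                  stringsAsFactors = FALSE)
      counts <- read_counts(p$counts)
      taxonomy <- read_taxonomy(p$taxonomy)
    }

    # --- stage: dendro ---------------------------------------------------
    stage <- "dendro"
    final_year <- max(rings$year)
    bai_all <- diam_all <- list()
    for (tid in unique(rings$tree_id)) {
      rw <- rings[rings$tree_id == tid, ]
      mdbh <- measured$dbh_cm[measured$tree_id == tid]
      if (length(mdbh) != 1) stop("no measured DBH for tree ", tid)
      dd <- reconstruct_dbh(rw, mdbh, max(rw$year))
      bb <- compute_bai(dd)
      diam_all[[tid]] <- cbind(tree_id = tid, dd)
      bai_all[[tid]] <- cbind(tree_id = tid, bb)
    }
    diameters <- do.call(rbind, diam_all)
    bai <- do.call(rbind, bai_all)
    rownames(diameters) <- rownames(bai) <- NULL
    win0 <- final_year - config$bai_window_years + 1
    mb <- vapply(split(bai, bai$tree_id), function(b) {
      mean_bai(b, win0, final_year)$mean_bai
    }, numeric(1))
    mean_bai_df <- data.frame(tree_id = names(mb), mean_bai = unname(mb),
                              stringsAsFactors = FALSE)
    utils::write.csv(bai, file.path(out, "bai.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(mean_bai_df, file.path(out, "mean_bai.csv"),
                     row.names = FALSE, quote = FALSE)

    # --- stage: growth model per species --------------------------------
    stage <- "growth_model"
    fits <- list()
    for (sp in sort(unique(trees$species))) {
      des <- build_design(bai, diameters, trees, temps, species = sp)
      samples <- run_mcmc(des, n_chains = config$growth$n_chains,
                          n_iter = config$growth$n_iter,
                          seed = config$seed + 10 + match(sp, sort(unique(trees$species))),
                          sere = config$growth$sere)
      fit <- summarize_fit(samples, des, allow_unconverged = TRUE)
      fits[[sp]] <- fit
      safe <- gsub("[^A-Za-z0-9]+", "_", sp)
      write_json_file(list(
        species = sp, n_obs = fit$n_obs, n_trees = fit$n_trees,
        summary = fit$summary, r2_log = fit$r2_log,
        r2_natural = fit$r2_natural,
        dic = if (is.null(fit$dic)) NULL else
          fit$dic[c("DIC", "pD")]),
        file.path(out, paste0("growth_fit_", safe, ".json")))
    }

    # --- stage: diversity ------------------------------------------------
    stage <- "diversity"
    sample_species <- trees$species[match(rownames(counts),
                                          trees$tree_id)]
    shared <- filter_shared(counts, sample_species,
                            min_trees = config$diversity$min_trees)
    rich <- chao1_per_sample(shared,
                             bias_corrected = config$diversity$bias_corrected,
                             min_depth = config$diversity$min_depth)
    meta_ix <- match(names(rich), trees$tree_id)
    mb_ix <- match(names(rich), mean_bai_df$tree_id)
    rich_df <- data.frame(tree_id = names(rich), chao1 = unname(rich),
                          nmin = trees$nmin[meta_ix],
                          mean_bai = mean_bai_df$mean_bai[mb_ix],
                          stringsAsFactors = FALSE)
    utils::write.csv(rich_df, file.path(out, "chao1_richness.csv"),
                     row.names = FALSE, quote = FALSE)
    reg_bai <- regress_diversity(rich_df$chao1, rich_df$mean_bai)
    reg_nmin <- regress_diversity(rich_df$chao1, rich_df$nmin)
    write_json_file(list(chao1_vs_mean_bai = reg_bai,
                         chao1_vs_nmin = reg_nmin,
                         n_asv_shared = ncol(shared),
                         retention = attr(shared, "retention")),
                    file.path(out, "diversity_regressions.json"))

    # --- stage: titan ----------------------------------------------------
    stage <- "titan"
    tcfg <- do.call(titan_config,
                    c(config$titan, list(seed = config$seed + 100)))
    gradients <- list(mean_bai = rich_df$mean_bai[match(rownames(shared),
                                                        rich_df$tree_id)],
                      nmin = trees$nmin[match(rownames(shared),
                                              trees$tree_id)])
    titan_out <- list()
    for (gname in names(gradients)) {
      for (level in c("asv", "vt")) {
        res <- classify_community(
          shared, gradients[[gname]], tcfg,
          taxonomy = if (level == "vt") taxonomy else NULL)
        key <- paste0(level, "_vs_", gname)
        titan_out[[key]] <- res
        write_titan_tsv(res, file.path(out, paste0("titan_", key,
                                                   ".tsv")))
      }
    }
    write_json_file(lapply(titan_out, function(r) {
      list(n_increasers = r$n_increasers, n_decreasers = r$n_decreasers,
           n_tested = r$n_tested)
    }), file.path(out, "titan_summary.json"))

    # --- stage: manifest -------------------------------------------------
    stage <- "manifest"
    files <- sort(setdiff(list.files(out), c("manifest.json",
                                             "failure.json")))
    hashes <- as.list(tools::md5sum(file.path(out, files)))
    names(hashes) <- files
    manifest <- list(
      package_version = as.character(utils::packageVersion("mycogrowth")),
      seed = config$seed,
      n_trees = nrow(trees),
      n_bai_rows = nrow(bai),
      n_asv_in = ncol(counts),
      n_asv_shared = ncol(shared),
      file_hashes = hashes)
    write_json_file(manifest, file.path(out, "manifest.json"))

    invisible(list(trees = trees, bai = bai, mean_bai = mean_bai_df,
                   fits = fits, richness = rich_df,
                   regressions = list(mean_bai = reg_bai,
                                      nmin = reg_nmin),
                   titan = titan_out, manifest = manifest))
  }, error = on_fail)
}

#' Validate a set of pipeline input files
#'
#' Schema and referential-integrity checks across the six input files.
#' Violations are collected, not fail-fast.
#'
#' @param paths named list with `rings`, `measured_dbh`, `trees`,
#'   `temps`, `counts`, `taxonomy`.
#' @return data.frame with columns `file`, `check`, `detail`; zero rows
#'   when everything is clean.
#' @export
validate_inputs <- function(paths) {
  v <- list()
  add <- function(file, check, detail) {
    v[[length(v) + 1]] <<- data.frame(file = file, check = check,
                                      detail = detail,
                                      stringsAsFactors = FALSE)
  }
  need <- c("rings", "measured_dbh", "trees", "temps", "counts",
            "taxonomy")
  for (nm in need) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      add(nm, "missing_file", paste("no file for input", nm))
    }
  }
  done <- function() {
    if (length(v)) do.call(rbind, v) else
      data.frame(file = character(0), check = character(0),
                 detail = character(0))
  }
  if (length(v)) return(done())

  rings <- tryCatch(read_ring_csv(paths$rings), error = function(e) e)
  trees <- utils::read.csv(paths$trees, stringsAsFactors = FALSE)
  temps <- utils::read.csv(paths$temps, stringsAsFactors = FALSE)
  measured <- utils::read.csv(paths$measured_dbh,
                              stringsAsFactors = FALSE)
  counts <- tryCatch(read_counts(paths$counts), error = function(e) e)
  taxonomy <- tryCatch(read_taxonomy(paths$taxonomy),
                       error = function(e) e)

  if (inherits(rings, "error")) {
    add("rings", "schema", conditionMessage(rings))
  } else {
    if (any(rings$width_mm < 0)) {
      add("rings", "negative_width",
          paste(sum(rings$width_mm < 0), "negative ring width(s)"))
    }
    orphan <- setdiff(unique(rings$tree_id), trees$tree_id)
    if (length(orphan)) {
      add("rings", "unknown_tree",
          paste("tree ids not in tree table:",
                paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }
  for (cn in c("tree_id", "site_id", "x", "y", "nmin", "species")) {
    if (!cn %in% names(trees)) add("trees", "schema",
                                   paste("missing column", cn))
  }
  if (!all(c("year", "may_min_temp") %in% names(temps))) {
    add("temps", "schema", "need columns year, may_min_temp")
  }
  if (!all(c("tree_id", "dbh_cm") %in% names(measured))) {
    add("measured_dbh", "schema", "need columns tree_id, dbh_cm")
  } else if (any(measured$dbh_cm <= 0)) {
    add("measured_dbh", "nonpositive_dbh",
        paste(sum(measured$dbh_cm <= 0), "non-positive DBH value(s)"))
  }
  if (inherits(counts, "error")) {
    add("counts", "schema", conditionMessage(counts))
  } else {
    if (any(counts < 0)) add("counts", "negative_count",
                             "negative entries in count table")
    orphan <- setdiff(rownames(counts), trees$tree_id)
    if (length(orphan)) {
      add("counts", "unknown_sample",
          paste("samples not in tree table:",
                paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }
  if (inherits(taxonomy, "error")) {
    add("taxonomy", "schema", conditionMessage(taxonomy))
  } else if (!inherits(counts, "error")) {
    unmapped <- setdiff(colnames(counts), taxonomy$asv_id)
    if (length(unmapped)) {
      add("taxonomy", "unmapped_asv",
          paste(length(unmapped), "ASV(s) without taxonomy entry"))
    }
  }
  done()
}
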