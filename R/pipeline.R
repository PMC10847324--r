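#' Default run configuration
#'
#' All stage parameters with their documented defaults. Unspecified keys of a
#' user config take these values; the merged config is echoed verbatim into
#' the run manifest.
#'
#' @return named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    cohort = list(source = "synthetic", spec = "demo", n_cells = 250L),
    paths = list(counts = NULL, cells = NULL, template = NULL),
    min_genes = 400L, n_hvg = 1000L, n_pcs = 16L,
    k_neighbors = 20L, resolution = 0.2,
    r_min = 0.7, n_bins = 24L, n_controls = 100L,
    tinf_threshold = 10, ihc_noise_sd = 5,
    n_perm = 1000L, alpha = 0.05, min_cells = 50L, min_frac = 0.1,
    p_adjust = "bonferroni",
    contrast_group = NULL,
    stages = list(scores = TRUE, lr = TRUE, contrast = TRUE)
  )
}

#' Read a run configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON; missing keys take the documented defaults.
#'
#' @param path config file.
#' @return merged config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_run_config(), cfg)
}

#' The demonstration configuration
#'
#' Runs the full pipeline on the packaged synthetic cohort
#' ([demo_cohort_spec()]) with parameters scaled to complete in well under a
#' minute: permissive gene-count filter (the demo gene universe is small),
#' 100 permutations and a 25-cell subcluster floor.
#'
#' @param seed global seed.
#' @return config list.
#' @export
demo_config <- function(seed = 1L) {
  utils::modifyList(default_run_config(), list(
    seed = as.integer(seed),
    min_genes = 200L, n_hvg = 300L, n_pcs = 12L,
    n_perm = 100L, min_cells = 25L))
}

# derived, named per-stage seed streams (kept below 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the pipeline end-to-end
#'
#' Executes filter -> TP10K normalization -> HVG -> scale/PCA -> SNN
#' clustering -> template annotation -> module scores -> composition
#' statistics -> LR permutation analysis -> moderated-t contrast, writing
#' each stage's outputs to its own subdirectory of `out_dir` plus a
#' `manifest.json` recording the config, per-stage seeds and output shapes.
#' No timestamps are written, so reruns with the same config and inputs are
#' byte-identical.
#'
#' @param config config list (see [default_run_config()]) or path to a
#'   YAML/JSON config.
#' @param out_dir output directory (created; must be empty or absent).
#' @return invisibly, a list with `out_dir` and the manifest.
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("filter", "normalize", "hvg", "pca", "cluster", "taca",
              "scores", "composition", "lr", "contrast")
  manifest <- list(package = "scTME",
                   version = as.character(utils::packageVersion("scTME")),
                   config = config,
                   stages = stats::setNames(vector("list", length(stages)),
                                            stages))
  note <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status,
                                        seed = stage_seed(config$seed, stage)),
                                   list(...))
  }

  # ---- input -------------------------------------------------------------
  if (identical(config$cohort$source, "synthetic")) {
    spec <- if (identical(config$cohort$spec, "standard"))
      standard_cohort_spec(seed = stage_seed(config$seed, "cohort"))
    else demo_cohort_spec(seed = stage_seed(config$seed, "cohort"),
                          n_cells = config$cohort$n_cells)
    cohort <- generate_cohort(spec)
    counts <- cohort$counts; cells <- cohort$cells
    template <- cohort$template; truth <- cohort$truth
  } else {
    counts <- read_count_matrix(config$paths$counts,
                                format = if (grepl("\\.mtx$",
                                                   config$paths$counts))
                                  "mtx" else "csv")
    cells <- read_table(config$paths$cells, schema = "cell_table")
    tpl <- utils::read.csv(config$paths$template, stringsAsFactors = FALSE)
    template <- template_annotation(tpl$cell_id, tpl$cell_type)
    truth <- NULL
  }
  manifest$input <- list(n_genes = nrow(counts), n_cells = ncol(counts),
                         n_samples = length(unique(cells$sample_id)))

  # ---- preprocess --------------------------------------------------------
  d <- file.path(out_dir, "01_preprocess")
  dir.create(d, showWarnings = FALSE)
  counts <- filter_cells(counts, min_genes = config$min_genes)
  cells <- cells[cells$cell_id %in% colnames(counts), , drop = FALSE]
  note("filter", "run", n_cells = ncol(counts))
  nm <- lognormalize_tp10k(counts)
  note("normalize", "run", n_cells = ncol(nm))
  hvg <- select_hvg(nm, n_hvg = min(config$n_hvg, nrow(nm)))
  writeLines(hvg, file.path(d, "hvg.txt"))
  note("hvg", "run", n_hvg = length(hvg))
  emb <- pca_embed(scale_center(nm, hvg), n_pcs = config$n_pcs)
  write_df(data.frame(cell_id = rownames(emb), round(unclass(emb), 6),
                      check.names = FALSE), file.path(d, "embedding.csv"))
  note("pca", "run", n_pcs = ncol(emb))

  # ---- cluster + annotate ------------------------------------------------
  d <- file.path(out_dir, "02_annotate")
  dir.create(d, showWarnings = FALSE)
  cl <- snn_cluster(emb, k_neighbors = config$k_neighbors,
                    resolution = config$resolution,
                    seed = stage_seed(config$seed, "cluster"))
  note("cluster", "run", n_clusters = length(cl$sizes))
  taca <- taca_assign(cl, template, r_min = config$r_min)
  cells$cluster <- unname(cl$cluster[cells$cell_id])
  cells$cell_type <- unname(taca$cell_type[cells$cell_id])
  write_df(data.frame(cluster = names(taca$cluster_label),
                      label = unname(taca$cluster_label),
                      n_template = as.integer(taca$n_template)),
           file.path(d, "cluster_labels.csv"))
  note("taca", "run",
       n_undecided = sum(cells$cell_type == "undecided"))

  if (isTRUE(config$stages$scores) && !is.null(truth)) {
    # demo signatures: the first three marker programs act as label modules
    labs <- utils::head(names(truth$markers), 3)
    sets <- list(subtype = signature_set("subtype", truth$markers[labs]))
    lab_tab <- classify_cells(nm, sets, n_bins = config$n_bins,
                              n_controls = config$n_controls,
                              seed = stage_seed(config$seed, "scores"))
    cells$subtype <- lab_tab$subtype[match(cells$cell_id, lab_tab$cell_id)]
    note("scores", "run", n_labeled = sum(!is.na(cells$subtype)))
  } else note("scores", "skipped")
  write_df(cells, file.path(d, "cells.csv"))

  # ---- composition -------------------------------------------------------
  d <- file.path(out_dir, "03_composition")
  dir.create(d, showWarnings = FALSE)
  comp <- build_composition(cells)
  comp <- classify_tinf(comp, threshold = config$tinf_threshold)
  write_df(comp, file.path(d, "composition.csv"))
  cmp_site <- tryCatch(compare_groups(comp, "site"), error = function(e) NULL)
  if (!is.null(cmp_site)) write_df(cmp_site, file.path(d, "compare_site.csv"))
  if (!is.null(truth)) {
    ihc <- pseudo_ihc(truth, noise_sd = config$ihc_noise_sd,
                      seed = stage_seed(config$seed, "ihc"))
    with_ihc <- merge(comp, ihc, by = "sample_id", sort = TRUE)
    corr <- tryCatch(ihc_correlate(with_ihc), error = function(e) NULL)
    if (!is.null(corr)) write_df(corr, file.path(d, "ihc_correlation.csv"))
  }
  note("composition", "run", n_samples = nrow(comp))

  # ---- ligand-receptor ---------------------------------------------------
  if (isTRUE(config$stages$lr)) {
    d <- file.path(out_dir, "04_lr")
    dir.create(d, showWarnings = FALSE)
    lr_db <- if (!is.null(truth) && !is.null(truth$planted_lr)) {
      decoys <- data.frame(
        ligand = rownames(nm)[seq(nrow(nm) - 15, nrow(nm) - 8)],
        receptor = rownames(nm)[seq(nrow(nm) - 7, nrow(nm))],
        stringsAsFactors = FALSE)
      build_lr_db(list(truth$planted_lr[, c("ligand", "receptor")], decoys),
                  tags = c("planted", "decoy"))
    } else {
      read_table(system.file("extdata", "lr_pairs_demo.csv",
                             package = "scTME", mustWork = TRUE),
                 schema = "lr_pairs")
    }
    sub <- subcluster_labels(cl, taca)
    sm_by_sample <- list()
    for (s in sort(unique(cells$sample_id))) {
      sc_cells <- cells$cell_id[cells$sample_id == s]
      res <- lr_test(nm[, sc_cells, drop = FALSE], sub[sc_cells], lr_db,
                     n_perm = config$n_perm,
                     seed = stage_seed(config$seed, paste0("lr_", s)),
                     min_frac = config$min_frac)
      sm <- significant_means(res, alpha = config$alpha,
                              min_cells = config$min_cells)
      sm$sample_id <- s
      sm_by_sample[[s]] <- sm
    }
    all_sm <- do.call(rbind, sm_by_sample)
    write_df(all_sm, file.path(d, "lr_results.csv"))
    counts_by_sample <- count_interactions(all_sm, by = "sample")
    write_df(data.frame(sample_id = names(counts_by_sample),
                        n_interactions = as.integer(counts_by_sample)),
             file.path(d, "interaction_counts.csv"))
    note("lr", "run", n_tests = nrow(all_sm))
  } else note("lr", "skipped")

  # ---- contrast ----------------------------------------------------------
  if (isTRUE(config$stages$lr) && isTRUE(config$stages$contrast)) {
    d <- file.path(out_dir, "05_contrast")
    dir.create(d, showWarnings = FALSE)
    groups <- stats::setNames(
      cells$histotype[match(sort(unique(cells$sample_id)), cells$sample_id)],
      sort(unique(cells$sample_id)))
    gname <- if (!is.null(config$contrast_group)) config$contrast_group
             else sort(unique(groups))[1]
    agg <- aggregate_significant_means(sm_by_sample)
    ctr <- tryCatch(lr_contrast(agg, groups, gname, alpha = config$alpha),
                    error = function(e) e)
    if (inherits(ctr, "error")) {
      writeLines(paste("contrast not computed:", conditionMessage(ctr)),
                 file.path(d, "NOTE.txt"))
      note("contrast", "degenerate")
    } else {
      write_df(ctr, file.path(d, "contrast.csv"))
      note("contrast", "run", group = gname,
           d0 = unname(attr(ctr, "d0")))
    }
  } else note("contrast", "skipped")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(out_dir = out_dir, manifest = manifest))
}
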