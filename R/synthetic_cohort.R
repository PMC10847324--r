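#' Specify a synthetic multi-sample cohort
#'
#' The generator's world: a gene universe with log-normal baseline rates,
#' cell types defined by disjoint marker-gene programs (multiplicative
#' elevation `marker_fold`), per-sample composition, log-normal library
#' sizes, count noise, and optionally planted ligand-receptor activity
#' (ligand elevated in a sender type, receptor in a receiver type).
#'
#' @param n_genes number of genes in the universe.
#' @param cell_types data.frame with columns `name`, `n_marker_genes`,
#'   `marker_fold` (> 1).
#' @param samples list of lists with fields `sample_id`, `site`, `histotype`,
#'   `n_cells`, `composition` (named numeric summing to 1 over type names).
#' @param library_size `c(mean_log, sd_log)` of the log-normal library size.
#' @param noise `"poisson"` or `list(type = "negative_binomial",
#'   dispersion = d)` (variance mu + d mu^2).
#' @param planted_lr `NULL` or data.frame with columns `ligand`, `receptor`,
#'   `sender_type`, `receiver_type`, `fold`; genes must be gene ids outside
#'   every marker program.
#' @param template_sample_id sample whose cells carry their true labels into
#'   the template annotation.
#' @param seed integer RNG seed; per-sample sub-streams are derived from it.
#' @return a validated `CohortSpec` list.
#' @export
cohort_spec <- function(n_genes, cell_types, samples,
                        library_size = c(log(2500), 0.3),
                        noise = "poisson",
                        planted_lr = NULL,
                        template_sample_id = samples[[1]]$sample_id,
                        seed = 1L) {
  stopifnot(is.data.frame(cell_types),
            all(c("name", "n_marker_genes", "marker_fold") %in%
                  names(cell_types)))
  if (any(cell_types$marker_fold <= 1))
    stop("marker_fold must exceed 1")
  if (sum(cell_types$n_marker_genes) > n_genes)
    stop("marker programs exceed the gene universe")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  markers <- list(); at <- 0L
  for (k in seq_len(nrow(cell_types))) {
    nk <- cell_types$n_marker_genes[k]
    markers[[cell_types$name[k]]] <- gene_ids[at + seq_len(nk)]
    at <- at + nk
  }
  for (s in samples) {
    comp <- s$composition
    if (is.null(names(comp)) || !all(names(comp) %in% cell_types$name))
      stop("spec error: composition of ", s$sample_id,
           " names unknown cell types")
    if (abs(sum(comp) - 1) > 1e-9)
      stop("spec error: composition of sample ", s$sample_id,
           " does not sum to 1")
  }
  if (!is.null(planted_lr)) {
    lr_genes <- c(planted_lr$ligand, planted_lr$receptor)
    if (!all(lr_genes %in% gene_ids))
      stop("spec error: planted LR genes outside the gene universe")
    if (any(lr_genes %in% unlist(markers)))
      stop("spec error: planted LR genes must be non-marker genes")
    if (!all(c(planted_lr$sender_type, planted_lr$receiver_type) %in%
               cell_types$name))
      stop("spec error: planted LR cell types unknown")
  }
  if (!template_sample_id %in% vapply(samples, `[[`, "", "sample_id"))
    stop("template_sample_id not among samples")
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 cell_types = cell_types, markers = markers,
                 samples = samples, library_size = library_size,
                 noise = noise, planted_lr = planted_lr,
                 template_sample_id = template_sample_id,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# deterministic integer split of n cells by proportions (largest remainder)
split_counts <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

#' Generate a synthetic cohort
#'
#' Counts for cell c of type t are drawn as
#' `noise(L_c * rate_g * fold_{g,t} / sum_g(rate_g * fold_{g,t}))` where
#' `L_c` is the log-normal library size, `rate_g` the log-normal baseline
#' rate and `fold` the marker / planted-LR elevation. Identical spec + seed
#' gives bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return list with `counts` (genes x cells count matrix), `cells`
#'   ([cell_table()]), `template` ([template_annotation()]) and `truth`
#'   (per-cell true type, per-sample true composition in percent, planted LR
#'   table, marker map).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  base_rate <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
  base_rate <- base_rate / sum(base_rate)
  names(base_rate) <- spec$gene_ids

  types <- spec$cell_types$name
  fold <- matrix(1, spec$n_genes, length(types),
                 dimnames = list(spec$gene_ids, types))
  for (k in seq_along(types)) {
    t <- types[k]
    fold[spec$markers[[t]], t] <- spec$cell_types$marker_fold[k]
  }
  if (!is.null(spec$planted_lr)) {
    for (r in seq_len(nrow(spec$planted_lr))) {
      p <- spec$planted_lr[r, ]
      fold[p$ligand, p$sender_type] <-
        fold[p$ligand, p$sender_type] * p$fold
      fold[p$receptor, p$receiver_type] <-
        fold[p$receptor, p$receiver_type] * p$fold
    }
  }
  # per-type expected expression profile, normalized to sum 1
  prof <- sweep(fold * base_rate, 2, colSums(fold * base_rate), "/")

  nb <- is.list(spec$noise)
  disp <- if (nb) spec$noise$dispersion else NA_real_

  blocks <- list(); meta <- list(); truth_type <- character(0)
  comp_true <- list()
  for (si in seq_along(spec$samples)) {
    s <- spec$samples[[si]]
    set.seed(spec$seed + 1000L * si)
    n_by_type <- split_counts(s$n_cells, s$composition)
    cell_type <- rep(names(n_by_type), n_by_type)
    n <- length(cell_type)
    lib <- stats::rlnorm(n, spec$library_size[1], spec$library_size[2])
    lam <- prof[, cell_type, drop = FALSE] *
      rep(lib, each = spec$n_genes)
    cnt <- if (nb) {
      stats::rnbinom(length(lam), mu = as.numeric(lam), size = 1 / disp)
    } else {
      stats::rpois(length(lam), as.numeric(lam))
    }
    cnt <- matrix(cnt, spec$n_genes, n)
    cid <- sprintf("%s_cell%04d", s$sample_id, seq_len(n))
    dimnames(cnt) <- list(spec$gene_ids, cid)
    blocks[[si]] <- cnt
    meta[[si]] <- data.frame(cell_id = cid, sample_id = s$sample_id,
                             site = s$site, histotype = s$histotype,
                             enrichment = "none", stringsAsFactors = FALSE)
    truth_type <- c(truth_type, stats::setNames(cell_type, cid))
    comp_true[[s$sample_id]] <- 100 * n_by_type / n
  }
  counts <- count_matrix(do.call(cbind, blocks))
  cells <- validate_cell_table(do.call(rbind, meta))
  tpl_cells <- cells$cell_id[cells$sample_id == spec$template_sample_id]
  template <- template_annotation(tpl_cells, truth_type[tpl_cells])
  truth <- structure(list(cell_type = truth_type,
                          composition = comp_true,
                          planted_lr = spec$planted_lr,
                          markers = spec$markers,
                          spec = spec),
                     class = "CohortTruth")
  list(counts = counts, cells = cells, template = template, truth = truth)
}

#' Default lineage map from major cell types to IHC stains
#'
#' CK7 marks epithelia (epithelial + ESC), vimentin marks stroma
#' (fibroblast + MSC + endothelial), CD45 marks immune cells
#' (macrophage + T + B + plasma B).
#' @return named list of character vectors.
#' @export
ihc_lineage_types <- function() {
  list(ck7  = c("epithelial", "esc"),
       vim  = c("fibroblast", "msc", "endothelial"),
       cd45 = c("macrophage", "t", "b", "plasma_b"))
}

#' Simulate immunohistochemistry percentages from cohort truth
#'
#' IHC percent = clamp(true lineage percent + Gaussian(0, noise_sd), 0, 100).
#' Types absent from a cohort contribute 0 to their lineage.
#'
#' @param truth a `CohortTruth` from [generate_cohort()].
#' @param noise_sd Gaussian noise standard deviation in percentage points.
#' @param mapping stain -> type list, default [ihc_lineage_types()].
#' @param seed RNG seed.
#' @return data.frame with `sample_id` and one column per stain.
#' @export
pseudo_ihc <- function(truth, noise_sd = 5, mapping = ihc_lineage_types(),
                       seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  out <- data.frame(sample_id = names(truth$composition),
                    stringsAsFactors = FALSE)
  for (stain in names(mapping)) {
    v <- vapply(truth$composition, function(comp) {
      sum(comp[intersect(names(comp), mapping[[stain]])])
    }, numeric(1))
    out[[stain]] <- pmin(100, pmax(0, v + stats::rnorm(length(v), 0, noise_sd)))
  }
  out
}

#' The standard synthetic cohort used by the recovery properties
#'
#' Two samples of 1,000 cells each (one primary, one metastatic), eight major
#' cell types with 25 disjoint marker genes at 10-fold elevation, 1,500
#' genes, Poisson noise, library sizes log-normal around 2,500 UMIs. The
#' composition keeps every type above 50 cells per sample.
#'
#' @param seed RNG seed.
#' @return a `CohortSpec`.
#' @export
standard_cohort_spec <- function(seed = 20240124L) {
  comp <- c(epithelial = 0.30, esc = 0.08, endothelial = 0.06,
            fibroblast = 0.16, msc = 0.07, macrophage = 0.10,
            b = 0.05, t = 0.18)
  ct <- data.frame(name = names(comp), n_marker_genes = 25, marker_fold = 10,
                   stringsAsFactors = FALSE)
  cohort_spec(
    n_genes = 1500, cell_types = ct,
    samples = list(
      list(sample_id = "S1", site = "primary", histotype = "hgsoc",
           n_cells = 1000, composition = comp),
      list(sample_id = "S2", site = "metastatic", histotype = "hgsoc",
           n_cells = 1000, composition = comp)),
    template_sample_id = "S1", seed = seed)
}

#' A small demonstration cohort with planted ligand-receptor activity
#'
#' Six samples (two histotypes, primary and metastatic sites), six cell
#' types with sample-to-sample composition variation (so composition
#' statistics and IHC correlations are informative), and two planted LR
#' pairs: epithelial -> fibroblast and t -> epithelial, elevated 6-fold in
#' their sender/receiver types.
#'
#' @param seed RNG seed.
#' @param n_cells cells per sample.
#' @return a `CohortSpec`.
#' @export
demo_cohort_spec <- function(seed = 1L, n_cells = 250L) {
  ct <- data.frame(name = c("epithelial", "fibroblast", "msc",
                            "macrophage", "b", "t"),
                   n_marker_genes = 20, marker_fold = 8,
                   stringsAsFactors = FALSE)
  planted <- data.frame(
    ligand = c("gene00500", "gene00502"),
    receptor = c("gene00501", "gene00503"),
    sender_type = c("epithelial", "t"),
    receiver_type = c("fibroblast", "epithelial"),
    fold = 6, stringsAsFactors = FALSE)
  comps <- list(  # epithelial, fibroblast, msc, macrophage, b, t
    D1 = c(0.40, 0.20, 0.08, 0.10, 0.06, 0.16),
    D2 = c(0.30, 0.26, 0.12, 0.12, 0.06, 0.14),
    D3 = c(0.46, 0.14, 0.06, 0.08, 0.06, 0.20),
    D4 = c(0.26, 0.30, 0.14, 0.12, 0.06, 0.12),
    D5 = c(0.36, 0.18, 0.10, 0.14, 0.06, 0.16),
    D6 = c(0.32, 0.24, 0.10, 0.10, 0.06, 0.18))
  sites <- c("primary", "metastatic", "primary",
             "metastatic", "primary", "metastatic")
  hist <- c("hgsoc", "hgsoc", "hgsoc",
            "clear_cell", "clear_cell", "clear_cell")
  samples <- lapply(seq_along(comps), function(i)
    list(sample_id = names(comps)[i], site = sites[i], histotype = hist[i],
         n_cells = n_cells,
         composition = stats::setNames(comps[[i]], ct$name)))
  cohort_spec(
    n_genes = 800, cell_types = ct,
    samples = samples,
    planted_lr = planted, template_sample_id = "D1", seed = seed)
}
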