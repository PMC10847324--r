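#' Template-based cluster annotation
#'
#' Each cluster is annotated by the majority cell-type label among its
#' template cells: with `r_ti` the fraction of the cluster's template cells
#' carrying type `t`, the cluster label is `argmax_t r_ti` when that maximum
#' reaches `r_min`, and `"undecided"` otherwise. Ties for the maximum are
#' labeled `"undecided"` (conservative). Clusters holding no template cell
#' are `"undecided"` with a warning. Every cell inherits its cluster's label.
#'
#' @param clusters a `ClusterAssignment` (or named integer vector of cluster
#'   ids per cell).
#' @param template a [template_annotation()].
#' @param r_min confidence threshold on the winning ratio (default 0.7).
#' @return `TacaResult`: list with `cell_type` (named vector over all
#'   clustered cells), `cluster_label` (per cluster), `ratios` (cluster x
#'   type matrix of r_ti), `n_template` (template cells per cluster),
#'   `r_min`.
#' @export
taca_assign <- function(clusters, template, r_min = 0.7) {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
        else clusters
  tpl <- intersect(names(cl), names(template))
  if (!length(tpl)) stop("no template cell falls in any cluster")
  types <- sort(unique(as.character(template)))
  ids <- sort(unique(cl))
  ratios <- matrix(NA_real_, length(ids), length(types),
                   dimnames = list(as.character(ids), types))
  n_tpl <- stats::setNames(integer(length(ids)), as.character(ids))
  label <- stats::setNames(rep("undecided", length(ids)), as.character(ids))
  for (i in as.character(ids)) {
    members <- tpl[cl[tpl] == as.integer(i)]
    n_tpl[i] <- length(members)
    if (!length(members)) next
    cnt <- table(factor(as.character(template[members]), levels = types))
    r <- as.numeric(cnt) / length(members)
    ratios[i, ] <- r
    top <- max(r)
    if (top >= r_min && sum(r == top) == 1)
      label[i] <- types[which.max(r)]
  }
  if (any(n_tpl == 0))
    warning("cluster(s) without template cells marked undecided: ",
            paste(names(n_tpl)[n_tpl == 0], collapse = ", "))
  structure(list(cell_type = stats::setNames(label[as.character(cl)],
                                             names(cl)),
                 cluster_label = label, ratios = ratios,
                 n_template = n_tpl, r_min = r_min),
            class = "TacaResult")
}

#' @export
print.TacaResult <- function(x, ...) {
  cat("TacaResult (r_min =", x$r_min, "):\n")
  print(data.frame(cluster = names(x$cluster_label),
                   label = x$cluster_label,
                   n_template = as.integer(x$n_template),
                   row.names = NULL))
  invisible(x)
}

# restore the caller's RNG stream after seeded sampling
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Binned-control module score
#'
#' Genes are ranked by mean normalized expression and cut into `n_bins`
#' equal-frequency bins; for each signature gene, `n_controls` control genes
#' are sampled from its bin (excluding all signature genes; with replacement
#' when the bin is too small, with a warning). The score of a cell is the
#' mean expression of the signature genes minus the mean over the pooled
#' control draws.
#'
#' @param nm normalized matrix (genes x cells).
#' @param signature character vector of gene ids; genes absent from the
#'   matrix are dropped with a warning (error if all absent).
#' @param n_bins expression bins (default 24).
#' @param n_controls control genes sampled per signature gene (default 100).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(nm, signature, n_bins = 24L, n_controls = 100L,
                         seed = 0L) {
  present <- intersect(signature, rownames(nm))
  if (!length(present))
    stop("signature entirely absent from the matrix")
  if (length(present) < length(signature))
    warning(length(signature) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  mu <- Matrix::rowMeans(nm)
  ord <- order(mu, rownames(nm))
  bin <- integer(nrow(nm))
  bin[ord] <- ceiling(seq_len(nrow(nm)) * n_bins / nrow(nm))
  names(bin) <- rownames(nm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- setdiff(names(bin)[bin == bin[g]], signature)
      if (!length(pool)) return(character(0))
      if (length(pool) >= n_controls) {
        sample(pool, n_controls)
      } else {
        warning("bin of gene ", g, " holds fewer than ", n_controls,
                " eligible controls; sampling with replacement")
        sample(pool, n_controls, replace = TRUE)
      }
    }))
  })
  sig_mean <- Matrix::colMeans(nm[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::colMeans(nm[ctrl, , drop = FALSE]) else 0
  sig_mean - ctrl_mean
}

#' Assign labels by highest positive score
#'
#' Per cell, the label with the largest module score is assigned when that
#' score is strictly positive; otherwise the cell is not assigned
#' (`NA_character_`). Ties are broken by column order.
#'
#' @param scores cells x labels numeric matrix (or data.frame).
#' @return named character vector of labels (NA where no score is positive).
#' @export
assign_by_max_positive_score <- function(scores) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) >= 1)
  idx <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), idx)]
  out <- ifelse(top > 0, colnames(scores)[idx], NA_character_)
  stats::setNames(out, rownames(scores))
}

#' Score and classify cells against signature sets
#'
#' Runs [module_score()] per label of each signature set and
#' [assign_by_max_positive_score()] per set, producing one label column per
#' set (e.g. `cycle_phase`, `subtype`, `outcome`).
#'
#' @param nm normalized matrix (genes x cells).
#' @param signature_sets named list of `GeneSignatureSet`s; the list names
#'   become the label columns.
#' @param n_bins,n_controls,seed passed to [module_score()]; each label gets
#'   a distinct deterministic sub-seed.
#' @return data.frame with `cell_id` and one factor-free character column per
#'   set; attribute `scores` holds the per-set score matrices.
#' @export
classify_cells <- function(nm, signature_sets, n_bins = 24L,
                           n_controls = 100L, seed = 0L) {
  out <- data.frame(cell_id = colnames(nm), stringsAsFactors = FALSE)
  all_scores <- list()
  k <- 0L
  for (set_name in names(signature_sets)) {
    set <- signature_sets[[set_name]]
    labs <- names(set$signatures)
    sc <- vapply(seq_along(labs), function(j) {
      module_score(nm, set$signatures[[labs[j]]], n_bins = n_bins,
                   n_controls = n_controls, seed = seed + 101L * (k + j))
    }, numeric(ncol(nm)))
    colnames(sc) <- labs
    rownames(sc) <- colnames(nm)
    all_scores[[set_name]] <- sc
    out[[set_name]] <- unname(assign_by_max_positive_score(sc))
    k <- k + length(labs)
  }
  attr(out, "scores") <- all_scores
  out
}
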