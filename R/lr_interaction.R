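#' Merge ligand-receptor pair tables into one database
#'
#' Set union over `(ligand, receptor)` with provenance tags concatenated for
#' pairs contributed by several sources; duplicate rows within a source are
#' collapsed with a warning.
#'
#' @param sources a data.frame or list of data.frames with columns
#'   `ligand`, `receptor` and optionally `source`.
#' @param tags optional character vector of source tags (recycled over
#'   `sources`) used when a table lacks a `source` column.
#' @return `LRDatabase` data.frame: ligand, receptor, source.
#' @export
build_lr_db <- function(sources, tags = NULL) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (is.null(tags)) tags <- sprintf("source%d", seq_along(sources))
  tabs <- lapply(seq_along(sources), function(k) {
    df <- sources[[k]]
    miss <- setdiff(c("ligand", "receptor"), names(df))
    if (length(miss))
      stop("schema error: missing required column(s): ",
           paste(miss, collapse = ", "))
    if (any(is.na(df$ligand) | is.na(df$receptor) |
              df$ligand == "" | df$receptor == ""))
      stop("validation error: missing ligand or receptor gene")
    if (is.null(df$source)) df$source <- tags[(k - 1) %% length(tags) + 1]
    key <- paste(df$ligand, df$receptor, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate (ligand, receptor) rows within a source collapsed")
      df <- df[!duplicated(key), , drop = FALSE]
    }
    df[, c("ligand", "receptor", "source")]
  })
  all <- do.call(rbind, tabs)
  if (!nrow(all)) stop("empty ligand-receptor union")
  key <- paste(all$ligand, all$receptor, sep = "\r")
  src <- tapply(all$source, key, function(s) paste(unique(s), collapse = ";"))
  out <- all[!duplicated(key), c("ligand", "receptor"), drop = FALSE]
  out$source <- as.character(src[paste(out$ligand, out$receptor, sep = "\r")])
  rownames(out) <- NULL
  class(out) <- c("LRDatabase", "data.frame")
  out
}

#' Compose subcluster labels from clusters and assigned types
#'
#' Produces labels of the form `<type>.<cluster>` (e.g. `epithelial.3`) so
#' the LR analysis can report lineage-aware subcluster pairs.
#'
#' @param clusters `ClusterAssignment` or named cluster-id vector.
#' @param taca optional `TacaResult`; without it the bare cluster id is used.
#' @return named character vector, cell_id -> subcluster label.
#' @export
subcluster_labels <- function(clusters, taca = NULL) {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
        else clusters
  if (is.null(taca)) return(stats::setNames(as.character(cl), names(cl)))
  stats::setNames(paste(taca$cell_type[names(cl)], cl, sep = "."), names(cl))
}

#' Ligand-receptor enrichment statistic
#'
#' The enrichment statistic of pair (ligand, receptor) on an ordered
#' subcluster pair is the average of the ligand's mean normalized expression
#' over the sender subcluster and the receptor's over the receiver. The
#' statistic is undefined (NA) unless the ligand is detected (value > 0) in
#' at least `min_frac` of sender cells and the receptor in at least
#' `min_frac` of receiver cells, or when either gene is absent.
#'
#' @param nm normalized matrix (genes x cells).
#' @param ligand,receptor gene ids.
#' @param sender_cells,receiver_cells cell id vectors.
#' @param min_frac detection-fraction gate (default 0.1).
#' @return numeric scalar or NA.
#' @export
lr_mean_statistic <- function(nm, ligand, receptor, sender_cells,
                              receiver_cells, min_frac = 0.1) {
  if (!ligand %in% rownames(nm) || !receptor %in% rownames(nm))
    return(NA_real_)
  l <- nm[ligand, sender_cells]
  r <- nm[receptor, receiver_cells]
  if (mean(l > 0) < min_frac || mean(r > 0) < min_frac) return(NA_real_)
  (mean(l) + mean(r)) / 2
}

#' Permutation test of every LR pair over every subcluster pair
#'
#' For one sample: subcluster labels are permuted across all profiled cells
#' of the sample `n_perm` times and the enrichment statistic recomputed; the
#' p-value is `(1 + #{perm >= observed}) / (1 + n_perm)` (add-one, never
#' exactly zero). All ordered subcluster pairs (self-pairs included) are
#' tested against every database pair whose genes are present.
#'
#' @param nm normalized matrix restricted to the sample's cells.
#' @param clusters named subcluster-label vector over (at least) those cells.
#' @param lr_db `LRDatabase`.
#' @param n_perm permutations (default 1000; below 100 warns).
#' @param seed RNG seed (caller's RNG stream untouched).
#' @param min_frac detection-fraction gate (default 0.1).
#' @return `LRTestResult` data.frame: ligand, receptor, sender, receiver,
#'   n_sender, n_receiver, stat, p (stat/p NA where undefined).
#' @export
lr_test <- function(nm, clusters, lr_db, n_perm = 1000L, seed = 0L,
                    min_frac = 0.1) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  cells <- intersect(colnames(nm), names(clusters))
  if (!length(cells)) stop("no clustered cells found in the matrix")
  nm <- nm[, cells, drop = FALSE]
  lab <- factor(clusters[cells])
  K <- nlevels(lab); n <- length(cells)
  sizes <- as.integer(table(lab))
  ind <- stats::model.matrix(~ 0 + lab)
  ind <- sweep(ind, 2, sizes, "/")          # n x K column means operator

  present <- lr_db$ligand %in% rownames(nm) & lr_db$receptor %in% rownames(nm)
  genes <- unique(c(lr_db$ligand[present], lr_db$receptor[present]))
  grid <- expand.grid(a = seq_len(K), b = seq_len(K))  # sender, receiver
  out <- data.frame(
    ligand = rep(lr_db$ligand, each = nrow(grid)),
    receptor = rep(lr_db$receptor, each = nrow(grid)),
    sender = rep(levels(lab)[grid$a], nrow(lr_db)),
    receiver = rep(levels(lab)[grid$b], nrow(lr_db)),
    n_sender = rep(sizes[grid$a], nrow(lr_db)),
    n_receiver = rep(sizes[grid$b], nrow(lr_db)),
    stat = NA_real_, p = NA_real_, stringsAsFactors = FALSE)

  if (any(present) && length(genes)) {
    G <- as.matrix(nm[genes, , drop = FALSE])
    li <- match(lr_db$ligand[present], genes)
    ri <- match(lr_db$receptor[present], genes)
    mns <- G %*% ind                         # genes x K subcluster means
    det <- (G > 0) %*% ind                   # detection fractions
    ia <- grid$a; ib <- grid$b
    # L x (K*K) matrices of twice-the-statistic and the gate
    obs2 <- mns[li, ia, drop = FALSE] + mns[ri, ib, drop = FALSE]
    gate <- det[li, ia, drop = FALSE] >= min_frac &
            det[ri, ib, drop = FALSE] >= min_frac
    ge <- matrix(0L, nrow(obs2), ncol(obs2))
    with_seed(seed, {
      for (pp in seq_len(n_perm)) {
        pm <- G %*% ind[sample.int(n), , drop = FALSE]
        perm2 <- pm[li, ia, drop = FALSE] + pm[ri, ib, drop = FALSE]
        ge <- ge + (perm2 >= obs2)
      }
    })
    pv <- (1 + ge) / (1 + n_perm)
    stat <- obs2 / 2
    stat[!gate] <- NA_real_
    pv[!gate] <- NA_real_
    idx <- rep(present, each = nrow(grid))
    out$stat[idx] <- as.numeric(t(stat))
    out$p[idx] <- as.numeric(t(pv))
  }
  class(out) <- c("LRTestResult", "data.frame")
  out
}

#' Permutation p-value for a single LR pair on one subcluster pair
#'
#' Single-pair form of [lr_test()]; labels are permuted across all cells in
#' `clusters` (the sample's profiled cells).
#'
#' @inheritParams lr_test
#' @param ligand,receptor gene ids.
#' @param sender,receiver subcluster labels.
#' @return list with `stat`, `p`, `n_perm`.
#' @export
permutation_test <- function(nm, ligand, receptor, sender, receiver,
                             clusters, n_perm = 1000L, seed = 0L,
                             min_frac = 0.1) {
  db <- build_lr_db(data.frame(ligand = ligand, receptor = receptor,
                               stringsAsFactors = FALSE))
  res <- lr_test(nm, clusters, db, n_perm = n_perm, seed = seed,
                 min_frac = min_frac)
  row <- res[res$sender == sender & res$receiver == receiver, ]
  if (!nrow(row)) stop("subcluster pair not found in the sample")
  list(stat = row$stat, p = row$p, n_perm = n_perm)
}

#' Zero non-significant or under-sized entries of the LR result
#'
#' The significant mean m of an (LR pair, subcluster pair) entry is the
#' observed statistic when its p-value is below `alpha` and both subclusters
#' hold at least `min_cells` cells; otherwise 0. Undefined statistics count
#' as 0. Optionally the rule is applied to within-sample BH-adjusted
#' p-values.
#'
#' @param results `LRTestResult` for one sample.
#' @param alpha significance level (default 0.05); `p >= alpha` is zeroed.
#' @param min_cells minimum subcluster size (default 50).
#' @param adjust `"none"` (default, the explicit zeroing rule) or `"bh"`.
#' @return the results with columns `p_used` and `m` appended.
#' @export
significant_means <- function(results, alpha = 0.05, min_cells = 50L,
                              adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  p_used <- results$p
  if (adjust == "bh") {
    ok <- !is.na(p_used)
    p_used[ok] <- stats::p.adjust(p_used[ok], method = "BH")
  }
  results$p_used <- p_used
  results$m <- ifelse(!is.na(results$stat) & !is.na(p_used) &
                        p_used < alpha &
                        results$n_sender >= min_cells &
                        results$n_receiver >= min_cells,
                      results$stat, 0)
  class(results) <- c("SignificantMeans", class(results))
  results
}

#' Reshape significant means into the LR x subcluster-pair matrix
#'
#' @param sm output of [significant_means()].
#' @return numeric matrix, rows `ligand_receptor`, columns
#'   `sender|receiver`.
#' @export
sigmeans_matrix <- function(sm) {
  rn <- paste(sm$ligand, sm$receptor, sep = "_")
  cn <- paste(sm$sender, sm$receiver, sep = "|")
  m <- matrix(0, length(unique(rn)), length(unique(cn)),
              dimnames = list(unique(rn), unique(cn)))
  m[cbind(rn, cn)] <- sm$m
  m
}

#' Count nonzero LR interactions
#'
#' @param sm output of [significant_means()] (one or several samples bound
#'   together with a `sample_id` column).
#' @param by `"subcluster_pair"`, `"subcluster"` (a subcluster counts when it
#'   appears on either side) or `"sample"`.
#' @return named integer vector of counts.
#' @export
count_interactions <- function(sm, by = c("subcluster_pair", "subcluster",
                                          "sample")) {
  by <- match.arg(by)
  nz <- sm$m > 0
  if (by == "subcluster_pair") {
    key <- paste(sm$sender, sm$receiver, sep = "|")
    vapply(split(nz, key), sum, integer(1))
  } else if (by == "subcluster") {
    subs <- unique(c(sm$sender, sm$receiver))
    stats::setNames(vapply(subs, function(s)
      sum(nz & (sm$sender == s | sm$receiver == s)), integer(1)), subs)
  } else {
    key <- if (!is.null(sm$sample_id)) sm$sample_id else "all"
    vapply(split(nz, key), sum, integer(1))
  }
}

#' Aggregate per-sample significant means to a sample x LR-pair table
#'
#' Each sample's significant-means entries are averaged over its tested
#' subcluster pairs, giving one value per LR pair per sample — the input of
#' the group contrast.
#'
#' @param sm_by_sample named list (sample id -> [significant_means()]
#'   output).
#' @return numeric matrix samples x LR pairs.
#' @export
aggregate_significant_means <- function(sm_by_sample) {
  pairs <- unique(unlist(lapply(sm_by_sample, function(d)
    paste(d$ligand, d$receptor, sep = "_"))))
  m <- matrix(0, length(sm_by_sample), length(pairs),
              dimnames = list(names(sm_by_sample), pairs))
  for (s in names(sm_by_sample)) {
    d <- sm_by_sample[[s]]
    key <- paste(d$ligand, d$receptor, sep = "_")
    agg <- tapply(d$m, key, mean)
    m[s, names(agg)] <- as.numeric(agg)
  }
  m
}

# Newton inversion of the trigamma function (tolerance 1e-8)
trigamma_inverse <- function(x, max_iter = 50L, tol = 1e-8) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < tol) return(y)
  }
  NA_real_  # non-convergent; caller applies the documented fallback
}

#' Empirical-Bayes variance shrinkage
#'
#' Fits a scaled inverse-chi-square prior to the ensemble of residual
#' variances by matching moments of `log(s^2)`: with
#' `e = log(s^2) - digamma(d/2) + log(d/2)`, the excess variance of `e` over
#' `trigamma(d/2)` equals `trigamma(d0/2)` (inverted by Newton's method,
#' tolerance 1e-8, fallback d0 = 4 if non-convergent), and the prior
#' variance follows from the mean of `e`. The posterior variance is the
#' degrees-of-freedom-weighted average `(d0 s0^2 + d s^2) / (d0 + d)`.
#'
#' @param s2 numeric vector of residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0`, `s02`, `s2_post`.
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("degenerate ensemble: all residual variances zero")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (length(e) < 2 || !is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    half_d0 <- trigamma_inverse(evar)
    if (is.na(half_d0)) {
      warning("prior df estimation did not converge; falling back to d0 = 4")
      d0 <- 4
    } else d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated-t contrast of LR signatures between sample groups
#'
#' Per LR pair, a two-group mean-difference linear model (the named group
#' against the rest) is fitted on the per-sample aggregated significant
#' means; residual variances are shrunk with [squeeze_var()] and the
#' moderated t-statistic `coef / (sqrt(1/n1 + 1/n0) * s_post)` is referred to
#' a t distribution on `d0 + d` degrees of freedom. P-values are BH-adjusted
#' across LR pairs; significant positive-coefficient pairs form the group's
#' signature. LR pairs that are zero in every sample are dropped before
#' fitting.
#'
#' @param mat samples x LR-pair matrix from [aggregate_significant_means()].
#' @param groups named character vector, sample id -> group.
#' @param group the group contrasted against all remaining samples.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param d0 `NULL` (estimate, the default) or a forced prior df: `0`
#'   recovers the ordinary t-test, `Inf` the fully-shrunk statistic.
#' @return `ContrastResult` data.frame: lr_pair, coef, s2, s2_post, t,
#'   df_total, p, adj_p, signature; attributes `d0` and `s02`.
#' @export
lr_contrast <- function(mat, groups, group, alpha = 0.05, d0 = NULL) {
  groups <- groups[rownames(mat)]
  if (any(is.na(groups))) stop("every sample row needs a group")
  sel <- groups == group
  n1 <- sum(sel); n0 <- sum(!sel)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 samples on each side of the contrast")
  keep <- colSums(mat != 0) > 0
  if (!any(keep)) stop("no LR pair with nonzero significant means")
  mat <- mat[, keep, drop = FALSE]
  m1 <- colMeans(mat[sel, , drop = FALSE])
  m0 <- colMeans(mat[!sel, , drop = FALSE])
  coef <- m1 - m0
  rss <- colSums(sweep(mat[sel, , drop = FALSE], 2, m1)^2) +
         colSums(sweep(mat[!sel, , drop = FALSE], 2, m0)^2)
  dfr <- n1 + n0 - 2
  s2 <- rss / dfr
  su <- sqrt(1 / n1 + 1 / n0)
  if (is.null(d0)) {
    sq <- squeeze_var(s2, dfr)
  } else if (d0 == 0) {
    sq <- list(d0 = 0, s02 = NA_real_, s2_post = s2)
  } else if (is.infinite(d0)) {
    est <- squeeze_var(s2, dfr)
    sq <- list(d0 = Inf, s02 = est$s02, s2_post = rep(est$s02, length(s2)))
  } else {
    est <- squeeze_var(s2, dfr)
    sq <- list(d0 = d0, s02 = est$s02,
               s2_post = (d0 * est$s02 + dfr * s2) / (d0 + dfr))
  }
  if (all(sq$s2_post == 0))
    stop("degenerate ensemble: all posterior variances zero")
  tval <- coef / (su * sqrt(sq$s2_post))
  df_total <- sq$d0 + dfr
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(lr_pair = colnames(mat), coef = coef, s2 = s2,
                    s2_post = sq$s2_post, t = tval, df_total = df_total,
                    p = p, adj_p = adj,
                    signature = adj < alpha & coef > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- sq$d0
  attr(out, "s02") <- sq$s02
  class(out) <- c("ContrastResult", "data.frame")
  out
}
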