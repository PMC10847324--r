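#' Per-sample cellular composition
#'
#' Percentage of each assigned cell type per sample, with all profiled cells
#' (including `"undecided"`) in the denominator; undecided cells are reported
#' in their own column. Percentages are kept at full precision; round only at
#' output.
#'
#' @param cells a `CellTable` with `sample_id` and `cell_type` columns (and
#'   optionally `site`, `tinf`, carried through when constant per sample).
#' @return a `CompositionTable`: one row per sample with `n_cells` and one
#'   percentage column per type.
#' @export
build_composition <- function(cells) {
  stopifnot(all(c("sample_id", "cell_type") %in% names(cells)))
  types <- sort(unique(cells$cell_type))
  types <- c(setdiff(types, "undecided"),
             intersect("undecided", types))
  tab <- table(cells$sample_id, factor(cells$cell_type, levels = types))
  n <- rowSums(tab)
  pct <- 100 * sweep(unclass(tab), 1, n, "/")
  out <- data.frame(sample_id = rownames(tab), n_cells = as.integer(n),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame.matrix(pct, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  for (extra in c("site", "histotype", "tinf")) {
    if (extra %in% names(cells)) {
      u <- tapply(cells[[extra]], cells$sample_id, function(v)
        if (length(unique(v)) == 1) v[1] else NA_character_)
      out[[extra]] <- as.character(u[out$sample_id])
    }
  }
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Classify T-cell infiltration
#'
#' A sample is `"High"` when its T-cell percentage strictly exceeds the
#' threshold and `"Low"` otherwise (the exact boundary is Low).
#'
#' @param comp `CompositionTable` with a T-cell percentage column.
#' @param threshold percentage threshold (default 10).
#' @param t_col name of the T-cell column (default `"t"`).
#' @return the table with a `tinf` column (`"High"`/`"Low"`).
#' @export
classify_tinf <- function(comp, threshold = 10, t_col = "t") {
  if (!t_col %in% names(comp))
    stop("T-cell percentage column '", t_col, "' not found")
  comp$tinf <- ifelse(comp[[t_col]] > threshold, "High", "Low")
  comp
}

#' Compare composition between sample groups
#'
#' Welch two-sided t-test per cell-type column on per-sample percentages,
#' between the two levels of a grouping column (tumor site or T-cell
#' infiltration). Degenerate columns (a group with n < 2, or both groups
#' constant) are flagged untestable with `NA` statistics.
#'
#' @param comp `CompositionTable` carrying the grouping column.
#' @param grouping `"site"` or `"tinf"` (any two-level column works).
#' @param type_cols percentage columns to test; default every numeric column
#'   except `n_cells`.
#' @return data.frame: cell_type, group levels, group means, t, p, testable.
#' @export
compare_groups <- function(comp, grouping = c("site", "tinf"),
                           type_cols = NULL) {
  grouping <- if (length(grouping) == 1) grouping else match.arg(grouping)
  g <- comp[[grouping]]
  if (is.null(g)) stop("grouping column '", grouping, "' not found")
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping must have exactly two levels")
  if (is.null(type_cols)) {
    num <- vapply(comp, is.numeric, logical(1))
    type_cols <- setdiff(names(comp)[num], c("n_cells", "patient"))
  }
  rows <- lapply(type_cols, function(cn) {
    a <- comp[[cn]][g == lev[1]]; b <- comp[[cn]][g == lev[2]]
    base <- data.frame(cell_type = cn, group_a = lev[1], group_b = lev[2],
                       mean_a = mean(a), mean_b = mean(b),
                       stringsAsFactors = FALSE)
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (length(a) < 2 || length(b) < 2 || is.null(tt)) {
      cbind(base, t = NA_real_, p = NA_real_, testable = FALSE)
    } else {
      cbind(base, t = unname(tt$statistic), p = tt$p.value, testable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("GroupComparison", "data.frame")
  out
}

#' Default IHC correlation map
#'
#' Maps each IHC stain column to the aggregate of annotated types it marks:
#' CD45 -> immune, VIM -> stroma, CK7 -> epithelia (see
#' [ihc_lineage_types()]).
#' @return list of entries `list(lineage, types, marker)`.
#' @export
ihc_correlation_map <- function() {
  m <- ihc_lineage_types()
  list(list(lineage = "epithelia", types = m$ck7, marker = "ck7"),
       list(lineage = "stroma", types = m$vim, marker = "vim"),
       list(lineage = "immune", types = m$cd45, marker = "cd45"))
}

#' Correlate annotated composition with IHC positivity
#'
#' Pearson product-moment correlation (two-sided p) between per-sample
#' aggregated cell-type percentages and the matching IHC stain percentages,
#' after excluding listed samples (e.g. enrichment-biased ones). Samples with
#' a missing value on either side of a pair are dropped pairwise.
#'
#' @param comp `CompositionTable` holding both the type percentage columns
#'   and the IHC columns.
#' @param mapping list of `list(lineage, types, marker)` entries
#'   (default [ihc_correlation_map()]); `types` absent from the table
#'   contribute zero.
#' @param exclude sample ids to drop before correlating.
#' @return `IhcCorrelation` data.frame: lineage, marker, n, r, p.
#' @export
ihc_correlate <- function(comp, mapping = ihc_correlation_map(),
                          exclude = character(0)) {
  d <- comp[!comp$sample_id %in% exclude, , drop = FALSE]
  rows <- lapply(mapping, function(m) {
    have <- intersect(m$types, names(d))
    if (!length(have))
      stop("no composition column for lineage '", m$lineage, "'")
    if (!m$marker %in% names(d))
      stop("IHC column '", m$marker, "' not found")
    x <- rowSums(d[, have, drop = FALSE])
    y <- d[[m$marker]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      stop("fewer than 3 paired samples for lineage '", m$lineage, "'")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("undefined correlation: constant vector for lineage '",
           m$lineage, "'")
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(lineage = m$lineage, marker = m$marker, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("IhcCorrelation", "data.frame")
  out
}
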