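# Shared fixture builders; everything is generated in code at test time.

# small deterministic count matrix
tiny_counts <- function(n_genes = 20, n_cells = 10, seed = 42, max_count = 9) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells)
  m[m > max_count] <- max_count
  count_matrix(m,
               gene_ids = sprintf("g%03d", seq_len(n_genes)),
               cell_ids = sprintf("c%03d", seq_len(n_cells)))
}

# two-type cohort spec for marker / scoring tests
two_type_spec <- function(seed = 11, n_cells = 300, marker_fold = 10) {
  ct <- data.frame(name = c("alpha", "beta"), n_marker_genes = 20,
                   marker_fold = marker_fold, stringsAsFactors = FALSE)
  cohort_spec(
    n_genes = 400, cell_types = ct,
    samples = list(list(sample_id = "S1", site = "primary",
                        histotype = "h1", n_cells = n_cells,
                        composition = c(alpha = 0.5, beta = 0.5))),
    seed = seed)
}

# single-type exchangeable cohort (null for LR calibration)
null_cohort_spec <- function(seed = 5, n_cells = 640, n_genes = 300) {
  ct <- data.frame(name = "only", n_marker_genes = 0, marker_fold = 2,
                   stringsAsFactors = FALSE)
  cohort_spec(
    n_genes = n_genes, cell_types = ct,
    samples = list(list(sample_id = "N1", site = "primary",
                        histotype = "h1", n_cells = n_cells,
                        composition = c(only = 1))),
    seed = seed)
}

# exact permutation p-value oracle for the LR statistic on a tiny sample:
# enumerate every assignment of the sender-label positions
exact_perm_p <- function(lig_vals, rec_vals, n_sender) {
  n <- length(lig_vals)
  obs <- (mean(lig_vals[seq_len(n_sender)]) +
            mean(rec_vals[-seq_len(n_sender)])) / 2
  subsets <- utils::combn(n, n_sender)
  stats <- apply(subsets, 2, function(s)
    (mean(lig_vals[s]) + mean(rec_vals[-s])) / 2)
  mean(stats >= obs)
}
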