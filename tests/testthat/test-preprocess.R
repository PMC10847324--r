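test_that("gene-count filter keeps exactly the cells at or above threshold", {
  # cell 1: 399 detected genes, cell 2: 400, cell 3: 401
  m <- matrix(0L, 500, 3)
  m[1:399, 1] <- 1L; m[1:400, 2] <- 1L; m[1:401, 3] <- 1L
  cm <- count_matrix(m, sprintf("g%03d", 1:500), c("a", "b", "c"))
  kept <- filter_cells(cm, min_genes = 400)
  expect_identical(colnames(kept), c("b", "c"))
  expect_identical(nrow(kept), nrow(cm))

  cm2 <- tiny_counts(30, 15, seed = 2)
  expect_identical(colnames(filter_cells(cm2, 0)), colnames(cm2))
  # brute-force oracle over every cell
  for (thr in c(3, 10, 20)) {
    keep <- vapply(seq_len(ncol(cm2)),
                   function(j) sum(cm2[, j] > 0) >= thr, logical(1))
    expect_identical(colnames(filter_cells(cm2, thr)), colnames(cm2)[keep])
  }
  expect_warning(filter_cells(cm2, 10000), "all cells removed")
})

test_that("TP10K log-normalization matches its closed form and conserves", {
  m <- matrix(0L, 3, 1)
  m[1, 1] <- 1L; m[2, 1] <- 9999L
  cm <- count_matrix(m, c("g1", "g2", "g3"), "c1")
  nm <- lognormalize_tp10k(cm)
  expect_equal(nm[1, 1], log(2))      # count 1 of total 10,000
  expect_equal(nm[3, 1], 0)           # zero count stays exactly zero

  cm2 <- tiny_counts(40, 25, seed = 3)
  nm2 <- lognormalize_tp10k(cm2)
  sums <- Matrix::colSums(expm1(as.matrix(nm2)))
  expect_true(all(abs(sums - 1e4) < 1e-6 * 1e4))

  z <- count_matrix(cbind(c(1L, 0L), c(0L, 0L)), c("g1", "g2"),
                    c("ok", "empty"))
  expect_error(lognormalize_tp10k(z), "empty")
})

test_that("HVG selection ranks planted variable genes first", {
  # deterministic toy: background genes oscillate +-1 around 15 mean
  # levels; 10 planted genes switch on/off with large amplitudes at means
  # spread through the background range. Antiphase pairing keeps every
  # cell's total identical, so variances are exactly as constructed.
  n_genes <- 200; n_cells <- 80
  hot_idx <- seq(5, 185, by = 20)
  bg_idx <- setdiff(seq_len(n_genes), hot_idx)
  phase <- rep(c(0L, 1L), length.out = n_cells)
  base <- matrix(0L, n_genes, n_cells)
  for (j in seq_along(bg_idx)) {
    g <- bg_idx[j]; L <- 2L + (g %% 15L)
    pm <- if (j %% 2) 1L else -1L
    base[g, ] <- L + pm * ifelse(phase == 1L, 1L, -1L)
  }
  lo  <- c(0L, 2L, 1L, 4L, 3L, 7L, 5L, 10L, 8L, 14L)
  amp <- c(8L, 8L, 14L, 14L, 20L, 20L, 26L, 26L, 32L, 32L)
  for (k in seq_along(hot_idx)) {
    on <- if (k %% 2) phase else 1L - phase
    base[hot_idx[k], ] <- lo[k] + amp[k] * on
  }
  rownames(base) <- sprintf("g%03d", seq_len(n_genes))
  colnames(base) <- sprintf("c%02d", seq_len(n_cells))
  nm <- lognormalize_tp10k(count_matrix(base))
  hot <- sprintf("g%03d", hot_idx)
  expect_setequal(select_hvg(nm, 10), hot)
  expect_setequal(select_hvg(nm, n_genes), rownames(base))

  # a constant gene (equal library sizes) is never selected while
  # non-constant genes remain
  cm <- matrix(c(4L, 4L, 4L, 0L, 3L, 6L, 8L, 5L, 2L), 3, 3, byrow = TRUE,
               dimnames = list(c("const", "v1", "v2"), c("a", "b", "c")))
  nmc <- lognormalize_tp10k(count_matrix(cm))
  expect_false("const" %in% select_hvg(nmc, 2))
})

test_that("scaling centers, standardizes, clips and guards constants", {
  nm <- lognormalize_tp10k(tiny_counts(30, 20, seed = 4))
  sc <- scale_center(nm)
  mu <- rowMeans(as.matrix(nm)); sdv <- apply(as.matrix(nm), 1, sd)
  nonconst <- sdv > 0
  expect_lt(max(abs(rowMeans(sc[nonconst, ]))), 1e-9)
  direct <- (as.matrix(nm) - mu) / ifelse(sdv == 0, Inf, sdv)
  direct[direct > 10] <- 10; direct[direct < -10] <- -10
  expect_equal(sc, direct, ignore_attr = TRUE)
  # constant gene -> all zeros, variable gene standardized
  sc2 <- scale_center(rbind(a = c(0, 2, 4), b = c(3, 3, 3)))
  expect_identical(sc2["b", ], c(0, 0, 0))
  expect_equal(unname(sc2["a", ]), c(-1, 0, 1))
})

test_that("PCA matches an eigendecomposition oracle and fixes signs", {
  set.seed(6)
  x <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%02d", 1:50)))
  xc <- x - rowMeans(x)
  emb <- pca_embed(xc, n_pcs = 10)
  ev_oracle <- sort(eigen(stats::cov(t(xc)), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(attr(emb, "sdev")[1:10]^2, ev_oracle[1:10], tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  rot <- attr(emb, "rotation")
  for (j in 1:10) expect_gt(rot[which.max(abs(rot[, j])), j], 0)

  # data on a line: PC1 explains > 99.9% of variance
  t_ <- rnorm(50)
  line <- outer(rnorm(20), t_) + matrix(rnorm(20 * 50, sd = 1e-4), 20)
  dimnames(line) <- dimnames(x)
  emb2 <- pca_embed(line - rowMeans(line), n_pcs = 5)
  sd2 <- attr(emb2, "sdev")
  expect_gt(sd2[1]^2 / sum(sd2^2), 0.999)

  # reconstruction error decreases monotonically in n_pcs
  errs <- vapply(1:8, function(k) {
    e <- pca_embed(xc, n_pcs = k)
    rec <- attr(e, "rotation")[, 1:k, drop = FALSE] %*% t(unclass(e)[, 1:k])
    sum((xc - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
})

test_that("SNN clustering recovers planted blobs and is deterministic", {
  set.seed(7)
  blob <- rbind(matrix(rnorm(100 * 2), 100, 2),
                matrix(rnorm(100 * 2, mean = 20), 100, 2))
  rownames(blob) <- sprintf("c%03d", 1:200)
  cl <- snn_cluster(blob, k_neighbors = 15, resolution = 0.2, seed = 1)
  expect_equal(length(cl$sizes), 2)
  expect_equal(length(unique(cl$cluster[1:100])), 1)
  expect_equal(length(unique(cl$cluster[101:200])), 1)

  cl2 <- snn_cluster(blob, k_neighbors = 15, resolution = 0.2, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  one <- matrix(rnorm(80 * 2), 80, 2,
                dimnames = list(sprintf("c%02d", 1:80), NULL))
  low <- snn_cluster(one, k_neighbors = 15, resolution = 0.01, seed = 1)
  expect_equal(length(low$sizes), 1)
  expect_error(snn_cluster(blob[1:2, ], 1), "at least 3")
})

test_that("rank-sum DE matches the exact distribution and is symmetric", {
  nm <- lognormalize_tp10k(tiny_counts(25, 10, seed = 8))
  a <- colnames(nm)[1:5]; b <- colnames(nm)[6:10]
  de <- wilcoxon_de(nm, a, b)
  expect_true(all(de$p_adj >= de$p - 1e-12))
  expect_true(all(de$p_adj <= 1))
  # oracle: exact rank-sum distribution per gene (ties -> normal approx both)
  x <- as.matrix(nm)
  for (g in rownames(nm)) {
    ex <- suppressWarnings(
      stats::wilcox.test(x[g, a], x[g, b], exact = TRUE, correct = TRUE))
    expect_lt(abs(de$p[de$gene == g] - ex$p.value), 0.02)
  }
  # swapping groups negates logFC and preserves p
  de2 <- wilcoxon_de(nm, b, a)
  expect_equal(de2$logFC, -de$logFC)
  expect_equal(de2$p, de$p)

  # identical groups -> p ~ 1 everywhere
  dup <- count_matrix(cbind(as.matrix(tiny_counts(10, 4, seed = 9)),
                            as.matrix(tiny_counts(10, 4, seed = 9))),
                      sprintf("g%02d", 1:10), sprintf("c%02d", 1:8))
  nm3 <- lognormalize_tp10k(dup)
  de3 <- wilcoxon_de(nm3, colnames(nm3)[1:4], colnames(nm3)[5:8])
  expect_true(all(de3$p > 0.9))

  # gene expressed only in group a: positive logFC, small p at 20 vs 20
  m <- matrix(1L, 2, 40); m[1, 21:40] <- 0L; m[2, ] <- rep(3:4, 20)
  nm4 <- lognormalize_tp10k(count_matrix(m, c("hit", "flat"),
                                         sprintf("c%02d", 1:40)))
  de4 <- wilcoxon_de(nm4, colnames(nm4)[1:20], colnames(nm4)[21:40])
  expect_gt(de4$logFC[de4$gene == "hit"], 0)
  expect_lt(de4$p[de4$gene == "hit"], 1e-6)
  expect_error(wilcoxon_de(nm4, colnames(nm4)[1:5], colnames(nm4)[5:9]),
               "overlap")
})
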