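test_that("LR database merge is a provenance-tagged set union", {
  a <- data.frame(ligand = sprintf("L%d", 1:10),
                  receptor = sprintf("R%d", 1:10))
  b <- data.frame(ligand = sprintf("L%d", 6:13),
                  receptor = sprintf("R%d", 6:13))
  db <- build_lr_db(list(a, b), tags = c("src_a", "src_b"))
  expect_equal(nrow(db), 13)
  expect_equal(db$source[db$ligand == "L7"], "src_a;src_b")
  expect_equal(db$source[db$ligand == "L1"], "src_a")

  one <- build_lr_db(a, tags = "solo")
  expect_equal(one$ligand, a$ligand)
  expect_true(all(one$source == "solo"))

  # randomized overlapping tables vs a set-union oracle
  set.seed(41)
  for (i in 1:5) {
    mk <- function() data.frame(
      ligand = sample(sprintf("L%d", 1:15), 12, replace = TRUE),
      receptor = sample(sprintf("R%d", 1:4), 12, replace = TRUE))
    t1 <- mk(); t2 <- mk()
    db_i <- suppressWarnings(build_lr_db(list(t1, t2)))
    oracle <- unique(rbind(t1, t2))
    expect_equal(nrow(db_i), nrow(oracle))
    expect_setequal(paste(db_i$ligand, db_i$receptor),
                    paste(oracle$ligand, oracle$receptor))
  }
  expect_error(build_lr_db(data.frame(ligand = "L", receptor = NA)),
               "missing ligand or receptor")
})

test_that("the enrichment statistic is the gated average of subcluster means", {
  set.seed(43)
  m <- matrix(rpois(40 * 60, 3), 40, 60,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("c%02d", 1:60)))
  nm <- lognormalize_tp10k(count_matrix(m))
  snd <- colnames(nm)[1:25]; rcv <- colnames(nm)[26:60]
  s <- lr_mean_statistic(nm, "g05", "g11", snd, rcv)
  expect_equal(s, (mean(nm["g05", snd]) + mean(nm["g11", rcv])) / 2,
               tolerance = 1e-12)
  # ligand detected in under 10% of sender cells -> undefined
  m2 <- m; m2["g05", ] <- 0L; m2["g05", 1] <- 5L
  nm2 <- lognormalize_tp10k(count_matrix(m2))
  expect_true(is.na(lr_mean_statistic(nm2, "g05", "g11", snd, rcv)))
  expect_true(is.na(lr_mean_statistic(nm, "absent", "g11", snd, rcv)))
})

test_that("permutation p-values match exhaustive enumeration on 6 cells", {
  set.seed(47)
  vals <- matrix(c(5, 4, 6, 1, 0, 2,    # ligand row
                   1, 2, 0, 6, 5, 7), 2, 6, byrow = TRUE,
                 dimnames = list(c("LIG", "REC"), sprintf("c%d", 1:6)))
  nm <- lognormalize_tp10k(count_matrix(vals))
  clusters <- setNames(rep(c("snd", "rcv"), each = 3), colnames(nm))
  res <- permutation_test(nm, "LIG", "REC", "snd", "rcv", clusters,
                          n_perm = 10000, seed = 3)
  x <- as.matrix(nm)
  p_exact <- exact_perm_p(x["LIG", ], x["REC", ], 3)
  expect_lt(abs(res$p - p_exact), 0.02)

  # all-identical expression: every permuted statistic equals the observed
  flat <- lognormalize_tp10k(count_matrix(
    matrix(3L, 2, 6, dimnames = dimnames(vals))))
  res2 <- permutation_test(flat, "LIG", "REC", "snd", "rcv", clusters,
                           n_perm = 500, seed = 4)
  expect_equal(res2$p, 1.0)

  # statistic far below the permutation distribution -> p = 1
  lo <- vals; lo["LIG", ] <- c(0, 0, 1, 9, 9, 9); lo["REC", ] <- c(9, 9, 9, 0, 0, 1)
  nml <- lognormalize_tp10k(count_matrix(lo))
  res3 <- permutation_test(nml, "LIG", "REC", "snd", "rcv", clusters,
                           n_perm = 400, seed = 5)
  expect_gt(res3$p, 0.9)
  expect_warning(permutation_test(nm, "LIG", "REC", "snd", "rcv", clusters,
                                  n_perm = 50, seed = 1), "coarse")
})

test_that("lr_test agrees with per-pair brute force on observed statistics", {
  set.seed(53)
  m <- matrix(rpois(30 * 120, 2), 30, 120,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("c%03d", 1:120)))
  nm <- lognormalize_tp10k(count_matrix(m))
  clusters <- setNames(sample(c("A", "B", "C"), 120, replace = TRUE),
                       colnames(nm))
  db <- build_lr_db(data.frame(ligand = c("g01", "g05", "g09"),
                               receptor = c("g02", "g06", "g10")))
  res <- lr_test(nm, clusters, db, n_perm = 100, seed = 1)
  expect_equal(nrow(res), 3 * 9)
  for (k in sample(nrow(res), 10)) {
    row <- res[k, ]
    oracle <- lr_mean_statistic(
      nm, row$ligand, row$receptor,
      names(clusters)[clusters == row$sender],
      names(clusters)[clusters == row$receiver])
    expect_equal(row$stat, oracle, tolerance = 1e-12)
  }
})

test_that("significant-means zeroing implements exactly the two rules", {
  res <- data.frame(ligand = "L", receptor = "R",
                    sender = "a", receiver = "b",
                    n_sender = c(60, 49, 60, 60, 60),
                    n_receiver = c(80, 80, 49, 80, 80),
                    stat = c(1.3, 2.0, 2.0, 1.1, NA),
                    p = c(0.01, 0.001, 0.001, 0.2, NA))
  sm <- significant_means(res, alpha = 0.05, min_cells = 50)
  expect_equal(sm$m, c(1.3, 0, 0, 0, 0))

  # randomized rule-table oracle
  set.seed(59)
  rnd <- data.frame(ligand = "L", receptor = "R", sender = "a",
                    receiver = "b",
                    n_sender = sample(30:70, 300, replace = TRUE),
                    n_receiver = sample(30:70, 300, replace = TRUE),
                    stat = abs(rnorm(300)),
                    p = runif(300, 0, 0.12))
  sm2 <- significant_means(rnd, alpha = 0.05, min_cells = 50)
  oracle <- ifelse(rnd$p < 0.05 & rnd$n_sender >= 50 & rnd$n_receiver >= 50,
                   rnd$stat, 0)
  expect_identical(sm2$m, oracle)
  # BH flag only tightens (within-sample adjustment)
  sm3 <- significant_means(rnd, alpha = 0.05, min_cells = 50, adjust = "bh")
  expect_true(all(sm3$m[sm2$m == 0] == 0))
})

test_that("interaction counting tallies nonzero entries by margin", {
  sm <- data.frame(ligand = c("L1", "L1", "L2", "L2"),
                   receptor = c("R1", "R1", "R2", "R2"),
                   sender = c("a", "a", "b", "c"),
                   receiver = c("b", "c", "a", "a"),
                   m = c(1.5, 0, 2.2, 0.7),
                   sample_id = c("s1", "s1", "s1", "s2"))
  expect_equal(count_interactions(sm, "sample"), c(s1 = 2L, s2 = 1L))
  expect_equal(unname(count_interactions(sm, "subcluster_pair")[["a|b"]]), 1L)
  bysub <- count_interactions(sm, "subcluster")
  expect_equal(unname(bysub[["a"]]), 3L)  # sender of a|b, receiver twice
  allz <- sm; allz$m <- 0
  expect_true(all(count_interactions(allz, "sample") == 0))
})

test_that("variance shrinkage matches limma and the closed formula", {
  skip_if_not_installed("limma")
  set.seed(61)
  s2 <- rchisq(200, df = 5) / 5 * exp(rnorm(200, 0, 0.7))
  df <- 10
  mine <- squeeze_var(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-6)
  # closed-form posterior with the estimated prior
  expect_equal(mine$s2_post,
               (mine$d0 * mine$s02 + df * s2) / (mine$d0 + df),
               tolerance = 1e-10)
  expect_error(squeeze_var(rep(0, 5), 4), "degenerate")
})

test_that("moderated-t contrast matches limma and its exact limits", {
  skip_if_not_installed("limma")
  set.seed(67)
  n1 <- 6; n0 <- 6
  # homogeneous pooled SD with 2-SD planted effects: ranking fixture
  mat <- matrix(abs(rnorm(12 * 50, 1, 0.5)), 12, 50,
                dimnames = list(sprintf("s%02d", 1:12),
                                sprintf("L%02d_R%02d", 1:50, 1:50)))
  planted <- 1:5
  mat[1:n1, planted] <- mat[1:n1, planted] + 2 * 0.5
  groups <- setNames(rep(c("g1", "rest"), c(n1, n0)), rownames(mat))
  ctr <- lr_contrast(mat, groups, "g1")
  expect_setequal(order(-abs(ctr$t))[1:5], planted)

  # heterogeneous per-pair scales: a non-trivial (finite d0) prior to match
  sd_j <- 0.5 * exp(rnorm(50, 0, 0.6))
  het <- matrix(abs(rnorm(12 * 50, 1, rep(sd_j, each = 12))), 12, 50,
                dimnames = dimnames(mat))
  ctrH <- lr_contrast(het, groups, "g1")
  design <- cbind(1, as.numeric(groups == "g1"))
  fit <- limma::eBayes(limma::lmFit(t(het), design))
  expect_true(is.finite(attr(ctrH, "d0")))
  expect_equal(attr(ctrH, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(unname(ctrH$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(ctrH$p), unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(ctrH$s2_post, unname(fit$s2.post), tolerance = 1e-6)

  # d0 = 0 recovers the ordinary two-group t
  ctr0 <- lr_contrast(mat, groups, "g1", d0 = 0)
  tt <- apply(mat, 2, function(v) {
    a <- v[1:n1]; b <- v[n1 + 1:n0]
    sp <- sqrt(((n1 - 1) * var(a) + (n0 - 1) * var(b)) / (n1 + n0 - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / n1 + 1 / n0))
  })
  expect_equal(unname(ctr0$t), unname(tt), tolerance = 1e-8)

  # d0 = Inf uses the prior variance for every pair
  ctrI <- lr_contrast(mat, groups, "g1", d0 = Inf)
  s02 <- attr(ctrI, "s02")
  tI <- ctr0$coef / (sqrt(1 / n1 + 1 / n0) * sqrt(s02))
  expect_equal(unname(ctrI$t), unname(tI), tolerance = 1e-8)

  # invariant to sample order; flipping the contrast negates coef and t
  perm <- sample(rownames(mat))
  ctrP <- lr_contrast(mat[perm, ], groups, "g1")
  expect_equal(ctrP$t, ctr$t, tolerance = 1e-12)
  ctrF <- lr_contrast(mat, groups, "rest")
  expect_equal(ctrF$coef, -ctr$coef, tolerance = 1e-12)
  expect_equal(ctrF$t, -ctr$t, tolerance = 1e-12)
  expect_equal(ctrF$p, ctr$p, tolerance = 1e-12)
})
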