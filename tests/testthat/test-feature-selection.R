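test_that("importances are normalized, ordered, and recover planted oil responders", {
  co <- tiny_cohort(seed = 4)
  rk <- rank_features_rfr(co$samples, num_trees = 600, seed = 1)
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(rk$importance) <= 1e-12)) # non-increasing
  expect_setequal(rk$taxon_index, seq_len(40))
  expect_gte(attr(rk, "r_squared"), 0.85)

  hits <- vapply(1:3, function(s) {
    cohort <- tiny_cohort(seed = 100 + s)
    r <- rank_features_rfr(cohort$samples, num_trees = 600, seed = s)
    length(intersect(select_top_k(r, 5), cohort$truth$responsive_taxa))
  }, numeric(1))
  expect_true(all(hits >= 2))
})

test_that("a signal-free cohort yields flat importances, far below a planted cohort's top taxa", {
  # under the null, mean-decrease-in-impurity noise is right-skewed but no
  # taxon stands out: none explains more than 2% of total importance
  # (planted cohorts put ~10% on each true responder)
  null_max <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_config(n_responsive = 0, seed = 300 + s))
    max(rank_features_rfr(co$samples, num_trees = 800, seed = s)$importance)
  }, numeric(1))
  expect_true(all(null_max < 0.02))

  planted <- generate_cohort(cohort_config(seed = 401))
  rk <- rank_features_rfr(planted$samples, num_trees = 800, seed = 1)
  expect_gt(rk$importance[1], 5 * max(null_max))
})

test_that("rankings are invariant to sample duplication and affine target rescaling", {
  co <- tiny_cohort(seed = 8)
  tbl <- co$samples
  rk <- rank_features_rfr(tbl, num_trees = 800, seed = 3)

  dup <- dplyr::bind_rows(tbl, dplyr::mutate(tbl, sample_id = paste0(sample_id, "_b")))
  rk_dup <- rank_features_rfr(dup, num_trees = 800, seed = 3)
  rho <- cor(rk$importance[order(rk$taxon_index)],
    rk_dup$importance[order(rk_dup$taxon_index)],
    method = "spearman"
  )
  expect_gt(rho, 0.95)

  aff <- dplyr::mutate(tbl, oil_enc = 3 * oil_enc + 7)
  rk_aff <- rank_features_rfr(aff, num_trees = 800, seed = 3)
  expect_lt(abs(attr(rk_aff, "r_squared") - attr(rk, "r_squared")), 0.01)
  rho_aff <- cor(rk$importance[order(rk$taxon_index)],
    rk_aff$importance[order(rk_aff$taxon_index)],
    method = "spearman"
  )
  expect_gt(rho_aff, 0.95)
})

test_that("degenerate ranking inputs raise classed errors and select_top_k bounds k", {
  co <- tiny_cohort(seed = 1)
  const <- dplyr::mutate(co$samples, oil_enc = 1)
  expect_error(rank_features_rfr(const), class = "microstress_metric_error")
  expect_error(rank_features_rfr(co$samples[1, ]), class = "microstress_validation_error")

  rk <- rank_features_rfr(co$samples, num_trees = 200, seed = 1)
  expect_equal(select_top_k(rk, 1), rk$taxon_index[1])
  expect_equal(select_top_k(rk, 40), rk$taxon_index)
  expect_error(select_top_k(rk, 0), class = "microstress_domain_error")
  expect_error(select_top_k(rk, 41), class = "microstress_domain_error")
})

test_that("PCA projects onto the top two axes with exact variance bookkeeping", {
  # rank-2 data: PC1+PC2 capture all variance and inner products are preserved
  withr::with_seed(31, {
    B <- matrix(rnorm(2 * 20), 2, 20)
    S <- matrix(rnorm(30 * 2), 30, 2)
  })
  X <- S %*% B
  p <- pca_2d(X)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p$var_explained) <= 0))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  G_full <- Xc %*% t(Xc)
  G_proj <- as.matrix(p$coords) %*% t(as.matrix(p$coords))
  expect_equal(G_proj, G_full, tolerance = 1e-8, ignore_attr = TRUE)

  # axes agree with a direct SVD oracle up to sign
  sv <- svd(Xc)
  oracle_pc1 <- sv$u[, 1] * sv$d[1]
  expect_gt(abs(cor(p$coords$PC1, oracle_pc1)), 1 - 1e-9)

  expect_error(pca_2d(X[1:2, ]), class = "microstress_validation_error")
  expect_error(pca_2d(matrix(1, 5, 4)), class = "microstress_metric_error")
})

test_that("t-SNE is seed-deterministic, separates distinct blobs, and guards perplexity", {
  withr::with_seed(12, {
    blob1 <- matrix(rnorm(40 * 5), 40, 5)
    blob2 <- matrix(rnorm(40 * 5, mean = 12), 40, 5)
  })
  X <- rbind(blob1, blob2)
  labels <- rep(c("a", "b"), each = 40)
  e1 <- tsne_2d(X, perplexity = 10, seed = 5)
  e2 <- tsne_2d(X, perplexity = 10, seed = 5)
  expect_identical(e1, e2)
  expect_gt(mean_silhouette(as.matrix(e1), labels), 0.5)
  expect_error(tsne_2d(X[1:10, ], perplexity = 5), class = "microstress_parameter_error")
})
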