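# Taxa ranking by random-forest importance against the encoded oil type,
# with 2-D PCA and t-SNE baselines for comparison/visualization.

#' Rank taxa by random-forest importance for encoded oil type
#'
#' Fits a random-forest regressor (2,500 trees, maximum depth 25, variance
#' split rule) of taxa counts on the encoded oil type and extracts
#' mean-decrease-in-impurity importances, normalized to sum to one. Ties are
#' broken by ascending taxon index so rankings are deterministic.
#'
#' @param table A sample table (or any data frame with `Bac_*` columns and
#'   the target column).
#' @param target Name of the target column (default `oil_enc`).
#' @param num_trees,max_depth Forest size and depth cap.
#' @param seed Integer seed for the forest.
#' @param importance `"impurity"` (default, the mean-decrease-in-impurity
#'   ranking) or `"permutation"` as an optional cross-check.
#' @return A `feature_ranking` tibble with columns `rank`, `taxon_index`,
#'   `taxon`, `importance`, carrying the forest's training R-squared as
#'   attribute `r_squared`.
#' @export
rank_features_rfr <- function(table, target = "oil_enc", num_trees = 2500,
                              max_depth = 25, seed = 0,
                              importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  tc <- taxa_cols(table)
  if (length(tc) == 0) {
    rlang::abort("no Bac_* taxa columns found", class = "microstress_schema_error")
  }
  if (nrow(table) < 2) {
    rlang::abort("need at least two samples", class = "microstress_validation_error")
  }
  y <- table[[target]]
  if (is.null(y)) {
    rlang::abort(paste0("missing target column: ", target), class = "microstress_schema_error")
  }
  if (stats::var(y) <= 0) {
    rlang::abort("target has zero variance", class = "microstress_metric_error")
  }
  dat <- as.data.frame(table[, tc, drop = FALSE])
  dat$..target.. <- y
  rf <- ranger::ranger(
    dependent.variable.name = "..target..", data = dat,
    num.trees = num_trees, max.depth = max_depth,
    importance = importance, seed = as.integer(seed),
    num.threads = 1, verbose = FALSE
  )
  imp <- rf$variable.importance[tc]
  imp[!is.finite(imp) | imp < 0] <- 0
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  idx <- seq_along(tc)
  ord <- order(-imp, idx)
  pred <- stats::predict(rf, data = dat, num.threads = 1)$predictions
  out <- tibble::tibble(
    rank = seq_along(tc),
    taxon_index = idx[ord],
    taxon = tc[ord],
    importance = unname(imp[ord])
  )
  attr(out, "r_squared") <- r_squared(y, pred)
  attr(out, "num_trees") <- num_trees
  attr(out, "max_depth") <- max_depth
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Take the top-k taxa of a feature ranking
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of taxa, `1 <= k <= n_taxa`.
#' @return Integer vector of the k top taxon indices, in rank order.
#' @export
select_top_k <- function(ranking, k) {
  n <- nrow(ranking)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != floor(k)) {
    rlang::abort(sprintf("k must be an integer in 1..%d", n),
      class = "microstress_domain_error"
    )
  }
  ranking$taxon_index[seq_len(k)]
}

#' Project taxa counts onto the first two principal components
#'
#' Column-centered (not scaled) PCA of the count matrix.
#'
#' @param counts Numeric matrix (samples x taxa) or a sample table.
#' @return A list with `coords` (tibble `PC1`, `PC2`) and `var_explained`
#'   (fractions of total variance, non-increasing).
#' @export
pca_2d <- function(counts) {
  counts <- counts_matrix(counts)
  if (nrow(counts) < 3) {
    rlang::abort("need at least three samples", class = "microstress_validation_error")
  }
  p <- stats::prcomp(counts, center = TRUE, scale. = FALSE)
  if (sum(p$sdev^2) < 1e-12) {
    rlang::abort("count matrix has no variance", class = "microstress_metric_error")
  }
  k <- min(2, ncol(p$x))
  coords <- tibble::as_tibble(as.data.frame(p$x[, seq_len(k), drop = FALSE]))
  if (k == 1) coords$PC2 <- 0
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(coords = coords[, c("PC1", "PC2")], var_explained = c(ve, 0)[1:2])
}

counts_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    tc <- taxa_cols(counts)
    if (length(tc) > 0) counts <- counts[, tc, drop = FALSE]
  }
  as.matrix(counts)
}

#' Embed taxa counts in two dimensions with t-SNE
#'
#' Exact (dense) t-distributed stochastic neighbor embedding with per-point
#' perplexity calibration by bisection, early exaggeration and momentum
#' gradient descent. Deterministic for a fixed seed. Intended for
#' visualization and baseline comparison only.
#'
#' @param counts Numeric matrix (samples x taxa) or a sample table.
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param seed Integer seed for the embedding jitter.
#' @param n_iter Gradient-descent iterations.
#' @return Tibble with columns `tsne1`, `tsne2`.
#' @export
tsne_2d <- function(counts, perplexity = 30, seed = 0, n_iter = 600) {
  X <- counts_matrix(counts)
  n <- nrow(X)
  if (n <= 3 * perplexity) {
    rlang::abort("perplexity too large: need n_samples > 3 * perplexity",
      class = "microstress_parameter_error"
    )
  }
  # PCA pre-reduction, standard practice for count matrices
  if (ncol(X) > 50) {
    X <- stats::prcomp(X, center = TRUE, rank. = 50)$x
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  P <- tsne_affinities(X, perplexity)
  # PCA initialization (scaled small) with seeded jitter: stabler and more
  # reproducible than a pure random start
  pc <- stats::prcomp(X, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  Y0 <- scale(pc, center = TRUE, scale = apply(pc, 2, stats::sd) * 1e4)
  withr::with_seed(as.integer(seed), {
    Y <- Y0 + matrix(stats::rnorm(n * 2, sd = 1e-6), n, 2)
  })
  tsne_descend(P, Y, n_iter = n_iter)
}

# symmetric input affinities at the target perplexity (bisection on beta)
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        H <- 0
      } else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + beta) / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_descend <- function(P, Y, n_iter = 500, lr = 200) {
  n <- nrow(Y)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  P_run <- P * 12 # early exaggeration
  for (it in seq_len(n_iter)) {
    if (it == 101) P_run <- P
    momentum <- if (it < 250) 0.5 else 0.8
    ss <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(ss, ss, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P_run - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(
      ifelse(sign(G) != sign(inc), gains + 0.2, gains * 0.8),
      0.01
    )
    inc <- momentum * inc - lr * gains * G
    Y <- Y + inc
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  tibble::tibble(tsne1 = Y[, 1], tsne2 = Y[, 2])
}
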