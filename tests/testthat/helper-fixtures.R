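# Small study-shaped cohorts for fast tests; the acceptance tests use the
# full default configuration.

tiny_config <- function(seed = 1, ...) {
  cohort_config(
    n_bottles = 24, samples_per_bottle_mean = 2.5, n_taxa = 40,
    n_responsive = 6, seed = seed, ...
  )
}

tiny_cohort <- function(seed = 1, ...) generate_cohort(tiny_config(seed = seed, ...))

# hand-computed mean silhouette for two-group separation checks
mean_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  D <- as.matrix(stats::dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(g) mean(D[i, labels == g]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# flatten all dense weights of a network for equality comparisons
net_weights <- function(net) {
  unlist(lapply(net$layers, function(l) {
    if (l$type == "dense") c(as.vector(l$W), l$b) else c(l$gamma, l$beta)
  }))
}
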