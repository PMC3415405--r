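# Shared fixtures and independent brute-force oracles.

# Handcrafted tiny matrix: 3 groups x 5 samples, 4 probes.
tiny_sheet <- function(groups = c("A", "B", "C"), n_per = 5L) {
  data.frame(sample_id = sprintf("s%02d", seq_len(length(groups) * n_per)),
             group = rep(groups, each = n_per), stringsAsFactors = FALSE)
}

tiny_matrix <- function(values, detection = NULL, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  if (!is.null(detection)) dimnames(detection) <- list(probes, samples)
  ExpressionMatrix(values, detection)
}

small_sim <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 400L,
                   chromosomes = c(chr1 = 120L, chr2 = 100L, chr7 = 80L, chr21 = 100L),
                   group_sizes = c("2N" = 6L, "CHD-" = 8L, AVSD = 6L, ASD = 5L, VSD = 5L),
                   n_de_per_contrast = c(AVSD = 20L, "ASD+VSD" = 20L),
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Brute-force oracle: P(>= 1 run of k contiguous successes) by enumerating
# every d-subset of N ordered positions.
brute_cluster_p <- function(N, d, k) {
  subsets <- utils::combn(N, d)
  has_run <- apply(subsets, 2, function(s) {
    if (k == 1) return(length(s) >= 1)
    any(s[k:d] - s[seq_len(d - k + 1)] == k - 1)
  })
  mean(has_run)
}

# Brute-force oracle: hypergeometric upper tail by enumerating every n-draw
# from a background of N genes containing B set members.
brute_hyper_tail <- function(N, B, n, b) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(s) sum(s <= B) >= b))
}

# Mean silhouette of a 2-group labelling on a score vector.
silhouette_1d <- function(x, labels) {
  d <- abs(outer(x, x, "-"))
  mean(vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(x) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
}
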