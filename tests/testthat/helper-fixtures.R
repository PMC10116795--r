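# Shared fixtures and independent oracles, all generated in code.

rand_count_table <- function(n, q, seed, depth = 500) {
  set.seed(seed)
  m <- t(sapply(seq_len(n), function(i) {
    rmultinom(1, depth, prob = rexp(q))[, 1]
  }))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(q)))
  count_table(m)
}

# Small Dirichlet-multinomial community + matching random tree, built with
# the package's own generators under a fixed seed.
dm_fixture <- function(n = 30, q = 40, depth = 500, seed = 99) {
  params <- synthesize_dm_params(q = q, theta = 0.02, seed = seed)
  tree <- simulate_taxon_tree(names(params$pi), seed = seed + 1)
  counts <- simulate_otu_counts(params, n = n, depth = depth, seed = seed + 2)
  list(params = params, tree = tree, counts = counts)
}

# All permutations of 1..n (for exact moment enumeration at small n).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Scalar-loop KRV oracle: explicit trace sums, no matrix products.
krv_bruteforce <- function(K, L) {
  n <- nrow(K)
  H <- diag(n) - 1 / n
  Kc <- H %*% K %*% H
  Lc <- H %*% L %*% H
  tKL <- 0; tKK <- 0; tLL <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tKL <- tKL + Kc[i, j] * Lc[j, i]
    tKK <- tKK + Kc[i, j] * Kc[j, i]
    tLL <- tLL + Lc[i, j] * Lc[j, i]
  }
  tKL / sqrt(tKK * tLL)
}

rand_psd <- function(n, seed, rank = n) {
  set.seed(seed)
  Z <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(Z)
}

# The six community kernels for a fixture, via the exported pipeline.
fixture_kernels <- function(fx) {
  rar <- fx$counts
  list(
    bray_curtis = microbiome_kernel(rar, "bray_curtis"),
    unweighted_unifrac = microbiome_kernel(rar, "unweighted_unifrac", tree = fx$tree),
    weighted_unifrac = microbiome_kernel(rar, "weighted_unifrac", tree = fx$tree),
    generalized_unifrac = microbiome_kernel(rar, "generalized_unifrac", tree = fx$tree),
    clr_linear = microbiome_kernel(rar, "clr_linear"),
    philr_linear = microbiome_kernel(rar, "philr_linear", tree = fx$tree)
  )
}
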