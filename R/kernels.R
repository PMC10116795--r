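#' Construct a kernel-matrix object
#'
#' @param K symmetric `n x n` similarity matrix.
#' @param label kernel label.
#' @param sample_ids row/column identifiers.
#' @param centered,psd_corrected bookkeeping flags.
#' @return a `krv_kernel` object (classed matrix).
#' @export
krv_kernel <- function(K, label = "kernel", sample_ids = rownames(K),
                       centered = FALSE, psd_corrected = FALSE) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  if (anyNA(K) || any(!is.finite(K))) stop("kernel matrix has non-finite entries")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel matrix must be symmetric")
  K <- (K + t(K)) / 2
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(K)))
  dimnames(K) <- list(sample_ids, sample_ids)
  structure(K, class = c("krv_kernel", "matrix"), label = label,
            centered = centered, psd_corrected = psd_corrected)
}

#' @export
print.krv_kernel <- function(x, ...) {
  cat(sprintf("krv_kernel: %d samples, label = %s%s%s\n", nrow(x),
              attr(x, "label"),
              if (isTRUE(attr(x, "centered"))) ", centered" else "",
              if (isTRUE(attr(x, "psd_corrected"))) ", psd-corrected" else ""))
  invisible(x)
}

kernel_data <- function(Z) {
  if (inherits(Z, "genotype_matrix")) Z$dosages
  else if (inherits(Z, "count_table")) unclass(Z)
  else as.matrix(Z)
}

#' Linear kernel
#'
#' `K = Z W Z'` with optional non-negative per-feature weights `W`
#' (default uniform). For genotype input the features are minor-allele
#' dosages, so `K_ij = g_i' g_j`; the same construction applied to CLR- or
#' ILR-transformed abundances gives the corresponding compositional
#' kernels. Positive semi-definite by construction.
#'
#' @param Z samples-by-features matrix, [genotype_matrix()] or
#'   [count_table()].
#' @param weights optional per-feature weights.
#' @return a [krv_kernel()].
#' @export
linear_kernel <- function(Z, weights = NULL) {
  Z <- kernel_data(Z)
  if (anyNA(Z) || any(!is.finite(Z))) stop("non-finite entries in feature matrix")
  if (!is.null(weights)) {
    if (length(weights) != ncol(Z) || any(weights < 0))
      stop("weights must be non-negative, one per feature")
    Z <- Z * rep(sqrt(weights), each = nrow(Z))
  }
  krv_kernel(tcrossprod(Z), label = "linear", sample_ids = rownames(Z),
             psd_corrected = TRUE)
}

#' Identity-by-state (IBS) kernel
#'
#' `K_ij = (1 / 2m) sum_l w_l (2 - |g_il - g_jl|)` over hard-call dosages in
#' `{0, 1, 2}` (dosage input is rounded with a warning). `K_ii = 1` and all
#' entries lie in `[0, 1]`.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param weights optional per-variant weights (mean-normalized).
#' @return a [krv_kernel()].
#' @export
ibs_kernel <- function(G, weights = NULL) {
  g <- kernel_data(G)
  m <- ncol(g)
  if (m == 0) stop("IBS kernel requires at least one variant")
  if (max(abs(g - round(g))) > 1e-8) {
    warning("IBS kernel expects hard calls; rounding dosages to {0,1,2}")
  }
  g <- round(g)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0))
    stop("weights must be non-negative, one per variant")
  w <- weights / mean(weights)
  A <- lapply(0:2, function(k) (g == k) * rep(w, each = nrow(g)))
  I <- lapply(0:2, function(k) (g == k) * 1)
  # sum_l w_l |g_il - g_jl| decomposed over genotype-value pairs
  mism <- tcrossprod(A[[1]], I[[2]]) + tcrossprod(A[[2]], I[[1]]) +
          tcrossprod(A[[2]], I[[3]]) + tcrossprod(A[[3]], I[[2]]) +
          2 * (tcrossprod(A[[1]], I[[3]]) + tcrossprod(A[[3]], I[[1]]))
  K <- (2 * m - (mism + t(mism)) / 2) / (2 * m)
  krv_kernel(K, label = "ibs", sample_ids = rownames(g), psd_corrected = FALSE)
}

#' Gower transform: dissimilarity matrix to centered kernel
#'
#' `L = -1/2 H D^2 H` with `H = I - 11'/n` and `D^2` the element-wise
#' square. For Euclidean distances of some data matrix this equals the
#' doubly centered Gram matrix of that data; for general beta-diversity
#' measures the result may be indefinite and is usually followed by
#' [psd_correct()].
#'
#' @param D a [krv_dist()] or symmetric matrix.
#' @return a centered [krv_kernel()].
#' @export
distance_to_kernel <- function(D) {
  metric <- if (inherits(D, "krv_dist")) attr(D, "metric") else "distance"
  D <- unclass(as.matrix(D))
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("distance matrix must be symmetric")
  D2 <- D * D
  rm <- rowMeans(D2)
  L <- -0.5 * (D2 - outer(rm, rm, "+") + mean(D2))
  krv_kernel(L, label = paste0("gower(", metric, ")"), sample_ids = rownames(D),
             centered = TRUE)
}

#' Clip negative eigenvalues to restore positive semi-definiteness
#'
#' Eigendecomposes the kernel, sets eigenvalues below `tol` times the
#' largest eigenvalue (including all negative ones) to zero and
#' reconstructs. Idempotent.
#'
#' @param K a [krv_kernel()] or symmetric matrix.
#' @param tol relative eigenvalue tolerance.
#' @return a psd-corrected [krv_kernel()].
#' @export
psd_correct <- function(K, tol = 1e-8) {
  label <- if (inherits(K, "krv_kernel")) attr(K, "label") else "kernel"
  centered <- isTRUE(attr(K, "centered"))
  M <- unclass(as.matrix(K))
  eg <- eigen(M, symmetric = TRUE)
  lam <- eg$values
  lam[lam < tol * max(lam, 0)] <- 0
  Kp <- eg$vectors %*% (lam * t(eg$vectors))
  krv_kernel(Kp, label = label, sample_ids = rownames(M),
             centered = centered, psd_corrected = TRUE)
}

#' Double-center a kernel matrix
#'
#' `K~ = H K H` with `H = I - 11'/n`; row and column sums of the result are
#' zero. Idempotent.
#'
#' @param K a [krv_kernel()] or symmetric matrix.
#' @return a centered [krv_kernel()].
#' @export
center_kernel <- function(K) {
  label <- if (inherits(K, "krv_kernel")) attr(K, "label") else "kernel"
  psd <- isTRUE(attr(K, "psd_corrected"))
  M <- unclass(as.matrix(K))
  M <- center_mat(M)
  krv_kernel(M, label = label, sample_ids = rownames(M), centered = TRUE,
             psd_corrected = psd)
}

center_mat <- function(M) {
  rm <- rowMeans(M)
  cm <- colMeans(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), cm) + mean(M)
}

#' Build a community-level microbiome kernel
#'
#' Convenience wrapper for the standard pipelines: Bray-Curtis and UniFrac
#' kernels are built from rarefied counts via the Gower transform followed
#' by eigenvalue clipping; CLR-linear and PhILR-linear kernels are linear
#' kernels on the log-ratio-transformed (pseudo-counted) counts, which is
#' equivalent to transforming Euclidean distances of the same data.
#'
#' @param x raw [count_table()] (rarefied for Bray-Curtis/UniFrac, absolute
#'   counts for CLR/PhILR).
#' @param kernel kernel name.
#' @param tree rooted tree, required for the UniFrac and PhILR kernels.
#' @param alpha generalized UniFrac exponent.
#' @param pseudo pseudo-count for the log-ratio transforms.
#' @param philr_weights balance weighting for the PhILR transform.
#' @return a [krv_kernel()].
#' @export
microbiome_kernel <- function(x,
    kernel = c("bray_curtis", "unweighted_unifrac", "weighted_unifrac",
               "generalized_unifrac", "clr_linear", "philr_linear"),
    tree = NULL, alpha = 0.5, pseudo = 1,
    philr_weights = c("blw", "uniform")) {
  kernel <- match.arg(kernel)
  needs_tree <- kernel %in% c("unweighted_unifrac", "weighted_unifrac",
                              "generalized_unifrac", "philr_linear")
  if (needs_tree && is.null(tree)) stop(kernel, " requires a phylogenetic tree")
  K <- switch(kernel,
    bray_curtis = psd_correct(distance_to_kernel(bray_curtis(x))),
    unweighted_unifrac = psd_correct(distance_to_kernel(
      unifrac(x, tree, variant = "unweighted"))),
    weighted_unifrac = psd_correct(distance_to_kernel(
      unifrac(x, tree, variant = "weighted_normalized"))),
    generalized_unifrac = psd_correct(distance_to_kernel(
      unifrac(x, tree, variant = "generalized", alpha = alpha))),
    clr_linear = linear_kernel(clr_transform(x, pseudo = pseudo)),
    philr_linear = linear_kernel(
      philr_transform(x, tree, pseudo = pseudo,
                      weights = match.arg(philr_weights))))
  attr(K, "label") <- kernel
  K
}

#' Write/read a kernel matrix as square TSV
#'
#' The header comment records the kernel label and flags.
#' @param K a [krv_kernel()].
#' @param path file path.
#' @export
write_kernel <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kernel label=%s centered=%s psd_corrected=%s",
                     attr(K, "label"), isTRUE(attr(K, "centered")),
                     isTRUE(attr(K, "psd_corrected"))), con)
  df <- data.frame(sample_id = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  lab <- sub(".*label=(\\S+).*", "\\1", hdr)
  krv_kernel(m, label = lab, sample_ids = rownames(m),
             centered = grepl("centered=TRUE", hdr),
             psd_corrected = grepl("psd_corrected=TRUE", hdr))
}
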