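#' Construct a distance-matrix object
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param metric label of the dissimilarity measure.
#' @param sample_ids row/column identifiers.
#' @return a `krv_dist` object (classed matrix).
#' @export
krv_dist <- function(D, metric, sample_ids = rownames(D)) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("distance matrix must be symmetric")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (any(D < -1e-12)) stop("distance matrix has negative entries")
  D[D < 0] <- 0
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(D)))
  dimnames(D) <- list(sample_ids, sample_ids)
  structure(D, class = c("krv_dist", "matrix"), metric = metric)
}

#' @export
print.krv_dist <- function(x, ...) {
  cat(sprintf("krv_dist: %d samples, metric = %s\n", nrow(x), attr(x, "metric")))
  invisible(x)
}

#' Write/read a distance matrix as square TSV
#' @param D a [krv_dist()].
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param metric metric label to attach on read.
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  krv_dist(m, metric = metric)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rarefy_row <- function(y, depth) {
  tot <- sum(y)
  if (tot == depth) return(y)
  pool <- rep.int(seq_along(y), y)
  take <- pool[sample.int(length(pool), depth)]
  tabulate(take, nbins = length(y))
}

#' Rarefy a count table to a fixed sequencing depth
#'
#' Subsamples each sample's reads without replacement down to `depth`
#' (samples already at `depth` are returned unchanged). When `seed` is
#' given, sample `i` uses its own seeded stream (`seed + i`), so results do
#' not depend on row order and are fully reproducible.
#'
#' @param x raw [count_table()].
#' @param depth target total count per sample.
#' @param seed optional integer seed.
#' @return a raw `count_table` whose rows all sum to `depth`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  if (is_transformed(x)) stop("rarefaction requires raw counts")
  counts <- unclass(x)
  tot <- rowSums(counts)
  if (any(tot < depth))
    stop("samples with total count below depth: ",
         paste(rownames(counts)[tot < depth], collapse = ", "))
  out <- counts
  todo <- which(tot > depth)
  if (is.null(seed)) {
    for (i in todo) out[i, ] <- rarefy_row(counts[i, ], depth)
  } else {
    with_seed(seed, {
      for (i in todo) {
        set.seed(seed + i)
        out[i, ] <- rarefy_row(counts[i, ], depth)
      }
    })
  }
  count_table(out, transformed = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' `D_ij = sum_t |x_it - x_jt| / sum_t (x_it + x_jt)`, in `[0, 1]` for
#' non-negative counts. Defined on counts only; transformed tables are
#' refused. Rarefied input (equal row totals) is recommended.
#'
#' @param x raw [count_table()].
#' @return a [krv_dist()].
#' @export
bray_curtis <- function(x) {
  if (is_transformed(x)) stop("Bray-Curtis is defined on count data; got a transformed table")
  counts <- unclass(x)
  zero <- rowSums(counts) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(rownames(counts)[zero], collapse = ", "))
  D <- as.matrix(vegan::vegdist(counts, method = "bray"))
  krv_dist(D, metric = "bray_curtis", sample_ids = rownames(counts))
}

# Per-edge structures of a rooted tree restricted to the table's taxa:
# sparse leaf-by-edge ancestry incidence and branch lengths.
tree_edge_structure <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra) > 0) tree <- ape::drop.tip(tree, extra)
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  E <- nrow(tree$edge)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(ntip)) desc[[k]] <- k
  ii <- vector("list", E)
  for (e in seq_len(E)) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    if (child > ntip && is.null(desc[[child]])) desc[[child]] <- integer(0)
    tips <- desc[[child]]
    ii[[e]] <- tips
    desc[[parent]] <- c(desc[[parent]], tips)
  }
  lens <- lengths(ii)
  inc <- Matrix::sparseMatrix(i = unlist(ii), j = rep(seq_len(E), lens),
                              x = 1, dims = c(ntip, E))
  rownames(inc) <- tree$tip.label
  list(incidence = inc[taxa, , drop = FALSE], branch_length = po$edge.length,
       tree = tree, postorder = po)
}

unifrac_from_proportions <- function(P, bl, variant, alpha) {
  res <- unifrac_pairwise_cpp(t(P), bl, if (is.na(alpha)) 0.5 else alpha)
  D <- switch(variant,
              unweighted = res$unweighted,
              weighted_normalized = res$weighted,
              generalized = res$generalized)
  diag(D) <- 0
  D
}

#' UniFrac distances
#'
#' Phylogeny-aware beta-diversity. For each branch, the fraction of each
#' sample's reads descending from that branch is computed; the unweighted
#' variant compares branch presence/absence (unique vs shared branch
#' length), the weighted normalized variant compares branch proportions
#' (`sum b |p_i - p_j| / sum b (p_i + p_j)`), and the generalized variant
#' interpolates with exponent `alpha`
#' (`sum b (p_i+p_j)^alpha |p_i-p_j|/(p_i+p_j) / sum b (p_i+p_j)^alpha`);
#' `alpha = 1` recovers the weighted normalized form.
#'
#' @param x raw [count_table()]; every taxon must map to a tree leaf.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param variant one of `"unweighted"`, `"weighted_normalized"`,
#'   `"generalized"`.
#' @param alpha exponent for the generalized variant (default 0.5).
#' @return a [krv_dist()] with entries in `[0, 1]`.
#' @export
unifrac <- function(x, tree,
                    variant = c("unweighted", "weighted_normalized", "generalized"),
                    alpha = 0.5) {
  variant <- match.arg(variant)
  if (is_transformed(x)) stop("UniFrac requires raw counts")
  counts <- unclass(x)
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("samples with zero total count: ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  es <- tree_edge_structure(tree, colnames(counts))
  P <- as.matrix((counts / tot) %*% es$incidence)
  D <- unifrac_from_proportions(P, es$branch_length, variant, alpha)
  label <- if (variant == "generalized") sprintf("generalized_unifrac(%g)", alpha)
           else paste0(sub("_normalized", "", variant), "_unifrac")
  krv_dist(D, metric = label, sample_ids = rownames(counts))
}

#' Centered log-ratio transform
#'
#' Per sample, `z_t = log(x_t + pseudo) - mean_t log(x_t + pseudo)`; each
#' output row sums to zero. The transform addresses the compositional
#' nature of count data; a unit pseudo-count (default) handles zeros.
#'
#' @param x raw [count_table()].
#' @param pseudo positive pseudo-count added to every cell.
#' @return a transformed `count_table`.
#' @export
clr_transform <- function(x, pseudo = 1) {
  if (is_transformed(x)) stop("CLR requires raw counts")
  counts <- unclass(x)
  if (pseudo <= 0 && any(counts == 0))
    stop("pseudo-count must be positive when zero counts are present")
  z <- log(counts + pseudo)
  z <- z - rowMeans(z)
  count_table(z, transformed = TRUE)
}

# Sequential binary partition of a strictly bifurcating rooted tree.
# Returns the q x (q-1) ILR contrast matrix (orthonormal columns) plus a
# per-balance branch-length weight (sum of the two child branch lengths).
tree_ilr_basis <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from tree: ", paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra) > 0) tree <- ape::drop.tip(tree, extra)
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    if (!ape::is.binary(tree)) stop("tree could not be resolved to binary form")
  }
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(ntip)) desc[[k]] <- k
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  # fill descendant sets in postorder
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  internal <- sort(unique(po$edge[, 1]))
  V <- matrix(0, ntip, length(internal))
  blw <- numeric(length(internal))
  for (j in seq_along(internal)) {
    node <- internal[j]
    ee <- kids[[as.character(node)]]
    if (length(ee) != 2) stop("non-binary node after resolution")
    left <- desc[[po$edge[ee[1], 2]]]
    right <- desc[[po$edge[ee[2], 2]]]
    r <- length(left); s <- length(right)
    V[left, j] <- sqrt(s / (r * (r + s)))
    V[right, j] <- -sqrt(r / (s * (r + s)))
    blw[j] <- po$edge.length[ee[1]] + po$edge.length[ee[2]]
  }
  rownames(V) <- tree$tip.label
  colnames(V) <- paste0("n", internal)
  list(contrast = V[taxa, , drop = FALSE], blw = blw, tree = tree)
}

#' Phylogenetic isometric log-ratio (ILR) transform
#'
#' One balance per internal node of the (strictly bifurcating) tree,
#' following the sequential binary partition the tree induces: the balance
#' contrasts the geometric means of the two child clades with the standard
#' orthonormal ILR coefficients. With `weights = "blw"` (the default) each
#' balance is additionally scaled by the summed branch lengths of the two
#' child branches, emphasizing splits across long branches; `"uniform"`
#' keeps the orthonormal basis.
#'
#' @param x raw [count_table()].
#' @param tree rooted [ape::phylo]; multifurcations are resolved
#'   deterministically to binary form with zero-length branches.
#' @param pseudo positive pseudo-count.
#' @param weights `"blw"` for branch-length weighting, `"uniform"` for the
#'   plain orthonormal basis.
#' @return a transformed `count_table` with `q - 1` balance columns.
#' @export
philr_transform <- function(x, tree, pseudo = 1, weights = c("blw", "uniform")) {
  weights <- match.arg(weights)
  if (is_transformed(x)) stop("PhILR requires raw counts")
  counts <- unclass(x)
  if (pseudo <= 0 && any(counts == 0))
    stop("pseudo-count must be positive when zero counts are present")
  basis <- tree_ilr_basis(tree, colnames(counts))
  philr_from_basis(counts, basis, pseudo, weights)
}

philr_from_basis <- function(counts, basis, pseudo, weights) {
  z <- log(counts + pseudo) %*% basis$contrast
  if (weights == "blw") z <- z * rep(basis$blw, each = nrow(z))
  count_table(z, sample_ids = rownames(counts), taxon_ids = colnames(basis$contrast),
              transformed = TRUE)
}
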