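#' Construct a sample-by-taxon count table
#'
#' The central microbiome container: an `n x q` matrix with samples in rows
#' and taxa in columns. Raw tables hold non-negative integer counts;
#' transformed tables (CLR, phylogenetic ILR balances) hold real values and
#' are flagged so that count-only operations can refuse them.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids identifiers; default to the dimnames of
#'   `counts`.
#' @param transformed logical; `TRUE` for real-valued transformed tables.
#' @return a `count_table` object (a classed matrix).
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts), transformed = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("t", seq_len(ncol(counts)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in count table")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids in count table")
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop("id lengths do not match count matrix dimensions")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("count table contains missing or non-finite values")
  if (!transformed) {
    if (any(counts < 0)) stop("raw count table contains negative entries")
    if (max(abs(counts - round(counts))) > 1e-8)
      stop("raw count table must be integer-valued")
    counts <- round(counts)
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(counts, class = c("count_table", "matrix"),
            transformed = transformed)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "transformed"))) "transformed" else "raw counts"))
  invisible(x)
}

is_transformed <- function(x) isTRUE(attr(x, "transformed"))

#' Read a count table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row of taxon ids and a
#' first column of sample ids (samples in rows).
#'
#' @param path file path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table must have a sample-id column and at least one taxon")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric entries in column '%s'", colnames(df)[-1][bad]))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric value at row '%s', column '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 ids[idx[1]], colnames(m)[idx[2]]))
  }
  count_table(m, sample_ids = ids, taxon_ids = colnames(m))
}

#' Write a count table to TSV
#'
#' @param x a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' Dosages are oriented so that each column counts the minor allele within
#' the loaded sample and lie in `[0, 2]`. `v` is the per-variant ratio of the
#' observed dosage variance to the expected binomial variance
#' `2 p (1 - p)`; it equals 1 for hard calls and enters the effective minor
#' allele count `N_eff = 2 p (1 - p) N v` used for variant filtering.
#'
#' @param dosages numeric matrix `n x m`, samples in rows.
#' @param variants data frame with columns `chrom`, `pos` (1-based), `id`,
#'   and optionally `ref`, `alt`.
#' @param v numeric vector of imputation-quality variance ratios; defaults
#'   to 1 (hard calls).
#' @param sample_ids row identifiers; default rownames.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variants, v = NULL,
                            sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosages)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id")
  if (!all(need %in% names(variants)))
    stop("variant metadata must have columns chrom, pos, id")
  if (nrow(variants) != ncol(dosages))
    stop("one metadata record required per dosage column")
  if (anyNA(dosages)) stop("dosages contain missing values; impute before construction")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie within [0, 2]")
  if (is.null(v)) v <- rep(1, ncol(dosages))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, v = v),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

fold_maf <- function(dosages) {
  p <- colMeans(dosages) / 2
  pmin(p, 1 - p)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input uses the `DS` (dosage) FORMAT field when present, otherwise the
#' `GT` hard calls. Dosages are re-oriented to count the minor allele: any
#' variant whose alternate-allele frequency exceeds 0.5 in the loaded sample
#' is flipped (`2 - dosage`). Missing genotypes are mean-imputed per variant
#' (`2 p`), with the number of imputed cells recorded in the
#' `"n_imputed"` attribute. For dosage input the variance ratio `v` is
#' estimated per variant; hard calls get `v = 1`.
#'
#' @param path path to a `.vcf` file or a dosage TSV (samples in rows,
#'   variant ids in the header, first column of sample ids).
#' @param metadata for TSV input, path to a sidecar variant-metadata TSV
#'   with columns `chrom`, `pos`, `id` (and optionally `ref`, `alt`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, metadata = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path)
  } else {
    if (is.null(metadata))
      stop("TSV dosage input requires a sidecar variant-metadata file")
    read_genotypes_tsv(path, metadata)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  has_ds <- "DS" %in% unlist(strsplit(vcf@gt[1, "FORMAT"], ":"))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
    hard <- FALSE
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(g) {
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    dos <- t(matrix(cnt(gt), nrow = nrow(gt), dimnames = dimnames(gt)))
    hard <- TRUE
  }
  finish_genotypes(dos,
                   data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                              id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                          paste0(fix$CHROM, ":", fix$POS), fix$ID),
                              ref = fix$REF, alt = fix$ALT,
                              stringsAsFactors = FALSE),
                   hard_calls = hard)
}

read_genotypes_tsv <- function(path, metadata) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- ids
  meta <- read.delim(metadata, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(dos))
    stop("metadata rows must match dosage columns")
  finish_genotypes(dos, meta, hard_calls = FALSE)
}

finish_genotypes <- function(dos, meta, hard_calls) {
  storage.mode(dos) <- "double"
  if (any(dos < 0 | dos > 2, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  n_imputed <- sum(is.na(dos))
  # alt-frequency orientation: flip columns so dosage counts the minor allele
  af <- colMeans(dos, na.rm = TRUE) / 2
  flip <- af > 0.5
  dos[, flip] <- 2 - dos[, flip]
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * p[j]
  }
  if (hard_calls) {
    v <- rep(1, ncol(dos))
  } else {
    denom <- 2 * p * (1 - p)
    v <- ifelse(denom > 0, apply(dos, 2, var) / denom, 0)
  }
  meta$maf <- fold_maf(dos)
  meta$flipped <- unname(flip)
  g <- genotype_matrix(dos, meta, v = v)
  attr(g, "n_imputed") <- n_imputed
  g
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Validates that the tree is rooted, leaf labels are unique and non-empty,
#' and branch lengths are present and non-negative.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
    stop("tree contains unlabeled leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Construct a covariate design
#'
#' Builds the full-rank design matrix `X` (with leading intercept) whose
#' column space is projected out of both kernels during covariate
#' adjustment. With no covariates the orthogonal projector reduces to the
#' centering matrix `H = I - 11'/n`.
#'
#' @param x covariate matrix or data frame (no intercept column needed), or
#'   `NULL` for an intercept-only design.
#' @param sample_ids row identifiers.
#' @param n number of samples, required when `x` is `NULL`.
#' @return a `covariate_design` object.
#' @export
covariate_design <- function(x = NULL, sample_ids = NULL, n = NULL) {
  if (is.null(x)) {
    if (is.null(n)) stop("n required for an intercept-only design")
    X <- matrix(1, n, 1, dimnames = list(sample_ids, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (is.null(sample_ids)) sample_ids <- rownames(x)
    has_intercept <- ncol(x) > 0 && all(x[, 1] == 1)
    X <- if (has_intercept) x else cbind("(Intercept)" = 1, x)
    rownames(X) <- sample_ids
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate design is rank-deficient; remove collinear columns")
  if (nrow(X) <= ncol(X))
    stop("need more samples than covariate columns")
  structure(list(X = X, qr = qrX, sample_ids = rownames(X)),
            class = "covariate_design")
}

#' @export
print.covariate_design <- function(x, ...) {
  cat(sprintf("covariate_design: %d samples, %d columns (incl. intercept)\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Read a covariate table from TSV (first column sample ids)
#' @param path file path.
#' @return a [covariate_design()].
#' @export
read_covariates <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df[[1]])
  covariate_design(data.matrix(df[, -1, drop = FALSE]), sample_ids = ids)
}

#' Read gene regions from a BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gene`; positions are 1-based inclusive.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data frame of gene regions.
#' @export
read_gene_regions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(df))) stop("gene file needs columns chrom, start, end, gene")
  if (any(df$start > df$end)) stop("gene region with start > end")
  df
}

#' Sample identifiers of a data object
#' @param x a package data object.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.count_table <- function(x) rownames(x)
#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dosages)
#' @export
sample_ids.covariate_design <- function(x) x$sample_ids
#' @export
sample_ids.krv_kernel <- function(x) rownames(unclass(x))
#' @export
sample_ids.krv_dist <- function(x) rownames(unclass(x))
#' @export
sample_ids.matrix <- function(x) rownames(x)

subset_samples_obj <- function(x, ids) {
  if (inherits(x, "count_table")) {
    count_table(unclass(x)[ids, , drop = FALSE], transformed = is_transformed(x))
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$dosages[ids, , drop = FALSE], x$variants, v = x$v)
  } else if (inherits(x, "covariate_design")) {
    covariate_design(x$X[ids, , drop = FALSE])
  } else if (inherits(x, "krv_kernel") || inherits(x, "krv_dist")) {
    m <- unclass(x)[ids, ids, drop = FALSE]
    attributes(m)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <-
      attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))]
    m
  } else if (is.matrix(x)) {
    x[ids, , drop = FALSE]
  } else stop("cannot subset object of class ", paste(class(x), collapse = "/"))
}

#' Restrict data objects to their common samples
#'
#' Intersects sample ids across all inputs (keeping the order of the first)
#' and returns every object restricted and reordered to that shared set, so
#' that all matrices index the same samples in the same order.
#'
#' @param ... count tables, genotype matrices, covariate designs, kernels or
#'   matrices with rownames.
#' @return a list of the restricted objects, with attribute `"sample_ids"`.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  if (length(objs) == 1 && is.list(objs[[1]]) && !inherits(objs[[1]], "genotype_matrix") &&
      !inherits(objs[[1]], "covariate_design"))
    objs <- objs[[1]]
  ids <- lapply(objs, sample_ids)
  common <- Reduce(intersect, ids)
  if (length(common) == 0) stop("no samples shared across inputs")
  out <- lapply(objs, subset_samples_obj, ids = common)
  message(sprintf("align_samples: %d common samples retained", length(common)))
  attr(out, "sample_ids") <- common
  out
}
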