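# Two-stage gene-then-variant genome-wide scan, variant filtering,
# inflation diagnostics and kernel-PC taxa attribution.

#' Filter variants on MAF and effective minor allele count
#'
#' Retains variants with folded minor allele frequency `p >= maf_min` and
#' effective minor allele count `N_eff = 2 p (1 - p) N v >= neff_min`,
#' where `v` is the imputation-quality variance ratio (1 for hard calls).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param neff_min minimum effective minor allele count (default 30).
#' @return the filtered [genotype_matrix()], with attribute `"n_removed"`.
#' @export
filter_variants <- function(G, maf_min = 0.05, neff_min = 30) {
  p <- fold_maf(G$dosages)
  neff <- 2 * p * (1 - p) * nrow(G$dosages) * G$v
  keep <- p >= maf_min & neff >= neff_min
  if (!any(keep)) {
    warning("no variants pass the MAF/N_eff filters; returning empty matrix")
  }
  out <- genotype_matrix(G$dosages[, keep, drop = FALSE],
                         G$variants[keep, , drop = FALSE], v = G$v[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Group variants into gene-level variant sets
#'
#' Assigns each variant to every gene whose flanked window
#' `[start - flank, end + flank]` (1-based inclusive) contains its
#' position; a variant may belong to several overlapping genes. Genes with
#' no member variants are dropped.
#'
#' @param G a (filtered) [genotype_matrix()].
#' @param regions gene regions data frame (`chrom`, `start`, `end`, `gene`).
#' @param flank window extension in bp (default 10 kb).
#' @return data frame of testable genes with a `members` list-column of
#'   variant column indices.
#' @export
build_gene_sets <- function(G, regions, flank = 10000) {
  v <- G$variants
  members <- lapply(seq_len(nrow(regions)), function(i) {
    which(v$chrom == regions$chrom[i] &
            v$pos >= regions$start[i] - flank &
            v$pos <= regions$end[i] + flank)
  })
  keep <- lengths(members) > 0
  if (!any(keep)) stop("no testable genes: no gene window contains a variant")
  out <- regions[keep, , drop = FALSE]
  out$members <- members[keep]
  out$n_variants <- lengths(out$members)
  out$flank <- flank
  rownames(out) <- NULL
  out
}

#' First-stage gene-level KRV scan
#'
#' Per gene, builds a linear kernel on the gene's variant dosage submatrix
#' and tests the covariate-adjusted KRV against the microbiome kernel.
#' Bonferroni significance uses `alpha / (number of testable genes)`;
#' genes whose kernel is degenerate after adjustment (e.g., all member
#' variants monomorphic) are reported with a missing p-value and excluded
#' from the Bonferroni denominator.
#'
#' @param genes output of [build_gene_sets()].
#' @param G a [genotype_matrix()] (already filtered to common variants).
#' @param L microbiome [krv_kernel()] (psd-corrected).
#' @param X a [covariate_design()] or covariate matrix (or `NULL`).
#' @param alpha family-wise level (default 0.05).
#' @return data frame of per-gene results, sorted by p-value, with the
#'   threshold used.
#' @export
stage1_scan <- function(genes, G, L, X = NULL, alpha = 0.05) {
  Lc <- prepare_kernel(L, X)
  fl <- frob2(Lc)
  if (fl <= 1e-24) stop("microbiome kernel degenerate after adjustment")
  W <- Lc / sqrt(fl)
  iw <- krv_invariants(W)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- genes$members[[i]]
    Z <- G$dosages[, idx, drop = FALSE]
    Kc <- if (is.null(X)) center_mat(tcrossprod(Z))
          else project_out(tcrossprod(Z), X)
    if (frob2(Kc) <= 1e-24)
      return(data.frame(gene = genes$gene[i], n_variants = length(idx),
                        statistic = NA_real_, p_value = NA_real_))
    t <- krv_test_prepared(Kc, Lc, iw = iw)
    data.frame(gene = genes$gene[i], n_variants = length(idx),
               statistic = t$statistic, p_value = t$p_value)
  })
  res <- do.call(rbind, res)
  n_testable <- sum(!is.na(res$p_value))
  if (n_testable == 0) stop("no testable genes (all degenerate)")
  threshold <- alpha / n_testable
  res$threshold <- threshold
  res$significant <- !is.na(res$p_value) & res$p_value < threshold
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "stage") <- "gene"
  attr(res, "n_tests") <- n_testable
  res
}

# Merge flanked intervals of stage-1 significant genes into disjoint
# regions (overlapping hits become one region, as overlapping genes share
# variants).
merge_gene_regions <- function(genes) {
  ord <- order(genes$chrom, genes$start)
  g <- genes[ord, , drop = FALSE]
  flank <- g$flank[1]
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(g))) {
    lo <- g$start[i] - flank; hi <- g$end[i] + flank
    if (!is.null(cur) && g$chrom[i] == cur$chrom && lo <= cur$hi) {
      cur$hi <- max(cur$hi, hi)
      cur$genes <- c(cur$genes, g$gene[i])
      cur$members <- union(cur$members, g$members[[i]])
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
      cur <- list(chrom = g$chrom[i], lo = lo, hi = hi, genes = g$gene[i],
                  members = g$members[[i]])
    }
  }
  regions[[length(regions) + 1]] <- cur
  regions
}

#' Second-stage variant-level KRV scan
#'
#' For the genes called significant in stage 1 (overlapping genes merged
#' into single regions, shared variants deduplicated), marginally tests
#' each member variant with a single-variant linear-kernel adjusted KRV.
#' Because the design is nested, the Bonferroni threshold is
#' `alpha / (total variants tested in this stage)`.
#'
#' @param stage1 output of [stage1_scan()].
#' @param genes output of [build_gene_sets()] (the same object passed to
#'   stage 1).
#' @param G,L,X,alpha as in [stage1_scan()].
#' @return data frame of per-variant results (empty if no stage-1 hits).
#' @export
stage2_scan <- function(stage1, genes, G, L, X = NULL, alpha = 0.05) {
  hits <- stage1$gene[stage1$significant]
  empty <- data.frame(region = character(0), variant = character(0),
                      chrom = character(0), pos = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      threshold = numeric(0), significant = logical(0))
  if (length(hits) == 0) return(empty)
  regions <- merge_gene_regions(genes[genes$gene %in% hits, , drop = FALSE])
  Lc <- prepare_kernel(L, X)
  W <- Lc / sqrt(frob2(Lc))
  iw <- krv_invariants(W)
  res <- list()
  for (r in regions) {
    lab <- paste(r$genes, collapse = "-")
    for (idx in r$members) {
      z <- G$dosages[, idx, drop = FALSE]
      Kc <- if (is.null(X)) center_mat(tcrossprod(z))
            else project_out(tcrossprod(z), X)
      if (frob2(Kc) <= 1e-24) next
      t <- krv_test_prepared(Kc, Lc, iw = iw)
      res[[length(res) + 1]] <-
        data.frame(region = lab, variant = G$variants$id[idx],
                   chrom = G$variants$chrom[idx], pos = G$variants$pos[idx],
                   statistic = t$statistic, p_value = t$p_value)
    }
  }
  if (length(res) == 0) return(empty)
  res <- do.call(rbind, res)
  threshold <- alpha / nrow(res)
  res$threshold <- threshold
  res$significant <- res$p_value < threshold
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "stage") <- "variant"
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Genomic inflation factor at an upper quantile
#'
#' Converts p-values to 1-df chi-square statistics through the upper-tail
#' inverse and reports the ratio of the observed to the theoretical
#' chi-square quantile at the upper `quantile` level (default the upper
#' 10th percentile, lambda_GC,0.1). Values near 1 indicate a calibrated
#' scan; values well above 1 indicate confounding or miscalibration.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param quantile upper-tail level (default 0.1).
#' @return list with `lambda`, `quantile` and `n`.
#' @export
genomic_inflation <- function(pvalues, quantile = 0.1) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  if (length(pvalues) < 100)
    warning("fewer than 100 p-values; inflation estimate is unstable")
  x <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  lam <- unname(stats::quantile(x, 1 - quantile, type = 7) /
                  qchisq(1 - quantile, df = 1))
  list(lambda = lam, quantile = quantile, n = length(pvalues))
}

#' Attribute a gene-microbiome association to specific taxa
#'
#' Step 1 regresses each of the leading `n_pcs` kernel principal component
#' score vectors of the microbiome kernel on the top variant's dosage with
#' the covariates included, and keeps PCs whose dosage coefficient passes
#' Benjamini-Hochberg FDR control at `fdr`. Step 2 reports, for each
#' significant PC, the taxa whose abundance has absolute Pearson
#' correlation `>= corr_min` with the PC scores (with sign).
#'
#' @param L microbiome [krv_kernel()].
#' @param counts [count_table()] of taxon abundances on the scale matched
#'   to the kernel (rarefied counts for Bray-Curtis/UniFrac kernels,
#'   CLR-transformed values for log-ratio kernels).
#' @param top_variant numeric dosage vector of the top variant.
#' @param X a [covariate_design()] or covariate matrix (or `NULL`).
#' @param n_pcs number of leading kernel PCs to screen (default 10).
#' @param fdr FDR level for PC selection (default 0.05).
#' @param corr_min absolute-correlation screen for taxa (default 0.5).
#' @return data frame (`pc`, `pc_p_adjusted`, `taxon`, `correlation`); zero
#'   rows with attribute `"note"` when no PC passes.
#' @export
taxa_attribution <- function(L, counts, top_variant, X = NULL, n_pcs = 10,
                             fdr = 0.05, corr_min = 0.5) {
  kp <- kernel_pca(L, n_components = n_pcs)
  S <- kp$scores
  Xc <- if (is.null(X)) NULL
        else if (inherits(X, "covariate_design")) X$X[, -1, drop = FALSE]
        else as.matrix(X)
  pv <- vapply(seq_len(ncol(S)), function(j) {
    dat <- if (is.null(Xc)) data.frame(y = S[, j], g = top_variant)
           else data.frame(y = S[, j], g = top_variant, Xc)
    fit <- lm(y ~ ., data = dat)
    summary(fit)$coefficients["g", "Pr(>|t|)"]
  }, numeric(1))
  padj <- p.adjust(pv, method = "BH")
  sig <- which(padj < fdr)
  if (length(sig) == 0) {
    out <- data.frame(pc = integer(0), pc_p_adjusted = numeric(0),
                      taxon = character(0), correlation = numeric(0))
    attr(out, "note") <- "no kernel PC significantly associated with the variant"
    return(out)
  }
  M <- unclass(counts)
  res <- lapply(sig, function(j) {
    cc <- suppressWarnings(cor(M, S[, j]))[, 1]
    cc[is.na(cc)] <- 0
    hit <- which(abs(cc) >= corr_min)
    if (length(hit) == 0) return(NULL)
    data.frame(pc = j, pc_p_adjusted = padj[j], taxon = colnames(M)[hit],
               correlation = unname(cc[hit]))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(pc = integer(0), pc_p_adjusted = numeric(0),
                      taxon = character(0), correlation = numeric(0))
  rownames(out) <- NULL
  out
}
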