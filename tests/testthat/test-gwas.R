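make_geno <- function(dosages, pos, chrom = "chr1", v = NULL) {
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos,
                             id = paste0("v", seq_along(pos))), v = v)
}

test_that("variant filtering applies the MAF and N_eff rules", {
  # p = 0.1, N = 1000, v = 1 -> N_eff = 180: retained
  set.seed(1)
  n <- 1000
  d1 <- rbinom(n, 2, 0.1)
  d1 <- d1 * 0.1 / (mean(d1) / 2)       # force p-hat exactly 0.1
  d1 <- pmin(d1, 2)
  neff <- function(d, v = 1) {
    p <- min(mean(d) / 2, 1 - mean(d) / 2)
    2 * p * (1 - p) * length(d) * v
  }
  expect_gt(neff(d1), 30)

  # p = 0.01, N = 1219, v = 1 -> N_eff ~ 24.1 < 30: excluded
  expect_equal(2 * 0.01 * 0.99 * 1219, 24.1, tolerance = 0.01)
  d2 <- c(rep(1, round(2 * 1219 * 0.01)), rep(0, 1219 - round(2 * 1219 * 0.01)))
  expect_lt(neff(d2), 30)

  G <- make_geno(cbind(rep(c(0, 1), 500), rep(c(0, 0, 0, 0, 1), 200),
                       rep(1, 1000)),
                 pos = c(100, 200, 300), v = c(1, 1, 0))
  # col1 p=0.25 keep; col2 p=0.1 but check; col3 p=0.5, v=0 -> N_eff = 0
  f <- filter_variants(G, maf_min = 0.05, neff_min = 30)
  expect_true("v1" %in% f$variants$id)
  expect_false("v3" %in% f$variants$id)   # zero variance ratio excludes it
  Gall_rare <- make_geno(cbind(c(1, rep(0, 99))), pos = 1)
  expect_warning(f2 <- filter_variants(Gall_rare), "no variants")
  expect_equal(ncol(f2$dosages), 0)
})

test_that("gene windows use flanked 1-based inclusive boundaries", {
  pos <- c(11999, 12001, 1500, 30000)
  G <- make_geno(matrix(rbinom(4 * 10, 2, 0.3), 10, 4), pos = pos)
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                        gene = "g1")
  gs <- build_gene_sets(G, regions, flank = 10000)
  expect_equal(gs$members[[1]], c(1, 3))  # 11999 in, 12001 out

  # overlapping genes share variants
  regions2 <- data.frame(chrom = "chr1",
                         start = c(1000, 11000), end = c(2000, 13000),
                         gene = c("gA", "gB"))
  gs2 <- build_gene_sets(G, regions2, flank = 1000)
  shared <- intersect(gs2$members[[1]], gs2$members[[2]])
  # brute-force interval overlap oracle
  oracle <- lapply(seq_len(2), function(i)
    which(pos >= regions2$start[i] - 1000 & pos <= regions2$end[i] + 1000))
  expect_equal(gs2$members, oracle)
  expect_true(length(shared) >= 0)
  expect_error(build_gene_sets(G, data.frame(chrom = "chr9", start = 1,
                                             end = 2, gene = "x")),
               "no testable genes")
})

test_that("bonferroni thresholds reproduce the two-stage arithmetic", {
  expect_equal(0.05 / 19223, 2.6e-6, tolerance = 0.01)
  expect_equal(0.05 / 557, 8.98e-5, tolerance = 0.001)
  expect_equal(0.05 / (288 + 174), 1.08e-4, tolerance = 0.001)
})

test_that("genomic inflation is calibrated and tracks injected inflation", {
  set.seed(70)
  p_unif <- runif(1e5)
  lam <- genomic_inflation(p_unif, quantile = 0.1)$lambda
  expect_lt(abs(lam - 1), 0.02)
  x <- stats::rchisq(1e5, df = 1) * 1.3
  p_infl <- stats::pchisq(x, df = 1, lower.tail = FALSE)
  lam2 <- genomic_inflation(p_infl, quantile = 0.1)$lambda
  expect_lt(abs(lam2 - 1.3), 0.05)
  expect_warning(genomic_inflation(runif(50)), "fewer than 100")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
})

# Shared small synthetic study with one planted associated gene.
planted_study <- local({
  res <- NULL
  function() {
    if (!is.null(res)) return(res)
    set.seed(81)
    n_per_pop <- 60
    n <- 2 * n_per_pop
    Gm <- simulate_genotypes(n_per_pop, n_variants = 120,
                             region_length = 3e5, fst = 0.1, seed = 82)
    params <- synthesize_dm_params(q = 120, theta = 0.02, seed = 83)
    counts <- simulate_otu_counts(params, n = n, depth = 800, seed = 84)
    pop <- attr(Gm, "population")
    conf <- apply_confounding(counts, pop, "T1", params$pi, depth = 800,
                              seed = 85)
    # plant: a common variant in the middle of the region drives common taxa
    maf <- Gm$variants$maf
    causal <- which(Gm$variants$pos > 1.4e5 & Gm$variants$pos < 1.6e5 &
                      maf >= 0.2)[1]
    g <- Gm$dosages[, causal]
    eff <- apply_genetic_effect(conf, g, "P1", effect_size = 1.5,
                                pi = params$pi, depth = 800, seed = 86)
    L <- microbiome_kernel(eff, "bray_curtis")
    X <- covariate_design(cbind(pc1 = krvgwas:::top_genotype_pc(Gm$dosages)))
    # contiguous gene tiling so every variant is covered
    regions <- data.frame(chrom = "chr1",
                          start = seq(1, 3e5, by = 3e4),
                          end = seq(1, 3e5, by = 3e4) + 29999)
    regions$gene <- paste0("gene", seq_len(nrow(regions)))
    Gf <- filter_variants(Gm, maf_min = 0.05, neff_min = 10)
    genes <- build_gene_sets(Gf, regions, flank = 2000)
    causal_pos <- Gm$variants$pos[causal]
    res <<- list(G = Gf, genes = genes, L = L, X = X, g = g,
                 causal_pos = causal_pos, counts = eff, params = params)
    res
  }
})

test_that("stage-1 scan recovers a planted gene and nests stage 2", {
  st <- planted_study()
  s1 <- stage1_scan(st$genes, st$G, st$L, st$X, alpha = 0.05)
  expect_equal(s1$threshold[1], 0.05 / sum(!is.na(s1$p_value)))
  # the gene containing the causal variant attains the smallest p-value
  top_gene <- s1$gene[1]
  win <- st$genes[st$genes$gene == top_gene, ]
  expect_true(st$causal_pos >= win$start - 2000 &&
                st$causal_pos <= win$end + 2000)
  expect_true(s1$significant[1])

  s2 <- stage2_scan(s1, st$genes, st$G, st$L, st$X)
  expect_gt(nrow(s2), 0)
  expect_equal(unique(s2$threshold), 0.05 / nrow(s2))
  # results ordered and flags consistent
  expect_true(all(diff(s2$p_value) >= 0))
  expect_equal(s2$significant, s2$p_value < s2$threshold[1])

  # no stage-1 hits -> empty stage 2
  s1_null <- s1
  s1_null$significant <- FALSE
  expect_equal(nrow(stage2_scan(s1_null, st$genes, st$G, st$L, st$X)), 0)
})

test_that("a permuted null scan is not significant and is order-invariant", {
  st <- planted_study()
  set.seed(90)
  p <- sample(nrow(st$L))
  Lp <- krv_kernel(unclass(st$L)[p, p], label = "permuted")
  s1 <- stage1_scan(st$genes, st$G, Lp, st$X)
  expect_false(any(s1$significant))
  # gene processing order does not change results
  genes_rev <- st$genes[rev(seq_len(nrow(st$genes))), ]
  s1_rev <- stage1_scan(genes_rev, st$G, Lp, st$X)
  expect_equal(s1_rev[order(s1_rev$gene), c("gene", "p_value")],
               s1[order(s1$gene), c("gene", "p_value")],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("taxa attribution recovers a planted single-taxon effect", {
  # inject a strong effect of the variant into one common taxon so that it
  # dominates a leading kernel PC
  set.seed(92)
  params <- synthesize_dm_params(q = 80, theta = 0.02, seed = 93)
  n <- 100
  counts <- simulate_otu_counts(params, n = n, depth = 1000, seed = 94)
  g <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.4, 0.15))
  m <- unclass(counts)
  target <- names(params$pi)[2]
  m[, target] <- round(m[, target] * (1 + 1.5 * g))
  driven <- count_table(krvgwas:::rarefy_rows(m, 1000))
  L <- microbiome_kernel(driven, "bray_curtis")
  att <- taxa_attribution(L, driven, g, X = NULL, n_pcs = 10)
  expect_true(target %in% att$taxon)
  expect_true(all(abs(att$correlation) >= 0.5))
  # sign agrees with the direction of the planted effect
  tgt <- att[att$taxon == target, ][1, ]
  S <- kernel_pca(L, n_components = 10)$scores
  expect_equal(sign(tgt$correlation),
               sign(cor(unclass(driven)[, target], S[, tgt$pc])))

  # duplicated taxon columns get identical correlations
  cnt2 <- cbind(unclass(driven), dup_taxon = unclass(driven)[, target])
  att2 <- taxa_attribution(L, count_table(cnt2), g, n_pcs = 10)
  c_orig <- att2$correlation[att2$taxon == target]
  c_dup <- att2$correlation[att2$taxon == "dup_taxon"]
  expect_equal(sort(c_dup), sort(c_orig), tolerance = 1e-12)

  # a variant unrelated to the microbiome gives an empty attribution
  set.seed(95)
  L0 <- microbiome_kernel(counts, "bray_curtis")
  g_null <- rbinom(n, 2, 0.3)
  att_null <- taxa_attribution(L0, counts, g_null, n_pcs = 5)
  expect_equal(nrow(att_null), 0)
  expect_match(attr(att_null, "note"), "no kernel PC")
})
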