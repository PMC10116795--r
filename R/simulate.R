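# Synthetic genotype and microbiome data with the statistical structure of
# a two-population microbiome GWAS: population stratification as a
# confounder of both data types, and pleiotropic single-SNP effects on
# groups of taxa. Drives the type-I-error and power experiments.

#' Simulate two-population genotypes under the Balding-Nichols model
#'
#' Each variant draws an ancestral allele frequency from
#' `Uniform(0.1, 0.9)` and population-specific frequencies from the
#' Balding-Nichols Beta distribution with differentiation `fst`;
#' individuals are formed by summing two binomially drawn haplotypes.
#' Variant positions are uniform over the region. The systematic
#' allele-frequency differences between the two populations make the top
#' genotype principal component a surrogate for population structure.
#'
#' @param n_per_pop individuals per population (two populations).
#' @param n_variants number of variants across the region.
#' @param region_length region length in bp (default 1 Mb).
#' @param fst Balding-Nichols differentiation parameter (default 0.1).
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with a `"population"` attribute
#'   (`"A"`/`"B"`).
#' @export
simulate_genotypes <- function(n_per_pop = 500, n_variants = 1000,
                               region_length = 1e6, fst = 0.1, seed = NULL) {
  if (n_per_pop < 2) stop("need at least 2 individuals per population")
  with_seed(seed, {
    n <- 2 * n_per_pop
    pos <- sort(sample.int(region_length, n_variants))
    p_anc <- runif(n_variants, 0.1, 0.9)
    if (fst > 0) {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      pA <- stats::rbeta(n_variants, a, b)
      pB <- stats::rbeta(n_variants, a, b)
    } else {
      pA <- pB <- p_anc
    }
    G <- matrix(0, n, n_variants)
    G[seq_len(n_per_pop), ] <-
      matrix(rbinom(n_per_pop * n_variants, 2, rep(pA, each = n_per_pop)),
             n_per_pop, n_variants)
    G[n_per_pop + seq_len(n_per_pop), ] <-
      matrix(rbinom(n_per_pop * n_variants, 2, rep(pB, each = n_per_pop)),
             n_per_pop, n_variants)
    rownames(G) <- paste0("ind", seq_len(n))
    meta <- data.frame(chrom = "chr1", pos = pos,
                       id = paste0("v", seq_len(n_variants)),
                       stringsAsFactors = FALSE)
    out <- genotype_matrix(G, meta)
    out$variants$maf <- fold_maf(G)
    attr(out, "population") <- rep(c("A", "B"), each = n_per_pop)
    out
  })
}

#' Dirichlet-multinomial parameters
#'
#' `synthesize_dm_params()` builds a realistic heavy-tailed taxon
#' abundance profile: `q` log-normal draws, sorted decreasing and
#' normalized to mean proportions `pi`, with overdispersion `theta`.
#' `estimate_dm_params()` recovers `(pi, theta)` from an observed count
#' table by the method of moments (pooled proportions and the standard
#' between/within mean-square estimator of `theta`).
#'
#' @param q number of taxa.
#' @param theta overdispersion in (0, 1).
#' @param sdlog log-normal spread of the abundance profile.
#' @param seed optional integer seed.
#' @return a `dm_params` list with elements `pi` (named, sums to 1) and
#'   `theta`.
#' @export
synthesize_dm_params <- function(q = 856, theta = 0.01, sdlog = 2.5,
                                 seed = NULL) {
  if (q < 2) stop("need at least 2 taxa")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  with_seed(seed, {
    raw <- sort(rlnorm(q, meanlog = 0, sdlog = sdlog), decreasing = TRUE)
    pi <- raw / sum(raw)
    names(pi) <- paste0("otu", seq_len(q))
    structure(list(pi = pi, theta = theta), class = "dm_params")
  })
}

#' @rdname synthesize_dm_params
#' @param x raw [count_table()].
#' @export
estimate_dm_params <- function(x) {
  m <- unclass(x)
  tot <- rowSums(m)
  if (all(tot == 0)) stop("all-zero count table")
  m <- m[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  n <- nrow(m)
  pr <- m / tot
  pi <- colSums(m) / sum(m)
  # Weir-Hill moment estimator of the overdispersion
  Nc <- (sum(tot) - sum(tot^2) / sum(tot)) / (n - 1)
  Sb <- colSums(tot * (pr - rep(pi, each = n))^2) / (n - 1)
  Gw <- colSums(tot * pr * (1 - pr)) / (sum(tot) - n)
  theta <- sum(Sb - Gw) / sum(Sb + (Nc - 1) * Gw)
  theta <- min(max(theta, 1e-8), 1 - 1e-8)
  structure(list(pi = pi, theta = theta), class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat(sprintf("dm_params: %d taxa, theta = %.4g, top taxon %.1f%%\n",
              length(x$pi), x$theta, 100 * max(x$pi)))
  invisible(x)
}

dm_counts_matrix <- function(pi, theta, n, depth) {
  conc <- pi * (1 - theta) / theta
  q <- length(pi)
  gam <- matrix(rgamma(n * q, shape = rep(conc, each = n)), n, q)
  gam[gam == 0] <- 1e-300
  pr <- gam / rowSums(gam)
  out <- matrix(0, n, q)
  for (i in seq_len(n)) out[i, ] <- rmultinom(1, depth, pr[i, ])[, 1]
  colnames(out) <- names(pi)
  out
}

#' Simulate Dirichlet-multinomial taxon counts
#'
#' Each sample draws a composition from a Dirichlet with concentration
#' `pi (1 - theta) / theta` and counts from a multinomial of size `depth`,
#' capturing the overdispersion of microbiome count data.
#'
#' @param params a `dm_params` object.
#' @param n number of samples.
#' @param depth total count per sample (default 1000).
#' @param seed optional integer seed.
#' @return a raw [count_table()] whose rows sum to `depth`.
#' @export
simulate_otu_counts <- function(params, n, depth = 1000, seed = NULL) {
  with_seed(seed, {
    m <- dm_counts_matrix(params$pi, params$theta, n, depth)
    rownames(m) <- paste0("ind", seq_len(n))
    count_table(m)
  })
}

#' Random bifurcating phylogeny over the simulated taxa
#'
#' Coalescent-style random topology ([ape::rcoal]) with the taxon
#' identifiers as tip labels, used for the UniFrac and PhILR kernels in
#' simulations.
#'
#' @param taxon_ids tip labels (or a single integer, the number of taxa).
#' @param seed optional integer seed.
#' @return a rooted binary [ape::phylo].
#' @export
simulate_taxon_tree <- function(taxon_ids, seed = NULL) {
  if (length(taxon_ids) == 1 && is.numeric(taxon_ids))
    taxon_ids <- paste0("otu", seq_len(taxon_ids))
  with_seed(seed, {
    tr <- ape::rcoal(length(taxon_ids), tip.label = sample(taxon_ids))
    validate_tree(tr)
  })
}

#' Pick the clade closest to a target total abundance
#'
#' Scans every clade (internal-node descendant set with at least two taxa)
#' and returns the member taxa of the clade whose summed mean proportion is
#' closest to `target` within `band`. Used as the affected set in the
#' common-cluster power scenario.
#'
#' @param tree rooted tree over the taxa.
#' @param pi named mean proportions.
#' @param target target clade abundance (default 0.103).
#' @param band admissible range of clade abundance.
#' @return character vector of taxon ids.
#' @export
select_abundant_clade <- function(tree, pi, target = 0.103,
                                  band = c(0.05, 0.2)) {
  es <- tree_edge_structure(tree, names(pi))
  tot <- as.numeric(pi %*% es$incidence)
  sizes <- Matrix::colSums(es$incidence)
  ok <- which(sizes >= 2 & tot >= band[1] & tot <= band[2])
  if (length(ok) == 0)
    stop(sprintf("no clade with total abundance in [%g, %g]", band[1], band[2]))
  best <- ok[which.min(abs(tot[ok] - target))]
  names(pi)[as.logical(es$incidence[, best])]
}

sround <- function(x) floor(x) + (runif(length(x)) < x - floor(x))

rarefy_rows <- function(m, depth) {
  tot <- rowSums(m)
  for (i in which(tot > depth)) m[i, ] <- rarefy_row(m[i, ], depth)
  m
}

#' Inject population-stratified confounding into taxon counts
#'
#' Scenario `"T1"` multiplies the counts of the 10 most common taxa
#' (ranked by the generating mean proportions `pi`) by 1.10 in the
#' affected population, with stochastic rounding to keep counts integral;
#' because these taxa are essentially always present, the shift changes
#' abundances but not presence/absence. Scenario `"T2"` adds a unit count
#' to 10 taxa drawn from the 40 rarest, changing presence/absence.
#' Counts are then re-rarefied to `depth` (skipped when `depth` is
#' `NULL`).
#'
#' @param x raw [count_table()].
#' @param populations per-sample population labels; the first label in
#'   sorted order is the affected population.
#' @param scenario `"T1"` or `"T2"`.
#' @param pi generating mean proportions (taxon prevalence ranking).
#' @param depth re-rarefaction depth (`NULL` to skip).
#' @param seed optional integer seed.
#' @return a raw [count_table()].
#' @export
apply_confounding <- function(x, populations, scenario = c("T1", "T2"), pi,
                              depth = 1000, seed = NULL) {
  scenario <- match.arg(scenario)
  m <- unclass(x)
  stopifnot(length(populations) == nrow(m), length(pi) == ncol(m))
  aff <- populations == sort(unique(populations))[1]
  with_seed(seed, {
    if (scenario == "T1") {
      idx <- order(pi, decreasing = TRUE)[1:10]
      m[aff, idx] <- matrix(sround(m[aff, idx] * 1.10), sum(aff), length(idx))
    } else {
      if (ncol(m) < 40) stop("T2 requires at least 40 taxa")
      rare <- order(pi)[1:40]
      idx <- sample(rare, 10)
      m[aff, idx] <- m[aff, idx] + 1
    }
    if (!is.null(depth)) m <- rarefy_rows(m, depth)
    count_table(m)
  })
}

#' Inject a pleiotropic single-SNP effect on taxon counts
#'
#' For genotype `g_i` at the causal SNP: scenario `"P1"` multiplies the
#' counts of the 11th-20th most common taxa by `f_i = 1 + c g_i`;
#' scenario `"P2"` applies the same multiplicative effect to the taxa of a
#' relatively abundant phylogenetic clade (about 10% of total abundance);
#' scenario `"P3"` adds `a_i = c g_i` to each of 5 taxa drawn from the 40
#' rarest. Fractional counts are stochastically rounded; counts are then
#' re-rarefied to `depth` (skipped when `depth` is `NULL`).
#'
#' @param x raw [count_table()].
#' @param g dosage vector (0/1/2) at the causal SNP.
#' @param scenario `"P1"`, `"P2"` or `"P3"`.
#' @param effect_size the scenario's effect size (`c1`, `c2` or `c3`).
#' @param pi generating mean proportions.
#' @param tree tree for clade selection (P2), unless `clade_taxa` given.
#' @param clade_taxa optional precomputed clade member ids for P2.
#' @param depth re-rarefaction depth (`NULL` to skip).
#' @param seed optional integer seed.
#' @return a raw [count_table()].
#' @export
apply_genetic_effect <- function(x, g, scenario = c("P1", "P2", "P3"),
                                 effect_size, pi, tree = NULL,
                                 clade_taxa = NULL, depth = 1000,
                                 seed = NULL) {
  scenario <- match.arg(scenario)
  m <- unclass(x)
  stopifnot(length(g) == nrow(m), length(pi) == ncol(m))
  with_seed(seed, {
    if (scenario == "P1") {
      idx <- order(pi, decreasing = TRUE)[11:20]
      f <- 1 + effect_size * g
      m[, idx] <- matrix(sround(m[, idx] * f), nrow(m), length(idx))
    } else if (scenario == "P2") {
      if (is.null(clade_taxa)) {
        if (is.null(tree)) stop("P2 requires a tree or precomputed clade taxa")
        clade_taxa <- select_abundant_clade(tree, pi)
      }
      idx <- match(clade_taxa, colnames(m))
      f <- 1 + effect_size * g
      m[, idx] <- matrix(sround(m[, idx] * f), nrow(m), length(idx))
    } else {
      if (ncol(m) < 40) stop("P3 requires at least 40 taxa")
      rare <- order(pi)[1:40]
      idx <- sample(rare, 5)
      a <- effect_size * g
      m[, idx] <- matrix(sround(m[, idx] + a), nrow(m), length(idx))
    }
    if (!is.null(depth)) m <- rarefy_rows(m, depth)
    count_table(m)
  })
}

# ---- experiment engine ----------------------------------------------------

sim_kernel_names <- c("bray_curtis", "unweighted_unifrac", "weighted_unifrac",
                      "generalized_unifrac", "clr_linear", "philr_linear")

# Fixed, seed-derived experiment context: taxon profile, phylogeny, edge
# structures, ILR basis and the P2 clade.
sim_setup <- function(q, theta, sdlog, alpha_gunifrac, seed) {
  with_seed(seed, {
    params <- synthesize_dm_params(q = q, theta = theta, sdlog = sdlog)
    tree <- simulate_taxon_tree(names(params$pi))
    edges <- tree_edge_structure(tree, names(params$pi))
    basis <- tree_ilr_basis(tree, names(params$pi))
    clade <- tryCatch(select_abundant_clade(tree, params$pi),
                      error = function(e) NULL)
    list(params = params, tree = tree, edges = edges, basis = basis,
         clade = clade, alpha = alpha_gunifrac,
         common_rank = order(params$pi, decreasing = TRUE),
         rare40 = order(params$pi)[1:40])
  })
}

gower_psd_eig <- function(D, need_score = FALSE) {
  D2 <- D * D
  rm <- rowMeans(D2)
  L <- -0.5 * (D2 - outer(rm, rm, "+") + mean(D2))
  eg <- eigen(L, symmetric = TRUE)
  lam <- eg$values
  lam[lam < 1e-8 * max(lam, 0)] <- 0
  K <- eg$vectors %*% (lam * t(eg$vectors))
  list(K = K, score = if (need_score) eg$vectors[, 1] * sqrt(lam[1]) else NULL)
}

top_kernel_score <- function(K) {
  eg <- eigen(center_mat(K), symmetric = TRUE)
  eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
}

# All six microbiome kernels from one replicate's (rarefied) table. The
# log-ratio kernels also use the rarefied counts: with a pseudo-count the
# CLR is not depth-invariant, so building it on unrarefied counts would
# let sequencing-depth differences leak into the kernel.
sim_kernels <- function(rarefied, setup, need_scores = FALSE) {
  rel <- rarefied / rowSums(rarefied)
  P <- as.matrix(rel %*% setup$edges$incidence)
  bl <- setup$edges$branch_length
  D_bc <- bray_curtis_cpp(t(rarefied))
  wg <- unifrac_pairwise_cpp(t(P), bl, setup$alpha)
  D_uw <- wg$unweighted
  zc <- log(rarefied + 1)
  zc <- zc - rowMeans(zc)
  K_clr <- tcrossprod(zc)
  zp <- log(rarefied + 1) %*% setup$basis$contrast
  zp <- zp * rep(setup$basis$blw, each = nrow(zp))
  K_philr <- tcrossprod(zp)
  g_bc <- gower_psd_eig(D_bc, need_scores)
  g_uw <- gower_psd_eig(D_uw, need_scores)
  g_w <- gower_psd_eig(wg$weighted, need_scores)
  g_g <- gower_psd_eig(wg$generalized, need_scores)
  kernels <- list(bray_curtis = g_bc$K, unweighted_unifrac = g_uw$K,
                  weighted_unifrac = g_w$K, generalized_unifrac = g_g$K,
                  clr_linear = K_clr, philr_linear = K_philr)
  scores <- if (need_scores)
    list(bray_curtis = g_bc$score, unweighted_unifrac = g_uw$score,
         weighted_unifrac = g_w$score, generalized_unifrac = g_g$score,
         clr_linear = top_kernel_score(K_clr),
         philr_linear = top_kernel_score(K_philr))
  else NULL
  list(kernels = kernels, scores = scores)
}

top_genotype_pc <- function(G) {
  mu <- colMeans(G)
  v <- colMeans(G * G) - mu * mu
  keep <- v > 0
  Z <- (G[, keep, drop = FALSE] - rep(mu[keep], each = nrow(G))) /
    rep(sqrt(v[keep]), each = nrow(G))
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  eg$vectors[, 1]
}

# One replicate: returns a named p-value vector or NULL on failure.
sim_replicate <- function(setup, scenario, effect_size, n_per_pop, n_variants,
                          region_length, subregion_length, fst, depth,
                          rep_seed) {
  set.seed(rep_seed)
  n <- 2 * n_per_pop
  pop <- rep(c("A", "B"), each = n_per_pop)
  Gm <- simulate_genotypes(n_per_pop, n_variants, region_length, fst)
  G <- Gm$dosages
  pos <- Gm$variants$pos
  maf <- fold_maf(G)
  sub_lo <- (region_length - subregion_length) / 2
  sub_idx <- which(pos > sub_lo & pos <= sub_lo + subregion_length & maf >= 0.05)
  if (length(sub_idx) == 0) return(NULL)
  power <- scenario %in% c("P1", "P2", "P3")
  causal <- NULL
  if (power) {
    causal <- sub_idx[order(abs(maf[sub_idx] - 0.3), pos[sub_idx])][1]
  }
  pc1 <- top_genotype_pc(G)
  X <- cbind(1, pc1)
  design <- covariate_design(X)

  raw0 <- dm_counts_matrix(setup$params$pi, setup$params$theta, n, depth)
  # confounding (T1 base for power scenarios), no intermediate rarefaction
  conf_scen <- if (power) "T1" else scenario
  pi <- setup$params$pi
  m <- raw0
  if (conf_scen == "T1") {
    idx <- setup$common_rank[1:10]
    affected <- pop == "A"
    m[affected, idx] <- matrix(sround(m[affected, idx] * 1.10),
                               sum(affected), length(idx))
  } else {
    idx <- sample(setup$rare40, 10)
    m[pop == "A", idx] <- m[pop == "A", idx] + 1
  }
  if (power) {
    g <- G[, causal]
    if (scenario == "P1") {
      idx <- setup$common_rank[11:20]
      m[, idx] <- matrix(sround(m[, idx] * (1 + effect_size * g)),
                         n, length(idx))
    } else if (scenario == "P2") {
      if (is.null(setup$clade)) stop("no abundant clade available for P2")
      idx <- match(setup$clade, colnames(m))
      m[, idx] <- matrix(sround(m[, idx] * (1 + effect_size * g)),
                         n, length(idx))
    } else {
      idx <- sample(setup$rare40, 5)
      m[, idx] <- matrix(sround(m[, idx] + effect_size * g), n, length(idx))
    }
  }
  rarefied <- rarefy_rows(m, depth)

  kk <- sim_kernels(rarefied, setup, need_scores = power)
  Kg <- tcrossprod(G[, sub_idx, drop = FALSE])

  out <- c()
  if (!power) {
    Ku <- center_mat(Kg)
    Ka <- project_out(Kg, design)
    Au <- Ku / sqrt(frob2(Ku)); iau <- krv_invariants(Au)
    Aa <- Ka / sqrt(frob2(Ka)); iaa <- krv_invariants(Aa)
    for (k in sim_kernel_names) {
      L <- kk$kernels[[k]]
      Lu <- if (k %in% c("clr_linear", "philr_linear")) center_mat(L) else L
      Wu <- Lu / sqrt(frob2(Lu))
      p_u <- pearson3_upper(sum(Au * Wu),
                            krv_perm_moments(iau, krv_invariants(Wu)))
      La <- project_out(L, design)
      Wa <- La / sqrt(frob2(La))
      p_a <- pearson3_upper(sum(Aa * Wa),
                            krv_perm_moments(iaa, krv_invariants(Wa)))
      out[paste0("unadjusted.", k)] <- p_u
      out[paste0("adjusted.", k)] <- p_a
    }
  } else {
    Ka <- project_out(Kg, design)
    Aa <- Ka / sqrt(frob2(Ka)); iaa <- krv_invariants(Aa)
    x_geno <- top_kernel_score(Kg)
    for (k in sim_kernel_names) {
      L <- kk$kernels[[k]]
      La <- project_out(L, design)
      Wa <- La / sqrt(frob2(La))
      out[paste0("krv.", k)] <-
        pearson3_upper(sum(Aa * Wa), krv_perm_moments(iaa, krv_invariants(Wa)))
      fit <- summary(lm(kk$scores[[k]] ~ x_geno + pc1))
      out[paste0("lm.", k)] <- fit$coefficients["x_geno", "Pr(>|t|)"]
    }
  }
  out
}

run_experiment <- function(scenario, effect_size, n_reps, n_per_pop, q, depth,
                           theta, sdlog, n_variants, region_length,
                           subregion_length, fst, alpha_gunifrac, seed,
                           verbose) {
  setup <- sim_setup(q, theta, sdlog, alpha_gunifrac, seed)
  rep_seeds <- with_seed(seed + 1, sample.int(.Machine$integer.max - 1, n_reps))
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    p <- tryCatch(
      sim_replicate(setup, scenario, effect_size, n_per_pop, n_variants,
                    region_length, subregion_length, fst, depth, rep_seeds[r]),
      error = function(e) NULL)
    if (is.null(p)) n_failed <- n_failed + 1L else rows[[r]] <- p
    if (verbose && r %% 100 == 0)
      message(sprintf("%s: replicate %d/%d", scenario, r, n_reps))
  }
  pmat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(pvalues = pmat, n_failed = n_failed, setup = setup)
}

#' Type-I-error experiment under population-stratified confounding
#'
#' Per replicate: simulate two-population genotypes and
#' Dirichlet-multinomial taxon counts, inject the confounding scenario,
#' build all six microbiome kernels from the re-rarefied table (the
#' log-ratio kernels use a unit pseudo-count; rarefying first keeps
#' population-correlated sequencing depth out of the CLR, which is not
#' depth-invariant once a pseudo-count is added) and the
#' linear genotype kernel on the common variants of the central test
#' subregion, then run both the unadjusted and the adjusted KRV test (the
#' covariate being the top genotype principal component). Rejection
#' proportions are tabulated at each `alphas` level.
#'
#' @param scenario `"T1"` (common-taxon confounding) or `"T2"`
#'   (rare-taxon confounding).
#' @param n_reps number of replicates (default 10000).
#' @param n_per_pop individuals per population (default 500).
#' @param q,depth,theta,sdlog taxon profile parameters.
#' @param n_variants,region_length,subregion_length,fst genotype region
#'   parameters.
#' @param alpha_gunifrac generalized UniFrac exponent.
#' @param alphas nominal levels for the rejection table.
#' @param seed master seed (drives everything).
#' @param verbose print progress.
#' @return a `krv_sim` list: `rejections` (method x kernel x alpha data
#'   frame), `pvalues` (replicates x test matrix), `n_failed`, `config`.
#' @export
run_type1_experiment <- function(scenario = c("T1", "T2"), n_reps = 10000,
                                 n_per_pop = 500, q = 856, depth = 1000,
                                 theta = 0.01, sdlog = 2.5,
                                 n_variants = 1000, region_length = 1e6,
                                 subregion_length = 8000, fst = 0.1,
                                 alpha_gunifrac = 0.5,
                                 alphas = c(0.05, 0.01, 0.001), seed = 1,
                                 verbose = FALSE) {
  scenario <- match.arg(scenario)
  res <- run_experiment(scenario, NULL, n_reps, n_per_pop, q, depth, theta,
                        sdlog, n_variants, region_length, subregion_length,
                        fst, alpha_gunifrac, seed, verbose)
  grid <- expand.grid(method = c("unadjusted", "adjusted"),
                      kernel = sim_kernel_names, alpha = alphas,
                      stringsAsFactors = FALSE)
  grid$rejection_rate <- mapply(function(m, k, a) {
    mean(res$pvalues[, paste0(m, ".", k)] < a)
  }, grid$method, grid$kernel, grid$alpha)
  grid$n_reps <- nrow(res$pvalues)
  structure(list(scenario = scenario, rejections = grid,
                 pvalues = res$pvalues, n_failed = res$n_failed,
                 config = list(n_per_pop = n_per_pop, q = q, depth = depth,
                               theta = theta, n_variants = n_variants,
                               seed = seed)),
            class = "krv_sim")
}

#' Power experiment with a pleiotropic causal SNP
#'
#' Builds on the common-taxon confounding scenario and adds a genetic
#' effect of a chosen common subregion SNP (folded MAF closest to 0.3) on
#' groups of taxa: common taxa (`"P1"`), an abundant phylogenetic clade
#' (`"P2"`), or rare taxa (`"P3"`). Methods compared per microbiome
#' kernel: the covariate-adjusted KRV and linear regression of the top
#' microbiome kernel PC on the top genotype kernel PC (covariate-adjusted
#' two-sided t-test).
#'
#' @inheritParams run_type1_experiment
#' @param scenario `"P1"`, `"P2"` or `"P3"`.
#' @param effect_set `"small"` (`c1 = c2 = 0.3, c3 = 0.5`) or `"large"`
#'   (`c1 = 0.8, c2 = 0.7, c3 = 1`).
#' @param alpha nominal level for power (default 0.05).
#' @return a `krv_sim` list with the power table (`method` x `kernel`).
#' @export
run_power_experiment <- function(scenario = c("P1", "P2", "P3"),
                                 effect_set = c("small", "large"),
                                 n_reps = 1000, alpha = 0.05,
                                 n_per_pop = 500, q = 856, depth = 1000,
                                 theta = 0.01, sdlog = 2.5,
                                 n_variants = 1000, region_length = 1e6,
                                 subregion_length = 8000, fst = 0.1,
                                 alpha_gunifrac = 0.5, seed = 1,
                                 verbose = FALSE) {
  scenario <- match.arg(scenario)
  effect_set <- match.arg(effect_set)
  eff <- effect_sizes(effect_set)[[scenario]]
  res <- run_experiment(scenario, eff, n_reps, n_per_pop, q, depth, theta,
                        sdlog, n_variants, region_length, subregion_length,
                        fst, alpha_gunifrac, seed, verbose)
  grid <- expand.grid(method = c("krv", "lm"), kernel = sim_kernel_names,
                      stringsAsFactors = FALSE)
  grid$power <- mapply(function(m, k) {
    mean(res$pvalues[, paste0(m, ".", k)] < alpha)
  }, grid$method, grid$kernel)
  grid$n_reps <- nrow(res$pvalues)
  structure(list(scenario = scenario, effect_set = effect_set,
                 effect_size = eff, alpha = alpha, power = grid,
                 pvalues = res$pvalues, n_failed = res$n_failed,
                 config = list(n_per_pop = n_per_pop, q = q, depth = depth,
                               theta = theta, seed = seed)),
            class = "krv_sim")
}

effect_sizes <- function(set = c("small", "large")) {
  set <- match.arg(set)
  if (set == "small") list(P1 = 0.3, P2 = 0.3, P3 = 0.5)
  else list(P1 = 0.8, P2 = 0.7, P3 = 1)
}

#' @export
print.krv_sim <- function(x, ...) {
  cat(sprintf("krv_sim: scenario %s, %d replicates kept, %d failed\n",
              x$scenario, nrow(x$pvalues), x$n_failed))
  print(if (!is.null(x$rejections)) x$rejections else x$power)
  invisible(x)
}
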