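test_that("two-population genotypes show (only) the intended stratification", {
  G0 <- simulate_genotypes(n_per_pop = 150, n_variants = 300, fst = 0,
                           seed = 1)
  pop <- attr(G0, "population")
  afA <- colMeans(G0$dosages[pop == "A", ]) / 2
  afB <- colMeans(G0$dosages[pop == "B", ]) / 2
  expect_lt(mean(abs(afA - afB)), 0.05)   # no differentiation limit

  G1 <- simulate_genotypes(n_per_pop = 150, n_variants = 300, fst = 0.1,
                           seed = 2)
  pc1 <- krvgwas:::top_genotype_pc(G1$dosages)
  pop1 <- attr(G1, "population")
  between <- (mean(pc1[pop1 == "A"]) - mean(pc1[pop1 == "B"]))^2
  within <- var(pc1[pop1 == "A"]) + var(pc1[pop1 == "B"])
  expect_gt(between, within)              # top PC separates the populations

  expect_identical(simulate_genotypes(20, 50, seed = 3)$dosages,
                   simulate_genotypes(20, 50, seed = 3)$dosages)
  expect_error(simulate_genotypes(1), "at least 2")
})

test_that("dirichlet-multinomial generation matches its target moments", {
  params <- synthesize_dm_params(q = 50, theta = 0.02, seed = 4)
  expect_equal(sum(params$pi), 1)
  expect_true(all(diff(params$pi) <= 0))  # sorted decreasing

  ct <- simulate_otu_counts(params, n = 5000, depth = 400, seed = 5)
  expect_true(all(rowSums(ct) == 400))
  phat <- colMeans(unclass(ct)) / 400
  # mean proportions recover pi (law of large numbers)
  expect_lt(max(abs(phat - params$pi)), 0.01)

  # method-of-moments estimation recovers theta within 20 percent
  est <- estimate_dm_params(ct)
  expect_lt(abs(est$theta - 0.02) / 0.02, 0.2)
  expect_lt(max(abs(est$pi - params$pi)), 0.01)

  # overdispersion: larger theta inflates the top taxon's variance,
  # approaching the multinomial variance as theta -> 0
  p_top <- params$pi[1]
  v_mult <- 400 * p_top * (1 - p_top)
  v_small <- var(unclass(simulate_otu_counts(
    structure(list(pi = params$pi, theta = 1e-4), class = "dm_params"),
    n = 2000, depth = 400, seed = 6))[, 1])
  v_big <- var(unclass(simulate_otu_counts(
    structure(list(pi = params$pi, theta = 0.1), class = "dm_params"),
    n = 2000, depth = 400, seed = 7))[, 1])
  expect_lt(abs(v_small - v_mult) / v_mult, 0.15)
  expect_gt(v_big, 2 * v_mult)
  expect_error(estimate_dm_params(count_table(matrix(0, 3, 4))), "all-zero")
})

test_that("confounding scenarios perturb the intended taxa only", {
  params <- synthesize_dm_params(q = 60, theta = 0.02, seed = 8)
  ct <- simulate_otu_counts(params, n = 40, depth = 500, seed = 9)
  pop <- rep(c("A", "B"), each = 20)

  # before re-rarefaction, population B rows are untouched
  t1 <- apply_confounding(ct, pop, "T1", params$pi, depth = NULL, seed = 10)
  expect_equal(unclass(t1)[pop == "B", ], unclass(ct)[pop == "B", ])
  common10 <- order(params$pi, decreasing = TRUE)[1:10]
  others <- setdiff(seq_len(60), common10)
  expect_equal(unclass(t1)[, others], unclass(ct)[, others])
  # multiplied taxa do not change presence (they were already present)
  expect_equal(unclass(t1)[, common10] > 0, unclass(ct)[, common10] > 0)
  # and on average gain about 10 percent in population A
  gain <- sum(unclass(t1)[pop == "A", common10]) /
    sum(unclass(ct)[pop == "A", common10])
  expect_lt(abs(gain - 1.10), 0.02)

  t1r <- apply_confounding(ct, pop, "T1", params$pi, depth = 500, seed = 10)
  expect_true(all(rowSums(t1r) == 500))

  # T2 turns some zero cells of rare taxa positive in population A
  t2 <- apply_confounding(ct, pop, "T2", params$pi, depth = NULL, seed = 11)
  changed <- which(unclass(t2) != unclass(ct), arr.ind = TRUE)
  expect_true(all(changed[, 1] <= 20))
  rare40 <- order(params$pi)[1:40]
  expect_true(all(changed[, 2] %in% rare40))
  expect_gt(sum(unclass(ct)[changed] == 0), 0)
  expect_error(apply_confounding(simulate_otu_counts(
    synthesize_dm_params(q = 20, seed = 1), 4, 100, seed = 1),
    rep(c("A", "B"), 2), "T2", rep(1 / 20, 20)), "40 taxa")
})

test_that("genetic effects follow the multiplicative/additive rules", {
  params <- synthesize_dm_params(q = 60, theta = 0.02, seed = 12)
  ct <- simulate_otu_counts(params, n = 30, depth = 500, seed = 13)
  g <- rep(c(0, 1, 2), each = 10)

  p1 <- apply_genetic_effect(ct, g, "P1", effect_size = 0.3, pi = params$pi,
                             depth = NULL, seed = 14)
  expect_equal(unclass(p1)[g == 0, ], unclass(ct)[g == 0, ])
  idx <- order(params$pi, decreasing = TRUE)[11:20]
  # g = 2, c1 = 0.3: factor 1.6 in expectation (stochastic rounding)
  ratio <- sum(unclass(p1)[g == 2, idx]) / sum(unclass(ct)[g == 2, idx])
  expect_lt(abs(ratio - 1.6), 0.05)

  p3 <- apply_genetic_effect(ct, g, "P3", effect_size = 1, pi = params$pi,
                             depth = NULL, seed = 15)
  added <- unclass(p3) - unclass(ct)
  expect_true(all(added[g == 0, ] == 0))
  expect_equal(unname(rowSums(added)), 5 * g)   # a_i = c3 g_i on 5 taxa

  tree <- simulate_taxon_tree(names(params$pi), seed = 16)
  clade <- select_abundant_clade(tree, params$pi)
  expect_gte(length(clade), 2)
  expect_gte(sum(params$pi[clade]), 0.05)
  expect_lte(sum(params$pi[clade]), 0.2)
  p2 <- apply_genetic_effect(ct, g, "P2", effect_size = 0.7, pi = params$pi,
                             tree = tree, depth = NULL, seed = 17)
  untouched <- setdiff(colnames(ct), clade)
  expect_equal(unclass(p2)[, untouched], unclass(ct)[, untouched])
})

test_that("experiment drivers are reproducible and honest about failures", {
  r1 <- run_type1_experiment("T1", n_reps = 8, n_per_pop = 25, q = 60,
                             depth = 300, n_variants = 150,
                             region_length = 2e5, subregion_length = 8000,
                             seed = 19)
  r2 <- run_type1_experiment("T1", n_reps = 8, n_per_pop = 25, q = 60,
                             depth = 300, n_variants = 150,
                             region_length = 2e5, subregion_length = 8000,
                             seed = 19)
  expect_identical(r1$pvalues, r2$pvalues)
  expect_true(all(r1$pvalues > 0 & r1$pvalues <= 1))
  expect_equal(nrow(r1$pvalues) + r1$n_failed, 8)

  pw <- run_power_experiment("P1", "large", n_reps = 6, n_per_pop = 25,
                             q = 60, depth = 300, n_variants = 150,
                             region_length = 2e5, subregion_length = 8000,
                             seed = 20)
  expect_equal(ncol(pw$pvalues), 12)   # 2 methods x 6 kernels
  expect_equal(pw$effect_size, 0.8)
})
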