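# Weir-Cockerham F_ST, pairwise matrices, AMOVA, spectrum summaries.

test_that("per-locus F_ST behaves at the no-differentiation and fixation poles", {
  # identical frequencies and sizes: theta near zero (small negative allowed)
  d <- rbind(rep(c(0L, 1L, 2L, 1L), 10))
  g <- genotype_matrix(d)
  labs <- rep(c("A", "B"), each = 20)
  res <- wc_fst_per_locus(g, labs)
  expect_true(abs(res$fst) < 0.05)

  # fixed difference, no heterozygotes: theta = 1
  d <- rbind(c(rep(0L, 10), rep(2L, 10)))
  res <- wc_fst_per_locus(genotype_matrix(d), rep(c("A", "B"), each = 10))
  expect_equal(res$fst, 1)

  # monomorphic locus flagged undefined
  d <- rbind(rep(0L, 20), c(rep(0L, 10), rep(2L, 10)))
  res <- wc_fst_per_locus(genotype_matrix(d), rep(c("A", "B"), each = 10))
  expect_false(res$defined[1])
  expect_true(res$defined[2])
})

test_that("per-locus components match the scalar oracle on random fixtures", {
  set.seed(42)
  for (rep_i in 1:5) {
    d <- matrix(sample(0:2, 3 * 18, replace = TRUE), 3, 18)
    labs <- rep(c("A", "B", "C"), each = 6)
    res <- wc_fst_per_locus(genotype_matrix(d), labs)
    for (l in 1:3) {
      o <- wc_oracle_locus(d[l, ], labs)
      if (!res$defined[l]) next
      expect_equal(res$a[l], o$a, tolerance = 1e-10)
      expect_equal(res$b[l], o$b, tolerance = 1e-10)
      expect_equal(res$c[l], o$c, tolerance = 1e-10)
      expect_equal(res$fst[l], o$fst, tolerance = 1e-10)
    }
  }
})

test_that("F_ST is invariant to allele relabeling and identical-group swaps", {
  set.seed(7)
  d <- matrix(sample(0:2, 5 * 30, replace = TRUE), 5, 30)
  labs <- rep(c("A", "B", "C"), each = 10)
  res1 <- wc_fst_per_locus(genotype_matrix(d), labs)
  res2 <- wc_fst_per_locus(genotype_matrix(2L - d), labs)  # swap alleles
  expect_equal(res1$fst, res2$fst, tolerance = 1e-12)
  labs2 <- rep(c("C", "A", "B"), each = 10)                # relabel groups
  res3 <- wc_fst_per_locus(genotype_matrix(d), labs2)
  expect_equal(res1$fst, res3$fst, tolerance = 1e-12)
})

test_that("multilocus F_ST is the ratio of summed components", {
  sim <- small_sim(55, n_variants = 50, n_per_pop = 15)
  res <- wc_fst_per_locus(sim$genotypes, sim$manifest$group)
  ml <- multilocus_fst(res)
  ok <- res$defined
  expect_equal(ml$fst,
               sum(res$a[ok]) / sum(res$a[ok] + res$b[ok] + res$c[ok]),
               tolerance = 1e-12)
  # single locus reduces to that locus
  one <- res[which(ok)[1], ]
  expect_equal(multilocus_fst(one)$fst, one$fst)
  # identical loci give the common value
  same <- res[rep(which(ok)[1], 4), ]
  expect_equal(multilocus_fst(same)$fst, one$fst)
  expect_error(multilocus_fst(res[0, ]), "no defined loci")
})

test_that("pairwise matrices are symmetric with zero diagonal and honest p-values", {
  sim <- small_sim(66, n_variants = 80, n_per_pop = 20, f_groups = 0.15)
  pw <- pairwise_fst(sim$genotypes, sim$manifest, "population",
                     n_permutations = 99, seed = 4)
  expect_equal(pw$fst, t(pw$fst))
  expect_equal(unname(diag(pw$fst)), rep(0, 4))
  expect_true(all(pw$p_value >= 1 / 100, na.rm = TRUE))

  # a unit split at random: fst ~ 0, large p
  man <- sim$manifest
  man$population <- rep("X", nrow(man))
  man$population[sample(nrow(man), nrow(man) / 2)] <- "Y"
  man$group <- "G"
  class(man) <- c("sample_manifest", "data.frame")
  pw0 <- pairwise_fst(sim$genotypes, man, "population",
                      n_permutations = 199, seed = 5)
  expect_lt(abs(pw0$fst["X", "Y"]), 0.01)
  expect_gt(pw0$p_value["X", "Y"], 0.05)

  expect_error(pairwise_fst(sim$genotypes, sim$manifest, "group",
                            n_permutations = 10), "seed")
})

test_that("pairwise F_ST recovers the generating differentiation", {
  cfg <- simulation_config(seed = 12, n_variants = 500,
                           hierarchy = list(A = c(P1 = 100), B = c(P2 = 100)),
                           f_between_groups = 0.2, f_within_groups = 0,
                           rare_fraction = 0, category_spec = NULL, n_index = 0)
  sim <- simulate_balding_nichols(cfg)
  pw <- pairwise_fst(sim$genotypes, sim$manifest, "group", n_permutations = 0)
  expect_lt(abs(unname(pw$fst["A", "B"]) - 0.2), 0.03)
})

test_that("AMOVA components match the sums-of-squares oracle", {
  set.seed(99)
  d <- matrix(sample(0:2, 20 * 80, replace = TRUE), 20, 80)
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 20)
  groups <- rep(c("G1", "G2"), each = 40)
  man <- sample_manifest(paste0("s", 1:80), pops, groups)
  colnames(d) <- man$sample
  am <- amova(genotype_matrix(d), man, n_permutations = 0)
  o <- amova_oracle(d, pops, groups)
  expect_equal(am$sigma2_a, unname(o["a"]), tolerance = 1e-10)
  expect_equal(am$sigma2_b, unname(o["b"]), tolerance = 1e-10)
  expect_equal(am$sigma2_c, unname(o["c"]), tolerance = 1e-10)
  expect_equal(unname(am$phi["phi_st"]),
               (am$sigma2_a + am$sigma2_b) /
                 (am$sigma2_a + am$sigma2_b + am$sigma2_c), tolerance = 1e-12)
})

test_that("AMOVA poles: panmixia gives phi near 0, fixed groups give phi_ct near 1", {
  # all populations drawn from one pool
  sim <- small_sim(3, n_variants = 120, n_per_pop = 20, f_groups = 0, f_pops = 0)
  am <- amova(sim$genotypes, sim$manifest, n_permutations = 199, seed = 8)
  expect_lt(abs(am$phi["phi_st"]), 0.02)
  expect_gt(am$p_value["phi_st"], 0.05)

  # groups fixed for alternative alleles, populations identical within group
  d <- cbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  pops <- rep(c("P1", "P2", "P3", "P4"), each = 10)
  groups <- rep(c("G1", "G2"), each = 20)
  man <- sample_manifest(paste0("s", 1:40), pops, groups)
  colnames(d) <- man$sample
  am2 <- amova(genotype_matrix(d), man, n_permutations = 0)
  expect_equal(unname(am2$phi["phi_ct"]), 1, tolerance = 1e-12)
  expect_equal(unname(am2$phi["phi_sc"]), 0, tolerance = 1e-12)
})

test_that("one population per group reduces AMOVA to the two-level case", {
  cfg <- simulation_config(seed = 21, n_variants = 400,
                           hierarchy = list(A = c(P1 = 80), B = c(P2 = 80)),
                           f_between_groups = 0.1, f_within_groups = 0,
                           rare_fraction = 0, category_spec = NULL, n_index = 0)
  sim <- simulate_balding_nichols(cfg)
  am <- amova(sim$genotypes, sim$manifest, n_permutations = 0)
  pw <- pairwise_fst(sim$genotypes, sim$manifest, "group", n_permutations = 0)
  expect_equal(unname(am$phi["phi_ct"]), unname(pw$fst["A", "B"]),
               tolerance = 0.02)
})

test_that("F_ST spectrum summary matches independent recomputation", {
  res <- data.frame(id = 1:3, a = 1, b = 1, c = 1,
                    fst = c(0.0, 0.05, 0.2), fis = 0,
                    defined = TRUE)
  s <- fst_spectrum_summary(res)
  expect_equal(s$median_fst, 0.05)
  expect_equal(s$fraction_below, 2 / 3)

  res2 <- res; res2$fst <- rep(0.2, 3)
  s2 <- fst_spectrum_summary(res2)
  expect_equal(s2$median_fst, 0.2)
  expect_equal(s2$fraction_below, 0)

  set.seed(10)
  f <- runif(1000)
  res3 <- data.frame(id = seq_along(f), a = 1, b = 1, c = 1, fst = f, fis = 0,
                     defined = TRUE)
  s3 <- fst_spectrum_summary(res3, threshold = 0.3)
  expect_equal(s3$median_fst, sort(f)[500:501] |> mean())
  expect_equal(s3$fraction_below, mean(f < 0.3))
})
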