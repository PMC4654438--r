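# LD estimation (phased counts and EM), tag binning, surrogate discovery.

test_that("haplotype LD hits the perfect-LD and equilibrium poles", {
  a <- rep(c(0L, 1L), 20)
  expect_equal(haplotype_ld(a, a)$r2, 1)
  # all four haplotypes at equal count -> r2 = 0
  hA <- c(0L, 0L, 1L, 1L); hB <- c(0L, 1L, 0L, 1L)
  expect_equal(haplotype_ld(rep(hA, 5), rep(hB, 5))$r2, 0)
  mono <- haplotype_ld(rep(0L, 10), rep(c(0L, 1L), 5))
  expect_false(mono$defined)
})

test_that("haplotype r2 equals squared Pearson correlation of indicators", {
  set.seed(31)
  for (i in 1:10) {
    a <- rbinom(40, 1, 0.4); b <- rbinom(40, 1, 0.6)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(haplotype_ld(a, b)$r2, cor(a, b)^2, tolerance = 1e-12)
  }
})

test_that("D-prime is 1 for never-recombined alleles and bounded in [0,1]", {
  # perfect coupling absence of 1-0 haplotype -> D' = 1 even when r2 < 1
  a <- c(rep(1L, 5), rep(0L, 15))
  b <- c(rep(1L, 10), rep(0L, 10))
  ld <- haplotype_ld(a, b)
  expect_equal(ld$d_prime, 1)
  expect_lt(ld$r2, 1)
  set.seed(13)
  for (i in 1:10) {
    a <- rbinom(60, 1, 0.5); b <- rbinom(60, 1, 0.5)
    ld <- haplotype_ld(a, b)
    if (!ld$defined) next
    expect_gte(ld$d_prime, 0); expect_lte(ld$d_prime, 1)
  }
})

test_that("EM haplotype frequencies are exact without double heterozygotes", {
  dosA <- c(0L, 2L, 0L, 2L, 1L, 0L)
  dosB <- c(0L, 2L, 2L, 0L, 0L, 1L)
  em <- em_haplotype_freqs(dosA, dosB)
  expect_true(em$converged)
  expect_equal(sum(em$freqs), 1)
  # count haplotypes by hand: unambiguous resolution
  expect_equal(unname(em$freqs["h11"]), 2 / 12)
  expect_equal(unname(em$freqs["h00"]), 4 / 12)
  # EM equals phased counting exactly in this unambiguous case
  hapA <- c(0,0, 1,1, 0,0, 1,1, 1,0, 0,0)
  hapB <- c(0,0, 1,1, 1,1, 0,0, 0,0, 1,0)
  expect_equal(unname(em$freqs["h11"]), mean(hapA == 1 & hapB == 1))
})

test_that("all-double-heterozygote symmetric case settles at 0.25 each", {
  em <- em_haplotype_freqs(rep(1L, 50), rep(1L, 50))
  expect_equal(unname(em$freqs), rep(0.25, 4), tolerance = 1e-6)
})

test_that("EM r2 from collapsed dosages tracks phased-count r2", {
  sim <- small_sim(202, n_variants = 30, n_per_pop = 50, f_groups = 0)
  g <- sim$genotypes
  af <- allele_frequencies(g)
  common <- which(af$maf >= 0.1)[1:6]
  for (i in seq_along(common)) for (j in seq_len(i - 1)) {
    vi <- common[i]; vj <- common[j]
    ph <- haplotype_ld(c(g$hap1[vi, ], g$hap2[vi, ]),
                       c(g$hap1[vj, ], g$hap2[vj, ]))
    em <- em_ld(g$dosages[vi, ], g$dosages[vj, ])
    expect_equal(em$r2, ph$r2, tolerance = 0.02)
  }
})

test_that("ld_matrix pairs combinatorics and MAF filtering are right", {
  h1 <- rbind(c(0L,1L,0L,1L,0L,1L,0L,1L,0L,1L),
              c(0L,1L,0L,1L,0L,1L,0L,1L,0L,1L),
              c(1L,0L,1L,0L,1L,0L,1L,0L,1L,0L),
              rep(0L, 10))
  h2 <- h1
  h2[4, 1] <- 1L  # singleton: MAF 1/20 = 0.05 at threshold boundary? no: keep below
  v <- variant_table("1", c(100, 200, 300, 400), paste0("v", 1:4), "A", "G")
  g <- genotype_matrix(h1 + h2, h1, h2, phased = TRUE)
  pairs <- ld_matrix(g, v, maf_min = 0.10)
  expect_equal(nrow(pairs), 3)                 # 3 passing variants -> 3 pairs
  expect_false("v4" %in% c(pairs$id_a, pairs$id_b))
  expect_equal(sort(unique(c(pairs$id_a, pairs$id_b))), c("v1", "v2", "v3"))
  expect_equal(pairs$distance[pairs$id_a == "v1" & pairs$id_b == "v2"], 100)
  r12 <- pairs$r2[pairs$id_a == "v1" & pairs$id_b == "v2"]
  expect_equal(r12, 1)
})

test_that("block-structured simulation has higher within-block LD", {
  blocks <- data.frame(start = 1283287, end = 1313287, founders = 2)
  cfg <- simulation_config(seed = 61, n_variants = 200,
                           hierarchy = list(G = c(P = 60)),
                           f_between_groups = 0, f_within_groups = 0,
                           rare_fraction = 0, ld_blocks = blocks,
                           category_spec = NULL, n_index = 0)
  sim <- simulate_balding_nichols(cfg)
  pairs <- ld_matrix(sim$genotypes, sim$variants, maf_min = 0.05)
  within <- pairs$pos_a >= blocks$start & pairs$pos_b <= blocks$end
  outside <- pairs$pos_b < blocks$start | pairs$pos_a > blocks$end
  expect_gt(mean(pairs$r2[within], na.rm = TRUE) -
              mean(pairs$r2[outside], na.rm = TRUE), 0.3)
})

test_that("greedy tag binning handles the clique/independent/chain cases", {
  info <- data.frame(id = c("A", "B", "C"), maf = c(0.2, 0.3, 0.25),
                     pos = c(100, 200, 300))
  mk_pairs <- function(r_ab, r_bc, r_ac)
    data.frame(id_a = c("A", "B", "A"), id_b = c("B", "C", "C"),
               pos_a = c(100, 200, 100), pos_b = c(200, 300, 300),
               distance = c(100, 100, 200), r2 = c(r_ab, r_bc, r_ac),
               d_prime = 1, method = "phased-count")
  # clique: one bin of 3
  bins <- greedy_tag_selection(mk_pairs(1, 1, 1), info, r2_min = 0.8)
  expect_equal(length(unique(bins$bin)), 1)
  # independent: three singleton bins
  bins <- greedy_tag_selection(mk_pairs(0, 0, 0), info, r2_min = 0.8)
  expect_equal(length(unique(bins$bin)), 3)
  expect_equal(bins$tag, bins$id)
  # chain A-B, B-C strong, A-C weak: B tags all three
  bins <- greedy_tag_selection(mk_pairs(0.9, 0.9, 0.5), info, r2_min = 0.8)
  expect_equal(length(unique(bins$bin)), 1)
  expect_equal(unique(bins$tag), "B")
})

test_that("tag bins partition the variant set and respect the exhaustive minimum", {
  set.seed(44)
  hits <- 0; trials <- 12
  for (t in seq_len(trials)) {
    n <- 8
    ids <- paste0("v", 1:n)
    pos <- sort(sample(1000, n))
    cmb <- combn(n, 2)
    pairs <- data.frame(id_a = ids[cmb[1, ]], id_b = ids[cmb[2, ]],
                        pos_a = pos[cmb[1, ]], pos_b = pos[cmb[2, ]],
                        distance = abs(pos[cmb[2, ]] - pos[cmb[1, ]]),
                        r2 = runif(ncol(cmb)), d_prime = 1,
                        method = "phased-count")
    info <- data.frame(id = ids, maf = runif(n, 0.05, 0.5), pos = pos)
    bins <- greedy_tag_selection(pairs, info, r2_min = 0.7)
    # partition: every variant in exactly one bin
    expect_setequal(bins$id, ids)
    expect_false(anyDuplicated(bins$id) > 0)
    n_greedy <- length(unique(bins$bin))
    expect_lte(n_greedy, n)
    n_min <- min_tag_count(pairs, ids, 0.7)
    expect_gte(n_greedy, n_min)
    if (n_greedy == n_min) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})

test_that("surrogate filtering applies all three thresholds and sorts by r2", {
  info <- data.frame(id = c("idx", "a", "b", "c", "d"),
                     maf = c(0.02, 0.10, 0.20, 0.30, 0.02),
                     pos = c(1000, 51000, 251000, 61000, 71000))
  pairs <- data.frame(
    id_a = rep("idx", 4), id_b = c("a", "b", "c", "d"),
    pos_a = 1000, pos_b = info$pos[-1],
    distance = info$pos[-1] - 1000,
    r2 = c(0.7, 0.7, 0.65, 0.9), d_prime = 1, method = "phased-count")
  ss <- find_surrogates("idx", pairs, info)
  # a passes; b fails distance (250 kb); c passes; d fails MAF
  expect_equal(ss$surrogates$id, c("a", "c"))
  expect_equal(ss$n_surrogates, 2)
  expect_true(all(diff(ss$surrogates$r2) <= 0))
  # the index itself may be low-MAF
  expect_error(find_surrogates("nope", pairs, info), "absent")

  # monotone non-increasing count as r2_min rises
  counts <- sapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(r)
    find_surrogates("idx", pairs, info, r2_min = r)$n_surrogates)
  expect_true(all(diff(counts) <= 0))
})

test_that("surrogate counts in a high-LD block equal co-member counts", {
  blocks <- data.frame(start = 1280000, end = 1320000, founders = 2)
  cfg <- simulation_config(seed = 71, n_variants = 150,
                           hierarchy = list(G = c(P = 80)),
                           f_between_groups = 0, f_within_groups = 0,
                           rare_fraction = 0, ld_blocks = blocks,
                           category_spec = NULL, n_index = 0)
  sim <- simulate_balding_nichols(cfg)
  af <- allele_frequencies(sim$genotypes)
  info <- data.frame(id = af$id, maf = af$maf, pos = sim$variants$pos)
  in_block <- sim$variants$pos >= blocks$start & sim$variants$pos <= blocks$end
  idx <- sim$variants$id[in_block & af$maf >= 0.05][1]
  pairs <- ld_matrix(sim$genotypes, sim$variants, maf_min = 0)
  ss <- find_surrogates(idx, pairs, info)
  # every surrogate lies in the block (outside LD is background noise)
  expect_true(all(ss$surrogates$id %in% sim$variants$id[in_block]))
  expect_gt(ss$n_surrogates, 0)
})
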