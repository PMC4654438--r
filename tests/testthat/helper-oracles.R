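# Independent brute-force oracles used to cross-check the vectorized
# implementations. All are deliberately naive: scalar loops, direct
# textbook formulas, exhaustive enumeration.

# allele frequency by literally counting alleles one genotype at a time
naive_allele_freq <- function(dos) {
  alt <- 0L; tot <- 0L
  for (g in dos) {
    if (is.na(g)) next
    alt <- alt + g
    tot <- tot + 2L
  }
  if (tot == 0) return(c(x1 = NA_real_, x2 = NA_real_, n_chrom = 0))
  c(x1 = 1 - alt / tot, x2 = alt / tot, n_chrom = tot)
}

# nucleotide diversity as the average Hamming distance over all chromosome
# pairs (phased, complete data), per bp
pi_all_pairs <- function(hap1, hap2, L) {
  H <- rbind(t(hap1), t(hap2))   # chromosomes x loci
  n <- nrow(H)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(n, 2) / L
}

# Weir & Cockerham (1984) theta, one locus, scalar translation of the
# published component formulas with explicit per-population loops
wc_oracle_locus <- function(dos, labels) {
  labs <- unique(labels)
  n <- p <- h <- numeric(length(labs))
  for (k in seq_along(labs)) {
    d <- dos[labels == labs[k]]
    d <- d[!is.na(d)]
    n[k] <- length(d)
    p[k] <- sum(d) / (2 * length(d))
    h[k] <- sum(d == 1) / length(d)
  }
  r <- length(labs)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Three-level allele-frequency AMOVA oracle: sums of squares from explicit
# loops over gene copies, variance components by solving the expected-mean-
# square linear system with solve().
amova_oracle <- function(dos, pops, groups) {
  # per locus on expanded gene copies (a het contributes one 0 and one 1),
  # then summed over loci
  tot <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(nrow(dos))) {
    val <- c(); pp <- c(); gg <- c()
    for (s in seq_along(pops)) {
      g <- dos[l, s]
      if (is.na(g)) next
      two <- switch(as.character(g), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
      val <- c(val, two); pp <- c(pp, rep(pops[s], 2)); gg <- c(gg, rep(groups[s], 2))
    }
    N <- length(val)
    P <- length(unique(pp)); G <- length(unique(gg))
    gmean <- mean(val)
    ss_ag <- 0; ss_ap <- 0; ss_wp <- 0
    for (g in unique(gg)) {
      vg <- val[gg == g]
      ss_ag <- ss_ag + length(vg) * (mean(vg) - gmean)^2
      for (p in unique(pp[gg == g])) {
        vp <- val[pp == p & gg == g]
        ss_ap <- ss_ap + length(vp) * (mean(vp) - mean(vg))^2
        ss_wp <- ss_wp + sum((vp - mean(vp))^2)
      }
    }
    np <- sapply(unique(pp), function(p) sum(pp == p))
    names(np) <- unique(pp)
    ng <- sapply(unique(gg), function(g) sum(gg == g))
    names(ng) <- unique(gg)
    grp_of <- sapply(unique(pp), function(p) gg[pp == p][1])
    sum_np2_by_g <- sapply(unique(gg), function(g)
      sum(np[names(grp_of)[grp_of == g]]^2))
    n1 <- (N - sum(sum_np2_by_g / ng)) / (P - G)
    n2 <- (sum(sum_np2_by_g / ng) - sum(np^2) / N) / (G - 1)
    n3 <- (N - sum(ng^2) / N) / (G - 1)
    ms <- c(ss_ag / (G - 1), ss_ap / (P - G), ss_wp / (N - P))
    # E[MS] = M %*% sigma2 with sigma2 = (a, b, c)
    M <- rbind(c(n3, n2, 1),
               c(0, n1, 1),
               c(0, 0, 1))
    sig <- solve(M, ms)
    tot <- tot + c(a = sig[1], b = sig[2], c = sig[3])
  }
  tot
}

# Welch t from the textbook closed form
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# exhaustive minimum tag-set size: smallest k such that some k-subset covers
# every variant (a variant is covered if it is a tag or r2 >= r2_min with
# one); only feasible for <= ~10 variants
min_tag_count <- function(pairs, ids, r2_min) {
  n <- length(ids)
  cover <- diag(n) > 0
  for (k in seq_len(nrow(pairs))) {
    if (is.na(pairs$r2[k]) || pairs$r2[k] < r2_min) next
    i <- match(pairs$id_a[k], ids); j <- match(pairs$id_b[k], ids)
    cover[i, j] <- cover[j, i] <- TRUE
  }
  for (k in seq_len(n)) {
    subs <- combn(n, k)
    for (c_i in seq_len(ncol(subs)))
      if (all(colSums(cover[subs[, c_i], , drop = FALSE]) > 0)) return(k)
  }
  n
}

# small Balding-Nichols fixture
small_sim <- function(seed, n_variants = 100, n_per_pop = 25,
                      f_groups = 0.1, f_pops = 0, ...) {
  cfg <- simulation_config(
    seed = seed, n_variants = n_variants,
    hierarchy = list(G1 = c(P1 = n_per_pop, P2 = n_per_pop),
                     G2 = c(P3 = n_per_pop, P4 = n_per_pop)),
    f_between_groups = f_groups, f_within_groups = f_pops,
    rare_fraction = 0, category_spec = NULL, n_index = 0, ...)
  simulate_balding_nichols(cfg)
}
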