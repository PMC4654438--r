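# Weir-Cockerham F_ST (per locus, multilocus, pairwise) and hierarchical
# AMOVA, with permutation significance.

# Per-locus, per-group summaries from a dosage matrix: called diploids N,
# alt-allele frequency P, observed heterozygote frequency H. Groups with no
# called individual at a locus get N = 0 and P = H = NA.
.group_locus_summaries <- function(dos, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  L <- nrow(dos)
  N <- P <- H <- matrix(NA_real_, L, length(groups),
                        dimnames = list(NULL, groups))
  for (j in seq_along(groups)) {
    dg <- dos[, labels == groups[j], drop = FALSE]
    called <- !is.na(dg)
    n <- rowSums(called)
    N[, j] <- n
    P[, j] <- ifelse(n > 0, rowSums(dg, na.rm = TRUE) / (2 * n), NA_real_)
    H[, j] <- ifelse(n > 0, rowSums(dg == 1L, na.rm = TRUE) / n, NA_real_)
  }
  list(N = N, P = P, H = H, groups = groups)
}

# Weir & Cockerham (1984) variance components a (among groups), b (among
# individuals within groups), c (within individuals), vectorized over loci.
# N, P, H are loci x groups matrices of sample sizes (diploids), allele
# frequencies and observed heterozygote frequencies.
.wc_components <- function(N, P, H, min_per_group = 2) {
  use <- N >= min_per_group
  r <- rowSums(use)
  Nu <- ifelse(use, N, 0)
  Pu <- ifelse(use, P, 0)
  Hu <- ifelse(use, H, 0)

  n_tot <- rowSums(Nu)
  nbar <- n_tot / r
  nc <- (n_tot - rowSums(Nu^2) / n_tot) / (r - 1)
  pbar <- rowSums(Nu * Pu) / n_tot
  s2 <- rowSums(Nu * (Pu - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(Nu * Hu) / n_tot

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2

  mono <- pbar <= 0 | pbar >= 1
  bad <- r < 2 | nbar <= 1 | mono | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  list(a = a, b = b, c = c_, monomorphic = mono, n_groups_used = r)
}

#' Per-locus Weir-Cockerham F_ST among groups
#'
#' The Weir & Cockerham (1984) theta estimator computed per locus from group
#' sample sizes, allele frequencies and observed heterozygote counts,
#' decomposed into variance components `a` (among groups), `b` (among
#' individuals within groups) and `c` (within individuals);
#' `fst = a / (a + b + c)`. Negative estimates are retained, never clamped.
#' Loci monomorphic across all groups (or with fewer than 2 groups of at
#' least `min_per_group` called individuals) are flagged `NA` and excluded
#' downstream from medians and multilocus sums.
#'
#' @param geno a [genotype_matrix()].
#' @param labels per-sample group assignment (length = samples).
#' @param min_per_group minimum called individuals per group at a locus.
#' @return data.frame with columns `id`, `a`, `b`, `c`, `fst`, `fis`
#'   (`b / (b + c)`, the within-population fixation analog) and `defined`.
#' @export
wc_fst_per_locus <- function(geno, labels, min_per_group = 2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (length(labels) != geno$n_samples)
    stop("labels must have one entry per sample")
  gs <- .group_locus_summaries(geno$dosages, labels)
  if (length(gs$groups) < 2) stop("need at least 2 groups")
  wc <- .wc_components(gs$N, gs$P, gs$H, min_per_group)
  tot <- wc$a + wc$b + wc$c
  data.frame(id = rownames(geno$dosages) %||% as.character(seq_len(geno$n_variants)),
             a = wc$a, b = wc$b, c = wc$c,
             fst = wc$a / tot,
             fis = wc$b / (wc$b + wc$c),
             defined = !is.na(wc$a),
             stringsAsFactors = FALSE)
}

#' Multilocus F_ST from per-locus components
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` over defined loci
#' (the reported multilocus value), plus the simple mean of per-locus
#' estimates (used for per-category averages).
#'
#' @param results data.frame from [wc_fst_per_locus()].
#' @return list with `fst` (ratio of sums), `mean_fst`, `n_loci`.
#' @export
multilocus_fst <- function(results) {
  ok <- results$defined & !is.na(results$a)
  if (!any(ok)) stop("no defined loci")
  a <- results$a[ok]; tot <- a + results$b[ok] + results$c[ok]
  list(fst = sum(a) / sum(tot),
       mean_fst = mean(results$fst[ok]),
       n_loci = sum(ok))
}

# Multilocus two-group WC F_ST for many group assignments at once.
# dos: loci x samples; member: samples x assignments logical/0-1 matrix
# marking group-1 membership. Returns one ratio-of-sums fst per assignment.
.wc_two_group_multi <- function(dos, member) {
  called <- !is.na(dos)
  dos0 <- dos; dos0[!called] <- 0L
  het <- (dos == 1L); het[!called] <- FALSE
  storage.mode(member) <- "double"

  n1 <- called %*% member                    # called diploids in group 1
  alt1 <- dos0 %*% member
  h1 <- het %*% member
  n_all <- rowSums(called); alt_all <- rowSums(dos0); h_all <- rowSums(het)
  n2 <- n_all - n1; alt2 <- alt_all - alt1; h2 <- h_all - h1

  p1 <- alt1 / (2 * n1); p2 <- alt2 / (2 * n2)
  hf1 <- h1 / n1; hf2 <- h2 / n2
  r <- 2
  n_tot <- n1 + n2
  nbar <- n_tot / r
  nc <- (n_tot - (n1^2 + n2^2) / n_tot)   # /(r-1) with r=2 -> /1
  pbar <- (alt1 + alt2) / (2 * n_tot)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hf1 + n2 * hf2) / n_tot

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2

  bad <- pbar <= 0 | pbar >= 1 | n1 < 2 | n2 < 2 | !is.finite(nc) | nc <= 0
  a[bad] <- NA; b[bad] <- NA; c_[bad] <- NA
  tot <- a + b + c_
  colSums(a, na.rm = TRUE) / colSums(tot, na.rm = TRUE)
}

#' Pairwise F_ST matrix with permutation p-values
#'
#' Multilocus ratio-of-sums Weir-Cockerham F_ST for every pair of units
#' (populations or ancestral groups). Significance per pair comes from
#' permuting individuals between the two units (unit sizes preserved);
#' `p = (exceedances + 1) / (n_permutations + 1)`.
#'
#' @param geno a [genotype_matrix()].
#' @param manifest a [sample_manifest()] aligned with the matrix columns.
#' @param level `"population"` or `"group"`.
#' @param n_permutations permutations per pair (default 10000; 0 skips
#'   p-values).
#' @param seed integer seed, mandatory when permutations are requested.
#' @return list with symmetric matrices `fst` and `p_value`, plus
#'   `n_permutations`, `seed`, and `skipped` (units with < 2 individuals).
#' @export
pairwise_fst <- function(geno, manifest, level = c("population", "group"),
                         n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(manifest, "sample_manifest"))
  level <- match.arg(level)
  if (n_permutations > 0 && is.null(seed))
    stop("seed is mandatory when permutations are requested")
  samples <- colnames(geno$dosages)
  man <- manifest[match(samples, manifest$sample), , drop = FALSE]
  if (anyNA(man$sample)) stop("genotyped samples missing from manifest")
  units <- man[[level]]
  u <- sort(unique(units))
  sizes <- table(units)
  skipped <- names(sizes)[sizes < 2]
  if (length(skipped) > 0)
    warning("unit(s) with < 2 individuals skipped: ", paste(skipped, collapse = ", "))
  u <- setdiff(u, skipped)
  if (length(u) < 2) stop("need at least 2 units with >= 2 individuals")

  fst <- matrix(0, length(u), length(u), dimnames = list(u, u))
  pval <- matrix(NA_real_, length(u), length(u), dimnames = list(u, u))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(u)) for (j in seq_len(i - 1L)) {
    sel <- units %in% c(u[i], u[j])
    dos <- geno$dosages[, sel, drop = FALSE]
    is_i <- units[sel] == u[i]
    obs <- .wc_two_group_multi(dos, matrix(is_i, ncol = 1))
    fst[i, j] <- fst[j, i] <- obs
    if (n_permutations > 0) {
      n_sel <- sum(sel); n_i <- sum(is_i)
      exceed <- 0L
      left <- n_permutations
      while (left > 0) {                 # chunked to bound memory
        m <- min(500L, left)
        member <- matrix(FALSE, n_sel, m)
        for (k in seq_len(m)) member[sample.int(n_sel, n_i), k] <- TRUE
        perm <- .wc_two_group_multi(dos, member)
        exceed <- exceed + sum(perm >= obs, na.rm = TRUE)
        left <- left - m
      }
      p <- (exceed + 1) / (n_permutations + 1)
      pval[i, j] <- pval[j, i] <- p
    }
  }
  list(fst = fst, p_value = pval, level = level,
       n_permutations = n_permutations, seed = seed, skipped = skipped)
}

# Three-level allele-frequency AMOVA variance components from per-population
# summaries, vectorized over loci; returns components summed across loci.
# grp_of_pop maps each population (column of n_p) to its group.
.amova_from_pops <- function(n_p, a_p, grp_of_pop) {
  grp_levels <- unique(grp_of_pop)
  if (length(grp_levels) < 2) stop("AMOVA needs at least 2 groups")
  if (ncol(n_p) < 2) stop("AMOVA needs at least 2 populations")
  M <- matrix(0, ncol(n_p), length(grp_levels),
              dimnames = list(colnames(n_p), grp_levels))
  M[cbind(seq_len(ncol(n_p)), match(grp_of_pop, grp_levels))] <- 1

  f_p <- ifelse(n_p > 0, a_p / n_p, 0)
  n_g <- n_p %*% M
  a_g <- a_p %*% M
  f_g <- ifelse(n_g > 0, a_g / n_g, 0)
  N <- rowSums(n_p)
  f <- ifelse(N > 0, rowSums(a_p) / N, 0)
  P_l <- rowSums(n_p > 0)
  G_l <- rowSums(n_g > 0)

  f_gp <- f_g %*% t(M)                       # group frequency per population
  ss_wp <- rowSums(n_p * f_p * (1 - f_p))
  ss_ap <- rowSums(n_p * (f_p - f_gp)^2)
  ss_ag <- rowSums(n_g * (f_g - f)^2)

  sum_np2_by_g <- (n_p^2) %*% M
  with_g <- ifelse(n_g > 0, sum_np2_by_g / n_g, 0)
  n_prime <- (N - rowSums(with_g)) / (P_l - G_l)
  n_dprime <- (rowSums(with_g) - rowSums(n_p^2) / N) / (G_l - 1)
  n_tprime <- (N - rowSums(n_g^2) / N) / (G_l - 1)

  ok <- P_l >= 2 & G_l >= 2 & N > P_l
  s_c <- ifelse(ok, ss_wp / (N - P_l), 0)
  s_b <- ifelse(ok & P_l > G_l,
                (ss_ap / pmax(P_l - G_l, 1) - s_c) / n_prime, 0)
  s_a <- ifelse(ok, (ss_ag / (G_l - 1) - s_c - n_dprime * s_b) / n_tprime, 0)
  c(a = sum(s_a), b = sum(s_b), c = sum(s_c))
}

#' Hierarchical AMOVA (groups / populations within groups / within populations)
#'
#' Three-level analysis of molecular variance on allele-indicator distances
#' (each gene copy is a unit), partitioning variance into among-group
#' (`sigma2_a`), among-population-within-group (`sigma2_b`) and
#' within-population (`sigma2_c`) components and the fixation indices
#' `phi_ct = a/(a+b+c)`, `phi_sc = b/(b+c)`, `phi_st = (a+b)/(a+b+c)`.
#' Components may be negative and are kept as estimated. Significance uses
#' the standard permutation schemes: whole populations among groups for
#' `phi_ct`, individuals among populations within groups for `phi_sc`,
#' individuals among all populations for `phi_st`.
#'
#' @param geno a [genotype_matrix()].
#' @param manifest a [sample_manifest()] aligned with matrix columns.
#' @param n_permutations permutations (default 10000; 0 skips p-values).
#' @param seed integer seed, mandatory when permutations are requested.
#' @return object of class `amova_result`: variance components, `phi`
#'   indices, `p_value` per index, `n_permutations`, `seed`.
#' @export
amova <- function(geno, manifest, n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(manifest, "sample_manifest"))
  if (n_permutations > 0 && is.null(seed))
    stop("seed is mandatory when permutations are requested")
  samples <- colnames(geno$dosages)
  man <- manifest[match(samples, manifest$sample), , drop = FALSE]
  if (anyNA(man$sample)) stop("genotyped samples missing from manifest")
  pops <- man$population; groups <- man$group
  dos <- geno$dosages

  called <- !is.na(dos)
  dos0 <- dos; dos0[!called] <- 0L
  pop_levels <- unique(pops)
  grp_of_pop <- groups[match(pop_levels, pops)]
  summar <- function(pop_assign) {
    ind <- matrix(0, ncol(dos), length(pop_levels),
                  dimnames = list(NULL, pop_levels))
    ind[cbind(seq_along(pop_assign), match(pop_assign, pop_levels))] <- 1
    list(n_p = 2 * (called %*% ind), a_p = dos0 %*% ind)
  }
  phi_of <- function(comp) {
    tot <- sum(comp)
    bc <- comp[["b"]] + comp[["c"]]
    c(phi_ct = comp[["a"]] / tot,
      # zero within-group variance leaves nothing to partition: 0, not 0/0
      phi_sc = if (bc > 0) comp[["b"]] / bc else 0,
      phi_st = (comp[["a"]] + comp[["b"]]) / tot)
  }

  ps <- summar(pops)
  comp <- .amova_from_pops(ps$n_p, ps$a_p, grp_of_pop)
  phi <- phi_of(comp)

  pv <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (n_permutations > 0) {
    set.seed(seed)
    exceed <- c(0, 0, 0)
    for (k in seq_len(n_permutations)) {
      # phi_st: individuals among all populations (groups follow populations)
      p_st <- pops[sample.int(length(pops))]
      ps_st <- summar(p_st)
      phi_st_k <- phi_of(.amova_from_pops(ps_st$n_p, ps_st$a_p, grp_of_pop))["phi_st"]
      # phi_sc: individuals among populations within their group
      p_sc <- pops
      for (g in unique(groups)) {
        sel <- groups == g
        p_sc[sel] <- pops[sel][sample.int(sum(sel))]
      }
      ps_sc <- summar(p_sc)
      phi_sc_k <- phi_of(.amova_from_pops(ps_sc$n_p, ps_sc$a_p, grp_of_pop))["phi_sc"]
      # phi_ct: whole populations among groups (population summaries reused)
      g_perm <- grp_of_pop[sample.int(length(grp_of_pop))]
      phi_ct_k <- phi_of(.amova_from_pops(ps$n_p, ps$a_p, g_perm))["phi_ct"]

      exceed <- exceed + c(phi_ct_k >= phi[["phi_ct"]],
                           phi_sc_k >= phi[["phi_sc"]],
                           phi_st_k >= phi[["phi_st"]])
    }
    pv <- (exceed + 1) / (n_permutations + 1)
    names(pv) <- c("phi_ct", "phi_sc", "phi_st")
  }
  structure(list(sigma2_a = unname(comp["a"]), sigma2_b = unname(comp["b"]),
                 sigma2_c = unname(comp["c"]), phi = phi, p_value = pv,
                 n_permutations = n_permutations, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (allele-frequency, 3-level)\n")
  cat(sprintf("  sigma2 among groups:                %.6g\n", x$sigma2_a))
  cat(sprintf("  sigma2 among pops within groups:    %.6g\n", x$sigma2_b))
  cat(sprintf("  sigma2 within populations:          %.6g\n", x$sigma2_c))
  for (nm in names(x$phi))
    cat(sprintf("  %s = %.5f  (p = %s)\n", nm, x$phi[nm],
                format(x$p_value[nm], digits = 3)))
  invisible(x)
}

#' Summary of the per-locus F_ST spectrum
#'
#' Median F_ST over defined loci and the fraction of loci below a
#' differentiation threshold (default 0.10, the genome-wide average for
#' autosomal SNPs used as a reference point).
#'
#' @param results data.frame from [wc_fst_per_locus()].
#' @param threshold F_ST cutoff.
#' @return list with `median_fst`, `fraction_below`, `n_loci`, `threshold`.
#' @export
fst_spectrum_summary <- function(results, threshold = 0.10) {
  ok <- results$defined & !is.na(results$fst)
  if (!any(ok)) stop("no defined loci")
  f <- results$fst[ok]
  list(median_fst = stats::median(f),
       fraction_below = mean(f < threshold),
       n_loci = length(f), threshold = threshold)
}
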