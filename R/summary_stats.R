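# Per-variant and per-region diversity statistics.

#' Per-variant allele frequencies within a sample scope
#'
#' Frequencies are computed from complete-case chromosomes: missing genotypes
#' are dropped per locus, and the number of chromosomes actually used is
#' recorded. Variants with no called genotype in the scope get `NA`
#' frequencies and are flagged.
#'
#' @param geno a [genotype_matrix()].
#' @param scope sample index (logical, integer or names); `NULL` = all.
#' @param scope_label label stored in the output (`all`, a group or a
#'   population name).
#' @return data.frame with columns `id`, `scope`, `x1` (reference-allele
#'   frequency), `x2` (alternate), `maf`, `het` (unbiased expected
#'   heterozygosity), `n_chrom`, `defined`.
#' @export
allele_frequencies <- function(geno, scope = NULL, scope_label = "all") {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (!is.null(scope)) d <- d[, scope, drop = FALSE]
  if (ncol(d) == 0) stop("empty sample scope")
  n_called <- rowSums(!is.na(d))
  n_chrom <- 2L * n_called
  alt <- rowSums(d, na.rm = TRUE)
  x2 <- ifelse(n_chrom > 0, alt / n_chrom, NA_real_)
  x1 <- 1 - x2
  maf <- pmin(x1, x2)
  het <- expected_heterozygosity(x1, x2, n_chrom)
  data.frame(id = rownames(d) %||% as.character(seq_len(nrow(d))),
             scope = scope_label, x1 = x1, x2 = x2, maf = maf, het = het,
             n_chrom = n_chrom, defined = n_chrom > 0,
             stringsAsFactors = FALSE)
}

#' Unbiased expected heterozygosity (gene diversity)
#'
#' `h = n/(n-1) * (1 - x1^2 - x2^2)` with `n` the number of chromosomes —
#' the small-sample-corrected probability that two random chromosomes carry
#' different alleles. Undefined (`NA`) when fewer than 2 chromosomes.
#'
#' @param x1,x2 allele frequencies summing to 1.
#' @param n_chrom chromosome count(s).
#' @return heterozygosity in `[0, 1]`, vectorized.
#' @export
expected_heterozygosity <- function(x1, x2, n_chrom) {
  if (any(abs(x1 + x2 - 1) > 1e-8, na.rm = TRUE))
    stop("allele frequencies must sum to 1")
  h <- (n_chrom / (n_chrom - 1)) * (1 - x1^2 - x2^2)
  h[n_chrom < 2] <- NA_real_
  pmin(pmax(h, 0), 1)
}

#' Watterson's theta per base pair (normalized variant-site count)
#'
#' `theta = K / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i` the harmonic
#' number of `n_chrom - 1`, `K` the number of variant sites, and `L` the
#' screened sequence length in bp. `n_chrom` counts chromosomes (2 x diploid
#' individuals).
#'
#' @param K variant-site count.
#' @param n_chrom chromosomes sampled.
#' @param L screened length (bp).
#' @return theta per bp; 0 when `K = 0`.
#' @export
watterson_theta <- function(K, n_chrom, L) {
  if (any(L <= 0)) stop("L must be positive")
  if (any(n_chrom < 2)) stop("need at least 2 chromosomes")
  a_n <- vapply(n_chrom, function(n) sum(1 / seq_len(n - 1)), numeric(1))
  K / (a_n * L)
}

#' SNP density denominator
#'
#' The region harbours one SNP per `round(L / K)` bp; reports are rendered
#' as the string `"1/N"`. Returns 0 when `K = 0` (density undefined).
#'
#' @param K variant count.
#' @param L screened length (bp).
#' @return integer bp-per-SNP denominator.
#' @export
snp_density <- function(K, L) {
  ifelse(K > 0, as.integer(round(L / K)), 0L)
}

#' Nucleotide diversity per base pair
#'
#' `pi = (1/L) * sum_sites n/(n-1) * 2 x1 x2`, the average per-site pairwise
#' difference between chromosomes, with per-site complete-case chromosome
#' counts `n`. Sites with fewer than 2 called chromosomes contribute 0.
#'
#' @param geno a [genotype_matrix()].
#' @param L screened length (bp).
#' @param scope sample index; `NULL` = all.
#' @return pi per bp.
#' @export
nucleotide_diversity <- function(geno, L, scope = NULL) {
  if (L <= 0) stop("L must be positive")
  af <- allele_frequencies(geno, scope)
  h <- (af$n_chrom / (af$n_chrom - 1)) * 2 * af$x1 * af$x2
  h[af$n_chrom < 2] <- 0
  sum(h, na.rm = TRUE) / L
}

#' Allele-frequency divergence between two populations
#'
#' `d = 1 - (sqrt(x1*y1) + sqrt(x2*y2))`: one minus the Bhattacharyya
#' affinity of the two allele-frequency distributions. 0 for identical
#' frequencies, 1 for disjoint allele sets; symmetric.
#'
#' @param x,y length-2 frequency vectors, each summing to 1.
#' @return divergence in `[0, 1]`.
#' @export
allelic_divergence <- function(x, y) {
  for (v in list(x, y)) {
    if (length(v) != 2 || anyNA(v) || any(v < 0) || abs(sum(v) - 1) > 1e-8)
      stop("each frequency pair must be two non-negative values summing to 1")
  }
  d <- 1 - (sqrt(x[1] * y[1]) + sqrt(x[2] * y[2]))
  min(max(d, 0), 1)
}

#' Region-level diversity summary
#'
#' Bundles the variant-site count `K`, screened length, Watterson's theta,
#' nucleotide diversity and the SNP-density denominator for one sample scope.
#' `K` counts sites polymorphic within the scope.
#'
#' @param geno a [genotype_matrix()].
#' @param L screened length (bp).
#' @param scope sample index; `NULL` = all.
#' @return one-row data.frame: `K`, `L`, `n_chrom` (maximum complete-case
#'   chromosomes), `theta_w`, `pi`, `density_denominator`.
#' @export
region_summary <- function(geno, L, scope = NULL) {
  af <- allele_frequencies(geno, scope)
  poly <- af$defined & !is.na(af$maf) & af$maf > 0
  K <- sum(poly)
  n_chrom <- max(af$n_chrom)
  data.frame(K = K, L = L, n_chrom = n_chrom,
             theta_w = if (K > 0) watterson_theta(K, n_chrom, L) else 0,
             pi = nucleotide_diversity(geno, L, scope),
             density_denominator = snp_density(K, L))
}
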