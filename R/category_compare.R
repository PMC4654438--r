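# Per-functional-category aggregation and two-group comparisons.

# Coarse reporting classes: non-coding pools intronic and UTR sites; coding
# pools synonymous and non-synonymous; the flanking/intergenic classes are
# reported separately when requested.
.coarse_category <- function(category) {
  ifelse(category %in% c("intron", "utr"), "non-coding",
         ifelse(category %in% c("synonymous", "non-synonymous"), "coding",
                category))
}

#' Per-category variation summary (region report rows)
#'
#' One row per reporting class — `non-coding` (intronic + UTR), `coding`
#' (all exonic coding), `synonymous`, `non-synonymous` — with the screened
#' length, variant count K, SNP-density denominator, Watterson's theta,
#' mean expected heterozygosity, mean MAF and mean per-locus F_ST.
#' Synonymous and non-synonymous share the coding length. Means are over
#' variants with defined values; variants monomorphic in scope contribute
#' MAF 0 and het 0 (they are real rows of the variant table, not dropped).
#'
#' @param variants a [variant_table()] with categories assigned.
#' @param stats per-variant frequencies from [allele_frequencies()] for the
#'   scope being summarized.
#' @param fst optional per-locus results from [wc_fst_per_locus()].
#' @param lengths named vector/list with elements `"non-coding"` and
#'   `"coding"` giving screened bp for each class.
#' @param n_chrom chromosomes for the theta computation; defaults to the
#'   maximum complete-case chromosome count in `stats`.
#' @param scope_label label stored in the output.
#' @return data.frame of class `category_stats`: `category`, `scope`,
#'   `bp_screened`, `K`, `density_denominator`, `theta_w`, `mean_het`,
#'   `mean_maf`, `mean_fst`.
#' @export
category_summary <- function(variants, stats, fst = NULL, lengths,
                             n_chrom = NULL, scope_label = "all") {
  stopifnot(inherits(variants, "variant_table"))
  if (!all(c("non-coding", "coding") %in% names(lengths)))
    stop("lengths must name 'non-coding' and 'coding' bp")
  if (is.null(n_chrom)) n_chrom <- max(stats$n_chrom)

  coarse <- .coarse_category(variants$category)
  member <- list(
    "non-coding" = coarse == "non-coding",
    "coding" = coarse == "coding",
    "synonymous" = variants$category == "synonymous",
    "non-synonymous" = variants$category == "non-synonymous")
  L_of <- c("non-coding" = unname(lengths[["non-coding"]]),
            "coding" = unname(lengths[["coding"]]),
            "synonymous" = unname(lengths[["coding"]]),
            "non-synonymous" = unname(lengths[["coding"]]))

  st <- stats[match(variants$id, stats$id), , drop = FALSE]
  fst_per <- if (!is.null(fst)) fst$fst[match(variants$id, fst$id)] else
    rep(NA_real_, nrow(variants))

  rows <- lapply(names(member), function(cat) {
    sel <- member[[cat]]
    K <- sum(sel)
    L <- L_of[[cat]]
    data.frame(category = cat, scope = scope_label, bp_screened = L, K = K,
               density_denominator = snp_density(K, L),
               theta_w = if (K > 0) watterson_theta(K, n_chrom, L) else NA_real_,
               mean_het = if (K > 0) mean(st$het[sel], na.rm = TRUE) else NA_real_,
               mean_maf = if (K > 0) mean(st$maf[sel], na.rm = TRUE) else NA_real_,
               mean_fst = if (any(sel & !is.na(fst_per)))
                 mean(fst_per[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("category_stats", "data.frame")
  out
}

#' Welch two-sample t-test (unequal variances, two-sided)
#'
#' A thin wrapper over [stats::t.test()] with `var.equal = FALSE` that also
#' handles the degenerate zero-variance cases the base test refuses:
#' both samples constant and equal means gives `t = 0, p = 1`; both constant
#' with different means gives `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric vectors (each with at least 2 non-missing values).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 defined values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p_value = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Squared Pearson correlation of per-variant values between two scopes
#'
#' Used for cross-group concordance of MAF and heterozygosity (e.g. the
#' European/American comparison). Pairs with a missing value in either scope
#' are dropped.
#'
#' @param a,b equal-length per-variant values for the two scopes.
#' @return list with `r2`, `n_pairs`, `defined` (`FALSE` with fewer than 3
#'   complete pairs or zero variance in either vector).
#' @export
group_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must be paired")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3 || stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0)
    return(list(r2 = NA_real_, n_pairs = sum(ok), defined = FALSE))
  list(r2 = stats::cor(a[ok], b[ok])^2, n_pairs = sum(ok), defined = TRUE)
}

#' Category contrasts (t-tests between functional classes)
#'
#' Runs the two standard contrasts — non-coding vs coding, synonymous vs
#' non-synonymous — on per-variant MAF, heterozygosity and (optionally)
#' per-locus F_ST, via [welch_t_test()].
#'
#' @param variants a [variant_table()] with categories.
#' @param stats per-variant frequencies ([allele_frequencies()]).
#' @param fst optional [wc_fst_per_locus()] results.
#' @return data.frame: `contrast`, `measure`, `t`, `df`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
category_contrasts <- function(variants, stats, fst = NULL) {
  coarse <- .coarse_category(variants$category)
  st <- stats[match(variants$id, stats$id), , drop = FALSE]
  measures <- list(maf = st$maf, het = st$het)
  if (!is.null(fst))
    measures$fst <- fst$fst[match(variants$id, fst$id)]
  contrasts <- list(
    "non-coding vs coding" = list(a = coarse == "non-coding", b = coarse == "coding"),
    "synonymous vs non-synonymous" = list(a = variants$category == "synonymous",
                                          b = variants$category == "non-synonymous"))
  rows <- list()
  for (cn in names(contrasts)) for (mn in names(measures)) {
    a <- measures[[mn]][contrasts[[cn]]$a]
    b <- measures[[mn]][contrasts[[cn]]$b]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) next
    w <- welch_t_test(a, b)
    rows[[length(rows) + 1]] <- data.frame(
      contrast = cn, measure = mn, t = w$t, df = w$df, p_value = w$p_value,
      mean_a = w$mean_a, mean_b = w$mean_b, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
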