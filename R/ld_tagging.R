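# Pairwise LD (r2, D'), EM haplotype-frequency estimation for unphased data,
# greedy tag-SNP binning, surrogate-SNP discovery.

# r2 and D' from the four haplotype frequencies (alt-allele convention:
# p11 = freq of the alt-alt haplotype, pA/pB = alt frequencies at each locus).
.ld_from_freqs <- function(p11, pA, pB) {
  D <- p11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  dmax <- ifelse(D >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  d_prime <- ifelse(denom > 0 & dmax > 0, abs(D) / dmax, NA_real_)
  list(r2 = r2, d_prime = d_prime, D = D)
}

#' LD between two loci from phased haplotypes
#'
#' Direct haplotype counting: with `p11` the frequency of the haplotype
#' carrying the alternate allele at both loci, `D = p11 - pA*pB`,
#' `r2 = D^2 / (pA qA pB qB)` and `D' = |D| / Dmax`. Haplotypes with a
#' missing allele at either locus are dropped pairwise.
#'
#' @param hapA,hapB equal-length 0/1 allele vectors (one entry per
#'   chromosome copy).
#' @return list with `r2`, `d_prime`, `D`, `n_haplotypes`, `defined`
#'   (`FALSE` when either locus is monomorphic in scope).
#' @export
haplotype_ld <- function(hapA, hapB) {
  if (length(hapA) != length(hapB)) stop("haplotype vectors must match in length")
  ok <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[ok]; b <- hapB[ok]
  n <- length(a)
  if (n == 0) return(list(r2 = NA_real_, d_prime = NA_real_, D = NA_real_,
                          n_haplotypes = 0L, defined = FALSE))
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r2 = NA_real_, d_prime = NA_real_, D = NA_real_,
                n_haplotypes = n, defined = FALSE))
  p11 <- mean(a == 1 & b == 1)
  ld <- .ld_from_freqs(p11, pA, pB)
  list(r2 = ld$r2, d_prime = ld$d_prime, D = ld$D,
       n_haplotypes = n, defined = TRUE)
}

#' EM estimate of two-locus haplotype frequencies from unphased dosages
#'
#' Only the double-heterozygote genotype is phase-ambiguous; the EM
#' iteration splits its two copies between the coupling (`11/00`) and
#' repulsion (`10/01`) resolutions in proportion to the current frequency
#' estimates. Convergence when the largest frequency change drops below
#' `tol` (default 1e-8) or after `max_iter` iterations (the last iterate is
#' returned, flagged unconverged).
#'
#' @param dosA,dosB equal-length dosage vectors in \{0, 1, 2, NA\}.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return list with `freqs` (named: `h00`, `h01`, `h10`, `h11`, summing to
#'   1), `converged`, `n_iter`, `n_samples`.
#' @export
em_haplotype_freqs <- function(dosA, dosB, tol = 1e-8, max_iter = 1000) {
  if (length(dosA) != length(dosB)) stop("dosage vectors must match in length")
  ok <- !is.na(dosA) & !is.na(dosB)
  a <- dosA[ok]; b <- dosB[ok]
  n <- length(a)
  if (n == 0) stop("no complete-case samples")
  # genotype combination counts
  cnt <- matrix(0L, 3, 3)
  for (i in seq_len(n)) cnt[a[i] + 1L, b[i] + 1L] <- cnt[a[i] + 1L, b[i] + 1L] + 1L
  total <- 2 * n
  # unambiguous haplotype counts; indices: [A allele, B allele]
  base <- c(h00 = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1],
            h01 = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
            h10 = 2 * cnt[3, 1] + cnt[2, 1] + cnt[3, 2],
            h11 = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3])
  ndh <- cnt[2, 2]                       # double heterozygotes
  f <- rep(0.25, 4); names(f) <- names(base)
  converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    coupling <- f["h11"] * f["h00"]
    repulsion <- f["h10"] * f["h01"]
    w <- if (coupling + repulsion > 0) coupling / (coupling + repulsion) else 0.5
    new <- base + ndh * c(w, 1 - w, 1 - w, w)
    new <- new / total
    if (max(abs(new - f)) < tol) { f <- new; converged <- TRUE; break }
    f <- new
    if (it >= max_iter) break
  }
  if (!converged && ndh > 0)
    warning("EM did not converge in ", max_iter, " iterations")
  if (ndh == 0) converged <- TRUE
  list(freqs = f, converged = converged, n_iter = it, n_samples = n)
}

#' LD between two loci from unphased dosages via EM
#'
#' @param dosA,dosB dosage vectors.
#' @return as [haplotype_ld()], with `method = "em"`.
#' @export
em_ld <- function(dosA, dosB) {
  ok <- !is.na(dosA) & !is.na(dosB)
  pA <- sum(dosA[ok]) / (2 * sum(ok)); pB <- sum(dosB[ok]) / (2 * sum(ok))
  if (sum(ok) == 0 || pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r2 = NA_real_, d_prime = NA_real_, D = NA_real_,
                n_haplotypes = 2L * sum(ok), defined = FALSE))
  em <- em_haplotype_freqs(dosA, dosB)
  ld <- .ld_from_freqs(em$freqs[["h11"]], pA, pB)
  list(r2 = ld$r2, d_prime = ld$d_prime, D = ld$D,
       n_haplotypes = 2L * sum(ok), defined = TRUE)
}

#' All-pairs LD among MAF-passing variants in a sample scope
#'
#' Computes r2 and D' for every pair of variants whose minor allele
#' frequency in the scope is at least `maf_min`. Phased matrices use direct
#' haplotype counting (vectorized over all pairs); unphased matrices fall
#' back to per-pair EM.
#'
#' @param geno a [genotype_matrix()].
#' @param variants the matching [variant_table()] (for positions).
#' @param scope sample index; `NULL` = all.
#' @param maf_min MAF filter applied within the scope (default 0.05).
#' @return data.frame of class `ld_pairs`: `id_a`, `id_b`, `pos_a`, `pos_b`,
#'   `distance` (bp, inclusive 1-based difference), `r2`, `d_prime`,
#'   `method`; attribute `passing_ids` records the MAF-passing variant set.
#' @export
ld_matrix <- function(geno, variants, scope = NULL, maf_min = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(variants, "variant_table"))
  if (nrow(variants) != geno$n_variants)
    stop("variant table / matrix mismatch")
  af <- allele_frequencies(geno, scope)
  pass <- which(af$defined & !is.na(af$maf) & af$maf >= maf_min)
  ids <- variants$id[pass]
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      pos_a = integer(0), pos_b = integer(0),
                      distance = integer(0), r2 = numeric(0),
                      d_prime = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
  if (length(pass) < 2) {
    attr(empty, "passing_ids") <- ids
    class(empty) <- c("ld_pairs", "data.frame")
    return(empty)
  }
  pos <- variants$pos[pass]
  pairs <- utils::combn(seq_along(pass), 2)
  ia <- pairs[1, ]; ib <- pairs[2, ]

  if (geno$phased && !is.null(geno$hap1)) {
    h1 <- geno$hap1[pass, , drop = FALSE]; h2 <- geno$hap2[pass, , drop = FALSE]
    if (!is.null(scope)) { h1 <- h1[, scope, drop = FALSE]; h2 <- h2[, scope, drop = FALSE] }
    H <- rbind(t(h1), t(h2))                       # haplotypes x loci
    method <- "phased-count"
    if (!anyNA(H)) {
      nh <- nrow(H)
      p <- colMeans(H)
      P11 <- crossprod(H) / nh                     # alt-alt haplotype freqs
      p11 <- P11[cbind(ia, ib)]
      ld <- .ld_from_freqs(p11, p[ia], p[ib])
      r2 <- ld$r2; dpr <- ld$d_prime
    } else {
      # pairwise deletion of haplotypes with a missing allele
      r2 <- dpr <- numeric(ncol(pairs))
      for (k in seq_len(ncol(pairs))) {
        ld <- haplotype_ld(H[, ia[k]], H[, ib[k]])
        r2[k] <- ld$r2; dpr[k] <- ld$d_prime
      }
    }
  } else {
    d <- geno$dosages[pass, , drop = FALSE]
    if (!is.null(scope)) d <- d[, scope, drop = FALSE]
    r2 <- dpr <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      ld <- em_ld(d[ia[k], ], d[ib[k], ])
      r2[k] <- ld$r2; dpr[k] <- ld$d_prime
    }
    method <- "em"
  }
  out <- data.frame(id_a = ids[ia], id_b = ids[ib],
                    pos_a = pos[ia], pos_b = pos[ib],
                    distance = abs(pos[ib] - pos[ia]),
                    r2 = r2, d_prime = dpr, method = method,
                    stringsAsFactors = FALSE)
  attr(out, "passing_ids") <- ids
  class(out) <- c("ld_pairs", "data.frame")
  out
}

#' Greedy tag-SNP binning
#'
#' Repeatedly selects the variant covering the most not-yet-tagged variants
#' at `r2 >= r2_min` (itself included), forms a bin from tag plus covered
#' variants, removes them, and repeats until every variant is binned;
#' variants linked to nothing become singleton bins. Ties are broken by
#' highest coverage, then highest MAF, then lowest position, so output is
#' deterministic.
#'
#' @param pairs an `ld_pairs` data.frame from [ld_matrix()] (already
#'   restricted to the MAF-passing scope).
#' @param variant_info data.frame with columns `id`, `maf`, `pos` covering
#'   every variant to bin (defaults to the ids in `pairs` if `NULL`, but the
#'   full MAF-passing set should be supplied so singletons are binned too).
#' @param r2_min tagging threshold (default 0.8).
#' @return data.frame: `id`, `tag`, `bin` (integer bin index); bins
#'   partition the input set.
#' @export
greedy_tag_selection <- function(pairs, variant_info = NULL, r2_min = 0.8) {
  if (is.null(variant_info)) {
    ids <- attr(pairs, "passing_ids")
    if (is.null(ids)) ids <- unique(c(pairs$id_a, pairs$id_b))
    variant_info <- data.frame(id = ids, maf = NA_real_, pos = NA_integer_,
                               stringsAsFactors = FALSE)
  }
  ids <- variant_info$id
  n <- length(ids)
  if (n == 0) return(data.frame(id = character(0), tag = character(0),
                                bin = integer(0), stringsAsFactors = FALSE))
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  strong <- pairs[!is.na(pairs$r2) & pairs$r2 >= r2_min, , drop = FALSE]
  for (k in seq_len(nrow(strong))) {
    a <- idx[[strong$id_a[k]]]; b <- idx[[strong$id_b[k]]]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  maf <- variant_info$maf; pos <- variant_info$pos
  maf[is.na(maf)] <- -Inf
  pos[is.na(pos)] <- .Machine$integer.max

  untagged <- rep(TRUE, n)
  tag_of <- character(n); bin_of <- integer(n)
  bin_id <- 0L
  while (any(untagged)) {
    cand <- which(untagged)
    cover <- vapply(cand, function(i) 1L + sum(untagged[adj[[i]]]), integer(1))
    best <- cover == max(cover)
    sel <- cand[best]
    sel <- sel[order(-maf[sel], pos[sel])][1]
    members <- c(sel, adj[[sel]][untagged[adj[[sel]]]])
    members <- unique(members)
    bin_id <- bin_id + 1L
    tag_of[members] <- ids[sel]
    bin_of[members] <- bin_id
    untagged[members] <- FALSE
  }
  data.frame(id = ids, tag = tag_of, bin = bin_of, stringsAsFactors = FALSE)
}

#' Surrogate SNPs for an index variant
#'
#' Surrogates are variants with `r2 >= r2_min` to the index, inter-marker
#' distance at most `max_dist` bp (1-based positions, inclusive) and MAF at
#' least `maf_min` in the scope. The index variant itself is exempt from the
#' MAF filter (low-frequency index SNPs still get surrogate reports).
#'
#' @param index_id index (e.g. trait-associated) variant id.
#' @param pairs `ld_pairs` for the scope, computed with `maf_min = 0` or the
#'   index included; candidate MAF filtering uses `variant_info`.
#' @param variant_info data.frame with `id`, `maf`, `pos` for the scope.
#' @param r2_min,max_dist,maf_min thresholds (defaults 0.6, 200000, 0.05).
#' @return object of class `surrogate_set`: `index`, `surrogates`
#'   (data.frame `id`, `r2`, `distance`, `maf`, sorted by descending r2),
#'   thresholds used.
#' @export
find_surrogates <- function(index_id, pairs, variant_info,
                            r2_min = 0.6, max_dist = 200000, maf_min = 0.05) {
  if (!index_id %in% variant_info$id)
    stop("index variant absent from genotype data: ", index_id)
  sel <- (pairs$id_a == index_id) | (pairs$id_b == index_id)
  cand <- pairs[sel, , drop = FALSE]
  other <- ifelse(cand$id_a == index_id, cand$id_b, cand$id_a)
  maf <- variant_info$maf[match(other, variant_info$id)]
  keep <- !is.na(cand$r2) & cand$r2 >= r2_min &
    cand$distance <= max_dist & !is.na(maf) & maf >= maf_min
  out <- data.frame(id = other[keep], r2 = cand$r2[keep],
                    distance = cand$distance[keep], maf = maf[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r2, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(index = index_id, surrogates = out,
                 r2_min = r2_min, max_dist = max_dist, maf_min = maf_min,
                 n_surrogates = nrow(out)),
            class = "surrogate_set")
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat(sprintf("surrogates for %s (r2 >= %.2f, dist <= %d bp, MAF >= %.2f): %d\n",
              x$index, x$r2_min, x$max_dist, x$maf_min, x$n_surrogates))
  if (x$n_surrogates > 0) print(utils::head(x$surrogates, 10))
  invisible(x)
}
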