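# Balding-Nichols structured-population genotype simulator with known
# ground truth: tunable two-level differentiation, mosaic LD blocks, and
# category-specific allele-frequency spectra.

#' Default two-level sample hierarchy
#'
#' Four ancestral groups subdivided into 14 populations with sizes matching
#' the reference-panel extract the package emulates (AFR 246, EUR 379,
#' AM 184, EA 286 diploid individuals; 1095 total).
#'
#' @return named list: group -> named integer vector population -> n.
#' @export
default_hierarchy <- function() {
  list(AFR = c(ASW = 61, LWK = 97, YRI = 88),
       EUR = c(CEU = 85, TSI = 98, FIN = 93, GBR = 89, IBS = 14),
       AM  = c(MXL = 66, PUR = 55, CLM = 63),
       EA  = c(CHB = 97, JPT = 89, CHS = 100))
}

#' Default per-category fractions and MAF bands
#'
#' Fractions mirror the functional composition of the emulated locus
#' (1627 variants: 167 upstream, 855 intronic, 48 UTR, 46 synonymous,
#' 26 non-synonymous, 353 intergenic, 132 downstream). MAF ceilings plant
#' the rare-coding / very-rare-non-synonymous spectrum: constrained classes
#' are filled from the low-frequency tail.
#'
#' @return data.frame: `category`, `fraction`, `maf_max`.
#' @export
default_category_spec <- function() {
  data.frame(
    category = c("non-synonymous", "synonymous", "utr", "upstream",
                 "downstream", "intergenic", "intron"),
    fraction = c(26, 46, 48, 167, 132, 353, 855) / 1627,
    maf_max  = c(0.02, 0.06, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' Build and validate a simulation configuration
#'
#' @param seed integer seed driving the single pseudo-random stream.
#' @param hierarchy group -> population -> size structure
#'   ([default_hierarchy()]).
#' @param n_variants number of biallelic SNVs.
#' @param chrom,region_start,region_length genomic frame for positions.
#' @param f_between_groups Balding-Nichols F for ancestral-group
#'   differentiation, in `[0, 1)`.
#' @param f_within_groups nested F for populations within a group.
#' @param maf_distribution `"uniform"` (default) draws ancestral frequencies
#'   uniformly on `[maf_min, maf_max]` with a rare point mass; `"neutral"`
#'   draws allele counts from the standard neutral site-frequency spectrum
#'   (probability proportional to 1/i for i derived copies among the total
#'   chromosomes), under which Watterson's theta and nucleotide diversity
#'   agree in expectation.
#' @param maf_min,maf_max ancestral allele-frequency range (uniform draw).
#' @param rare_fraction point mass of rare variants; that fraction of sites
#'   draws its ancestral frequency from `[rare_min, rare_max]` instead,
#'   emulating the rare-variant excess of sequencing panels (uniform mode
#'   only).
#' @param rare_min,rare_max rare-band bounds.
#' @param ld_blocks optional data.frame `start`, `end`, `founders`:
#'   mosaic-copy blocks ([inject_ld_blocks()]); `NULL` = none.
#' @param category_spec per-category fractions and MAF ceilings
#'   ([default_category_spec()]); `NULL` skips category assignment.
#' @param n_index index (trait-associated) SNPs to flag among common
#'   non-coding variants.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              hierarchy = default_hierarchy(),
                              n_variants = 1627,
                              chrom = "5",
                              region_start = 1243287,
                              region_length = 111716,
                              f_between_groups = 0.1,
                              f_within_groups = 0.01,
                              maf_distribution = c("uniform", "neutral"),
                              maf_min = 0.01, maf_max = 0.5,
                              rare_fraction = 0.3,
                              rare_min = 0.001, rare_max = 0.02,
                              ld_blocks = NULL,
                              category_spec = default_category_spec(),
                              n_index = 23) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  maf_distribution <- match.arg(maf_distribution)
  for (f in c(f_between_groups, f_within_groups))
    if (f < 0 || f >= 1) stop("F values must be in [0, 1)")
  if (n_variants < 1) stop("n_variants must be positive")
  if (region_length < n_variants) stop("region too short for n_variants")
  if (!is.list(hierarchy) || is.null(names(hierarchy)))
    stop("hierarchy must be a named list of named population-size vectors")
  if (!is.null(category_spec)) {
    if (abs(sum(category_spec$fraction) - 1) > 1e-6)
      stop("category fractions must sum to 1")
    if (!all(category_spec$category %in% VALID_CATEGORIES))
      stop("invalid category in spec")
  }
  if (!is.null(ld_blocks)) {
    end_pos <- region_start + region_length - 1
    if (any(ld_blocks$start < region_start | ld_blocks$end > end_pos))
      stop("ld_blocks outside region")
    if (any(ld_blocks$start > ld_blocks$end)) stop("malformed ld_block interval")
    o <- order(ld_blocks$start)
    if (nrow(ld_blocks) > 1 &&
        any(ld_blocks$start[o][-1] <= ld_blocks$end[o][-nrow(ld_blocks)]))
      stop("ld_blocks overlap")
    if (any(ld_blocks$founders < 1)) stop("founders must be >= 1")
  }
  structure(list(seed = as.integer(seed), hierarchy = hierarchy,
                 n_variants = as.integer(n_variants), chrom = chrom,
                 region_start = as.integer(region_start),
                 region_length = as.integer(region_length),
                 f_between_groups = f_between_groups,
                 f_within_groups = f_within_groups,
                 maf_distribution = maf_distribution,
                 maf_min = maf_min, maf_max = maf_max,
                 rare_fraction = rare_fraction,
                 rare_min = rare_min, rare_max = rare_max,
                 ld_blocks = ld_blocks, category_spec = category_spec,
                 n_index = as.integer(n_index)),
            class = "simulation_config")
}

# Balding-Nichols draw: daughter frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F),
# degenerate at p for F = 0.
.bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate structured-population genotypes (Balding-Nichols model)
#'
#' Per variant, an ancestral frequency is drawn from the configured
#' distribution; each ancestral group's frequency is a Balding-Nichols Beta
#' draw around it with `f_between_groups`; each population's frequency is a
#' nested draw around its group with `f_within_groups`; haplotypes are
#' independent Bernoulli draws (Hardy-Weinberg genotypes). LD blocks, if
#' configured, are injected by mosaic founder copying; functional categories
#' are planted from the realized allele-frequency spectrum. Fully
#' reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return list: `genotypes` (phased [genotype_matrix()]), `variants`
#'   ([variant_table()] with categories and index flags), `manifest`
#'   ([sample_manifest()]), `truth` (generating parameters and realized
#'   ancestral/group/population frequencies).
#' @export
simulate_balding_nichols <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nv <- config$n_variants

  pos <- sort(sample.int(config$region_length, nv)) + config$region_start - 1L
  ids <- sprintf("sv%05d", seq_len(nv))

  sizes_all <- unlist(lapply(config$hierarchy, identity), use.names = FALSE)
  if (identical(config$maf_distribution, "neutral")) {
    # neutral SFS: i derived copies among 2N chromosomes w.p. prop. to 1/i
    n_ch <- 2L * sum(sizes_all)
    i <- sample.int(n_ch - 1L, nv, replace = TRUE,
                    prob = 1 / seq_len(n_ch - 1L))
    p_anc <- i / n_ch
  } else {
    # uniform band + rare point mass
    rare <- stats::runif(nv) < config$rare_fraction
    p_anc <- ifelse(rare,
                    stats::runif(nv, config$rare_min, config$rare_max),
                    stats::runif(nv, config$maf_min, config$maf_max))
  }

  groups <- names(config$hierarchy)
  p_group <- sapply(groups, function(g) .bn_draw(p_anc, config$f_between_groups))
  pops <- unlist(lapply(groups, function(g) names(config$hierarchy[[g]])))
  pop_group <- unlist(lapply(groups, function(g)
    rep(g, length(config$hierarchy[[g]]))))
  p_pop <- sapply(seq_along(pops), function(k)
    .bn_draw(p_group[, pop_group[k]], config$f_within_groups))
  colnames(p_pop) <- pops

  sizes <- unlist(lapply(groups, function(g) config$hierarchy[[g]]),
                  use.names = FALSE)
  n_total <- sum(sizes)
  sample_pop <- rep(pops, sizes)
  sample_group <- rep(pop_group, sizes)
  sample_ids <- sprintf("%s%04d", sample_pop, unlist(lapply(sizes, seq_len)))

  hap1 <- hap2 <- matrix(0L, nv, n_total, dimnames = list(ids, sample_ids))
  exact_sfs <- identical(config$maf_distribution, "neutral") &&
    config$f_between_groups == 0 && config$f_within_groups == 0
  if (exact_sfs) {
    # panmictic neutral mode: realize the drawn allele counts exactly in the
    # sample (i copies placed uniformly among the 2N chromosomes), so the
    # sample SFS is the neutral SFS by construction
    n_ch <- 2L * n_total
    counts <- as.integer(round(p_anc * n_ch))
    H <- matrix(0L, nv, n_ch)
    for (l in seq_len(nv)) H[l, sample.int(n_ch, counts[l])] <- 1L
    hap1[] <- H[, seq_len(n_total), drop = FALSE]
    hap2[] <- H[, n_total + seq_len(n_total), drop = FALSE]
  } else {
    for (k in seq_along(pops)) {
      cols <- which(sample_pop == pops[k])
      pf <- p_pop[, k]
      hap1[, cols] <- stats::rbinom(nv * length(cols), 1L, pf)
      hap2[, cols] <- stats::rbinom(nv * length(cols), 1L, pf)
    }
  }

  if (!is.null(config$ld_blocks)) {
    h <- inject_ld_blocks(hap1, hap2, pos, config$ld_blocks, sample_pop)
    hap1 <- h$hap1; hap2 <- h$hap2
  }

  geno <- genotype_matrix(hap1 + hap2, hap1, hap2, phased = TRUE)
  variants <- variant_table(chrom = config$chrom, pos = pos, id = ids,
                            ref = "A", alt = "G")
  manifest <- sample_manifest(sample_ids, sample_pop, sample_group)

  if (!is.null(config$category_spec))
    variants <- assign_synthetic_categories(variants, geno, config$category_spec)

  if (config$n_index > 0) {
    af <- allele_frequencies(geno)
    eligible <- which(!is.na(af$maf) & af$maf >= 0.05 &
                        variants$category %in% c("intron", "intergenic",
                                                 "utr", NA_character_))
    n_idx <- min(config$n_index, length(eligible))
    variants$is_index[sample(eligible, n_idx)] <- TRUE
  }

  truth <- list(config = config[setdiff(names(config), "category_spec")],
                p_ancestral = p_anc,
                p_group = p_group, p_population = p_pop,
                variant_ids = ids, positions = pos)
  list(genotypes = geno, variants = variants, manifest = manifest,
       truth = truth)
}

#' Inject high-LD blocks by mosaic founder copying
#'
#' Within each block (a genomic interval), every haplotype in a population
#' is replaced by a copy of one of `founders` founder haplotypes drawn from
#' that population's own pool, so within-block r2 is high (approaching 1 as
#' `founders` approaches 2) while between-block independence and
#' between-population differentiation are preserved. With no blocks the
#' input is returned untouched.
#'
#' @param hap1,hap2 0/1 haplotype matrices (variants x samples).
#' @param positions per-variant 1-based positions.
#' @param blocks data.frame `start`, `end`, `founders`.
#' @param sample_pop per-sample population labels (copying is within
#'   population); a single label vector recycles to one pool.
#' @return list with modified `hap1`, `hap2`.
#' @export
inject_ld_blocks <- function(hap1, hap2, positions, blocks, sample_pop) {
  if (is.null(blocks) || nrow(blocks) == 0) return(list(hap1 = hap1, hap2 = hap2))
  n_samp <- ncol(hap1)
  if (length(sample_pop) == 1) sample_pop <- rep(sample_pop, n_samp)
  for (b in seq_len(nrow(blocks))) {
    rows <- which(positions >= blocks$start[b] & positions <= blocks$end[b])
    if (length(rows) == 0) next
    nf <- blocks$founders[b]
    for (p in unique(sample_pop)) {
      cols <- which(sample_pop == p)
      # pool of 2n haplotypes for this population, block rows only
      pool <- cbind(hap1[rows, cols, drop = FALSE],
                    hap2[rows, cols, drop = FALSE])
      founders <- pool[, sample.int(ncol(pool), min(nf, ncol(pool))),
                       drop = FALSE]
      pick1 <- sample.int(ncol(founders), length(cols), replace = TRUE)
      pick2 <- sample.int(ncol(founders), length(cols), replace = TRUE)
      hap1[rows, cols] <- founders[, pick1, drop = FALSE]
      hap2[rows, cols] <- founders[, pick2, drop = FALSE]
    }
  }
  list(hap1 = hap1, hap2 = hap2)
}

#' Plant functional categories with category-specific MAF spectra
#'
#' Assigns category labels so each category's realized minor-allele
#' frequencies respect its configured ceiling: categories are filled in
#' order of ascending `maf_max` (most constrained first) by sampling from
#' the still-unassigned variants whose overall MAF is within the band.
#' Errors with a diagnostic when a band has too few eligible variants.
#' Genic categories get a gene label by position (two tandem gene spans);
#' intergenic/flanking labels keep `intergenic`.
#'
#' @param variants a [variant_table()].
#' @param geno the matching [genotype_matrix()] (for realized MAF).
#' @param category_spec data.frame `category`, `fraction`, `maf_max`.
#' @return the variant table with `category` and `gene` filled.
#' @export
assign_synthetic_categories <- function(variants, geno, category_spec) {
  stopifnot(inherits(variants, "variant_table"))
  if (abs(sum(category_spec$fraction) - 1) > 1e-6)
    stop("category fractions must sum to 1")
  nv <- nrow(variants)
  maf <- allele_frequencies(geno)$maf
  counts <- round(category_spec$fraction * nv)
  # adjust rounding drift on the least-constrained category
  counts[which.max(category_spec$maf_max)] <-
    counts[which.max(category_spec$maf_max)] + (nv - sum(counts))

  ord <- order(category_spec$maf_max)
  assigned <- rep(NA_character_, nv)
  for (k in ord) {
    need <- counts[k]
    if (need == 0) next
    elig <- which(is.na(assigned) & !is.na(maf) &
                    maf <= category_spec$maf_max[k])
    if (length(elig) < need)
      stop(sprintf(
        "infeasible category spec: '%s' needs %d variants with MAF <= %g but only %d are available",
        category_spec$category[k], need, category_spec$maf_max[k], length(elig)))
    assigned[sample(elig, need)] <- category_spec$category[k]
  }
  variants$category <- assigned
  genic <- assigned %in% c("intron", "utr", "synonymous", "non-synonymous")
  mid <- stats::median(variants$pos)
  variants$gene <- ifelse(genic,
                          ifelse(variants$pos <= mid, "GENE1", "GENE2"),
                          "intergenic")
  variants
}

#' Write a simulation to pipeline input files
#'
#' Emits the phased VCF (seed recorded in the header), panel TSV, annotation
#' TSV (`id`, `chrom`, `pos`, `gene`, `category`, `is_index`) and a truth
#' JSON holding the generating parameters and realized frequencies.
#'
#' @param sim result of [simulate_balding_nichols()].
#' @param dir output directory (created if needed).
#' @return named vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- sim$truth$config$seed
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             panel = file.path(dir, "panel.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, sim$variants, paths["vcf"],
            extra_header = paste0("##locusdiv_seed=", seed))
  write_panel(sim$manifest, paths["panel"])
  write_report(as.data.frame(sim$variants)[, c("id", "chrom", "pos", "gene",
                                               "category", "is_index")],
               paths["annotation"])
  truth <- sim$truth
  truth$p_group <- as.data.frame(truth$p_group)
  truth$p_population <- as.data.frame(truth$p_population)
  truth$config$hierarchy <- lapply(truth$config$hierarchy, as.list)
  truth$config$ld_blocks <- if (is.null(truth$config$ld_blocks)) NULL else
    as.data.frame(truth$config$ld_blocks)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
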