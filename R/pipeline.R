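# End-to-end orchestration: one config in, the full report bundle out.

#' Build and validate a run configuration
#'
#' All analysis constants are surfaced here with the study defaults: tag
#' threshold r2 >= 0.8, surrogate thresholds r2 >= 0.6 / distance <= 200 kb /
#' MAF >= 0.05, low-differentiation cutoff F_ST < 0.10, 10,000 permutations.
#'
#' @param vcf,panel,annotation input paths (VCF genotypes; sample panel TSV;
#'   per-variant annotation TSV with `id`, `gene`, `category`, `is_index`).
#' @param out_dir report directory (created; wiped of partial output on
#'   failure).
#' @param lengths named list/vector: screened bp for `"non-coding"` and
#'   `"coding"`.
#' @param seed integer seed; mandatory when `n_permutations > 0`.
#' @param n_permutations permutation count for F_ST / AMOVA p-values.
#' @param tag_r2,surrogate_r2,max_dist,maf_min,fst_threshold thresholds.
#' @param exclude optional path to a one-column file of sample ids to drop
#'   (e.g. related individuals), or a character vector.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, panel, annotation, out_dir,
                       lengths = c("non-coding" = 61757, "coding" = 7126),
                       seed = NULL, n_permutations = 10000,
                       tag_r2 = 0.8, surrogate_r2 = 0.6,
                       max_dist = 200000, maf_min = 0.05,
                       fst_threshold = 0.10, exclude = NULL) {
  if (n_permutations > 0 && is.null(seed))
    stop("seed is mandatory when permutations are requested")
  for (v in c(tag_r2, surrogate_r2, maf_min))
    if (v < 0 || v > 1) stop("thresholds must be in [0, 1]")
  if (max_dist <= 0) stop("max_dist must be positive")
  structure(list(vcf = vcf, panel = panel, annotation = annotation,
                 out_dir = out_dir, lengths = lengths, seed = seed,
                 n_permutations = n_permutations, tag_r2 = tag_r2,
                 surrogate_r2 = surrogate_r2, max_dist = max_dist,
                 maf_min = maf_min, fst_threshold = fst_threshold,
                 exclude = exclude),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lengths)) y$lengths <- unlist(y$lengths)
  do.call(run_config, y)
}

#' Run the full locus characterization
#'
#' Loads genotypes, panel and annotation; computes per-variant statistics
#' for all samples and per ancestral group; per-locus and pairwise
#' Weir-Cockerham F_ST with permutation p-values; AMOVA; per-category
#' summaries and contrasts; per-group LD, tag bins and surrogate reports for
#' every index SNP. Writes the report bundle as TSV plus a run log, and is
#' deterministic given config + seed. Any stage error aborts the run and
#' removes partial outputs.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return named list of report paths plus the in-memory results, invisibly.
#' @export
run_locus_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_report(df, p)
    written <<- c(written, p)
    p
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- load ---------------------------------------------------------------
  inputs <- run_stage("load", {
    vcf <- read_vcf(config$vcf)
    note("loaded %d variants x %d samples (%d record(s) dropped)",
         vcf$genotypes$n_variants, vcf$genotypes$n_samples, vcf$n_dropped)
    man <- read_panel(config$panel, samples = colnames(vcf$genotypes$dosages))
    excl <- config$exclude
    if (!is.null(excl) && length(excl) == 1 && file.exists(excl))
      excl <- readLines(excl)
    if (!is.null(excl)) {
      n0 <- nrow(man)
      man <- man[!man$sample %in% excl, , drop = FALSE]
      class(man) <- c("sample_manifest", "data.frame")
      note("excluded %d sample(s) from exclusion list", n0 - nrow(man))
    }
    keep <- colnames(vcf$genotypes$dosages) %in% man$sample
    geno <- subset_genotypes(vcf$genotypes, samples = keep)
    note("analyzing %d samples in %d populations / %d groups",
         nrow(man), length(unique(man$population)), length(unique(man$group)))
    ann <- read_report(config$annotation)
    variants <- vcf$variants
    m <- match(variants$id, ann$id)
    if (anyNA(m)) stop(sum(is.na(m)), " variant(s) missing from annotation")
    variants$gene <- ann$gene[m]
    variants$category <- ann$category[m]
    variants$is_index <- as.logical(ann$is_index[m])
    list(geno = geno, man = man, variants = variants)
  })
  geno <- inputs$geno; man <- inputs$man; variants <- inputs$variants
  man <- man[match(colnames(geno$dosages), man$sample), , drop = FALSE]
  class(man) <- c("sample_manifest", "data.frame")
  groups <- sort(unique(man$group))
  paths <- list()
  results <- list()

  # --- per-variant statistics ----------------------------------------------
  run_stage("summary_stats", {
    af_all <- allele_frequencies(geno, scope_label = "all")
    af_grp <- lapply(groups, function(g)
      allele_frequencies(geno, man$group == g, scope_label = g))
    names(af_grp) <- groups
    results$af_all <- af_all
    results$af_grp <- af_grp
    paths$variant_stats <- emit(do.call(rbind, c(list(af_all), af_grp)),
                                 "variant_stats.tsv")
  })

  # --- differentiation ------------------------------------------------------
  run_stage("differentiation", {
    fst <- wc_fst_per_locus(geno, man$group)
    results$fst <- fst
    spec <- fst_spectrum_summary(fst, config$fst_threshold)
    note("per-locus F_ST: median %.4g, %.1f%% of %d defined loci below %.2f",
         spec$median_fst, 100 * spec$fraction_below, spec$n_loci,
         spec$threshold)
    results$fst_spectrum <- spec
    freq_cols <- sapply(groups, function(g)
      results$af_grp[[g]]$x2[match(fst$id, results$af_grp[[g]]$id)])
    colnames(freq_cols) <- paste0("x2_", groups)
    per_snp <- data.frame(id = fst$id,
                          pos = variants$pos[match(fst$id, variants$id)],
                          gene = variants$gene[match(fst$id, variants$id)],
                          category = variants$category[match(fst$id, variants$id)],
                          is_index = variants$is_index[match(fst$id, variants$id)],
                          freq_cols, fst = fst$fst, fis = fst$fis,
                          stringsAsFactors = FALSE)
    paths$per_snp_fst <- emit(per_snp, "per_snp_fst.tsv")

    pw <- pairwise_fst(geno, man, "group",
                       n_permutations = config$n_permutations,
                       seed = config$seed)
    results$pairwise_group <- pw
    m <- as.data.frame(pw$fst); m <- cbind(unit = rownames(pw$fst), m)
    paths$pairwise_fst_group <- emit(m, "pairwise_fst_group.tsv")
    pm <- as.data.frame(pw$p_value); pm <- cbind(unit = rownames(pw$p_value), pm)
    paths$pairwise_fst_group_p <- emit(pm, "pairwise_fst_group_pvalues.tsv")

    am <- amova(geno, man, n_permutations = min(config$n_permutations, 1000),
                seed = config$seed)
    results$amova <- am
    paths$amova <- emit(data.frame(
      component = c("among_groups", "among_pops_within_groups",
                    "within_populations"),
      sigma2 = c(am$sigma2_a, am$sigma2_b, am$sigma2_c),
      phi = unname(am$phi), p_value = unname(am$p_value),
      n_permutations = am$n_permutations), "amova.tsv")
  })

  # --- per-group diversity --------------------------------------------------
  run_stage("group_diversity", {
    L_total <- sum(unlist(config$lengths))
    mk_row <- function(scope, label) {
      rs <- region_summary(geno, L_total, scope)
      af <- if (label == "all") results$af_all else results$af_grp[[label]]
      data.frame(scope = label, n_individuals = if (is.null(scope)) nrow(man)
                 else sum(scope),
                 n_polymorphic = rs$K, heterozygosity = mean(af$het, na.rm = TRUE),
                 het_sd = stats::sd(af$het, na.rm = TRUE),
                 nucleotide_diversity = rs$pi, theta_w = rs$theta_w,
                 stringsAsFactors = FALSE)
    }
    tab <- rbind(mk_row(NULL, "all"),
                 do.call(rbind, lapply(groups, function(g)
                   mk_row(man$group == g, g))))
    results$group_diversity <- tab
    paths$group_diversity <- emit(tab, "group_diversity.tsv")
  })

  # --- category tables and contrasts ---------------------------------------
  run_stage("category_compare", {
    cat_all <- category_summary(variants, results$af_all, results$fst,
                                config$lengths, scope_label = "all")
    cat_grp <- do.call(rbind, lapply(groups, function(g)
      category_summary(variants, results$af_grp[[g]], results$fst,
                       config$lengths,
                       n_chrom = 2 * sum(man$group == g), scope_label = g)))
    results$category_stats <- rbind(cat_all, cat_grp)
    paths$category_table <- emit(rbind(cat_all, cat_grp), "category_table.tsv")

    ct <- category_contrasts(variants, results$af_all, results$fst)
    results$contrasts <- ct
    paths$comparisons <- emit(ct, "comparisons.tsv")

    if (length(groups) >= 2) {
      combos <- utils::combn(groups, 2)
      cor_rows <- lapply(seq_len(ncol(combos)), function(k) {
        g1 <- combos[1, k]; g2 <- combos[2, k]
        r_maf <- group_correlation(results$af_grp[[g1]]$maf,
                                   results$af_grp[[g2]]$maf)
        r_het <- group_correlation(results$af_grp[[g1]]$het,
                                   results$af_grp[[g2]]$het)
        data.frame(group_a = g1, group_b = g2, r2_maf = r_maf$r2,
                   r2_het = r_het$r2, n_pairs = r_maf$n_pairs,
                   stringsAsFactors = FALSE)
      })
      results$group_correlations <- do.call(rbind, cor_rows)
      paths$group_correlations <- emit(results$group_correlations,
                                        "group_correlations.tsv")
    }
  })

  # --- LD, tags, surrogates -------------------------------------------------
  run_stage("ld_tagging", {
    index_ids <- variants$id[variants$is_index %in% TRUE]
    surr_counts <- matrix(0L, length(index_ids), length(groups),
                          dimnames = list(index_ids, groups))
    tag_rows <- list()
    for (g in groups) {
      scope <- man$group == g
      pairs <- ld_matrix(geno, variants, scope, maf_min = 0)
      af_g <- results$af_grp[[g]]
      info <- data.frame(id = af_g$id, maf = af_g$maf,
                         pos = variants$pos[match(af_g$id, variants$id)],
                         stringsAsFactors = FALSE)
      pass <- info[!is.na(info$maf) & info$maf >= config$maf_min, ,
                   drop = FALSE]
      pass_pairs <- pairs[pairs$id_a %in% pass$id & pairs$id_b %in% pass$id, ,
                          drop = FALSE]
      bins <- greedy_tag_selection(pass_pairs, pass, r2_min = config$tag_r2)
      if (nrow(bins) > 0) {
        bins$scope <- g
        tag_rows[[g]] <- bins
        note("%s: %d MAF-passing variants in %d tag bins", g, nrow(bins),
             length(unique(bins$bin)))
      }
      for (idx in index_ids) {
        ss <- find_surrogates(idx, pairs, info, r2_min = config$surrogate_r2,
                              max_dist = config$max_dist,
                              maf_min = config$maf_min)
        surr_counts[idx, g] <- ss$n_surrogates
      }
    }
    if (length(tag_rows) > 0)
      paths$tag_bins <- emit(do.call(rbind, tag_rows), "tag_bins.tsv")
    surr <- data.frame(id = index_ids,
                       pos = variants$pos[match(index_ids, variants$id)],
                       gene = variants$gene[match(index_ids, variants$id)],
                       surr_counts, stringsAsFactors = FALSE)
    results$surrogates <- surr
    paths$surrogate_table <- emit(surr, "surrogate_table.tsv")
  })

  log_lines <- c(log_lines,
                 sprintf("inputs: %d variants, %d samples", geno$n_variants,
                         geno$n_samples),
                 sprintf("seed: %s; permutations: %d",
                         format(config$seed), config$n_permutations))
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths$log <- log_path
  invisible(list(paths = paths, results = results, log = log_lines))
}
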