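# Containers and file I/O: genotype matrix, variant table, sample manifest.
# Coordinates are 1-based inclusive throughout (VCF/GRanges convention).

VALID_CATEGORIES <- c("upstream", "intron", "utr", "synonymous",
                      "non-synonymous", "intergenic", "downstream")

#' Construct a genotype matrix
#'
#' A diploid allele-dosage store for biallelic SNVs: a variants x samples
#' integer matrix of alternate-allele dosages in \{0, 1, 2\} with `NA` for
#' missing genotypes, optionally backed by phased haplotypes.
#'
#' @param dosages integer matrix (variants x samples) of alt-allele dosages;
#'   rownames are variant ids, colnames sample ids.
#' @param hap1,hap2 optional 0/1 matrices of the same shape holding the two
#'   chromosome copies; required together. When present, `hap1 + hap2` must
#'   equal `dosages` wherever not missing.
#' @param phased logical flag; `TRUE` only when haplotypes are meaningful.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `hap1`, `hap2`, `phased`, `n_variants`, `n_samples`.
#' @export
genotype_matrix <- function(dosages, hap1 = NULL, hap2 = NULL, phased = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (xor(is.null(hap1), is.null(hap2))) stop("hap1 and hap2 required together")
  if (!is.null(hap1)) {
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    if (!identical(dim(hap1), dim(dosages)) || !identical(dim(hap2), dim(dosages)))
      stop("haplotype matrices must match dosage dimensions")
    s <- hap1 + hap2
    ok <- is.na(dosages) | (!is.na(s) & s == dosages)
    if (!all(ok)) stop("haplotypes inconsistent with dosages")
  }
  structure(list(dosages = dosages, hap1 = hap1, hap2 = hap2,
                 phased = isTRUE(phased),
                 n_variants = nrow(dosages), n_samples = ncol(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%s)\n",
              x$n_variants, x$n_samples,
              if (x$phased) "phased" else "unphased"))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix by variants and/or samples
#'
#' @param geno a [genotype_matrix()].
#' @param variants,samples index vectors (logical, integer or names); `NULL`
#'   keeps everything.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, variants = NULL, samples = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(variants)) variants <- seq_len(geno$n_variants)
  if (is.null(samples))  samples  <- seq_len(geno$n_samples)
  sub <- function(m) if (is.null(m)) NULL else m[variants, samples, drop = FALSE]
  genotype_matrix(sub(geno$dosages), sub(geno$hap1), sub(geno$hap2),
                  phased = geno$phased)
}

#' Construct a variant table
#'
#' Per-variant coordinates, alleles, gene label, functional category and
#' index-SNP flag. Positions must be non-decreasing within a chromosome and
#' every record biallelic (single REF/ALT base).
#'
#' @param chrom,pos,id,ref,alt,gene,category,is_index per-variant vectors;
#'   `category` must be one of upstream, intron, utr, synonymous,
#'   non-synonymous, intergenic, downstream (or `NA` before annotation).
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, id, ref, alt,
                          gene = NA_character_, category = NA_character_,
                          is_index = FALSE) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   id = as.character(id), ref = as.character(ref),
                   alt = as.character(alt), gene = as.character(gene),
                   category = as.character(category),
                   is_index = as.logical(is_index),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate variant ids")
  ok_cat <- is.na(df$category) | df$category %in% VALID_CATEGORIES
  if (!all(ok_cat))
    stop("invalid category: ", paste(unique(df$category[!ok_cat]), collapse = ", "))
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Construct a sample manifest
#'
#' Maps each sample to exactly one population and each population to exactly
#' one ancestral group (e.g. the AFR/EUR/AM/EA hierarchy of a reference
#' panel).
#'
#' @param sample,population,group character vectors of equal length.
#' @return a `data.frame` of class `sample_manifest`.
#' @export
sample_manifest <- function(sample, population, group) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   group = as.character(group), stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  pg <- unique(df[, c("population", "group")])
  if (anyDuplicated(pg$population))
    stop("population mapped to more than one group")
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Read biallelic SNVs from a VCF file
#'
#' Loads GT fields into a [genotype_matrix()] and site records into a
#' [variant_table()]. Multi-allelic records, non-SNVs (indels, symbolic
#' alleles) and records without GT are dropped, with a message reporting the
#' count. The matrix is flagged phased only when every non-missing genotype
#' separator is `|`.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param region optional `list(chrom =, start =, end =)` restricting to a
#'   1-based inclusive interval.
#' @return `list(genotypes = genotype_matrix, variants = variant_table,
#'   n_dropped = count)`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) stop("VCF contains no variant records")
  if (is.null(v@gt) || ncol(v@gt) < 2) stop("VCF has no sample genotype columns")

  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!is.null(region)) {
    pos <- as.integer(fix$POS)
    keep <- keep & fix$CHROM == region$chrom &
      pos >= region$start & pos <= region$end
  }
  n_dropped <- n_in - sum(keep)
  if (sum(keep) == 0) stop("no biallelic SNVs retained",
                           if (!is.null(region)) " in region" else "")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  rownames(gt) <- ids

  gt[gt %in% c(".", "./.", ".|.")] <- NA
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE)) && any(!is.na(gt))
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  hap1 <- matrix(a1, nrow = nrow(gt), dimnames = dimnames(gt))
  hap2 <- matrix(a2, nrow = nrow(gt), dimnames = dimnames(gt))
  dos <- hap1 + hap2

  variants <- variant_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                            id = ids, ref = fix$REF, alt = fix$ALT)
  geno <- if (phased) genotype_matrix(dos, hap1, hap2, phased = TRUE)
          else genotype_matrix(dos, phased = FALSE)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped (multi-allelic, non-SNV or outside region)")
  list(genotypes = geno, variants = variants, n_dropped = n_dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample panel file
#'
#' Tab-separated text with header columns `sample`, `population`, `group`.
#' When `samples` is supplied (the genotype file's sample ids), panel rows
#' are restricted to it and samples missing from the panel are reported and
#' excluded.
#'
#' @param path panel file path.
#' @param samples optional character vector of genotyped sample ids.
#' @return a [sample_manifest()]; when `samples` was given, attribute
#'   `excluded` lists genotyped samples absent from the panel.
#' @export
read_panel <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("cannot read panel: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "population", "group")
  if (!all(need %in% names(df)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  man <- sample_manifest(df$sample, df$population, df$group)
  if (!is.null(samples)) {
    excluded <- character(0)
    excluded <- setdiff(samples, man$sample)
    if (length(excluded) > 0)
      warning(length(excluded), " genotyped sample(s) absent from panel; excluded: ",
              paste(utils::head(excluded, 5), collapse = ", "),
              if (length(excluded) > 5) ", ..." else "")
    man <- man[man$sample %in% samples, , drop = FALSE]
    class(man) <- c("sample_manifest", "data.frame")
    attr(man, "excluded") <- excluded
  }
  man
}

#' Assign functional categories from a gene model
#'
#' Labels each variant by interval overlap: exonic variants take their coding
#' consequence (`synonymous` / `non-synonymous`) or `utr`; variants inside a
#' gene span but no exon are `intron`; variants within `flank` bp upstream or
#' downstream of the nearest gene span are `upstream` / `downstream`;
#' everything else is `intergenic` (with a warning for variants outside all
#' annotation).
#'
#' @param variants a [variant_table()].
#' @param gene_model data.frame with columns `gene`, `feature` (one of
#'   `gene`, `exon`, `utr`), `start`, `end` (1-based inclusive).
#' @param consequence optional named character vector (`variant id` ->
#'   `synonymous` / `non-synonymous`) for exonic coding variants.
#' @param flank bp defining the upstream/downstream flanks (default 10000).
#' @return the variant table with `gene` and `category` filled in; attribute
#'   `category_counts` tabulates the assignment.
#' @export
assign_categories <- function(variants, gene_model, consequence = NULL,
                              flank = 10000) {
  stopifnot(inherits(variants, "variant_table"))
  need <- c("gene", "feature", "start", "end")
  if (!all(need %in% names(gene_model)))
    stop("gene_model must have columns: ", paste(need, collapse = ", "))
  genes <- gene_model[gene_model$feature == "gene", , drop = FALSE]
  exons <- gene_model[gene_model$feature == "exon", , drop = FALSE]
  utrs  <- gene_model[gene_model$feature == "utr", , drop = FALSE]
  if (nrow(genes) == 0) stop("gene_model contains no gene spans")

  in_span <- function(pos, spans) {
    hit <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(spans))) {
      sel <- is.na(hit) & pos >= spans$start[i] & pos <= spans$end[i]
      hit[sel] <- i
    }
    hit
  }

  pos <- variants$pos
  cat_out <- rep(NA_character_, length(pos))
  gene_out <- rep("intergenic", length(pos))

  g_hit <- in_span(pos, genes)
  e_hit <- in_span(pos, exons)
  u_hit <- in_span(pos, utrs)

  inside <- !is.na(g_hit)
  gene_out[inside] <- genes$gene[g_hit[inside]]

  exonic <- inside & !is.na(e_hit)
  if (any(exonic)) {
    cons <- rep(NA_character_, sum(exonic))
    if (!is.null(consequence))
      cons <- unname(consequence[variants$id[exonic]])
    bad <- !is.na(cons) & !cons %in% c("synonymous", "non-synonymous")
    if (any(bad)) stop("consequence must be synonymous or non-synonymous")
    cat_out[exonic] <- ifelse(is.na(cons), "utr", cons)
  }
  utr_only <- inside & is.na(e_hit) & !is.na(u_hit)
  cat_out[utr_only] <- "utr"
  intronic <- inside & is.na(cat_out)
  cat_out[intronic] <- "intron"

  # outside all gene spans: between two genes is intergenic; only positions
  # before the first gene (within flank) are upstream and positions after
  # the last gene are downstream
  outside <- !inside
  if (any(outside)) {
    first_start <- min(genes$start); last_end <- max(genes$end)
    n_far <- 0L
    for (i in which(outside)) {
      if (pos[i] < first_start) {
        if (first_start - pos[i] <= flank) {
          j <- which.min(genes$start - pos[i] + ifelse(genes$start > pos[i], 0, Inf))
          cat_out[i] <- "upstream"; gene_out[i] <- genes$gene[j]
        } else {
          cat_out[i] <- "intergenic"; n_far <- n_far + 1L
        }
      } else if (pos[i] > last_end) {
        if (pos[i] - last_end <= flank) {
          j <- which.min(pos[i] - genes$end + ifelse(genes$end < pos[i], 0, Inf))
          cat_out[i] <- "downstream"; gene_out[i] <- genes$gene[j]
        } else {
          cat_out[i] <- "intergenic"; n_far <- n_far + 1L
        }
      } else {
        cat_out[i] <- "intergenic"
      }
    }
    if (n_far > 0)
      warning(n_far, " variant(s) outside all annotation; labeled intergenic")
  }

  variants$gene <- gene_out
  variants$category <- cat_out
  attr(variants, "category_counts") <- table(factor(cat_out, VALID_CATEGORIES))
  variants
}

#' Write a report table as TSV
#'
#' All pipeline reports go through this writer: tab-separated, header row,
#' no quoting, `NA` rendered as empty.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path file written by [write_report()].
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write genotypes to a (plain-text) VCF 4.2 file
#'
#' Phased genotype matrices are written with `|` separators from their
#' haplotypes; unphased with `/` from dosages (heterozygotes as `0/1`).
#'
#' @param geno a [genotype_matrix()].
#' @param variants the matching [variant_table()].
#' @param path output path (`.vcf`, uncompressed).
#' @param extra_header optional character vector of additional `##` lines
#'   (e.g. a simulation seed record).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path, extra_header = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(variants, "variant_table"))
  if (nrow(variants) != geno$n_variants) stop("variant table / matrix mismatch")
  samples <- colnames(geno$dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(geno$n_samples))
  if (geno$phased && !is.null(geno$hap1)) {
    gt <- matrix(paste0(geno$hap1, "|", geno$hap2), nrow = geno$n_variants)
    gt[is.na(geno$hap1) | is.na(geno$hap2)] <- ".|."
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosages + 1L], nrow = geno$n_variants)
    gt[is.na(geno$dosages)] <- "./."
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=locusdiv",
              extra_header,
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a sample panel TSV
#'
#' @param manifest a [sample_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(manifest, path) {
  stopifnot(inherits(manifest, "sample_manifest"))
  write_report(as.data.frame(manifest), path)
}
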