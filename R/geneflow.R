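# Detection of outside gene flow into a backcross-founded population:
# catalogue every allele carried by the BC1 founders at well-genotyped sites,
# then score later samples for called alleles absent from that catalogue.

#' Read diploid genotype calls from a VCF
#'
#' Thin wrapper around `VariantAnnotation::readVcf()` producing the
#' allele-string representation used by the gene-flow functions. Only the GT
#' field is consumed; alleles are normalized to uppercase strings.
#' Multi-allelic sites are supported.
#'
#' @param path Path to a VCF 4.2 file with a GT FORMAT field.
#' @return A list of class `genotype_calls`: `sites` (chrom, pos, ref, alt
#'   comma-joined), `a1` and `a2` (sites x samples character matrices, `NA`
#'   for missing) and `samples`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF files requires the VariantAnnotation package",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  ref <- toupper(as.character(VariantAnnotation::ref(vcf)))
  alt_list <- lapply(VariantAnnotation::alt(vcf),
                     function(a) toupper(as.character(a)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref,
    alt = vapply(alt_list, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  ns <- nrow(gt)
  a1 <- matrix(NA_character_, ns, ncol(gt), dimnames = dimnames(gt))
  a2 <- a1
  split_gt <- strsplit(gt, "[/|]")
  idx1 <- suppressWarnings(as.integer(vapply(split_gt, `[`, character(1), 1)))
  idx2 <- suppressWarnings(as.integer(vapply(split_gt, function(x)
    if (length(x) >= 2) x[2] else NA_character_, character(1))))
  dim(idx1) <- dim(gt); dim(idx2) <- dim(gt)
  alleles_of <- function(i) c(ref[i], alt_list[[i]])
  for (i in seq_len(ns)) {
    al <- alleles_of(i)
    a1[i, ] <- al[idx1[i, ] + 1L]
    a2[i, ] <- al[idx2[i, ] + 1L]
  }
  structure(list(sites = sites, a1 = a1, a2 = a2, samples = colnames(gt)),
            class = "genotype_calls")
}

#' Build the BC1 allele catalogue
#'
#' Restricts to sites genotyped in at least `min_samples` BC1 (founder)
#' samples, and records for each retained site the set of alleles (reference
#' or alternate) carried by any BC1 genotype there. Alleles seen only in
#' non-founder samples never enter the catalogue; later samples are scored
#' against it for outside gene flow.
#'
#' @param genotypes A `genotype_calls` or `genotype_sim` object.
#' @param bc1_samples Character vector of founder sample IDs (must be present
#'   in the genotypes).
#' @param min_samples Minimum non-missing BC1 genotypes per retained site
#'   (default 20).
#' @return A list of class `allele_catalogue`: `alleles` (list of allele
#'   sets, one per retained site), `site_index` (row indices into the input
#'   sites), `bc1_count` (non-missing founder genotypes per retained site),
#'   `min_samples`, `sites`.
#' @export
build_allele_catalogue <- function(genotypes, bc1_samples, min_samples = 20) {
  g <- as_genotype_calls(genotypes)
  if (length(bc1_samples) == 0L) stop("empty BC1 sample set", call. = FALSE)
  missing_ids <- setdiff(bc1_samples, g$samples)
  if (length(missing_ids) > 0L) {
    stop("BC1 sample(s) not in genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  bc <- match(bc1_samples, g$samples)
  a1 <- g$a1[, bc, drop = FALSE]
  a2 <- g$a2[, bc, drop = FALSE]
  n_called <- rowSums(!is.na(a1) & !is.na(a2))
  keep <- which(n_called >= min_samples)
  alleles <- lapply(keep, function(i) {
    sort(unique(stats::na.omit(c(a1[i, ], a2[i, ]))))
  })
  structure(list(alleles = alleles, site_index = keep,
                 bc1_count = n_called[keep], min_samples = min_samples,
                 sites = g$sites[keep, , drop = FALSE]),
            class = "allele_catalogue")
}

#' Fraction of a sample's called alleles absent from the catalogue
#'
#' Scores one sample at the catalogued sites. In the default
#' `"allele"` unit, each called diploid genotype contributes two allele
#' observations and a heterozygous novel call counts 1 of 2; in the
#' `"variant"` unit a site counts once and is novel if either of its called
#' alleles is outside the catalogue. Missing calls are skipped.
#'
#' @param genotypes A `genotype_calls` or `genotype_sim` object.
#' @param sample Sample ID.
#' @param catalogue An `allele_catalogue` built from the same site set.
#' @param unit `"allele"` (default) or `"variant"`.
#' @return Percentage in \[0, 100\], or `NA` (with a warning) if the sample
#'   has no called genotype at any catalogued site.
#' @export
novel_allele_fraction <- function(genotypes, sample, catalogue,
                                  unit = c("allele", "variant")) {
  unit <- match.arg(unit)
  g <- as_genotype_calls(genotypes)
  j <- match(sample, g$samples)
  if (is.na(j)) stop("sample not found: ", sample, call. = FALSE)
  a1 <- g$a1[catalogue$site_index, j]
  a2 <- g$a2[catalogue$site_index, j]
  called <- !is.na(a1) & !is.na(a2)
  if (!any(called)) {
    warning("sample ", sample, " has no called variants at catalogued sites",
            call. = FALSE)
    return(NA_real_)
  }
  idx <- which(called)
  novel1 <- !mapply(function(i, a) a %in% catalogue$alleles[[i]], idx, a1[idx])
  novel2 <- !mapply(function(i, a) a %in% catalogue$alleles[[i]], idx, a2[idx])
  if (unit == "allele") {
    100 * sum(novel1 + novel2) / (2 * length(idx))
  } else {
    100 * sum(novel1 | novel2) / length(idx)
  }
}

#' Per-sample and per-generation gene-flow summary
#'
#' Computes each sample's novel-allele percentage against the BC1 catalogue,
#' flags samples at or above the admixture threshold, and aggregates by
#' generation: fraction of admixed samples, mean novel percentage over all
#' samples, and mean over admixed samples only.
#'
#' @param genotypes A `genotype_calls` or `genotype_sim` object.
#' @param catalogue An [build_allele_catalogue()] result.
#' @param generation_map Named vector mapping every scored sample ID to its
#'   generation (a `genotype_sim` carries one as `$generation`).
#' @param samples Samples to score (default: all mapped samples present).
#' @param threshold Admixture threshold on the novel percentage
#'   (default 0.5, i.e. samples below 0.5\% novel alleles are treated as
#'   having no outside ancestry).
#' @param unit Passed to [novel_allele_fraction()].
#' @return A list of class `gene_flow_report` with `per_sample` (sample,
#'   generation, novel_pct, admixed) and `per_generation` (generation,
#'   n, fraction_admixed, mean_novel_pct, mean_novel_pct_admixed).
#' @export
summarize_gene_flow <- function(genotypes, catalogue, generation_map,
                                samples = NULL, threshold = 0.5,
                                unit = c("allele", "variant")) {
  unit <- match.arg(unit)
  g <- as_genotype_calls(genotypes)
  if (is.null(samples)) samples <- intersect(g$samples, names(generation_map))
  unmapped <- setdiff(samples, names(generation_map))
  if (length(unmapped) > 0L) {
    stop("sample(s) without a generation: ",
         paste(utils::head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  pct <- vapply(samples, function(s)
    suppressWarnings(novel_allele_fraction(g, s, catalogue, unit)), numeric(1))
  per_sample <- data.frame(
    sample = samples,
    generation = as.integer(generation_map[samples]),
    novel_pct = pct,
    admixed = !is.na(pct) & pct >= threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  gens <- sort(unique(per_sample$generation))
  per_generation <- do.call(rbind, lapply(gens, function(gen) {
    sub <- per_sample[per_sample$generation == gen & !is.na(per_sample$novel_pct), ]
    data.frame(generation = gen, n = nrow(sub),
               fraction_admixed = mean(sub$admixed),
               mean_novel_pct = mean(sub$novel_pct),
               mean_novel_pct_admixed =
                 if (any(sub$admixed)) mean(sub$novel_pct[sub$admixed]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per_sample, per_generation = per_generation,
                 threshold = threshold, unit = unit),
            class = "gene_flow_report")
}

#' Read a sample-to-generation map from a two-column CSV
#' @param path CSV with columns `sample` and `generation`.
#' @return Named integer vector (sample -> generation).
#' @export
read_generation_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "generation") %in% names(df))) {
    stop("generation map needs 'sample' and 'generation' columns", call. = FALSE)
  }
  stats::setNames(as.integer(df$generation), df$sample)
}

#' Write gene-flow reports as CSV
#' @param report A `gene_flow_report`.
#' @param per_sample_path,per_generation_path Output paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_gene_flow_csv <- function(report, per_sample_path = NULL,
                                per_generation_path = NULL) {
  if (!is.null(per_sample_path)) {
    utils::write.csv(report$per_sample, per_sample_path, row.names = FALSE)
  }
  if (!is.null(per_generation_path)) {
    utils::write.csv(report$per_generation, per_generation_path, row.names = FALSE)
  }
  invisible(c(per_sample_path, per_generation_path))
}
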