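test_that("catalogue keeps only sites with enough genotyped founders", {
  # 2 sites x 25 BC1 samples; site 2 missing in 6 samples (19 called < 20)
  n <- 25
  a1 <- rbind(rep("A", n), rep("G", n))
  a2 <- rbind(rep(c("A", "T"), length.out = n), rep("G", n))
  a1[2, 1:6] <- NA; a2[2, 1:6] <- NA
  g <- make_geno(a1, a2, paste0("bc", 1:n), ref = c("A", "G"),
                 alt = c("T", "C"))
  cat_ <- build_allele_catalogue(g, g$samples, min_samples = 20)
  expect_equal(cat_$site_index, 1L)
  expect_equal(cat_$alleles[[1]], c("A", "T"))  # union of {A/A, A/T}
})

test_that("alleles seen only in non-founder samples stay out of the catalogue", {
  n <- 21
  a1 <- matrix("A", 1, n + 1); a2 <- matrix("A", 1, n + 1)
  a2[1, n + 1] <- "C"  # later-generation sample carries C
  g <- make_geno(a1, a2, c(paste0("bc", 1:n), "late1"))
  cat_ <- build_allele_catalogue(g, paste0("bc", 1:n), min_samples = 20)
  expect_equal(cat_$alleles[[1]], "A")
  expect_error(build_allele_catalogue(g, character(0)), "empty")
  expect_error(build_allele_catalogue(g, "missing_sample"), "not in genotypes")
})

test_that("novel-allele percentage counts allele observations at catalogued sites", {
  # 200 catalogued sites, founder allele A everywhere; the focal sample is
  # heterozygous novel (A/C) at 5 sites -> 5 novel of 400 observations
  ns <- 200
  founders <- paste0("bc", 1:25)
  a1 <- matrix("A", ns, 26); a2 <- matrix("A", ns, 26)
  a2[1:5, 26] <- "C"
  g <- make_geno(a1, a2, c(founders, "s1"))
  cat_ <- build_allele_catalogue(g, founders, min_samples = 20)
  expect_equal(novel_allele_fraction(g, "s1", cat_), 100 * 5 / 400)  # 1.25%
  # per-variant unit: 5 novel sites of 200
  expect_equal(novel_allele_fraction(g, "s1", cat_, unit = "variant"), 2.5)
  # founder sample scores 0 against its own catalogue
  expect_equal(novel_allele_fraction(g, "bc1", cat_), 0)
})

test_that("the 0.5% admixture threshold separates trace from real gene flow", {
  # 1 novel allele observation out of 250 -> 0.4%, below threshold
  ns <- 125
  founders <- paste0("bc", 1:25)
  a1 <- matrix("A", ns, 26); a2 <- matrix("A", ns, 26)
  a2[1, 26] <- "C"
  g <- make_geno(a1, a2, c(founders, "s1"))
  cat_ <- build_allele_catalogue(g, founders, min_samples = 20)
  expect_equal(novel_allele_fraction(g, "s1", cat_), 0.4)
  gmap <- setNames(c(rep(1L, 25), 3L), g$samples)
  rep_ <- summarize_gene_flow(g, cat_, gmap)
  expect_false(rep_$per_sample$admixed[rep_$per_sample$sample == "s1"])
  expect_equal(rep_$per_generation$fraction_admixed, c(0, 0))
})

test_that("a closed simulated population reports zero admixture everywhere", {
  gs <- simulate_genotypes(genotype_sim_config(
    n_sites = 250, m = 0, n_generations = 4, pop_size = 80, n_per_gen = 25),
    seed = 22)
  g <- as_genotype_calls(gs)
  cat_ <- build_allele_catalogue(g, gs$samples[gs$generation == 1], 20)
  rep_ <- summarize_gene_flow(g, cat_, gs$generation)
  expect_true(all(rep_$per_sample$novel_pct == 0, na.rm = TRUE))
  expect_true(all(rep_$per_generation$fraction_admixed == 0))
})

test_that("catalogue grows monotonically as founder samples are added", {
  gs <- simulate_genotypes(genotype_sim_config(
    n_sites = 150, m = 0, n_generations = 1, n_bc1 = 60, pop_size = 60,
    missing_rate = 0), seed = 23)
  g <- as_genotype_calls(gs)
  small <- build_allele_catalogue(g, gs$samples[1:30], min_samples = 20)
  big <- build_allele_catalogue(g, gs$samples[1:60], min_samples = 20)
  common <- intersect(small$site_index, big$site_index)
  for (s in common) {
    expect_true(all(small$alleles[[match(s, small$site_index)]] %in%
                      big$alleles[[match(s, big$site_index)]]))
  }
})

test_that("unmapped samples and zero-call samples are flagged", {
  founders <- paste0("bc", 1:21)
  a1 <- matrix("A", 30, 22); a2 <- matrix("A", 30, 22)
  a1[, 22] <- NA; a2[, 22] <- NA  # s1 has no calls at all
  g <- make_geno(a1, a2, c(founders, "s1"))
  cat_ <- build_allele_catalogue(g, founders, min_samples = 20)
  expect_warning(p <- novel_allele_fraction(g, "s1", cat_), "no called")
  expect_true(is.na(p))
  expect_error(summarize_gene_flow(g, cat_, setNames(1L, "bc1"),
                                   samples = c("bc1", "s1")),
               "without a generation")
})

test_that("VCF output round-trips through VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  gs <- simulate_genotypes(genotype_sim_config(
    n_sites = 40, m = 0.2, n_generations = 3, pop_size = 40, n_per_gen = 10,
    n_bc1 = 25, missing_rate = 0.1), seed = 24)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gs, path)
  back <- suppressWarnings(read_genotypes_vcf(path))
  direct <- as_genotype_calls(gs)
  expect_equal(back$samples, direct$samples)
  expect_equal(unname(back$a1), unname(direct$a1))
  expect_equal(unname(back$a2), unname(direct$a2))
  # gene-flow summaries agree between the two routes
  cat_v <- build_allele_catalogue(back, gs$samples[gs$generation == 1], 15)
  cat_d <- build_allele_catalogue(direct, gs$samples[gs$generation == 1], 15)
  rep_v <- summarize_gene_flow(back, cat_v, gs$generation)
  rep_d <- summarize_gene_flow(direct, cat_d, gs$generation)
  expect_equal(rep_v$per_generation, rep_d$per_generation)
})

test_that("generation maps read from CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("a", "b"), generation = c(1, 3)), path,
            row.names = FALSE)
  gm <- read_generation_map(path)
  expect_equal(gm, c(a = 1L, b = 3L))
  write.csv(data.frame(x = 1), path, row.names = FALSE)
  expect_error(read_generation_map(path), "columns")
})
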