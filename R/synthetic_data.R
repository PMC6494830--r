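# Seeded generators for phenotype tables and BC1-derived genotype matrices
# with the statistical structure the downstream analyses assume: per-lineage
# linear generational trends in standardized traits, a generation-1 cohort
# with known selection gradients, and a closed backcross population receiving
# migrant gametes at a configurable rate.

#' Configuration for the phenotype-table simulator
#'
#' Defaults emulate the planting design of an eight-year, three-lineage field
#' experiment: a control and a hybrid lineage followed over generations 1 and
#' 5-8 plus a second hybrid lineage with generations 1 and 8 only, 60 plants
#' in the endpoint generations (1 and 8) and 30 in intermediate ones, and a
#' locally adapted reference cohort. Per-trait trend slopes default to the
#' published per-trait haldane rates (standardized units per generation) and
#' fitness slopes to the published standardized fitness slopes (0.001
#' control, 0.154 / 0.115 for the two hybrid lineages); residual SD defaults
#' to 1 so slopes are on the phenotypic-SD scale.
#'
#' @param lineages Experimental lineages to simulate.
#' @param generations Either a numeric vector used for every lineage or a
#'   named list of generation vectors per lineage.
#' @param n_per_gen Plants per generation per lineage: a single count, or a
#'   vector `c(endpoint =, intermediate =)` (defaults 60 / 30).
#' @param traits Trait columns to simulate (default: all 27).
#' @param trait_slopes Named list `lineage -> named slope vector`; defaults
#'   to the published haldane table.
#' @param trait_intercepts Named list like `trait_slopes` (default all 0).
#' @param residual_sd Residual SD per trait (single value or named; default 1).
#' @param fitness_intercepts,fitness_slopes Named per-lineage values for the
#'   fitness trend (defaults: intercepts 5 / 4.7 / 4.7, slopes 0.001 / 0.154
#'   / 0.115 for control / hybrid_LBJ / hybrid_BFL).
#' @param fitness_sd Fitness residual SD (default 1); fitness is truncated
#'   at 0 (seed counts cannot be negative).
#' @param texanus_means Named trait means of the locally adapted reference.
#'   Default places the reference at `hybrid_LBJ slope / 0.12` for each
#'   trait, emulating a world in which lineages evolve toward the local
#'   phenotype at a rate proportional to their distance from it.
#' @param texanus_fitness_mean Mean reference fitness (default 7).
#' @param n_texanus Reference plants (default 60; 0 to omit).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(lineages = c("control", "hybrid_LBJ", "hybrid_BFL"),
                              generations = NULL,
                              n_per_gen = c(endpoint = 60, intermediate = 30),
                              traits = fieldevol_traits(),
                              trait_slopes = NULL,
                              trait_intercepts = NULL,
                              residual_sd = 1,
                              fitness_intercepts = c(control = 5, hybrid_LBJ = 4.7,
                                                     hybrid_BFL = 4.7),
                              fitness_slopes = c(control = 0.001, hybrid_LBJ = 0.154,
                                                 hybrid_BFL = 0.115),
                              fitness_sd = 1,
                              texanus_means = NULL,
                              texanus_fitness_mean = 7,
                              n_texanus = 60) {
  if (is.null(generations)) {
    generations <- list(control = c(1, 5:8), hybrid_LBJ = c(1, 5:8),
                        hybrid_BFL = c(1, 8))
  }
  if (!is.list(generations)) {
    generations <- stats::setNames(rep(list(generations), length(lineages)),
                                   lineages)
  }
  published <- tryCatch(published_haldanes(), error = function(e) NULL)
  if (is.null(trait_slopes)) {
    if (is.null(published)) stop("published rate table unavailable", call. = FALSE)
    trait_slopes <- lapply(
      stats::setNames(c("control", "hybrid_LBJ", "hybrid_BFL"),
                      c("control", "hybrid_LBJ", "hybrid_BFL")),
      function(l) stats::setNames(published[[l]], published$trait))
  }
  if (is.null(trait_intercepts)) {
    trait_intercepts <- lapply(stats::setNames(lineages, lineages),
                               function(l) stats::setNames(rep(0, length(traits)), traits))
  }
  if (length(residual_sd) == 1L && is.null(names(residual_sd))) {
    residual_sd <- stats::setNames(rep(residual_sd, length(traits)), traits)
  }
  if (any(residual_sd <= 0) || fitness_sd <= 0) {
    stop("residual SDs must be positive", call. = FALSE)
  }
  if (is.null(texanus_means)) {
    texanus_means <- stats::setNames(
      vapply(traits, function(tr) {
        s <- trait_slopes[["hybrid_LBJ"]][tr]
        if (is.null(s) || is.na(s)) 0 else unname(s) / 0.12
      }, numeric(1)), traits)
  }
  if (length(n_per_gen) == 1L) {
    n_per_gen <- c(endpoint = unname(n_per_gen), intermediate = unname(n_per_gen))
  }
  if (any(n_per_gen < 1)) stop("counts must be >= 1", call. = FALSE)
  structure(list(lineages = lineages, generations = generations,
                 n_per_gen = n_per_gen, traits = traits,
                 trait_slopes = trait_slopes, trait_intercepts = trait_intercepts,
                 residual_sd = residual_sd,
                 fitness_intercepts = fitness_intercepts,
                 fitness_slopes = fitness_slopes, fitness_sd = fitness_sd,
                 texanus_means = texanus_means,
                 texanus_fitness_mean = texanus_fitness_mean,
                 n_texanus = n_texanus),
            class = "simulation_config")
}

#' Simulate a multi-generation phenotype table
#'
#' Each trait value is `lineage intercept + slope * generation +
#' Normal(0, residual SD)`; fitness follows the same linear structure with
#' its own slope and is truncated at 0. Reference (`texanus`) rows are drawn
#' around their configured means with no generational role. Output is
#' byte-identical under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `phenotype_table`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  blocks <- list()
  for (lin in config$lineages) {
    gens <- config$generations[[lin]]
    gen_range <- range(gens)
    for (g in gens) {
      n <- if (g %in% gen_range) config$n_per_gen[["endpoint"]] else
        config$n_per_gen[["intermediate"]]
      df <- data.frame(
        plant_id = sprintf("%s_g%d_%03d", lin, g, seq_len(n)),
        lineage = lin, generation = g,
        longevity_days = 100, transplant_death = FALSE,
        scarification_damage = FALSE, apical_bud_weevil = FALSE,
        stringsAsFactors = FALSE)
      for (tr in config$traits) {
        mu <- config$trait_intercepts[[lin]][tr] +
          config$trait_slopes[[lin]][tr] * g
        if (is.na(mu)) mu <- 0
        df[[tr]] <- stats::rnorm(n, unname(mu), config$residual_sd[tr])
      }
      df$fitness <- pmax(0, stats::rnorm(
        n, config$fitness_intercepts[lin] + config$fitness_slopes[lin] * g,
        config$fitness_sd))
      blocks[[length(blocks) + 1L]] <- df
    }
  }
  if (config$n_texanus > 0) {
    n <- config$n_texanus
    df <- data.frame(
      plant_id = sprintf("texanus_%03d", seq_len(n)),
      lineage = "texanus", generation = NA_integer_,
      longevity_days = 100, transplant_death = FALSE,
      scarification_damage = FALSE, apical_bud_weevil = FALSE,
      stringsAsFactors = FALSE)
    for (tr in config$traits) {
      df[[tr]] <- stats::rnorm(n, config$texanus_means[tr],
                               config$residual_sd[tr])
    }
    df$fitness <- pmax(0, stats::rnorm(n, config$texanus_fitness_mean,
                                       config$fitness_sd))
    blocks[[length(blocks) + 1L]] <- df
  }
  phenotype_table(do.call(rbind, blocks))
}

#' Simulate a generation-1 cohort under known selection gradients
#'
#' Traits are independent standard normal (optionally correlated via a
#' supplied correlation matrix); relative fitness is
#' `w = 1 + sum_k beta_k z_k + Normal(0, noise SD)`, truncated at 0. The
#' recorded `fitness` column is `w * mean_seed_count`, i.e. absolute viable
#' seed production around `mean_seed_count` seeds per plant.
#'
#' @param gradients Named selection gradients over the simulated traits.
#'   Names must be canonical trait abbreviations.
#' @param n_per_treatment Plants per treatment (default 200).
#' @param treatments Lineages to generate (default control and hybrid_LBJ).
#' @param noise_sd Fitness noise SD on the relative-fitness scale
#'   (default 0.3).
#' @param trait_correlation Optional trait correlation matrix
#'   (`length(gradients)` square); default independent.
#' @param mean_seed_count Scale from relative to absolute fitness
#'   (default 100).
#' @param seed Integer seed.
#' @return A `phenotype_table` (all rows generation 1) with attribute
#'   `n_truncated`, the number of fitness values truncated at 0.
#' @export
simulate_selection_generation <- function(gradients = c(SLA = 0.3, DiskDiam = 0.2,
                                                        MidgeDam = -0.2),
                                          n_per_treatment = 200,
                                          treatments = c("control", "hybrid_LBJ"),
                                          noise_sd = 0.3,
                                          trait_correlation = NULL,
                                          mean_seed_count = 100,
                                          seed = 1L) {
  traits <- names(gradients)
  if (is.null(traits) || !all(traits %in% fieldevol_traits())) {
    stop("gradients must be named with canonical trait abbreviations",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise SD must be nonnegative", call. = FALSE)
  set.seed(seed)
  k <- length(traits)
  blocks <- list()
  n_trunc <- 0L
  for (lin in treatments) {
    Z <- matrix(stats::rnorm(n_per_treatment * k), ncol = k)
    if (!is.null(trait_correlation)) {
      stopifnot(nrow(trait_correlation) == k)
      Z <- Z %*% chol(trait_correlation)
    }
    colnames(Z) <- traits
    w <- 1 + drop(Z %*% gradients) +
      if (noise_sd > 0) stats::rnorm(n_per_treatment, 0, noise_sd) else 0
    n_trunc <- n_trunc + sum(w < 0)
    w <- pmax(0, w)
    df <- data.frame(
      plant_id = sprintf("%s_g1_%03d", lin, seq_len(n_per_treatment)),
      lineage = lin, generation = 1L,
      longevity_days = 100, transplant_death = FALSE,
      scarification_damage = FALSE, apical_bud_weevil = FALSE,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(Z))
    df$fitness <- w * mean_seed_count
    blocks[[length(blocks) + 1L]] <- df
  }
  out <- phenotype_table(do.call(rbind, blocks))
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Configuration for the BC1 genotype simulator
#'
#' The founder (BC1) population carries biallelic variants whose expected
#' alternate-allele frequencies fall in the three backcross classes 25\%,
#' 50\% and 75\%. Later generations are produced by random mating; each
#' offspring gamete is, with probability `m`, a migrant haplotype from
#' outside the experiment. Migrant haplotypes carry an outside-private
#' allele (absent from the founder pool) at a configurable fraction of
#' sites, and founder-pool alleles at outside frequencies elsewhere.
#'
#' @param n_sites Number of variant sites (default 1000).
#' @param freq Per-site expected BC1 alternate-allele frequency: either a
#'   vector over sites with values in \{0.25, 0.5, 0.75\} or a single class
#'   applied to all sites; default samples the three classes with weights
#'   0.5 / 0.25 / 0.25 at generation time.
#' @param n_bc1 BC1 (founder) samples retained for genotyping (default 90).
#' @param pop_size Breeding population size per generation (default 250).
#' @param n_per_gen Genotyped samples per later generation (default 45).
#' @param n_generations Number of generations including the BC1 generation
#'   (default 6).
#' @param m Migration rate: probability a gamete is of outside origin,
#'   in \[0, 1\] (default 0).
#' @param private_fraction Fraction of sites at which a migrant haplotype
#'   carries an outside-private allele (default 0.1).
#' @param missing_rate Per-genotype missing-call probability (default 0.05).
#' @return A list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_sites = 1000, freq = NULL, n_bc1 = 90,
                                pop_size = 250, n_per_gen = 45,
                                n_generations = 6, m = 0,
                                private_fraction = 0.1, missing_rate = 0.05) {
  if (m < 0 || m > 1) stop("migration rate m must be in [0, 1]", call. = FALSE)
  if (!is.null(freq) && !all(freq %in% c(0.25, 0.5, 0.75))) {
    stop("BC1 allele frequencies are restricted to 0.25, 0.50, 0.75",
         call. = FALSE)
  }
  stopifnot(n_sites >= 1, n_bc1 >= 1, pop_size >= 2, n_per_gen >= 1,
            n_generations >= 1, private_fraction >= 0, private_fraction <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_sites = n_sites, freq = freq, n_bc1 = n_bc1,
                 pop_size = pop_size, n_per_gen = n_per_gen,
                 n_generations = n_generations, m = m,
                 private_fraction = private_fraction,
                 missing_rate = missing_rate),
            class = "genotype_sim_config")
}

# one haplotype matrix (sites x n) drawn from outside the experiment:
# private allele (code 2) at private_fraction of sites, otherwise the
# founder-pool alleles at the site's class frequency
.migrant_haplotypes <- function(n, p_alt, private_fraction) {
  n_sites <- length(p_alt)
  h <- matrix(stats::rbinom(n_sites * n, 1, p_alt), nrow = n_sites)
  priv <- matrix(stats::runif(n_sites * n) < private_fraction, nrow = n_sites)
  h[priv] <- 2L
  h
}

#' Simulate BC1-founded genotype matrices across generations
#'
#' Draws diploid BC1 genotypes per site at the configured backcross allele
#' frequency, then propagates the population by random mating for
#' `n_generations - 1` further generations, with each gamete replaced by a
#' migrant haplotype with probability `m`. With `m = 0` the population is
#' closed: no allele absent from the BC1 founder pool can ever appear.
#'
#' @param config A [genotype_sim_config()].
#' @param seed Integer seed.
#' @return A list of class `genotype_sim` with `sites` (data.frame: chrom,
#'   pos, ref, alt, priv — the outside-private allele base), allele-code
#'   matrices `a1`, `a2` (sites x samples; 0 ref, 1 alt, 2 private, NA
#'   missing), `samples`, `generation` (per sample), and the `config`.
#' @export
simulate_genotypes <- function(config = genotype_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "genotype_sim_config"))
  set.seed(seed)
  ns <- config$n_sites
  p_alt <- config$freq
  if (is.null(p_alt)) {
    p_alt <- sample(c(0.25, 0.5, 0.75), ns, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
  } else if (length(p_alt) == 1L) {
    p_alt <- rep(p_alt, ns)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  priv <- vapply(seq_len(ns), function(i)
    sample(setdiff(bases, c(ref[i], alt[i])), 1), character(1))
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(ns * 100, ns)),
                      ref = ref, alt = alt, priv = priv,
                      stringsAsFactors = FALSE)

  npop <- config$pop_size
  # founder generation: genotypes drawn at the BC1 class frequency
  A1 <- matrix(stats::rbinom(ns * npop, 1, p_alt), nrow = ns)
  A2 <- matrix(stats::rbinom(ns * npop, 1, p_alt), nrow = ns)

  draw_gametes <- function(A1, A2) {
    parents <- sample.int(npop, npop, replace = TRUE)
    pick2 <- matrix(stats::runif(ns * npop) < 0.5, nrow = ns)
    g <- A1[, parents, drop = FALSE]
    g2 <- A2[, parents, drop = FALSE]
    g[pick2] <- g2[pick2]
    if (config$m > 0) {
      mig <- which(stats::runif(npop) < config$m)
      if (length(mig) > 0) {
        g[, mig] <- .migrant_haplotypes(length(mig), p_alt,
                                        config$private_fraction)
      }
    }
    g
  }

  take_sample <- function(A1, A2, gen, n_take) {
    idx <- sample.int(ncol(A1), n_take)
    list(a1 = A1[, idx, drop = FALSE], a2 = A2[, idx, drop = FALSE],
         ids = sprintf("g%d_s%03d", gen, seq_len(n_take)), gen = gen)
  }

  samples <- list(take_sample(A1, A2, 1L, min(config$n_bc1, npop)))
  if (config$n_generations > 1) {
    for (gen in 2:config$n_generations) {
      N1 <- draw_gametes(A1, A2)
      N2 <- draw_gametes(A1, A2)
      A1 <- N1; A2 <- N2
      samples[[gen]] <- take_sample(A1, A2, gen,
                                    min(config$n_per_gen, npop))
    }
  }
  a1 <- do.call(cbind, lapply(samples, `[[`, "a1"))
  a2 <- do.call(cbind, lapply(samples, `[[`, "a2"))
  ids <- unlist(lapply(samples, `[[`, "ids"))
  gens <- unlist(lapply(samples, function(s) rep(s$gen, length(s$ids))))
  colnames(a1) <- colnames(a2) <- ids
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(a1)) < config$missing_rate,
                   nrow = nrow(a1))
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  structure(list(sites = sites, a1 = a1, a2 = a2, samples = ids,
                 generation = stats::setNames(gens, ids), config = config),
            class = "genotype_sim")
}

#' Convert simulated genotypes to allele-string calls
#'
#' Normalizes a `genotype_sim` to the representation the gene-flow functions
#' consume: two sites-by-samples character matrices of uppercase allele
#' strings (`NA` for missing calls).
#'
#' @param x A `genotype_sim` (or an object already of class
#'   `genotype_calls`, returned unchanged).
#' @return A list of class `genotype_calls` with `sites`, `a1`, `a2`,
#'   `samples`.
#' @export
as_genotype_calls <- function(x) {
  if (inherits(x, "genotype_calls")) return(x)
  stopifnot(inherits(x, "genotype_sim"))
  base_by_code <- list(`0` = x$sites$ref, `1` = x$sites$alt, `2` = x$sites$priv)
  code_to_base <- function(codes) {
    out <- matrix(NA_character_, nrow(codes), ncol(codes),
                  dimnames = dimnames(codes))
    for (code in 0:2) {
      hit <- which(codes == code, arr.ind = TRUE)
      if (nrow(hit) > 0) out[hit] <- base_by_code[[as.character(code)]][hit[, 1]]
    }
    out
  }
  structure(list(sites = x$sites, a1 = code_to_base(x$a1),
                 a2 = code_to_base(x$a2), samples = x$samples),
            class = "genotype_calls")
}

#' Write simulated genotypes as a VCF 4.2 file
#'
#' Diploid GT-only VCF with one sample column per plant; the outside-private
#' allele is emitted as a second ALT allele so genotype codes are stable
#' across samples. Sample IDs encode the generation (`g<gen>_s<idx>`).
#'
#' @param gsim A `genotype_sim`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gsim, path) {
  stopifnot(inherits(gsim, "genotype_sim"))
  gt_field <- function(i) {
    a1 <- gsim$a1[i, ]; a2 <- gsim$a2[i, ]
    out <- paste(a1, a2, sep = "/")
    out[is.na(a1) | is.na(a2)] <- "./."
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fieldevol.simulate_genotypes",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gsim$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(gsim$sites)), function(i) {
    paste(c(gsim$sites$chrom[i], gsim$sites$pos[i], ".",
            gsim$sites$ref[i],
            paste(gsim$sites$alt[i], gsim$sites$priv[i], sep = ","),
            ".", "PASS", ".", "GT", gt_field(i)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
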