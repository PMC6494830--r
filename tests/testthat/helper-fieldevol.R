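# Shared fixtures, all built in code.

# reduced MCMC regime used throughout the tests; the model is conjugate and
# draws are nearly independent, so 10,000 pooled draws suffice
fast_mcmc <- list(chains = 2, iterations = 6000, burnin = 1000, thin = 1)

fit_fast <- function(y, x, group, seed = 1L, ...) {
  do.call(gibbs_linear_model,
          c(list(y = y, x = x, group = group, seed = seed), fast_mcmc,
            list(...)))
}

# minimal valid phenotype table
tiny_table <- function(n = 6) {
  phenotype_table(data.frame(
    plant_id = paste0("p", seq_len(n)),
    lineage = rep(c("control", "hybrid_LBJ"), length.out = n),
    generation = rep(1:2, length.out = n),
    fitness = seq_len(n),
    longevity_days = 100,
    SLA = seq_len(n) + 0.5))
}

# hand-built genotype calls: sites x samples allele matrices
make_geno <- function(a1, a2, samples, ref = NULL, alt = NULL) {
  ns <- nrow(a1)
  colnames(a1) <- colnames(a2) <- samples
  structure(list(
    sites = data.frame(chrom = "chr1", pos = seq_len(ns) * 100,
                       ref = if (is.null(ref)) rep("A", ns) else ref,
                       alt = if (is.null(alt)) rep("T", ns) else alt,
                       stringsAsFactors = FALSE),
    a1 = a1, a2 = a2, samples = samples),
    class = "genotype_calls")
}
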