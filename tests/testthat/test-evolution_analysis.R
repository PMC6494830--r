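make_trend_table <- function(h_slope = 0.2, c_slope = 0, sd = 0.01,
                             n = 20, seed = 1) {
  set.seed(seed)
  gens <- rep(1:8, each = n)
  df <- rbind(
    data.frame(plant_id = paste0("h", seq_along(gens)), lineage = "hybrid_LBJ",
               generation = gens, fitness = 1,
               SLA = h_slope * gens + rnorm(length(gens), sd = sd)),
    data.frame(plant_id = paste0("c", seq_along(gens)), lineage = "control",
               generation = gens, fitness = 1,
               SLA = c_slope * gens + rnorm(length(gens), sd = sd)))
  phenotype_table(df)
}

test_that("a near-deterministic trend is detected with strong support", {
  tab <- make_trend_table()
  fit <- do.call(fit_trait_evolution,
                 c(list(tab, "SLA", seed = 2), fast_mcmc))
  res <- fit$results
  hyb <- res[res$lineage == "hybrid_LBJ", ]
  expect_equal(hyb$support, "strong")
  expect_equal(hyb$slope_mean, 0.2, tolerance = 0.02)
  expect_equal(hyb$sign, "+")
  expect_equal(res$support[res$lineage == "control"], "none")
})

test_that("support classes are nested (strong implies 80% significance)", {
  tab <- make_trend_table(h_slope = 0.1, sd = 1, n = 40, seed = 3)
  fit <- do.call(fit_trait_evolution, c(list(tab, "SLA", seed = 3), fast_mcmc))
  for (i in seq_len(nrow(fit$results))) {
    row <- fit$results[i, ]
    if (row$support == "strong") {
      expect_true(row$ci80_lower > 0 || row$ci80_upper < 0)
    }
    if (row$support == "moderate") {
      expect_true(row$ci95_lower <= 0 && row$ci95_upper >= 0)
    }
  }
})

test_that("degenerate trend inputs are rejected or skipped", {
  tab <- phenotype_table(data.frame(
    plant_id = paste0("p", 1:4), lineage = "hybrid_LBJ", generation = 1,
    fitness = 1, SLA = rnorm(4)))
  expect_error(do.call(fit_trait_evolution, c(list(tab, "SLA"), fast_mcmc)),
               "fewer than 2 generations")
  tab$SLA <- NA_real_
  expect_warning(res <- fit_trait_evolution(tab, "SLA"), "skipped")
  expect_null(res)
  expect_error(fit_trait_evolution(tab, "NotAColumn"), "no such column")
})

test_that("slope-magnitude comparison handles constants, identity and noise", {
  cmp <- compare_slope_magnitudes(rep(0.4, 100), rep(-0.1, 100))
  expect_equal(unique(cmp$diff_draws), 0.3)
  expect_equal(cmp$steeper, "hybrid")
  expect_equal(cmp$support, "strong")

  d <- rnorm(100)
  cmp_id <- compare_slope_magnitudes(d, d)
  expect_true(all(cmp_id$diff_draws == 0))
  expect_equal(cmp_id$support, "none")

  set.seed(4)
  cmp_mc <- compare_slope_magnitudes(rnorm(10000, 0.3, 0.05),
                                     rnorm(10000, 0.1, 0.05))
  expect_true(cmp_mc$ci95$excludes_zero)
  expect_equal(cmp_mc$steeper, "hybrid")

  expect_error(compare_slope_magnitudes(rnorm(10), rnorm(9)),
               "refusing to resample")
})

test_that("swapping comparison inputs flips the sign of the difference", {
  set.seed(5)
  a <- rnorm(500, 0.3, 0.1); b <- rnorm(500, 0.1, 0.1)
  ab <- compare_slope_magnitudes(a, b)
  ba <- compare_slope_magnitudes(b, a)
  expect_equal(ab$mean, -ba$mean)
  expect_equal(ab$diff_draws, -ba$diff_draws)
})

test_that("fitness contrast finds a shift and stays null without one", {
  build <- function(shift, seed) {
    set.seed(seed)
    n <- 100
    phenotype_table(data.frame(
      plant_id = paste0("p", 1:(2 * n)),
      lineage = rep(c("control", "hybrid_LBJ"), each = n),
      generation = 8,
      fitness = c(rnorm(n, 5, 0.2), rnorm(n, 5 + shift, 0.2))))
  }
  tab <- build(0.5, 6)
  fc <- suppressWarnings(fitness_generation_contrast(tab, 8, seed = 6))
  expect_true(fc$ci95$excludes_zero)
  expect_equal(fc$significance, "95")
  expect_equal(fc$mean_diff, 0.5, tolerance = 0.15)

  fc0 <- suppressWarnings(fitness_generation_contrast(build(0, 7), 8, seed = 7))
  expect_false(fc0$ci95$excludes_zero)

  only_c <- tab[tab$lineage == "control", ]
  class(only_c) <- class(tab)
  expect_error(fitness_generation_contrast(only_c, 8), "lacks one")
})

test_that("contrast coverage: shifted groups recover the shift", {
  # scaled-down coverage check: 10 seeded replicates, +0.5 SD shift
  hits_sig <- 0L; hits_cov <- 0L
  for (r in 1:10) {
    set.seed(300 + r)
    n <- 100
    tab <- phenotype_table(data.frame(
      plant_id = paste0("p", 1:(2 * n)),
      lineage = rep(c("control", "hybrid_LBJ"), each = n),
      generation = 8,
      fitness = c(rnorm(n, 1, 0.2), rnorm(n, 1.5, 0.2))))
    fc <- suppressWarnings(
      fitness_generation_contrast(tab, 8, seed = 300 + r, chains = 2,
                                  iterations = 1000, burnin = 500))
    if (fc$ci95$excludes_zero) hits_sig <- hits_sig + 1L
    if (fc$ci95$lower <= 0.5 && fc$ci95$upper >= 0.5) hits_cov <- hits_cov + 1L
  }
  expect_gte(hits_sig, 9L)
  expect_gte(hits_cov, 9L)
})

test_that("strong support has a calibrated type-I error on null data", {
  # 200 seeded null datasets (slope 0, unit SD); the 95% credible interval
  # should exclude zero in about 5% of them
  hits <- 0L
  for (r in 1:200) {
    set.seed(1000 + r)
    y <- rnorm(400)
    ps <- fit_fast(y, rep(1:8, each = 50), rep("h", 400), seed = 2000 + r)
    if (credible_interval(ps$draws[, "beta_h"], 0.95)$excludes_zero) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.08)
})

test_that("distance regression recovers an exact linear relation", {
  recs <- data.frame(trait = paste0("t", 1:10),
                     distance = seq(-2, 2.5, by = 0.5))
  recs$slope <- 0.12 * recs$distance
  reg <- suppressWarnings(regress_rate_on_distance(recs))  # perfect-fit lm note
  expect_equal(reg$coefficient, 0.12, tolerance = 1e-10)
  expect_equal(reg$intercept, 0, tolerance = 1e-10)
  expect_lt(reg$p_value, 1e-6)

  expect_error(regress_rate_on_distance(recs[1:2, ]), "at least 3")
  recs0 <- recs; recs0$distance <- 1
  expect_error(regress_rate_on_distance(recs0), "zero variance")
})

test_that("distance regression p-values are calibrated under the null", {
  # permutation null: slope independent of distance
  set.seed(8)
  hits <- 0L
  for (r in 1:200) {
    recs <- data.frame(trait = paste0("t", 1:20), distance = rnorm(20),
                       slope = rnorm(20))
    if (regress_rate_on_distance(recs)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.02)
  expect_lte(hits / 200, 0.08)
})

test_that("distance records are reference mean minus generation-1 mean", {
  tab <- simulate_experiment(simulation_config(
    generations = 1:2, n_per_gen = 30, traits = c("SLA", "LDMC")), seed = 9)
  st <- standardize(tab, columns = c("SLA", "LDMC"))
  recs <- compute_distance_records(st, c(SLA = 0.1, LDMC = -0.1), "hybrid_LBJ")
  ref <- mean(st$SLA[st$lineage == "texanus"])
  g1 <- mean(st$SLA[st$lineage == "hybrid_LBJ" & st$generation == 1])
  expect_equal(recs$distance[recs$trait == "SLA"], ref - g1)
})
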