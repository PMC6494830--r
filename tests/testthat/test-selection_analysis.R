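test_that("relative fitness has mean exactly one per treatment", {
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1.0, 1.5))
  expect_equal(relative_fitness(rep(7, 5)), rep(1, 5))
  w <- c(2, 4, 6, 30, 10, 20)
  tr <- rep(c("control", "hybrid"), each = 3)
  wr <- relative_fitness(w, tr)
  expect_equal(mean(wr[tr == "control"]), 1)
  expect_equal(mean(wr[tr == "hybrid"]), 1)
  expect_error(relative_fitness(c(0, 0, 0)), "not positive")
})

test_that("selection differential is the sample covariance with relative fitness", {
  expect_equal(selection_differential(c(-1, 0, 1), c(0.5, 1.0, 1.5)), 0.5)
  expect_equal(selection_differential(c(-1, 0, 1), rep(1, 3)), 0)
  set.seed(16)
  expect_lt(abs(selection_differential(rnorm(10000), 1 + rnorm(10000, 0, 1))),
            0.05)
  expect_error(selection_differential(1:3, 1:4), "mismatch")
})

test_that("gradients are exact for a noiseless linear fitness surface", {
  set.seed(17)
  Z <- cbind(z1 = rnorm(50), z2 = rnorm(50))
  w <- 1 + 0.3 * Z[, 1] - 0.2 * Z[, 2]
  expect_equal(selection_gradients(Z, w), c(z1 = 0.3, z2 = -0.2),
               tolerance = 1e-12)
})

test_that("gradients equal differentials for exactly orthogonal traits", {
  n <- 100
  z1 <- rep(c(-1, 1), n / 2) * sqrt((n - 1) / n)   # mean 0, sd exactly 1
  z2 <- rep(c(-1, 1), each = n / 2) * sqrt((n - 1) / n)
  set.seed(18)
  w <- 1 + 0.4 * z1 - 0.1 * z2 + rnorm(n, 0, 0.2)
  w_rel <- relative_fitness(w)
  b <- selection_gradients(cbind(z1 = z1, z2 = z2), w_rel)
  expect_equal(unname(b["z1"]), selection_differential(z1, w_rel),
               tolerance = 1e-10)
  expect_equal(unname(b["z2"]), selection_differential(z2, w_rel),
               tolerance = 1e-10)
})

test_that("collinear traits raise a rank error naming the culprit", {
  Z <- cbind(a = rnorm(20), b = rnorm(20))
  Z <- cbind(Z, dup = Z[, "a"])
  expect_error(selection_gradients(Z, rnorm(20)), "rank deficient.*dup")
})

test_that("bootstrap CI degenerates to a point for constant data", {
  ci <- bootstrap_ci(rep(3, 10), mean, replicates = 200, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(3, 3))
  expect_true(ci$excludes_zero)
})

test_that("BCa endpoints approach percentile endpoints in the symmetric limit", {
  set.seed(19)
  x <- rnorm(1000)
  bca <- bootstrap_ci(x, mean, replicates = 10000, type = "bca", seed = 2)
  pct <- bootstrap_ci(x, mean, replicates = 10000, type = "percentile", seed = 2)
  expect_lt(abs(bca$lower - pct$lower), 0.01)
  expect_lt(abs(bca$upper - pct$upper), 0.01)
  expect_lt(abs(bca$z0), 0.05)
  expect_lt(abs(bca$acceleration), 0.02)
})

test_that("undefined resamples are redrawn and counted", {
  set.seed(20)
  x <- c(rep(0, 5), rnorm(20))
  frag <- function(v) if (all(v == 0)) stop("degenerate") else mean(v)
  ci <- bootstrap_ci(x, frag, replicates = 200, seed = 3)
  expect_true(is.finite(ci$lower))
  expect_gte(ci$n_redrawn, 0L)
  expect_error(bootstrap_ci(1:2, mean), "at least 3")
})

test_that("full PSA recovers simulated gradients with calibrated intervals", {
  beta <- c(SLA = 0.3, DiskDiam = -0.2)
  tot <- 0L; cov <- 0L
  for (r in 1:15) {
    tab <- simulate_selection_generation(beta, n_per_treatment = 200,
                                         treatments = "hybrid_LBJ",
                                         noise_sd = 0.3, seed = 40 + r)
    res <- selection_analysis(tab, traits = names(beta), treatment = "hybrid",
                              replicates = 400, seed = 70 + r)
    for (k in names(beta)) {
      row <- res[res$trait == k, ]
      tot <- tot + 1L
      if (row$beta_lower <= beta[k] && row$beta_upper >= beta[k]) {
        cov <- cov + 1L
      }
    }
  }
  expect_gte(cov / tot, 0.9)
})

test_that("PSA output carries both statistics with significance flags", {
  tab <- simulate_selection_generation(c(SLA = 0.5), n_per_treatment = 150,
                                       treatments = "control", noise_sd = 0.1,
                                       seed = 90)
  res <- selection_analysis(tab, traits = "SLA", treatment = "control",
                            replicates = 400, seed = 91)
  expect_s3_class(res, "selection_result")
  expect_true(res$s_significant)
  expect_true(res$beta_significant)
  expect_equal(res$beta, 0.5, tolerance = 0.1)
  # single trait: gradient equals differential exactly
  expect_equal(res$beta, res$s_prime, tolerance = 1e-10)
})

test_that("adaptive classification follows the sign-and-significance rule", {
  evo <- data.frame(trait = "SLA", lineage = "hybrid_LBJ", slope_mean = 0.2,
                    support = "strong", stringsAsFactors = FALSE)
  sel_pos <- data.frame(trait = "SLA", beta = 0.3, beta_significant = TRUE)
  sel_neg <- data.frame(trait = "SLA", beta = -0.3, beta_significant = TRUE)
  sel_ns <- data.frame(trait = "SLA", beta = 0.3, beta_significant = FALSE)

  expect_equal(classify_adaptive(evo, sel_pos)$verdict, "adaptive")
  expect_equal(classify_adaptive(evo, sel_neg)$verdict, "not adaptive")
  expect_equal(classify_adaptive(evo, sel_ns)$verdict, "not adaptive")
  expect_equal(classify_adaptive(evo, NULL)$verdict, "not assessable")

  evo$support <- "moderate"
  expect_equal(classify_adaptive(evo, sel_pos)$verdict, "adaptive")
  expect_equal(classify_adaptive(evo, sel_pos, "strong")$verdict,
               "not adaptive")
  evo$support <- "none"
  expect_equal(classify_adaptive(evo, sel_pos)$verdict, "not adaptive")
})

test_that("traits absent from the PSA are not assessable", {
  evo <- data.frame(trait = c("SLA", "Chloro"), lineage = "hybrid_LBJ",
                    slope_mean = c(0.2, 0.2), support = "strong",
                    stringsAsFactors = FALSE)
  sel <- data.frame(trait = "SLA", beta = 0.3, beta_significant = TRUE)
  calls <- classify_adaptive_all(evo, sel, "hybrid_LBJ")
  expect_equal(calls$verdict[calls$trait == "SLA"], "adaptive")
  expect_equal(calls$verdict[calls$trait == "Chloro"], "not assessable")
})
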