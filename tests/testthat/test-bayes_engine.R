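test_that("with no data the posterior equals the prior", {
  ps <- gibbs_linear_model(numeric(0), numeric(0), character(0),
                           chains = 2, iterations = 11000, burnin = 1000,
                           thin = 2, seed = 4)
  d <- ps$draws[, "beta0_all"]
  expect_gte(length(d), 10000)
  expect_equal(mean(d), 0, tolerance = 0.05)
  expect_equal(var(d), 1, tolerance = 0.1)
  expect_true(all(ps$draws[, "tau"] > 0))
})

test_that("intercept-only posterior matches the conjugate closed form", {
  # tau fixed at 1, y = (1,1,1,1): posterior N(4/5, 1/5)
  ps <- fit_fast(rep(1, 4), rep(0, 4), rep("all", 4), tau_fixed = 1, seed = 3)
  d <- ps$draws[, "beta0_all"]
  mcse <- sqrt(0.2 / length(d))
  expect_lt(abs(mean(d) - 0.8), 3 * mcse)
  expect_equal(var(d), 0.2, tolerance = 0.02)
})

test_that("slope posterior mean agrees with the penalized least-squares oracle", {
  set.seed(7)
  x <- rep(1:8, each = 50)
  y <- 0.15 * x + rnorm(length(x))
  ps <- fit_fast(y, x, rep("g", length(x)), seed = 8)
  tau_hat <- mean(ps$draws[, "tau"])
  X <- cbind(1, x)
  ridge <- solve(tau_hat * crossprod(X) + diag(2), tau_hat * crossprod(X, y))
  expect_equal(mean(ps$draws[, "beta_g"]), ridge[2], tolerance = 0.05)
})

test_that("fixed-tau Gibbs marginals match the analytic normal (KS oracle)", {
  set.seed(9)
  x <- rep(1:8, each = 10)
  y <- 0.3 * x + rnorm(length(x), sd = 2)
  tau <- 1 / 4
  ps <- gibbs_linear_model(y, x, rep("g", length(x)), chains = 2,
                           iterations = 6000, burnin = 1000, thin = 1,
                           tau_fixed = tau, seed = 10)
  X <- cbind(1, x)
  V <- solve(tau * crossprod(X) + diag(2))
  mu <- V %*% (tau * crossprod(X, y))
  for (k in 1:2) {
    ks <- suppressWarnings(
      ks.test(ps$draws[, k], "pnorm", mu[k], sqrt(V[k, k])))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("the N(0,1) prior contracts slopes relative to OLS", {
  # balanced symmetric design => orthogonal columns => componentwise shrinkage
  x <- rep(seq(-3.5, 3.5, by = 1), each = 10)
  for (seed in 1:5) {
    set.seed(seed)
    y <- 0.4 * x + rnorm(length(x))
    ps <- fit_fast(y, x, rep("g", length(x)), seed = 100 + seed)
    ols <- coef(lm(y ~ x))[2]
    mcse <- 3 * sd(ps$draws[, "beta_g"]) / sqrt(nrow(ps$draws))
    expect_lt(abs(mean(ps$draws[, "beta_g"])), abs(ols) + mcse)
  }
})

test_that("doubling the data narrows the 95% credible interval", {
  width <- function(n, seed) {
    set.seed(seed)
    x <- rep(1:8, length.out = n)
    y <- 0.2 * x + rnorm(n)
    ps <- fit_fast(y, x, rep("g", n), seed = 200 + seed)
    ci <- credible_interval(ps$draws[, "beta_g"], 0.95)
    ci$upper - ci$lower
  }
  for (seed in 1:3) expect_lt(width(320, seed), width(80, seed))
})

test_that("non-finite data are rejected; burn-in must precede the end", {
  expect_error(fit_fast(c(1, Inf), c(1, 2), c("a", "a")), "non-finite")
  expect_error(gibbs_linear_model(1, 1, "a", iterations = 100, burnin = 100),
               "burn-in")
})

test_that("hierarchical contrast is null for identical groups and exact for a shift", {
  y <- rep(c(1, 2, 3, 4), 10)
  suppressWarnings({
    ps <- fit_hierarchical_group_model(
      c(y, y), rep(c("control", "hybrid"), each = 40),
      rep(c("c1", "h1"), each = 40), seed = 5)
  })
  d <- ps$draws[, "diff"]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(200))  # generous MC bound
  # near-noiseless shift of +0.5
  set.seed(6)
  yc <- rnorm(100, 0, 0.01); yh <- rnorm(100, 0.5, 0.01)
  suppressWarnings({
    ps2 <- fit_hierarchical_group_model(
      c(yc, yh), rep(c("control", "hybrid"), each = 100),
      rep(c("c1", "h1"), each = 100), seed = 7)
  })
  expect_equal(mean(ps2$draws[, "diff"]), 0.5, tolerance = 0.02)
})

test_that("hierarchical model flags degenerate designs", {
  expect_error(fit_hierarchical_group_model(1:4, rep("a", 4), rep("l", 4)),
               "2 treatment levels")
  w <- capture_warnings(
    fit_hierarchical_group_model(rnorm(20), rep(c("a", "b"), 10),
                                 rep(c("l1", "l2"), 10), chains = 2,
                                 iterations = 200, burnin = 100, seed = 1))
  expect_true(any(grepl("single lineage", w)))
})

test_that("credible intervals are equal-tailed empirical quantiles", {
  ci <- credible_interval(rep(5, 10), 0.95)
  expect_equal(c(ci$lower, ci$upper), c(5, 5))
  expect_true(ci$excludes_zero)

  set.seed(11)
  d <- rnorm(10000, 0.5, 0.1)
  ci95 <- credible_interval(d, 0.95)
  expect_lt(abs(ci95$lower - (0.5 - 1.96 * 0.1)), 0.01)
  expect_lt(abs(ci95$upper - (0.5 + 1.96 * 0.1)), 0.01)

  sym <- c(-3, -1, 0, 1, 3)
  expect_false(credible_interval(sym, 0.8)$excludes_zero)
  expect_error(credible_interval(numeric(0)), "no draws")
})

test_that("Gelman-Rubin matches the hand-computed formula", {
  # two identical chains (1,2,3,4): B = 0, W = 5/3, Rhat = sqrt(3/4)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(0.75), tolerance = 1e-12)
  set.seed(12)
  expect_true(abs(gelman_rubin(list(rnorm(10000), rnorm(10000))) - 1) < 0.01)
  expect_gt(gelman_rubin(list(rnorm(100, 0), rnorm(100, 10))), 3)
  expect_warning(r <- gelman_rubin(list(rep(1, 5), rep(1, 5))), "undefined")
  expect_true(is.na(r))
  expect_error(gelman_rubin(list(1:3)), "2 chains")
})

test_that("posterior draws export as chain-annotated CSV", {
  ps <- fit_fast(rnorm(20), rep(1:4, 5), rep("g", 20), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_posterior_csv(ps, path)
  df <- read.csv(path)
  expect_setequal(unique(df$chain), 1:2)
  expect_true(all(c("beta0_g", "beta_g", "tau") %in% names(df)))
})
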