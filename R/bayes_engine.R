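# Self-contained MCMC machinery: conjugate Gibbs sampling for the
# treatment-specific linear trend model, a hierarchical group-contrast model
# (Gibbs-within-Metropolis), equal-tailed credible intervals, and the
# Gelman-Rubin potential-scale-reduction diagnostic.

#' @useDynLib fieldevol, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

posterior_sample <- function(draws, chain_draws, rhat, warnings = character(0)) {
  structure(list(draws = draws, chain_draws = chain_draws, rhat = rhat,
                 n_saved = nrow(draws), warnings = warnings),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", x$n_saved, "pooled draws,",
      length(x$chain_draws), "chains\n")
  s <- rbind(mean = colMeans(x$draws), sd = apply(x$draws, 2, stats::sd),
             rhat = x$rhat)
  print(round(t(s), 4))
  if (length(x$warnings) > 0) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Gibbs sampler for the group-specific linear trend model
#'
#' Fits `y_i = beta0_j + beta_j * x_i + eps_i` with a separate intercept and
#' slope per group `j` (e.g. treatment or lineage), coefficient priors
#' Normal(0, 1), and a Gamma(1, 1) prior on the noise precision
#' `tau = 1 / var(eps)`. The sampler alternates exact conjugate updates
#' (coefficients jointly normal given `tau`; `tau` gamma given the
#' coefficients), so no tuning is needed. With zero rows the posterior equals
#' the prior.
#'
#' Defaults follow the common JAGS regime for this model class — 5 chains of
#' 100,000 iterations, 25,000 burn-in, thinning interval 25 — which yields
#' 15,000 saved draws; these are evenly subsampled down to `save_target`
#' (default 10,000) pooled draws. Each chain gets its own RNG stream seeded
#' as `seed + chain`.
#'
#' @param y Response vector (standardized trait or fitness values).
#' @param x Covariate (generation number).
#' @param group Group label per row (character or factor); one intercept and
#'   slope pair per level.
#' @param chains,iterations,burnin,thin MCMC regime (see above).
#' @param save_target Pooled draws kept after thinning (default 10,000).
#' @param prior_sd Prior SD of every coefficient (default 1).
#' @param tau_shape,tau_rate Gamma prior on the noise precision (default 1, 1).
#' @param tau_fixed Optionally hold `tau` fixed (used for validating the
#'   conjugate normal marginals); `NULL` to sample it.
#' @param seed Master seed; chain `c` uses `seed + c`.
#' @return A `posterior_sample` with columns `beta0_<group>`, `beta_<group>`
#'   per level plus `tau`; per-parameter split-free R-hat across chains; a
#'   convergence warning (not an error) is attached when any R-hat exceeds
#'   1.01.
#' @export
gibbs_linear_model <- function(y, x, group,
                               chains = 5, iterations = 100000,
                               burnin = 25000, thin = 25,
                               save_target = 10000,
                               prior_sd = 1, tau_shape = 1, tau_rate = 1,
                               tau_fixed = NULL, seed = 1L) {
  if (length(y) != length(x) || length(y) != length(group)) {
    stop("y, x and group must have equal length", call. = FALSE)
  }
  keep <- !(is.na(y) | is.na(x) | is.na(group))
  y <- y[keep]; x <- x[keep]; group <- as.character(group[keep])
  if (length(y) > 0 && (!all(is.finite(y)) || !all(is.finite(x)))) {
    stop("non-finite values in y or x", call. = FALSE)
  }
  if (burnin >= iterations) stop("burn-in must be below iterations", call. = FALSE)
  stopifnot(prior_sd > 0, tau_shape > 0, tau_rate > 0)

  levels_g <- if (length(group) > 0) sort(unique(group)) else "all"
  p <- 2L * length(levels_g)
  n <- length(y)
  X <- matrix(0, nrow = n, ncol = p)
  for (i in seq_along(levels_g)) {
    rows <- group == levels_g[i]
    X[rows, 2L * i - 1L] <- 1
    X[rows, 2L * i] <- x[rows]
  }
  par_names <- c(rbind(paste0("beta0_", levels_g), paste0("beta_", levels_g)), "tau")

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    d <- .gibbs_chain_cpp(X, y, rep(1 / prior_sd^2, p),
                          tau_shape, tau_rate,
                          as.integer(iterations), as.integer(burnin),
                          as.integer(thin),
                          if (is.null(tau_fixed)) -1 else tau_fixed, 1.0)
    colnames(d) <- par_names
    chain_draws[[ch]] <- d
  }

  pooled <- do.call(rbind, chain_draws)
  if (nrow(pooled) > save_target) {
    idx <- round(seq(1, nrow(pooled), length.out = save_target))
    pooled <- pooled[idx, , drop = FALSE]
  }
  rhat <- vapply(par_names, function(pn) {
    gelman_rubin(lapply(chain_draws, function(d) d[, pn]), quiet = TRUE)
  }, numeric(1))
  warn <- character(0)
  est_pars <- if (is.null(tau_fixed)) par_names else setdiff(par_names, "tau")
  bad <- est_pars[!is.na(rhat[est_pars]) & rhat[est_pars] > 1.01]
  if (length(bad) > 0) {
    warn <- paste0("R-hat above 1.01 for: ", paste(bad, collapse = ", "))
    warning(warn, call. = FALSE)
  }
  posterior_sample(pooled, chain_draws, rhat, warn)
}

#' Hierarchical group-contrast model for standardized fitness
#'
#' Fits `y_i = eta_{t(i)} + u_{l(i)} + eps_i` where `t` indexes treatment
#' (fixed cell means with Normal(0, 100) priors — variance 100), `l` indexes
#' lineage (random intercepts `u_l ~ N(0, sigma_u^2)` with a half-Normal(0, 10)
#' hyperprior on `sigma_u`), and `1/var(eps) ~ Gamma(1, 1)`. All conditionals
#' are conjugate except `sigma_u`, which is updated by a random-walk
#' Metropolis step on `log(sigma_u)` (Gibbs-within-Metropolis).
#'
#' The treatment contrast is returned as paired draws of the difference in
#' fitted treatment means *including* the lineage effects,
#' `diff = (eta_2 + mean(u_l in level 2)) - (eta_1 + mean(u_l in level 1))`
#' (second sorted level minus first, i.e. hybrid minus control). Contrasting
#' the fitted means rather than the fixed effects alone keeps the difference
#' identified even when a treatment contains a single lineage, in which case
#' the fixed effect and the lineage intercept are individually confounded.
#'
#' @param y Standardized fitness values.
#' @param treatment Two-level factor/character (e.g. control vs hybrid).
#' @param lineage Lineage label per row (random-intercept grouping).
#' @param chains,iterations,burnin MCMC regime (default 4 x 2000, 1000 burn-in).
#' @param seed Master seed; chain `c` uses `seed + c`.
#' @return A `posterior_sample` with columns `eta_<level>` per treatment
#'   level, `diff` (second minus first level), `sigma_u` and `tau`.
#' @export
fit_hierarchical_group_model <- function(y, treatment, lineage,
                                         chains = 4, iterations = 2000,
                                         burnin = 1000, seed = 1L) {
  keep <- !(is.na(y) | is.na(treatment) | is.na(lineage))
  y <- y[keep]; treatment <- as.character(treatment[keep])
  lineage <- as.character(lineage[keep])
  t_levels <- sort(unique(treatment))
  if (length(t_levels) < 2L) {
    stop("need at least 2 treatment levels with data", call. = FALSE)
  }
  l_levels <- sort(unique(lineage))
  if (any(table(factor(treatment, t_levels)) == 0)) {
    stop("a treatment level has no rows", call. = FALSE)
  }
  lin_per_treat <- tapply(lineage, treatment, function(x) length(unique(x)))
  if (any(lin_per_treat < 2)) {
    warning("a treatment has a single lineage; the random-intercept scale ",
            "is weakly identified", call. = FALSE)
  }
  t_idx <- match(treatment, t_levels)
  l_idx <- match(lineage, l_levels)
  n <- length(y); nt <- length(t_levels); nl <- length(l_levels)
  prior_var_eta <- 100; hyper_sd <- 10
  par_names <- c(paste0("eta_", t_levels), "diff", "sigma_u", "tau")

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    eta <- rep(0, nt); u <- rep(0, nl); sigma_u <- 1; tau <- 1
    n_save <- iterations - burnin
    out <- matrix(NA_real_, n_save, length(par_names),
                  dimnames = list(NULL, par_names))
    n_t <- tabulate(t_idx, nt); n_l <- tabulate(l_idx, nl)
    for (it in seq_len(iterations)) {
      # eta_t | rest (conjugate normal)
      r <- y - u[l_idx]
      for (t in seq_len(nt)) {
        prec <- tau * n_t[t] + 1 / prior_var_eta
        m <- tau * sum(r[t_idx == t]) / prec
        eta[t] <- stats::rnorm(1, m, sqrt(1 / prec))
      }
      # u_l | rest
      r <- y - eta[t_idx]
      for (l in seq_len(nl)) {
        prec <- tau * n_l[l] + 1 / sigma_u^2
        m <- tau * sum(r[l_idx == l]) / prec
        u[l] <- stats::rnorm(1, m, sqrt(1 / prec))
      }
      # tau | rest
      resid <- y - eta[t_idx] - u[l_idx]
      tau <- stats::rgamma(1, 1 + n / 2, rate = 1 + sum(resid^2) / 2)
      # sigma_u | u: random-walk Metropolis on log scale
      log_post <- function(ls) {
        s <- exp(ls)
        sum(stats::dnorm(u, 0, s, log = TRUE)) - s^2 / (2 * hyper_sd^2) + ls
      }
      prop <- log(sigma_u) + stats::rnorm(1, 0, 0.5)
      if (log(stats::runif(1)) < log_post(prop) - log_post(log(sigma_u))) {
        sigma_u <- exp(prop)
      }
      if (it > burnin) {
        mu_t <- vapply(seq_len(nt), function(t)
          eta[t] + mean(u[unique(l_idx[t_idx == t])]), numeric(1))
        out[it - burnin, ] <- c(eta, mu_t[2] - mu_t[1], sigma_u, tau)
      }
    }
    out
  }
  chain_draws <- lapply(seq_len(chains), function(ch) run_chain(seed + ch))
  pooled <- do.call(rbind, chain_draws)
  rhat <- vapply(par_names, function(pn) {
    gelman_rubin(lapply(chain_draws, function(d) d[, pn]), quiet = TRUE)
  }, numeric(1))
  warn <- character(0)
  bad <- par_names[!is.na(rhat) & rhat > 1.01]
  if (length(bad) > 0) {
    warn <- paste0("R-hat above 1.01 for: ", paste(bad, collapse = ", "))
    warning(warn, call. = FALSE)
  }
  posterior_sample(pooled, chain_draws, rhat, warn)
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` with linear
#' interpolation (quantile type 7), plus an excludes-zero flag used for
#' support classification (95\% level = strong support, 80\% = moderate).
#'
#' @param draws Numeric vector of posterior draws (length >= 2, or length 1
#'   for a degenerate point interval).
#' @param level Credible level, typically 0.95 or 0.80.
#' @return List of class `credible_interval`: `level`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) == 0L) stop("no draws supplied", call. = FALSE)
  stopifnot(level > 0, level < 1)
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  structure(list(level = level, lower = q[1], upper = q[2],
                 excludes_zero = q[1] > 0 || q[2] < 0),
            class = "credible_interval")
}

#' Gelman-Rubin potential scale reduction (R-hat)
#'
#' Classic formulation: with `m` chains of length `n`, within-chain variance
#' `W` (mean of the per-chain variances) and between-chain variance
#' `B = n * var(chain means)`, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.
#' Values near 1 indicate the chains sample the same distribution; above
#' 1.01 is treated as non-convergence by the model fitters.
#'
#' @param chains List of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @param quiet Suppress the zero-variance warning (internal use).
#' @return R-hat, or `NA` (flagged) if every chain has zero internal variance.
#' @export
gelman_rubin <- function(chains, quiet = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(i) chains[, i])
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 2L) stop("chains must have length >= 2", call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) {
    if (!quiet) warning("zero within-chain variance in all chains; R-hat undefined",
                        call. = FALSE)
    return(NA_real_)
  }
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Export posterior draws as CSV
#'
#' One row per saved draw with chain and iteration indices, one column per
#' parameter — suitable for external diagnostics.
#'
#' @param posterior A `posterior_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_posterior_csv <- function(posterior, path) {
  dfs <- lapply(seq_along(posterior$chain_draws), function(ch) {
    d <- as.data.frame(posterior$chain_draws[[ch]])
    cbind(chain = ch, iteration = seq_len(nrow(d)), d)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}
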