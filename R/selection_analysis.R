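# Lande-Arnold phenotypic selection analysis: relative fitness, selection
# differentials (covariance of a standardized trait with relative fitness),
# selection gradients (partial regression coefficients), bootstrap confidence
# intervals (bias-corrected-and-accelerated), and the adaptive-evolution
# concordance call.

#' Relative fitness within treatment
#'
#' Divides each plant's fitness by the mean fitness of its treatment, so the
#' output has mean exactly 1 per treatment — the scale on which selection
#' differentials and gradients are defined.
#'
#' @param w Fitness vector (nonnegative).
#' @param treatment Optional treatment label per plant; `NULL` treats all
#'   plants as one population.
#' @return Relative fitness vector.
#' @export
relative_fitness <- function(w, treatment = NULL) {
  if (is.null(treatment)) treatment <- rep("all", length(w))
  out <- rep(NA_real_, length(w))
  for (tr in unique(treatment[!is.na(treatment)])) {
    rows <- !is.na(treatment) & treatment == tr
    mw <- mean(w[rows], na.rm = TRUE)
    if (is.na(mw) || mw <= 0) {
      stop("mean fitness is not positive in treatment ", tr, call. = FALSE)
    }
    out[rows] <- w[rows] / mw
  }
  out
}

#' Linear selection differential
#'
#' `s' = cov(z, w_rel)` with the sample (n - 1) covariance: the total
#' strength of selection on a standardized trait, direct plus indirect.
#'
#' @param z Standardized trait values.
#' @param w_rel Relative fitness ([relative_fitness()]).
#' @return The selection differential.
#' @export
selection_differential <- function(z, w_rel) {
  if (length(z) != length(w_rel)) stop("length mismatch", call. = FALSE)
  ok <- stats::complete.cases(z, w_rel)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  stats::cov(z[ok], w_rel[ok])
}

#' Linear selection gradients
#'
#' Partial regression coefficients of relative fitness on all standardized
#' traits jointly (multiple regression with intercept): the direct selection
#' on each trait holding the others constant. When the traits are mutually
#' uncorrelated each gradient equals the corresponding differential.
#'
#' @param Z Matrix or data.frame of standardized traits (columns named).
#' @param w_rel Relative fitness vector.
#' @return Named vector of gradients, one per trait column.
#' @export
selection_gradients <- function(Z, w_rel) {
  Z <- as.matrix(Z)
  ok <- stats::complete.cases(Z, w_rel)
  Z <- Z[ok, , drop = FALSE]; w_rel <- w_rel[ok]
  if (nrow(Z) <= ncol(Z) + 1L) {
    stop("need more plants than traits + 1", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("trait matrix is rank deficient (collinear): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  stats::setNames(qr.coef(qr_x, w_rel)[-1], colnames(Z))
}

#' Bootstrap confidence interval (BCa by default)
#'
#' Case resampling of rows with `replicates` draws. The default interval is
#' bias-corrected-and-accelerated: the bias correction `z0` comes from the
#' fraction of replicate statistics below the point estimate, and the
#' acceleration `a` from the jackknife skewness of the statistic. `"bc"`
#' drops the acceleration term, `"percentile"` drops both. A replicate on
#' which the statistic is undefined (error or `NA`) is redrawn, up to
#' `10 * replicates` attempts; the number redrawn is returned.
#'
#' @param data A vector, or a data.frame resampled by rows.
#' @param statistic Function of (a resample of) `data` returning one number.
#' @param replicates Bootstrap replicates (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param type `"bca"`, `"bc"` or `"percentile"`.
#' @param seed Integer seed.
#' @return List of class `bootstrap_ci`: `estimate`, `lower`, `upper`,
#'   `level`, `type`, `z0`, `acceleration`, `n_redrawn`,
#'   `excludes_zero`.
#' @export
bootstrap_ci <- function(data, statistic, replicates = 10000, level = 0.95,
                         type = c("bca", "bc", "percentile"), seed = 1L) {
  type <- match.arg(type)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  t_hat <- statistic(data)
  set.seed(seed)
  t_boot <- numeric(replicates)
  n_redrawn <- 0L
  b <- 1L
  attempts <- 0L
  while (b <= replicates && attempts < 10L * replicates) {
    attempts <- attempts + 1L
    v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                  error = function(e) NA_real_)
    if (is.na(v)) { n_redrawn <- n_redrawn + 1L; next }
    t_boot[b] <- v
    b <- b + 1L
  }
  if (b <= replicates) stop("statistic undefined on too many resamples", call. = FALSE)
  .bca_interval(t_hat, t_boot, data, statistic, take, n, level, type,
                n_redrawn)
}

# shared BCa endpoint computation (also used by the vectorized PSA bootstrap)
.bca_interval <- function(t_hat, t_boot, data, statistic, take, n, level,
                          type, n_redrawn = 0L) {
  alpha <- (1 - level) / 2
  if (all(t_boot == t_hat)) {
    ci <- c(t_hat, t_hat)
    z0 <- 0; a <- 0
  } else if (type == "percentile") {
    ci <- stats::quantile(t_boot, c(alpha, 1 - alpha), names = FALSE)
    z0 <- 0; a <- 0
  } else {
    z0 <- stats::qnorm((sum(t_boot < t_hat) + 0.5 * sum(t_boot == t_hat)) /
                         length(t_boot))
    a <- 0
    if (type == "bca") {
      t_jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
      d <- mean(t_jack) - t_jack
      denom <- sum(d^2)^1.5
      if (denom > 0) a <- sum(d^3) / (6 * denom)
    }
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    ci <- stats::quantile(t_boot, adj, names = FALSE)
  }
  structure(list(estimate = t_hat, lower = ci[1], upper = ci[2],
                 level = level, type = type, z0 = z0, acceleration = a,
                 n_redrawn = n_redrawn,
                 excludes_zero = ci[1] > 0 || ci[2] < 0),
            class = "bootstrap_ci")
}

#' Phenotypic selection analysis for one treatment
#'
#' Computes, within one treatment of a generation-1 cohort: relative fitness,
#' per-trait selection differentials, joint selection gradients, and
#' bootstrap confidence intervals for every differential and gradient from a
#' single set of case resamples (rows resampled once per replicate, all
#' statistics recomputed). Significance is a bootstrap CI excluding zero.
#'
#' Traits are standardized within treatment (the analysis' own convention);
#' pass a table already standardized in `within_treatment` mode, or a raw
#' table to have this done internally.
#'
#' @param table A `phenotype_table` (generation-1 rows are used).
#' @param traits Trait columns to analyse (default: all present with
#'   complete-enough data).
#' @param treatment `"control"` or `"hybrid"`.
#' @param replicates Bootstrap replicates (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param type Bootstrap interval type (default `"bca"`).
#' @param seed Integer seed.
#' @param transforms Optional named list of per-trait functions applied
#'   before standardization (normality transforms); not applied by default.
#' @return data.frame of class `selection_result`: trait, `s_prime`, its CI
#'   and significance flag, `beta`, its CI and significance flag, treatment,
#'   n.
#' @export
selection_analysis <- function(table, traits = NULL, treatment = "hybrid",
                               replicates = 10000, level = 0.95,
                               type = c("bca", "bc", "percentile"),
                               seed = 1L, transforms = NULL) {
  type <- match.arg(type)
  rows <- !is.na(table$treatment) & table$treatment == treatment
  if ("generation" %in% names(table)) {
    rows <- rows & !is.na(table$generation) &
      table$generation == min(table$generation[rows], na.rm = TRUE)
  }
  sub <- as.data.frame(table)[rows, , drop = FALSE]
  if (is.null(traits)) traits <- trait_columns(table)
  traits <- traits[vapply(traits, function(tr)
    sum(!is.na(sub[[tr]])) >= 3, logical(1))]
  if (length(traits) == 0L) stop("no analysable traits", call. = FALSE)
  for (tr in names(transforms)) {
    if (tr %in% traits) sub[[tr]] <- transforms[[tr]](sub[[tr]])
  }
  keep <- stats::complete.cases(sub[, c(traits, "fitness")])
  sub <- sub[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n <= length(traits) + 1L) {
    stop("insufficient data: ", n, " plants for ", length(traits), " traits",
         call. = FALSE)
  }

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  stat_all <- function(d) {
    Z <- vapply(traits, function(tr) zscore(d[[tr]]), numeric(nrow(d)))
    w_rel <- relative_fitness(d$fitness)
    s <- vapply(traits, function(tr)
      stats::cov(Z[, tr], w_rel), numeric(1))
    b <- selection_gradients(Z, w_rel)
    c(stats::setNames(s, paste0("s_", traits)),
      stats::setNames(b, paste0("b_", traits)))
  }
  t_hat <- stat_all(sub)

  set.seed(seed)
  t_boot <- matrix(NA_real_, replicates, length(t_hat),
                   dimnames = list(NULL, names(t_hat)))
  b <- 1L; attempts <- 0L; n_redrawn <- 0L
  while (b <= replicates && attempts < 10L * replicates) {
    attempts <- attempts + 1L
    v <- tryCatch(stat_all(sub[sample.int(n, n, replace = TRUE), , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(v) || anyNA(v)) { n_redrawn <- n_redrawn + 1L; next }
    t_boot[b, ] <- v
    b <- b + 1L
  }
  if (b <= replicates) stop("statistics undefined on too many resamples",
                            call. = FALSE)
  t_jack <- if (type == "bca") {
    t(vapply(seq_len(n), function(i)
      stat_all(sub[-i, , drop = FALSE]), t_hat))
  } else NULL

  ci_for <- function(k) {
    tb <- t_boot[, k]
    alpha <- (1 - level) / 2
    if (all(tb == t_hat[k])) return(c(t_hat[k], t_hat[k]))
    if (type == "percentile") {
      return(stats::quantile(tb, c(alpha, 1 - alpha), names = FALSE))
    }
    z0 <- stats::qnorm((sum(tb < t_hat[k]) + 0.5 * sum(tb == t_hat[k])) /
                         length(tb))
    a <- 0
    if (type == "bca") {
      d <- mean(t_jack[, k]) - t_jack[, k]
      denom <- sum(d^2)^1.5
      if (denom > 0) a <- sum(d^3) / (6 * denom)
    }
    zq <- stats::qnorm(c(alpha, 1 - alpha))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    stats::quantile(tb, adj, names = FALSE)
  }

  out <- do.call(rbind, lapply(traits, function(tr) {
    cs <- ci_for(paste0("s_", tr))
    cb <- ci_for(paste0("b_", tr))
    data.frame(trait = tr,
               s_prime = unname(t_hat[paste0("s_", tr)]),
               s_lower = cs[1], s_upper = cs[2],
               s_significant = cs[1] > 0 || cs[2] < 0,
               beta = unname(t_hat[paste0("b_", tr)]),
               beta_lower = cb[1], beta_upper = cb[2],
               beta_significant = cb[1] > 0 || cb[2] < 0,
               treatment = treatment, n = n, stringsAsFactors = FALSE)
  }))
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "type") <- type
  class(out) <- c("selection_result", "data.frame")
  out
}

#' Classify a trait's evolution as adaptive or not
#'
#' A trait evolved adaptively when its generational trend and its
#' generation-1 selection gradient are both statistically supported and point
#' in the same direction. Evolution support counts at the
#' `"strong_or_moderate"` threshold by default (80\% credible level or
#' better); set `evolution_threshold = "strong"` to require the 95\% level.
#' A trait missing from either analysis is `"not assessable"`.
#'
#' @param evolution One row of evolution results (trait, slope_mean, support).
#' @param selection One row of selection results (trait, beta,
#'   beta_significant), or `NULL`.
#' @param evolution_threshold `"strong_or_moderate"` (default) or `"strong"`.
#' @return List of class `adaptive_call`: trait, lineage, verdict
#'   (`"adaptive"`, `"not adaptive"`, `"not assessable"`), and the inputs'
#'   signs/flags.
#' @export
classify_adaptive <- function(evolution, selection,
                              evolution_threshold = c("strong_or_moderate",
                                                      "strong")) {
  evolution_threshold <- match.arg(evolution_threshold)
  if (is.null(selection) || nrow(selection) == 0L) {
    return(structure(list(trait = evolution$trait, lineage = evolution$lineage,
                          verdict = "not assessable"),
                     class = "adaptive_call"))
  }
  evo_sig <- if (evolution_threshold == "strong") {
    evolution$support == "strong"
  } else {
    evolution$support %in% c("strong", "moderate")
  }
  same_sign <- sign(evolution$slope_mean) == sign(selection$beta)
  verdict <- if (evo_sig && selection$beta_significant && same_sign) {
    "adaptive"
  } else "not adaptive"
  structure(list(trait = evolution$trait, lineage = evolution$lineage,
                 verdict = verdict,
                 evolution_support = evolution$support,
                 evolution_sign = sign(evolution$slope_mean),
                 gradient_significant = selection$beta_significant,
                 gradient_sign = sign(selection$beta)),
            class = "adaptive_call")
}

#' Adaptive-evolution calls for all traits of one lineage
#'
#' @param evolution_results data.frame from [fit_all_traits()] (one lineage's
#'   rows are selected).
#' @param selection_results A `selection_result` data.frame.
#' @param lineage Lineage to classify.
#' @param evolution_threshold Passed to [classify_adaptive()].
#' @return data.frame: trait, lineage, verdict.
#' @export
classify_adaptive_all <- function(evolution_results, selection_results,
                                  lineage,
                                  evolution_threshold = "strong_or_moderate") {
  evo <- evolution_results[evolution_results$lineage == lineage, , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(evo)), function(i) {
    sel <- selection_results[selection_results$trait == evo$trait[i], ,
                             drop = FALSE]
    call <- classify_adaptive(evo[i, ], if (nrow(sel)) sel else NULL,
                              evolution_threshold)
    data.frame(trait = call$trait, lineage = lineage, verdict = call$verdict,
               stringsAsFactors = FALSE)
  }))
}

#' Write PSA results as CSV
#' @param results A `selection_result` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
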