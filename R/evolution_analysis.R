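# Trait and fitness trend estimation across generations, support
# classification at the 95% / 80% credible levels, hybrid-vs-control
# slope-magnitude comparison, per-generation fitness contrasts, and the
# regression of evolutionary rate on distance from the locally adapted
# phenotype.

.classify_support <- function(draws) {
  ci95 <- credible_interval(draws, 0.95)
  ci80 <- credible_interval(draws, 0.80)
  cls <- if (ci95$excludes_zero) "strong" else
    if (ci80$excludes_zero) "moderate" else "none"
  m <- mean(draws)
  list(mean = m, ci95 = ci95, ci80 = ci80, support = cls,
       sign = if (m > 0) "+" else if (m < 0) "-" else "0")
}

#' Bayesian trend model for one trait across generations
#'
#' Regresses a standardized trait on generation with a separate intercept and
#' slope per lineage via [gibbs_linear_model()], then classifies support for
#' each lineage's slope: `strong` if the 95\% credible interval excludes
#' zero, `moderate` if only the 80\% interval does, `none` otherwise.
#' Reference (`texanus`) rows are excluded; rows with a missing trait value
#' are dropped per trait (casewise deletion, no imputation).
#'
#' @param table A `standardized_table` (global standardization).
#' @param trait Trait column name (or `"fitness"`).
#' @param lineages Lineages to fit (default: all non-reference lineages
#'   present).
#' @param ... MCMC settings passed to [gibbs_linear_model()]
#'   (`chains`, `iterations`, `burnin`, `thin`, `seed`, ...).
#' @return A list of class `evolution_fit`: `results` (data.frame, one row
#'   per lineage: slope mean, both CIs, support class, sign), `slope_draws`
#'   (named list of pooled slope draws per lineage), `posterior`.
#' @export
fit_trait_evolution <- function(table, trait, lineages = NULL, ...) {
  if (!trait %in% names(table)) stop("no such column: ", trait, call. = FALSE)
  rows <- table$lineage != "texanus" & !is.na(table[[trait]]) &
    !is.na(table$generation)
  sub <- table[rows, , drop = FALSE]
  if (is.null(lineages)) lineages <- sort(unique(sub$lineage))
  sub <- sub[sub$lineage %in% lineages, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no usable values for ", trait, "; skipped", call. = FALSE)
    return(NULL)
  }
  for (lin in lineages) {
    gens <- unique(sub$generation[sub$lineage == lin])
    if (length(gens) < 2L) {
      stop("lineage ", lin, " has fewer than 2 generations with data for ",
           trait, call. = FALSE)
    }
  }
  post <- gibbs_linear_model(sub[[trait]], sub$generation, sub$lineage, ...)
  slope_draws <- lapply(stats::setNames(lineages, lineages), function(lin) {
    post$draws[, paste0("beta_", lin)]
  })
  results <- do.call(rbind, lapply(lineages, function(lin) {
    cl <- .classify_support(slope_draws[[lin]])
    data.frame(trait = trait, lineage = lin, slope_mean = cl$mean,
               ci95_lower = cl$ci95$lower, ci95_upper = cl$ci95$upper,
               ci80_lower = cl$ci80$lower, ci80_upper = cl$ci80$upper,
               support = cl$support, sign = cl$sign, stringsAsFactors = FALSE)
  }))
  structure(list(results = results, slope_draws = slope_draws,
                 posterior = post),
            class = "evolution_fit")
}

#' Fit trend models for many traits
#'
#' Runs [fit_trait_evolution()] for each trait, collecting per-lineage
#' results and slope draws. Traits whose data cannot support a fit are
#' skipped with a warning.
#'
#' @param table A `standardized_table`.
#' @param traits Columns to fit (default: trait columns plus fitness).
#' @param ... Passed to [fit_trait_evolution()].
#' @return List with `results` (row-bound data.frame) and `fits` (named list
#'   of `evolution_fit` objects).
#' @export
fit_all_traits <- function(table, traits = NULL, ...) {
  if (is.null(traits)) traits <- c(trait_columns(table), "fitness")
  fits <- list()
  for (tr in traits) {
    f <- tryCatch(fit_trait_evolution(table, tr, ...),
                  error = function(e) {
                    warning("trait ", tr, ": ", conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[tr]] <- f
  }
  list(results = do.call(rbind, c(lapply(fits, `[[`, "results"),
                                  make.row.names = FALSE)),
       fits = fits)
}

#' Compare slope magnitudes between a hybrid and a control lineage
#'
#' Forms the paired-draw distribution `|beta_hybrid| - |beta_control|` (draws
#' paired by pooled index) and classifies support for a difference in
#' steepness at the 95\% and 80\% credible levels. A positive mean means the
#' hybrid slope is steeper.
#'
#' @param hybrid_draws,control_draws Pooled posterior slope draws (equal
#'   length; mismatched lengths are an error, never silently resampled).
#' @param trait Optional label.
#' @return A list of class `slope_comparison`: `diff_draws`, `mean`, `ci95`,
#'   `ci80`, `support`, `steeper` (`"hybrid"`, `"control"` or `"neither"`).
#' @export
compare_slope_magnitudes <- function(hybrid_draws, control_draws,
                                     trait = NA_character_) {
  if (length(hybrid_draws) != length(control_draws)) {
    stop("draw counts differ; refusing to resample silently", call. = FALSE)
  }
  d <- abs(hybrid_draws) - abs(control_draws)
  cl <- .classify_support(d)
  structure(list(trait = trait, diff_draws = d, mean = cl$mean,
                 ci95 = cl$ci95, ci80 = cl$ci80, support = cl$support,
                 steeper = if (cl$support == "none") "neither" else
                   if (cl$mean > 0) "hybrid" else "control"),
            class = "slope_comparison")
}

#' Slope-magnitude comparisons for all fitted traits
#'
#' @param fits The `fits` element of [fit_all_traits()] output.
#' @param hybrid,control Lineage names to compare.
#' @return data.frame: trait, mean difference, CI bounds, support, steeper.
#' @export
compare_all_slopes <- function(fits, hybrid, control = "control") {
  do.call(rbind, lapply(names(fits), function(tr) {
    sd_h <- fits[[tr]]$slope_draws[[hybrid]]
    sd_c <- fits[[tr]]$slope_draws[[control]]
    if (is.null(sd_h) || is.null(sd_c)) return(NULL)
    cmp <- compare_slope_magnitudes(sd_h, sd_c, trait = tr)
    data.frame(trait = tr, hybrid = hybrid, mean_diff = cmp$mean,
               ci95_lower = cmp$ci95$lower, ci95_upper = cmp$ci95$upper,
               ci80_lower = cmp$ci80$lower, ci80_upper = cmp$ci80$upper,
               support = cmp$support, steeper = cmp$steeper,
               stringsAsFactors = FALSE)
  }))
}

#' Hybrid-minus-control fitness contrast within one generation
#'
#' Fits the hierarchical group model ([fit_hierarchical_group_model()]) to a
#' single generation's standardized fitness, with treatment fixed effects and
#' lineage random intercepts, and summarizes the posterior of the
#' hybrid-minus-control difference. The attained significance level is 95 if
#' the 95\% credible interval excludes zero, 80 if only the 80\% interval
#' does, otherwise none.
#'
#' @param table A `standardized_table` containing standardized fitness.
#' @param generation Generation to contrast.
#' @param lineages Optional lineage subset (e.g. exclude one hybrid line).
#' @param ... Passed to [fit_hierarchical_group_model()].
#' @return A list of class `fitness_contrast`: `generation`, `mean_diff`,
#'   `ci95`, `ci80`, `significance` (`"95"`, `"80"` or `"none"`), and the
#'   posterior.
#' @export
fitness_generation_contrast <- function(table, generation, lineages = NULL, ...) {
  rows <- !is.na(table$generation) & table$generation == generation &
    !is.na(table$treatment) & !is.na(table$fitness)
  sub <- table[rows, , drop = FALSE]
  if (!is.null(lineages)) sub <- sub[sub$lineage %in% lineages, , drop = FALSE]
  if (length(unique(sub$treatment)) < 2L) {
    stop("generation ", generation, " lacks one of the treatments", call. = FALSE)
  }
  if (min(table(sub$treatment)) < 2L) {
    warning("a treatment has a single plant in generation ", generation,
            "; the contrast will be very wide", call. = FALSE)
  }
  post <- fit_hierarchical_group_model(sub$fitness, sub$treatment, sub$lineage, ...)
  d <- post$draws[, "diff"]  # hybrid minus control (levels sorted)
  cl <- .classify_support(d)
  structure(list(generation = generation, mean_diff = cl$mean,
                 ci95 = cl$ci95, ci80 = cl$ci80,
                 significance = if (cl$ci95$excludes_zero) "95" else
                   if (cl$ci80$excludes_zero) "80" else "none",
                 posterior = post),
            class = "fitness_contrast")
}

#' Signed distances from generation-1 means to the local reference phenotype
#'
#' For each trait, distance = (mean standardized reference value) - (mean
#' standardized generation-1 value of the focal lineage), so a positive
#' regression of slope on distance means evolution toward the local
#' phenotype.
#'
#' @param table A `standardized_table` (global mode, reference rows
#'   transformed on the same scale).
#' @param slopes Named vector of posterior-mean slopes per trait for the
#'   focal lineage.
#' @param lineage Focal lineage.
#' @param reference Reference lineage (default `"texanus"`).
#' @return data.frame: trait, distance, slope.
#' @export
compute_distance_records <- function(table, slopes, lineage,
                                     reference = "texanus") {
  ref_rows <- table$lineage == reference
  g1_rows <- table$lineage == lineage & !is.na(table$generation) &
    table$generation == min(table$generation[table$lineage == lineage],
                            na.rm = TRUE)
  if (!any(ref_rows)) stop("no reference rows (", reference, ")", call. = FALSE)
  recs <- lapply(names(slopes), function(tr) {
    if (!tr %in% names(table)) return(NULL)
    d <- mean(table[[tr]][ref_rows], na.rm = TRUE) -
      mean(table[[tr]][g1_rows], na.rm = TRUE)
    if (!is.finite(d)) return(NULL)
    data.frame(trait = tr, distance = d, slope = unname(slopes[tr]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Regress evolutionary rate on distance from the local phenotype
#'
#' Ordinary least squares of the Bayesian slope estimates on signed
#' phenotypic distance, with a two-sided t-test (n - 2 df) on the
#' coefficient. A positive coefficient indicates that traits starting far
#' from the locally adapted phenotype evolved faster, and toward it. Set
#' `absolute = TRUE` to regress |slope| on |distance| instead.
#'
#' @param records data.frame with `distance` and `slope` columns
#'   ([compute_distance_records()]).
#' @param absolute Use absolute distance and rate (default FALSE).
#' @return List of class `distance_regression`: `coefficient`, `intercept`,
#'   `p_value`, `r_squared`, `n`.
#' @export
regress_rate_on_distance <- function(records, absolute = FALSE) {
  records <- records[stats::complete.cases(records[, c("distance", "slope")]), ]
  if (nrow(records) < 3L) stop("need at least 3 traits", call. = FALSE)
  x <- records$distance; y <- records$slope
  if (absolute) { x <- abs(x); y <- abs(y) }
  if (stats::var(x) == 0) stop("zero variance in distances", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(coefficient = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 r_squared = sm$r.squared, n = nrow(records)),
            class = "distance_regression")
}

#' Write evolution results as CSV (machine twin of the trend heatmap)
#' @param results The `results` data.frame from [fit_all_traits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evolution_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
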