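# Evolutionary rates in haldanes, rate summaries, faster-lineage counts and
# the 1-df equal-expectation chi-square comparison of trait counts.

#' Evolutionary rate in haldanes between two generations
#'
#' The haldane is the change in a trait's mean, in pooled within-population
#' phenotypic standard deviations, per generation:
#' `H = ((ybar_late - ybar_early) / s_p) / g`, where the means are taken on
#' the natural-log scale when `log_transform = TRUE` and `s_p` is the pooled
#' standard deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' Traits that can take nonpositive values (e.g. carbon-isotope ratios, zero
#' damage fractions) cannot be log-transformed; rather than shifting by an
#' arbitrary offset (which changes `H`), the rate is computed on the raw
#' scale and flagged via `log_transform_applied = FALSE`.
#'
#' @param values_early Trait values in the earlier generation (length >= 2).
#' @param values_late Trait values in the later generation (length >= 2).
#' @param g Generations elapsed (default 7, generations 1 to 8).
#' @param log_transform Apply the natural-log transform first (default TRUE).
#' @param trait,lineage Optional labels carried into the result.
#' @return A list of class `haldane_result`: `H`, `ybar_early`, `ybar_late`,
#'   `s_p`, `g`, `log_transform_applied`, `trait`, `lineage`.
#' @export
haldane_rate <- function(values_early, values_late, g = 7, log_transform = TRUE,
                         trait = NA_character_, lineage = NA_character_) {
  values_early <- values_early[!is.na(values_early)]
  values_late <- values_late[!is.na(values_late)]
  if (length(values_early) < 2L || length(values_late) < 2L) {
    stop("need at least 2 values per generation", call. = FALSE)
  }
  applied <- FALSE
  if (log_transform) {
    if (all(values_early > 0) && all(values_late > 0)) {
      values_early <- log(values_early)
      values_late <- log(values_late)
      applied <- TRUE
    } else {
      warning("nonpositive values: haldane computed on the raw scale ",
              "(log_transform_applied = FALSE)", call. = FALSE)
    }
  }
  n1 <- length(values_early); n2 <- length(values_late)
  s_p <- sqrt(((n1 - 1) * stats::var(values_early) +
               (n2 - 1) * stats::var(values_late)) / (n1 + n2 - 2))
  if (s_p == 0) stop("pooled standard deviation is zero", call. = FALSE)
  y1 <- mean(values_early); y2 <- mean(values_late)
  structure(list(H = ((y2 - y1) / s_p) / g,
                 ybar_early = y1, ybar_late = y2, s_p = s_p, g = g,
                 log_transform_applied = applied,
                 trait = trait, lineage = lineage),
            class = "haldane_result")
}

#' Haldane rates for all traits of a phenotype table
#'
#' Computes [haldane_rate()] for each trait (and fitness) of one lineage,
#' contrasting its first and last observed generations.
#'
#' @param table A `phenotype_table` (raw scale, not standardized).
#' @param lineage Lineage to rate.
#' @param traits Trait columns (default: all present).
#' @param gen_early,gen_late Generations to contrast (defaults: min and max
#'   observed for the lineage).
#' @param log_transform Passed to [haldane_rate()].
#' @return data.frame with trait, lineage, H, s_p, g, log_transform_applied.
#' @export
haldane_table <- function(table, lineage, traits = NULL,
                          gen_early = NULL, gen_late = NULL,
                          log_transform = TRUE) {
  rows <- table$lineage == lineage
  if (!any(rows)) stop("no rows for lineage ", lineage, call. = FALSE)
  sub <- table[rows, , drop = FALSE]
  if (is.null(gen_early)) gen_early <- min(sub$generation, na.rm = TRUE)
  if (is.null(gen_late)) gen_late <- max(sub$generation, na.rm = TRUE)
  g <- gen_late - gen_early
  if (g <= 0) stop("need two distinct generations", call. = FALSE)
  if (is.null(traits)) traits <- c(trait_columns(table), "fitness")
  res <- lapply(traits, function(tr) {
    v1 <- sub[[tr]][sub$generation == gen_early]
    v2 <- sub[[tr]][sub$generation == gen_late]
    hr <- tryCatch(
      suppressWarnings(haldane_rate(v1, v2, g = g, log_transform = log_transform,
                                    trait = tr, lineage = lineage)),
      error = function(e) NULL)
    if (is.null(hr)) return(NULL)
    data.frame(trait = tr, lineage = lineage, H = hr$H, s_p = hr$s_p, g = g,
               log_transform_applied = hr$log_transform_applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summarize absolute haldane rates across traits
#'
#' Mean, maximum and minimum of the absolute rates, as reported in
#' lineage-level "global average" rows. Values are additionally returned
#' rounded to 3 decimals for reporting.
#'
#' @param rates Numeric vector of signed haldane rates (one per trait).
#' @param lineage Optional label.
#' @return List with `mean_abs`, `max_abs`, `min_abs`, rounded `mean_abs_3`,
#'   `n_traits`, `lineage`.
#' @export
summarize_rates <- function(rates, lineage = NA_character_) {
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0L) stop("no rates supplied", call. = FALSE)
  a <- abs(rates)
  list(mean_abs = mean(a), max_abs = max(a), min_abs = min(a),
       mean_abs_3 = round(mean(a), 3), n_traits = length(a),
       lineage = lineage)
}

#' Count which lineage evolved faster, trait by trait
#'
#' Compares absolute haldane rates per trait between two lineages with strict
#' inequality; equal magnitudes are counted as ties.
#'
#' @param ratesA,ratesB Named (or identically ordered) signed rate vectors
#'   over the same trait set.
#' @return List with `countA` (traits where A is faster), `countB`, `ties`.
#' @export
count_faster <- function(ratesA, ratesB) {
  if (length(ratesA) != length(ratesB)) {
    stop("rate vectors must cover the same traits", call. = FALSE)
  }
  if (!is.null(names(ratesA)) && !is.null(names(ratesB)) &&
      !identical(names(ratesA), names(ratesB))) {
    stop("trait names differ or are ordered differently", call. = FALSE)
  }
  a <- abs(ratesA); b <- abs(ratesB)
  list(countA = sum(a > b), countB = sum(b > a), ties = sum(a == b))
}

#' Chi-square comparison of two trait counts
#'
#' Tests whether two counts (e.g. numbers of significantly evolving traits in
#' two lineages) differ, as a 1-df goodness-of-fit test against equal
#' expected frequencies: `X^2 = (a - b)^2 / (a + b)`, no continuity
#' correction. A 2x2 contingency variant (each count out of `n_traits`
#' possible) is available for comparison.
#'
#' @param a,b Nonnegative counts.
#' @param method `"goodness_of_fit"` (default) or `"contingency"`.
#' @param n_traits Total traits per lineage, required for the contingency
#'   variant.
#' @return List of class `count_comparison`: `counts`, `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
chisq_equal_counts <- function(a, b, method = c("goodness_of_fit", "contingency"),
                               n_traits = NULL) {
  method <- match.arg(method)
  if (a < 0 || b < 0) stop("counts must be nonnegative", call. = FALSE)
  if (a + b == 0) stop("both counts are zero", call. = FALSE)
  if (method == "goodness_of_fit") {
    stat <- (a - b)^2 / (a + b)
  } else {
    if (is.null(n_traits)) stop("contingency method needs n_traits", call. = FALSE)
    tab <- rbind(c(a, n_traits - a), c(b, n_traits - b))
    stat <- unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
  }
  structure(list(counts = c(a = a, b = b), statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = method),
            class = "count_comparison")
}

#' Published per-trait haldane rates
#'
#' The printed per-trait evolutionary rates (haldanes) for the control,
#' LBJ-hybrid and BFL-hybrid lineages of the eight-year sunflower field
#' experiment, shipped as a plain-text fixture. Used to recompute the
#' lineage-level rate summaries and faster-lineage counts.
#'
#' @return data.frame with columns `trait`, `control`, `hybrid_LBJ`,
#'   `hybrid_BFL` (27 rows).
#' @export
published_haldanes <- function() {
  path <- system.file("extdata", "published_haldanes.csv", package = "fieldevol")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a rate table CSV (trait x lineage plus a global-average row)
#' @param rate_df data.frame with `trait` plus one column per lineage.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rate_df, path) {
  lineage_cols <- setdiff(names(rate_df), "trait")
  avg <- c(trait = "global_average_abs",
           lapply(rate_df[lineage_cols], function(x) round(mean(abs(x), na.rm = TRUE), 3)))
  out <- rbind(rate_df, as.data.frame(avg, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
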