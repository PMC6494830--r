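# Core data structures: tidy per-plant phenotype tables, standardization,
# exclusion filters, and the derived-trait / fitness formulas applied before
# any downstream analysis.

#' Canonical trait abbreviations
#'
#' The 27 trait abbreviations used throughout the package, grouped into
#' ecophysiological, phenological, architectural, resistance/palatability and
#' herbivore-damage traits. Phenotype CSV trait columns must use these names.
#'
#' @return Character vector of length 27.
#' @export
fieldevol_traits <- function() {
  c(
    # ecophysiology
    "SLA", "LeafLong", "LDMC", "Succ", "Chloro", "LWR", "WUE",
    # phenology
    "DaysToBud", "SMT", "Longevity",
    # architecture
    "DiskDiam", "Volume", "HtLow", "Bushy", "RelBrDiam",
    # resistance / palatability
    "GlandDens", "HairDens", "CNratio",
    # herbivore damage
    "SuckDam", "ChewDam", "StemBorer", "WeevilDam", "MidgeDam",
    "ParaDam", "HoleDam", "GSW", "RecepDam"
  )
}

#' Known lineage labels
#' @return Character vector of the four recognised lineage labels.
#' @export
fieldevol_lineages <- function() {
  c("control", "hybrid_LBJ", "hybrid_BFL", "texanus")
}

#' Construct a phenotype table
#'
#' Builds the package's central observational record: one row per plant with
#' lineage, generation, survival/damage flags, fitness (viable seeds per
#' plant) and any subset of the 27 named trait columns (see
#' [fieldevol_traits()]). A `treatment` column (control/hybrid) is derived
#' from `lineage`; reference (`texanus`) rows carry `NA` treatment and play
#' no role in generational trends.
#'
#' @param data A data.frame with at least `plant_id`, `lineage`, `generation`
#'   and `fitness` columns. Optional: `longevity_days`, `transplant_death`,
#'   `scarification_damage`, `apical_bud_weevil`, and trait columns named by
#'   [fieldevol_traits()]. Missing cells are `NA` (empty fields in CSV).
#' @return A data.frame of class `phenotype_table` with a derived `treatment`
#'   column and a `traits` attribute listing the trait columns present.
#' @export
phenotype_table <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("plant_id", "lineage", "generation", "fitness")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(data$lineage), fieldevol_lineages())
  if (length(bad) > 0L) {
    stop("unknown lineage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gen <- data$generation
  if (any(!is.na(gen) & (gen < 1 | gen > 8 | gen != round(gen)))) {
    stop("generation must be an integer in 1..8", call. = FALSE)
  }
  data$generation <- as.integer(gen)
  data$treatment <- ifelse(data$lineage == "control", "control",
                    ifelse(data$lineage %in% c("hybrid_LBJ", "hybrid_BFL"),
                           "hybrid", NA_character_))
  for (fl in c("transplant_death", "scarification_damage", "apical_bud_weevil")) {
    if (!fl %in% names(data)) data[[fl]] <- FALSE
    data[[fl]] <- as.logical(data[[fl]])
  }
  if (!"longevity_days" %in% names(data)) data$longevity_days <- NA_real_
  if (any(data$fitness < 0, na.rm = TRUE)) {
    stop("fitness must be nonnegative", call. = FALSE)
  }
  attr(data, "traits") <- intersect(fieldevol_traits(), names(data))
  class(data) <- c("phenotype_table", "data.frame")
  data
}

#' List trait columns present in a phenotype table
#' @param table A `phenotype_table`.
#' @return Character vector of trait column names.
#' @export
trait_columns <- function(table) {
  tr <- attr(table, "traits")
  if (is.null(tr)) tr <- intersect(fieldevol_traits(), names(table))
  tr
}

#' Standardize trait (and fitness) columns to mean zero, unit SD
#'
#' Z-scores each requested column using the sample standard deviation
#' (`n - 1` denominator). Two modes are available:
#'
#' * `"global_across_lines"` — one mean/SD per column, fitted jointly across
#'   control and hybrid rows (reference `texanus` rows are transformed with
#'   the fitted scale but excluded from fitting it), as used by the
#'   trait-evolution analyses.
#' * `"within_treatment"` — separate mean/SD per treatment (control, hybrid),
#'   as used by the phenotypic selection analysis; rows with no treatment
#'   (reference accessions) become `NA`.
#'
#' Missing cells stay missing. The fitted scales are stored so the transform
#' can be inverted with [inverse_standardize()].
#'
#' @param table A `phenotype_table`.
#' @param mode `"global_across_lines"` (default) or `"within_treatment"`.
#' @param columns Columns to standardize; defaults to all trait columns
#'   present plus `fitness`.
#' @return The table with the selected columns replaced by z-scores, class
#'   `standardized_table`, carrying `scaling` and `mode` attributes.
#' @export
standardize <- function(table,
                        mode = c("global_across_lines", "within_treatment"),
                        columns = NULL) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) stop("cannot standardize an empty table", call. = FALSE)
  if (is.null(columns)) columns <- c(trait_columns(table), "fitness")
  columns <- intersect(columns, names(table))
  scaling <- list()
  fit_scale <- function(x, label) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      stop("need at least 2 non-missing values to standardize ", label,
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (s == 0) {
      stop("zero variance in column '", label, "'; cannot standardize",
           call. = FALSE)
    }
    c(mean = mean(x), sd = s)
  }
  if (mode == "global_across_lines") {
    fit_rows <- table$lineage != "texanus"
    for (cl in columns) {
      sc <- fit_scale(table[[cl]][fit_rows], cl)
      table[[cl]] <- (table[[cl]] - sc["mean"]) / sc["sd"]
      scaling[[cl]] <- sc
    }
  } else {
    for (cl in columns) {
      sc_by <- list()
      out <- rep(NA_real_, nrow(table))
      for (tr in c("control", "hybrid")) {
        rows <- !is.na(table$treatment) & table$treatment == tr
        if (!any(rows)) next
        sc <- fit_scale(table[[cl]][rows], paste0(cl, " (", tr, ")"))
        out[rows] <- (table[[cl]][rows] - sc["mean"]) / sc["sd"]
        sc_by[[tr]] <- sc
      }
      table[[cl]] <- out
      scaling[[cl]] <- sc_by
    }
  }
  attr(table, "scaling") <- scaling
  attr(table, "mode") <- mode
  class(table) <- unique(c("standardized_table", class(table)))
  table
}

#' Invert a standardization
#'
#' Restores original units for the columns standardized by [standardize()],
#' using the stored means and SDs. Missing cells stay missing.
#'
#' @param table A `standardized_table`.
#' @return The table on the original scale (class `phenotype_table`).
#' @export
inverse_standardize <- function(table) {
  scaling <- attr(table, "scaling")
  mode <- attr(table, "mode")
  if (is.null(scaling)) stop("table carries no scaling attribute", call. = FALSE)
  for (cl in names(scaling)) {
    sc <- scaling[[cl]]
    if (mode == "global_across_lines") {
      table[[cl]] <- table[[cl]] * sc["sd"] + sc["mean"]
    } else {
      out <- rep(NA_real_, nrow(table))
      for (tr in names(sc)) {
        rows <- !is.na(table$treatment) & table$treatment == tr
        out[rows] <- table[[cl]][rows] * sc[[tr]]["sd"] + sc[[tr]]["mean"]
      }
      table[[cl]] <- out
    }
  }
  attr(table, "scaling") <- NULL
  attr(table, "mode") <- NULL
  class(table) <- setdiff(class(table), "standardized_table")
  table
}

#' Apply the study's plant-exclusion rules
#'
#' Removes plants that cannot contribute trait measurements: early transplant
#' deaths, plants damaged during seed scarification, and plants that lived
#' less than 75 days (strictly less; a plant surviving exactly 75 days is
#' kept). In the `"architectural"` context, plants with weevil damage to the
#' primary (apical) bud are additionally removed because their growth
#' architecture is abnormal. Rules are applied in that order and each removed
#' plant is attributed to the first rule it matches.
#'
#' @param table A `phenotype_table`.
#' @param context `"general"` (default) or `"architectural"`.
#' @return A list with `table` (the retained rows) and `report`, a data.frame
#'   of rule name and number of plants removed by that rule.
#' @export
filter_individuals <- function(table, context = c("general", "architectural")) {
  context <- match.arg(context)
  rules <- list(
    transplant_death = function(t) !is.na(t$transplant_death) & t$transplant_death,
    scarification_damage = function(t) !is.na(t$scarification_damage) & t$scarification_damage,
    longevity_lt_75 = function(t) !is.na(t$longevity_days) & t$longevity_days < 75
  )
  if (context == "architectural") {
    rules$apical_bud_weevil <-
      function(t) !is.na(t$apical_bud_weevil) & t$apical_bud_weevil
  }
  removed_by <- rep(NA_character_, nrow(table))
  for (rn in names(rules)) {
    hit <- rules[[rn]](table) & is.na(removed_by)
    removed_by[hit] <- rn
  }
  report <- data.frame(
    rule = names(rules),
    n_removed = vapply(names(rules), function(rn) sum(removed_by == rn, na.rm = TRUE),
                       integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  kept <- table[is.na(removed_by), , drop = FALSE]
  attr(kept, "traits") <- attr(table, "traits")
  class(kept) <- class(table)
  list(table = kept, report = report)
}

#' Plant volume from stem diameter and height
#'
#' Cylinder approximation of overall plant size:
#' `V = pi * (stem_diameter / 2)^2 * height`.
#'
#' @param stem_diameter Primary stem diameter (cm), nonnegative.
#' @param height Plant height (cm), nonnegative.
#' @return Volume in cubic centimetres (vectorized).
#' @export
plant_volume <- function(stem_diameter, height) {
  if (any(stem_diameter < 0, na.rm = TRUE) || any(height < 0, na.rm = TRUE)) {
    stop("stem diameter and height must be nonnegative", call. = FALSE)
  }
  pi * (stem_diameter / 2)^2 * height
}

#' Bushiness: mean branch position of flowering heads
#'
#' Heads on the main stem have branch position 1, heads on primary branches
#' position 2, heads on secondary branches position 3; bushiness is the mean
#' position over all flowering heads.
#'
#' @param head_positions Integer vector of branch positions, one per head.
#' @return Mean branch position, or `NA` if no heads.
#' @export
bushiness <- function(head_positions) {
  head_positions <- head_positions[!is.na(head_positions)]
  if (length(head_positions) == 0L) return(NA_real_)
  if (any(head_positions < 1)) stop("branch positions start at 1", call. = FALSE)
  mean(head_positions)
}

#' Relative branch diameter
#'
#' Mean diameter of qualifying primary branches (basal diameter at least
#' `min_diameter`, default 3 mm) divided by the primary stem diameter — a
#' measure of investment in branches relative to the main stem.
#'
#' @param branch_diameters Basal diameters of primary branches (mm).
#' @param stem_diameter Primary stem diameter (mm), positive.
#' @param min_diameter Qualification threshold (mm); branches thinner than
#'   this are ignored.
#' @return Ratio, or `NA` if no branch qualifies.
#' @export
relative_branch_diameter <- function(branch_diameters, stem_diameter,
                                     min_diameter = 3) {
  if (is.na(stem_diameter) || stem_diameter <= 0) {
    stop("stem diameter must be positive", call. = FALSE)
  }
  q <- branch_diameters[!is.na(branch_diameters) & branch_diameters >= min_diameter]
  if (length(q) == 0L) return(NA_real_)
  mean(q) / stem_diameter
}

#' Seed-damage fractions from category counts
#'
#' Converts per-category seed counts (viable, parasitoid-attacked,
#' midge-damaged, hole-damaged, gray-seed-weevil-damaged) into fractions of
#' total seeds scored per plant. With zero seeds scored the fractions are
#' undefined and returned as `NA`, never as zero.
#'
#' @param counts Named numeric vector of nonnegative category counts. Must
#'   include `viable`; damage categories are everything else (typically
#'   `ParaDam`, `MidgeDam`, `HoleDam`, `GSW`).
#' @return Named vector of fractions for the damage categories plus
#'   `viable`; entries sum to 1 when defined.
#' @export
seed_damage_fractions <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || !"viable" %in% names(counts)) {
    stop("counts must be named and include 'viable'", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (is.na(total) || total == 0) {
    return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  }
  counts / total
}

#' Seed census record for one plant
#'
#' Raw seed-scoring data for one plant: total heads produced (bagged plus
#' unbagged), viable-seed counts for each bagged head, per-category seed
#' counts across all scored seeds, and larval hole counts for the sampled
#' receptacles.
#'
#' @param plant_id Plant identifier.
#' @param heads_total Total number of heads produced (bagged + unbagged).
#' @param bagged_viable Viable-seed count per bagged head (integer vector,
#'   possibly empty).
#' @param category_counts Named nonnegative counts including `viable` (see
#'   [seed_damage_fractions()]); defaults to none.
#' @param receptacle_holes Hole counts for 1-8 sampled receptacles.
#' @return A list of class `seed_census`.
#' @export
seed_census <- function(plant_id, heads_total, bagged_viable = integer(0),
                        category_counts = NULL, receptacle_holes = numeric(0)) {
  if (heads_total < 0) stop("heads_total must be nonnegative", call. = FALSE)
  if (length(bagged_viable) > heads_total) {
    stop("more bagged heads than total heads", call. = FALSE)
  }
  if (any(bagged_viable < 0, na.rm = TRUE) || any(receptacle_holes < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  structure(list(plant_id = plant_id, heads_total = heads_total,
                 bagged_viable = bagged_viable,
                 category_counts = category_counts,
                 receptacle_holes = receptacle_holes),
            class = "seed_census")
}

#' Estimate fitness as viable seed production
#'
#' Per-plant fitness is estimated as total heads produced (bagged + unbagged)
#' multiplied by the mean viable-seed count over the bagged heads. A plant
#' with zero heads has fitness 0. A plant with heads but no bagged head has
#' no usable per-head estimate: fitness is `NA` with a warning.
#'
#' @param census A `seed_census`, or a numeric `heads_total` (with
#'   `bagged_viable` supplied separately).
#' @param bagged_viable Viable counts per bagged head when `census` is numeric.
#' @return Estimated viable seeds per plant.
#' @export
estimate_fitness <- function(census, bagged_viable = NULL) {
  if (inherits(census, "seed_census")) {
    heads_total <- census$heads_total
    bagged_viable <- census$bagged_viable
  } else {
    heads_total <- census
  }
  if (heads_total == 0) return(0)
  bagged_viable <- bagged_viable[!is.na(bagged_viable)]
  if (length(bagged_viable) == 0L) {
    warning("no bagged heads scored; fitness is missing", call. = FALSE)
    return(NA_real_)
  }
  heads_total * mean(bagged_viable)
}

#' Derive named trait values from raw measurements
#'
#' Convenience wrapper applying the architectural and seed-damage formulas to
#' one plant's raw measurements. Any measurement left `NULL` yields `NA` for
#' the corresponding trait.
#'
#' @param measurements A list with any of: `stem_diameter_cm` and `height_cm`
#'   (for `Volume`); `head_positions` (for `Bushy`); `branch_diameters_mm`
#'   and `stem_diameter_mm` (for `RelBrDiam`); `seed_counts` (named, incl.
#'   `viable`, for damage fractions); `receptacle_holes` (for `RecepDam`).
#' @return Named list of derived trait values.
#' @export
derive_traits <- function(measurements) {
  m <- measurements
  out <- list()
  if (!is.null(m$stem_diameter_cm) && !is.null(m$height_cm)) {
    out$Volume <- plant_volume(m$stem_diameter_cm, m$height_cm)
  }
  if (!is.null(m$head_positions)) out$Bushy <- bushiness(m$head_positions)
  if (!is.null(m$branch_diameters_mm) && !is.null(m$stem_diameter_mm)) {
    out$RelBrDiam <- relative_branch_diameter(m$branch_diameters_mm,
                                              m$stem_diameter_mm)
  }
  if (!is.null(m$seed_counts)) {
    fr <- seed_damage_fractions(m$seed_counts)
    for (nm in setdiff(names(fr), "viable")) out[[nm]] <- unname(fr[nm])
  }
  if (!is.null(m$receptacle_holes)) {
    out$RecepDam <- if (length(m$receptacle_holes) == 0L) NA_real_ else
      mean(m$receptacle_holes, na.rm = TRUE)
  }
  out
}

#' Read a phenotype CSV
#'
#' Expects a header row with `plant_id`, `lineage`, `generation`, `fitness`,
#' optionally `longevity_days` and the three exclusion flags, and trait
#' columns named by the canonical abbreviations. Empty fields are missing
#' values.
#'
#' @param path Path to the CSV file.
#' @return A `phenotype_table`.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (fl in c("transplant_death", "scarification_damage", "apical_bud_weevil")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  phenotype_table(df)
}

#' Write a phenotype CSV
#' @param table A `phenotype_table`.
#' @param path Output path. Missing values are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an exclusion report CSV
#' @param report The `report` element of [filter_individuals()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
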