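# FOPL counterfactual engine: food-class classification, per-class percentage
# nutrient reductions, the counterfactual-calorie formula (sugars 4 kcal/g,
# saturated fat 9 kcal/g), re-estimation of usual intakes on adjusted records,
# and the non-overlapping-CI significance rule.

FOOD_CLASSES <- c("food", "beverage", "snack_food", "alcoholic_beverage",
                  "meal_replacement")
EXEMPT_CLASSES <- c("alcoholic_beverage", "meal_replacement")

#' Food-class map
#'
#' Maps recall category codes to the five classes the scenario engine
#' distinguishes. Every category code appearing in the data must be mapped;
#' unmapped codes raise an error rather than defaulting silently. Each entry
#' carries a provenance note so classification decisions are auditable.
#'
#' @param codes character vector of category codes
#' @param classes parallel vector of food classes
#' @param provenance parallel vector of notes (recycled)
#' @return data frame with class `food_class_map`
#' @export
food_class_map <- function(codes, classes, provenance = "user supplied") {
  stopifnot(length(codes) == length(classes))
  bad <- setdiff(classes, FOOD_CLASSES)
  if (length(bad)) stop("unknown food class(es): ", paste(bad, collapse = ", "))
  structure(data.frame(category_code = codes, food_class = classes,
                       provenance = provenance, stringsAsFactors = FALSE),
            class = c("food_class_map", "data.frame"))
}

#' Default food-class map matching the synthetic category table
#' @return a [food_class_map()] covering [default_categories()]
#' @export
default_food_class_map <- function() {
  cats <- default_categories()
  food_class_map(cats$category_code, cats$food_class,
                 provenance = "synthetic category table")
}

#' Classify one or more recall records
#'
#' @param records recall records with a `category_code` column
#' @param map a [food_class_map()]
#' @return character vector of food classes
#' @export
classify_item <- function(records, map) {
  idx <- match(records$category_code, map$category_code)
  if (anyNA(idx)) {
    missing <- unique(records$category_code[is.na(idx)])
    stop("unmapped category code(s): ", paste(missing, collapse = ", "))
  }
  map$food_class[idx]
}

#' Counterfactual scenario specification
#'
#' Percentage changes per food class for sodium, sugars, saturated fat and
#' calories (negative = reduction), the exempt classes (alcoholic beverages
#' and meal replacements, regulated separately), and the calorie mode:
#' `derived_from_macros` leaves item energy untouched (counterfactual calories
#' are derived downstream from sugar and saturated-fat changes), `direct`
#' rescales item energy by its percentage change.
#'
#' @param name scenario name
#' @param deltas named list: `food_class -> c(sodium=, sugars=, satfat=, calories=)`
#'   percentages
#' @param exempt_classes classes never altered
#' @param calorie_mode `"derived_from_macros"` or `"direct"`
#' @return a `scenario_spec`
#' @export
scenario_spec <- function(name, deltas,
                          exempt_classes = EXEMPT_CLASSES,
                          calorie_mode = c("derived_from_macros", "direct")) {
  calorie_mode <- match.arg(calorie_mode)
  for (cl in names(deltas)) {
    d <- deltas[[cl]]
    if (any(d <= -100)) stop("delta <= -100% is not allowed (class ", cl, ")")
    if (any(d > 100)) stop("delta > 100% is not allowed (class ", cl, ")")
    if (cl %in% exempt_classes && any(d != 0))
      stop("exempt class ", cl, " must receive no change")
    if (calorie_mode == "direct" && !("calories" %in% names(d)))
      stop("calorie_mode = 'direct' requires a calories delta for class ", cl)
  }
  structure(list(name = name, deltas = deltas,
                 exempt_classes = exempt_classes, calorie_mode = calorie_mode),
            class = "scenario_spec")
}

#' Built-in scenario library
#'
#' The four policy scenarios plus the WHO-criteria sensitivity scenario, as
#' percentage changes in purchases observed under 'high in' labelling:
#' S1 applies overall changes to all foods and beverages; S2 splits food vs
#' beverage changes; S3 targets snack foods and beverages only; S4 applies
#' meta-analytic overall changes; WHO applies calorie/satfat/sodium criteria
#' directly (no sugars term, direct calorie mode).
#'
#' @return named list of [scenario_spec()] objects: S1, S2, S3, S4, WHO
#' @export
scenario_library <- function() {
  all_classes <- c("food", "snack_food", "beverage")
  spread <- function(d, classes = all_classes)
    stats::setNames(rep(list(d), length(classes)), classes)
  list(
    S1 = scenario_spec("S1", spread(
      c(sodium = -4.7, sugars = -10.2, satfat = -3.9, calories = -3.5))),
    S2 = scenario_spec("S2", c(
      spread(c(sodium = -4.6, sugars = -5.4, satfat = -3.6, calories = -1.7),
             c("food", "snack_food")),
      spread(c(sodium = -5.2, sugars = -13.2, satfat = -5.6, calories = -9.9),
             "beverage"))),
    S3 = scenario_spec("S3", c(
      spread(c(sodium = -6.3, sugars = -0.1, satfat = -6.5, calories = -3.0),
             "snack_food"),
      spread(c(sodium = -5.5, sugars = -8.7, satfat = -19.5, calories = -10.5),
             "beverage"))),
    S4 = scenario_spec("S4", spread(
      c(sodium = -7.8, sugars = -7.3, satfat = -16.3, calories = -12.9))),
    WHO = scenario_spec("WHO", spread(
      c(sodium = -6.4, sugars = 0, satfat = -12.9, calories = -5.3)),
      calorie_mode = "direct"))
}

#' Apply a counterfactual scenario to item-level records
#'
#' Each record in a targeted, non-exempt class has its nutrient amounts scaled
#' by `1 + delta/100`. Untargeted and exempt classes pass through unchanged.
#' Energy is rescaled only in `direct` calorie mode; in
#' `derived_from_macros` mode counterfactual calories are computed downstream
#' from the sugar and saturated-fat changes. Record count and identifiers are
#' preserved.
#'
#' @param records item-level recall records
#' @param scenario a [scenario_spec()]
#' @param map a [food_class_map()] covering all codes in `records`
#' @return adjusted records, same shape and order
#' @export
apply_scenario <- function(records, scenario, map) {
  cls <- classify_item(records, map)
  out <- records
  for (target in names(scenario$deltas)) {
    if (target %in% scenario$exempt_classes) next
    sel <- cls == target
    if (!any(sel)) next
    d <- scenario$deltas[[target]]
    for (nm in c("sodium", "sugars", "satfat")) {
      if (!is.na(d[nm]) && nm %in% names(out))
        out[[nm]][sel] <- out[[nm]][sel] * (1 + d[[nm]] / 100)
    }
    if (scenario$calorie_mode == "direct" && "calories" %in% names(d))
      out$energy[sel] <- out$energy[sel] * (1 + d[["calories"]] / 100)
  }
  out
}

#' Counterfactual calories from sugar and saturated-fat changes
#'
#' `counterfactual kcal = baseline kcal - (4 * delta_sugars + 9 * delta_satfat)`
#' with deltas as positive reduction magnitudes in g/day. The implied calorie
#' change `4 * delta_sugars + 9 * delta_satfat` is attached as attribute
#' `delta_kcal`.
#'
#' @param baseline_kcal baseline energy, kcal/day
#' @param delta_sugars,delta_satfat reductions (positive magnitudes), g/day
#' @return counterfactual kcal/day with attribute `delta_kcal`
#' @export
derive_counterfactual_calories <- function(baseline_kcal, delta_sugars,
                                           delta_satfat) {
  dk <- delta_kcal_from_macros(delta_sugars, delta_satfat)
  out <- baseline_kcal - dk
  if (any(out < 0)) stop("counterfactual calories would be negative")
  attr(out, "delta_kcal") <- dk
  out
}

#' @rdname derive_counterfactual_calories
#' @export
delta_kcal_from_macros <- function(delta_sugars, delta_satfat) {
  4 * delta_sugars + 9 * delta_satfat
}

#' Re-estimate usual intakes under a counterfactual scenario
#'
#' Runs the full one-part pipeline per nutrient on the scenario-adjusted
#' records with the same estimation configuration as the baseline run (same
#' Box-Cox grid, covariates, weights). Counterfactual energy follows the
#' scenario's calorie mode: in `derived_from_macros` mode each person's
#' counterfactual energy is their baseline usual energy minus
#' `4 * (sugars_base - sugars_cf) + 9 * (satfat_base - satfat_cf)`; in
#' `direct` mode energy is re-fit from the rescaled records. Saturated-fat %TE
#' uses the counterfactual energy.
#'
#' @param records baseline item-level records
#' @param scenario a [scenario_spec()]
#' @param map a [food_class_map()]
#' @param respondents roster with weights
#' @param covariates per-respondent covariate frame (see
#'   [fit_one_part_model()])
#' @param baseline_person optional list of baseline person-level usual-intake
#'   frames per nutrient (computed if missing)
#' @param lambda_grid Box-Cox grid shared with the baseline run
#' @param fay_coef replicate-weight Fay coefficient
#' @return list with `estimates` (stacked usual-intake rows, diet_label =
#'   scenario name) and `person` (per-nutrient person-level usual intakes)
#' @export
reestimate_counterfactual <- function(records, scenario, map, respondents,
                                      covariates,
                                      baseline_person = NULL,
                                      lambda_grid = seq(0, 1, by = 0.05),
                                      fay_coef = 0) {
  adj <- apply_scenario(records, scenario, map)
  if (is.null(baseline_person)) {
    baseline_person <- person_usual_by_nutrient(records, covariates,
                                                lambda_grid = lambda_grid)
  }
  nutrients_to_fit <- c("sodium", "sugars", "satfat",
                        if (scenario$calorie_mode == "direct") "energy")
  cf_person <- list()
  for (nm in nutrients_to_fit) {
    fit <- fit_one_part_model(daily_totals(adj), covariates, nutrient = nm,
                              lambda_grid = lambda_grid)
    cf_person[[nm]] <- person_usual_intake(fit)
  }
  if (scenario$calorie_mode == "derived_from_macros") {
    grab <- function(df, nm) {
      out <- df[c("respondent_id", "usual")]
      names(out)[2] <- nm
      out
    }
    dd <- Reduce(function(a, b) merge(a, b, by = "respondent_id"), list(
      grab(baseline_person$energy, "energy_b"),
      grab(baseline_person$sugars, "sugars_b"),
      grab(cf_person$sugars, "sugars_c"),
      grab(baseline_person$satfat, "satfat_b"),
      grab(cf_person$satfat, "satfat_c")))
    e_cf <- derive_counterfactual_calories(
      dd$energy_b, dd$sugars_b - dd$sugars_c, dd$satfat_b - dd$satfat_c)
    cf_person$energy <- data.frame(respondent_id = dd$respondent_id,
                                   usual = as.numeric(e_cf))
  }
  # satfat %TE from counterfactual satfat and energy
  te <- merge(cf_person$satfat, cf_person$energy, by = "respondent_id",
              suffixes = c("_sf", "_en"))
  cf_person$satfat_pcte <- data.frame(
    respondent_id = te$respondent_id,
    usual = 100 * 9 * te$usual_sf / te$usual_en)
  est <- do.call(rbind, lapply(names(cf_person), function(nm)
    estimate_usual_distribution(cf_person[[nm]], respondents, nutrient = nm,
                                diet_label = scenario$name,
                                fay_coef = fay_coef)))
  list(estimates = est, person = cf_person)
}

#' Baseline person-level usual intakes for every nutrient
#'
#' Fits the one-part model per nutrient on the baseline records and returns
#' person-level usual intakes, including saturated fat as % of total energy.
#'
#' @inheritParams reestimate_counterfactual
#' @param covariates per-respondent covariates
#' @return named list of data frames (`energy`, `sodium`, `sugars`, `satfat`,
#'   `satfat_pcte`)
#' @export
person_usual_by_nutrient <- function(records, covariates,
                                     lambda_grid = seq(0, 1, by = 0.05)) {
  dt <- daily_totals(records)
  out <- list()
  for (nm in NUTRIENTS) {
    fit <- fit_one_part_model(dt, covariates, nutrient = nm,
                              lambda_grid = lambda_grid)
    out[[nm]] <- person_usual_intake(fit)
  }
  te <- merge(out$satfat, out$energy, by = "respondent_id",
              suffixes = c("_sf", "_en"))
  out$satfat_pcte <- data.frame(respondent_id = te$respondent_id,
                                usual = 100 * 9 * te$usual_sf / te$usual_en)
  out
}

#' Non-overlapping confidence-interval rule for meaningful differences
#'
#' Two estimates for the same stratum and nutrient differ meaningfully iff
#' their 95% intervals are disjoint as closed intervals (touching endpoints
#' overlap, hence not meaningful).
#'
#' @param baseline,counterfactual single rows of usual-intake estimates
#' @return logical
#' @export
meaningful_difference <- function(baseline, counterfactual) {
  if (baseline$stratum != counterfactual$stratum ||
      baseline$nutrient != counterfactual$nutrient)
    stop("estimates must be for the same stratum and nutrient")
  baseline$ci_high < counterfactual$ci_low ||
    counterfactual$ci_high < baseline$ci_low
}
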