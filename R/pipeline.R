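# End-to-end orchestration: simulate -> estimate baseline -> apply scenarios
# -> re-estimate -> CRA -> report, with a reproducible run manifest.

#' Share of total diet-related NCD deaths
#'
#' `100 * averted / total`, reported to one decimal with half-up rounding.
#'
#' @param deaths_averted_total deaths averted or delayed
#' @param total_diet_related_deaths total diet-related NCD deaths in the
#'   baseline year
#' @return percentage, one decimal
#' @export
summarize_share_of_total <- function(deaths_averted_total,
                                     total_diet_related_deaths) {
  if (any(total_diet_related_deaths <= 0)) stop("total deaths must be positive")
  round_half_up(100 * deaths_averted_total / total_diet_related_deaths, 1)
}

#' Run the full macrosimulation pipeline on synthetic data
#'
#' Executes simulate -> filter -> misreporting classification -> baseline
#' usual-intake estimation -> scenario application and re-estimation -> CRA
#' -> report bundle, deterministically given the seeds in `config`.
#'
#' @param config a [synth_config()] controlling the synthetic survey
#' @param scenarios list of [scenario_spec()]s (default the built-in library
#'   entry S1)
#' @param cra_params a `cra_params` from [read_cra_params()]
#' @param lambda_grid Box-Cox grid used for every fit
#' @param n_mc_iterations Monte Carlo iterations for uncertainty intervals
#'   (0 skips the Monte Carlo stage)
#' @param mc_seed seed for the Monte Carlo stage
#' @param mortality_scale passed to [generate_stratum_tables()]
#' @return list with `bundle` (intake table with significance flags,
#'   deaths-averted tables by sex/disease, attribution table, share-of-total
#'   summary) and `manifest` (seeds, sizes, stage record)
#' @export
run_pipeline <- function(config = synth_config(),
                         scenarios = scenario_library()["S1"],
                         cra_params = read_cra_params(),
                         lambda_grid = seq(0, 1, by = 0.05),
                         n_mc_iterations = 1000,
                         mc_seed = config$rng_seed + 10L,
                         mortality_scale = 1) {
  manifest <- list(pipeline_version = "0.1.0",
                   rng_seed = config$rng_seed, mc_seed = mc_seed,
                   n_respondents = config$n_respondents,
                   n_brr_replicates = config$n_brr_replicates,
                   n_mc_iterations = n_mc_iterations,
                   lambda_grid = lambda_grid,
                   scenarios = names(scenarios), stages = character(0))
  stage <- function(nm) manifest$stages <<- c(manifest$stages, nm)

  stage("simulate")
  respondents <- generate_respondents(config)
  recalls <- generate_recalls(respondents, config)
  tables <- generate_stratum_tables(config, mortality_scale = mortality_scale)

  stage("filter")
  fs <- filter_sample(respondents, recalls)
  kept <- fs$kept
  recalls <- recalls[recalls$respondent_id %in% kept$id, ]

  stage("misreporting")
  cuts <- misreport_cutoffs()
  dt <- daily_totals(recalls)
  ei <- stats::aggregate(energy ~ respondent_id, data = dt, FUN = mean)
  kept$tee <- compute_tee(kept, cuts)
  kept$misreporting_status <- classify_misreporting(
    ei$energy[match(kept$id, ei$respondent_id)], kept$tee, cuts)

  covariates <- data.frame(id = kept$id, age = kept$age, sex = kept$sex,
                           misreporting_status = kept$misreporting_status,
                           stringsAsFactors = FALSE)

  stage("estimate_baseline")
  baseline_person <- person_usual_by_nutrient(recalls, covariates,
                                              lambda_grid = lambda_grid)
  baseline_est <- do.call(rbind, lapply(names(baseline_person), function(nm)
    estimate_usual_distribution(baseline_person[[nm]], kept, nutrient = nm,
                                diet_label = "baseline",
                                fay_coef = config$fay_coef)))

  anthro <- summarize_anthropometrics(kept, fay_coef = config$fay_coef)
  map <- default_food_class_map()

  results <- list()
  intake_rows <- list(baseline_est)
  for (sc in scenarios) {
    stage(paste0("scenario_", sc$name))
    cf <- reestimate_counterfactual(recalls, sc, map, kept, covariates,
                                    baseline_person = baseline_person,
                                    lambda_grid = lambda_grid,
                                    fay_coef = config$fay_coef)
    intake_rows[[length(intake_rows) + 1]] <- cf$estimates

    stage(paste0("cra_", sc$name))
    model <- build_cra_model(baseline_person, cf$person, kept, tables,
                             anthro, cra_params)
    if (n_mc_iterations > 0) {
      mc <- monte_carlo_ui(model, n_iterations = n_mc_iterations,
                           seed = mc_seed)
    } else {
      mc <- list(point = cra_point_estimate(model), ui_total = c(NA, NA))
    }
    attr_tab <- attribute_by_factor(model)
    results[[sc$name]] <- list(model = model, mc = mc, attribution = attr_tab)
  }

  stage("report")
  intakes <- do.call(rbind, intake_rows)
  flags <- significance_flags(intakes)
  total_deaths <- sum(tables$deaths$count)
  summary_tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(scenario = nm,
               deaths_averted = r$mc$point$total,
               ui_low = r$mc$ui_total[1], ui_high = r$mc$ui_total[2],
               under_75 = r$mc$point$under_75,
               share_of_total_pct = summarize_share_of_total(
                 r$mc$point$total, total_deaths),
               stringsAsFactors = FALSE)
  }))
  by_sex <- do.call(rbind, lapply(names(results), function(nm) {
    b <- results[[nm]]$mc$point$by_sex
    b$scenario <- nm
    b
  }))
  by_disease <- do.call(rbind, lapply(names(results), function(nm) {
    b <- results[[nm]]$mc$point$by_disease
    b$scenario <- nm
    b
  }))
  attribution <- do.call(rbind, lapply(names(results), function(nm) {
    a <- results[[nm]]$attribution
    a$scenario <- nm
    a
  }))
  bundle <- list(sample_tally = fs$tally,
                 anthropometrics = anthro,
                 intakes = intakes,
                 significance = flags,
                 summary = summary_tab,
                 by_sex = by_sex,
                 by_disease = by_disease,
                 attribution = attribution,
                 total_diet_related_deaths = total_deaths)
  list(bundle = bundle, manifest = manifest, results = results)
}

# Non-overlapping-CI flags, baseline vs each scenario, per stratum x nutrient.
significance_flags <- function(intakes) {
  base <- intakes[intakes$diet_label == "baseline", ]
  cfs <- intakes[intakes$diet_label != "baseline", ]
  if (nrow(cfs) == 0) return(NULL)
  out <- lapply(seq_len(nrow(cfs)), function(i) {
    b <- base[base$stratum == cfs$stratum[i] &
                base$nutrient == cfs$nutrient[i], ]
    if (nrow(b) != 1) return(NULL)
    data.frame(stratum = cfs$stratum[i], nutrient = cfs$nutrient[i],
               diet_label = cfs$diet_label[i],
               significant = meaningful_difference(b[1, ], cfs[i, ]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read pipeline tables as CSV
#'
#' Plain UTF-8 CSVs with header row and RFC-4180 quoting; numbers survive a
#' write -> read round trip at better than 12 significant digits.
#'
#' @param df data frame (matrix columns are not supported here)
#' @param path file path
#' @return `read_table_csv` returns the data frame
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published reference values used for arithmetic cross-checks
#'
#' Printed summary statistics from the published Canadian 'high in' FOPL
#' impact analysis of CCHS-Nutrition 2015: baseline usual-intake means,
#' per-scenario mean reductions, sample-exclusion bookkeeping, total 2019
#' diet-related NCD deaths, and per-scenario deaths averted with their
#' disease and risk-factor breakdowns. These are inputs for reporting
#' identities (e.g. shares of total deaths, counterfactual-calorie
#' arithmetic); the package never fits to them.
#'
#' @return nested list of published values
#' @export
reference_values <- function() {
  list(
    baseline_means = list(energy_kcal = 1889, sodium_mg = 2729,
                          sugars_g = 86.4, satfat_g = 22.8,
                          satfat_pcte = 10.6),
    exclusions = list(eligible = 13919, breastfeeding = 188,
                      zero_consumption = 4,
                      underweight_or_missing_anthropometrics = 1735),
    reductions = list(
      S1 = list(sodium_mg = 128, sugars_g = 8.7, satfat_g = 0.9),
      S2 = list(sodium_mg = 126, sugars_g = 6.6, satfat_g = 0.9),
      S3 = list(sodium_mg = 31, sugars_g = 2.3, satfat_g = 0.8),
      S4 = list(sodium_mg = 212, sugars_g = 6.3, satfat_g = 3.72)),
    deaths_averted = list(S1 = 6442, S2 = 5151, S3 = 2183, S4 = 8907,
                          WHO = 12416),
    s1_by_disease = list(CVD = 4403, diabetes = 898, cancer = 631,
                         `liver disease` = 332,
                         `chronic renal failure` = 183),
    s1_by_factor = list(calories = 5930, sodium = 495, satfat = 59),
    total_diet_related_deaths_2019 = 92845)
}
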