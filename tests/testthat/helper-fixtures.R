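# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_config <- function(n = 300, seed = 11, reps = 8, ...) {
  synth_config(n_respondents = n, n_brr_replicates = reps, rng_seed = seed, ...)
}

# A small fitted study: roster, recalls, covariates, baseline person-level
# usual intakes. Coarse lambda grid keeps it quick; all tests that compare
# baseline vs counterfactual reuse the same grid.
small_study <- function() {
  fixture("small_study", function() {
    cfg <- small_config()
    respondents <- generate_respondents(cfg)
    recalls <- generate_recalls(respondents, cfg)
    kept <- filter_sample(respondents, recalls)$kept
    recalls <- recalls[recalls$respondent_id %in% kept$id, ]
    cuts <- misreport_cutoffs()
    dt <- daily_totals(recalls)
    ei <- stats::aggregate(energy ~ respondent_id, data = dt, FUN = mean)
    kept$tee <- compute_tee(kept, cuts)
    kept$misreporting_status <- classify_misreporting(
      ei$energy[match(kept$id, ei$respondent_id)], kept$tee, cuts)
    covariates <- data.frame(id = kept$id, age = kept$age, sex = kept$sex,
                             misreporting_status = kept$misreporting_status,
                             stringsAsFactors = FALSE)
    grid <- c(0, 0.5, 1)
    baseline_person <- person_usual_by_nutrient(recalls, covariates,
                                                lambda_grid = grid)
    list(config = cfg, respondents = respondents, kept = kept,
         recalls = recalls, covariates = covariates,
         baseline_person = baseline_person, lambda_grid = grid,
         daily = dt)
  })
}

# Repeated-measures data generated at lambda = 1 with known parameters:
# y = 15 + 2 * x + 0.5 * male + u + e, u ~ N(0, sigma_u2), e ~ N(0, sigma_e2)
make_lambda1_data <- function(n = 2000, second_fraction = 0.35,
                              sigma_u2 = 4, sigma_e2 = 1, seed = 1) {
  set.seed(seed)
  u <- rnorm(n, 0, sqrt(sigma_u2))
  x <- runif(n, -1, 1)
  male <- rbinom(n, 1, 0.5)
  two_days <- runif(n) < second_fraction
  rows <- data.frame(
    respondent_id = c(seq_len(n), which(two_days)),
    recall_day = c(rep(1L, n), rep(2L, sum(two_days))),
    weekend = FALSE)
  idx <- rows$respondent_id
  rows$y <- 15 + 2 * x[idx] + 0.5 * male[idx] + u[idx] +
    rnorm(nrow(rows), 0, sqrt(sigma_e2))
  cov <- data.frame(id = seq_len(n), age = x,
                    sex = ifelse(male == 1, "male", "female"))
  list(day_totals = rows, covariates = cov,
       truth = list(beta = c(intercept = 15, age = 2, sexmale = 0.5),
                    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2))
}

# One-stratum toy CRA model assembled directly (satfat %TE pathway: normal
# exposure, so the mortality ratio has the closed form exp(theta * delta)).
make_toy_model <- function(deaths_count = 1000, exposure_mean = 10,
                           exposure_sd = 1, delta = -1,
                           rr = 1.25, se_log = 0.05,
                           satfat_to_chol = 0.05, chol_se = 0,
                           extra_energy = NULL) {
  strata <- data.frame(sex = "male", age_low = 51, age_high = 55,
                       mid = 53, dri_group = "51-70 (m)",
                       stringsAsFactors = FALSE)
  moments <- data.frame(dri_group = "51-70 (m)", factor = "satfat_pcte",
                        mean = exposure_mean, sd = exposure_sd,
                        cf_mean = exposure_mean + delta, cf_sd = exposure_sd,
                        stringsAsFactors = FALSE)
  rrs <- data.frame(disease = "CVD", mediator = "chol", rr_per_unit = rr,
                    se_log = se_log, stringsAsFactors = FALSE)
  if (!is.null(extra_energy)) {
    moments <- rbind(moments, data.frame(
      dri_group = "51-70 (m)", factor = "energy",
      mean = extra_energy$mean, sd = extra_energy$sd,
      cf_mean = extra_energy$mean + extra_energy$delta,
      cf_sd = extra_energy$sd))
    rrs <- rbind(rrs, data.frame(disease = "CVD", mediator = "bmi",
                                 rr_per_unit = extra_energy$rr,
                                 se_log = extra_energy$se_log))
  }
  params <- structure(list(
    mediators = list(
      energy_to_weight = list(value = 0.042, se = 0),
      sodium_to_sbp = list(value = 2.0, se = 0),
      satfat_to_chol = list(value = satfat_to_chol, se = chol_se),
      sodium_salt_factor = 2.5),
    relative_risks = rrs), class = "cra_params")
  model <- list(strata = strata, moments = moments,
                heights = data.frame(dri_group = "51-70 (m)",
                                     mean_height = 1.75),
                deaths = data.frame(disease = "CVD", sex = "male",
                                    age_low = 51, age_high = 55,
                                    count = deaths_count,
                                    stringsAsFactors = FALSE),
                population = data.frame(sex = "male", age_low = 51,
                                        age_high = 55, count = 1e5),
                params = params)
  model$quadrature <- foplimpact:::cra_quadrature(model)
  class(model) <- "cra_model"
  model
}
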