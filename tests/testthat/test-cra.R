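params <- read_cra_params()

test_that("mediator pathways are linear with the stated unit conversions", {
  med <- list(energy_to_weight = list(value = 0.02),
              sodium_to_sbp = list(value = 1.0),
              satfat_to_chol = list(value = 0.05),
              sodium_salt_factor = 2.5)
  # 0.02 kg per kcal/day, -50 kcal/day, height 1.70 m: -1 / 2.89
  expect_equal(mediate_energy_to_bmi(-50, 1.70, med), -1 / 2.89,
               tolerance = 1e-9)
  expect_equal(mediate_energy_to_bmi(0, 1.70, med), 0)
  expect_equal(mediate_energy_to_bmi(-100, 1.70, med),
               2 * mediate_energy_to_bmi(-50, 1.70, med))

  # 1 mmHg per g salt, 1,000 mg sodium, 2.5 g salt per g sodium -> 2.5 mmHg
  expect_equal(mediate_sodium_to_sbp(1000, med), 2.5)
  expect_equal(mediate_sodium_to_sbp(0, med), 0)
  expect_lt(mediate_sodium_to_sbp(-500, med), 0)

  expect_equal(mediate_satfat_to_chol(-1.2, med), -0.06)
  expect_equal(mediate_satfat_to_chol(0, med), 0)
})

test_that("distribution shifts preserve spread and reject nonpositive lognormals", {
  d <- risk_factor_dist("sodium", 100, 10, "normal")
  s <- shift_distribution(d, -5)
  expect_equal(s$mean, 95)
  expect_equal(s$sd, 10)
  expect_identical(shift_distribution(d, 0), d)

  ln <- risk_factor_dist("sodium", 2729, 600, "lognormal")
  ln2 <- shift_distribution(ln, -128)
  expect_equal(ln2$mean, 2601)
  # moment-matched re-parameterisation reproduces the target mean exactly
  p <- foplimpact:::lnorm_pars(ln2$mean, ln2$sd)
  expect_equal(exp(p$mu + p$sigma^2 / 2), 2601, tolerance = 1e-9)
  expect_error(shift_distribution(ln, -3000), "nonpositive")
})

test_that("stratum mortality ratio matches closed forms and a sampling oracle", {
  # rr = 1: ratio 1 regardless of distributions
  b <- risk_factor_dist("sodium", 2729, 500, "lognormal", c(200, 12000))
  cf <- shift_distribution(b, -128)
  expect_equal(stratum_mortality_ratio(b, cf, 1, 0.005), 1)
  # cf = base: ratio 1
  expect_equal(stratum_mortality_ratio(b, b, 1.02, 0.005), 1, tolerance = 1e-12)

  # point masses: ratio = rr^(x1 - x0); rr 1.02/unit, shift -5 -> 1.02^-5
  pm <- risk_factor_dist("satfat_pcte", 10, 0, "normal")
  pm_cf <- shift_distribution(pm, -5)
  expect_equal(stratum_mortality_ratio(pm, pm_cf, 1.02, 1), 1.02^-5,
               tolerance = 1e-6)
  expect_equal(1.02^-5, 0.90573, tolerance = 1e-5)

  # quadrature vs 1e6-draw Monte Carlo on normal(0, 1), rr = 1.1
  n01 <- risk_factor_dist("satfat_pcte", 0, 1, "normal", c(-8, 8))
  theta <- log(1.1)
  quad <- foplimpact:::expected_rr(n01, theta, ref = 0, method = "adaptive")
  set.seed(99)
  mc <- mean(exp(theta * rnorm(1e6)))
  expect_equal(quad, mc, tolerance = 0.005)
  # and the untruncated normal closed form exp(theta^2 / 2)
  expect_equal(quad, exp(theta^2 / 2), tolerance = 1e-6)

  # adaptive and Gauss-Legendre paths agree
  g <- stratum_mortality_ratio(b, cf, 1.02, 0.005, method = "gauss")
  a <- stratum_mortality_ratio(b, cf, 1.02, 0.005, method = "adaptive")
  expect_equal(g, a, tolerance = 1e-6)
})

test_that("deaths averted follows the product rule and conserves totals", {
  deaths <- data.frame(disease = "CVD", sex = "male", age_low = 51,
                       age_high = 55, count = 100)
  one <- data.frame(disease = "CVD", sex = "male", age_low = 51,
                    factor = "energy", ratio = 0.9)
  res <- deaths_averted(deaths, one)
  expect_equal(res$total, 10)

  # two pathways: combined 0.95 * 0.98 = 0.931 -> averted = 6.9
  two <- rbind(one, one)
  two$factor <- c("energy", "sodium")
  two$ratio <- c(0.95, 0.98)
  res2 <- deaths_averted(deaths, two)
  expect_equal(res2$total, 100 * (1 - 0.95 * 0.98), tolerance = 1e-12)

  # all ratios 1: zero averted
  null <- one; null$ratio <- 1
  expect_equal(deaths_averted(deaths, null)$total, 0)

  # missing ratio for a stratum with deaths errors
  deaths2 <- rbind(deaths, data.frame(disease = "diabetes", sex = "male",
                                      age_low = 51, age_high = 55, count = 5))
  expect_error(deaths_averted(deaths2, one), "missing mortality ratio")
})

test_that("toy model: point estimate matches the closed form, attribution exact", {
  # satfat %TE pathway, normal exposure: ratio = exp(theta * delta) up to
  # truncation, theta = satfat_to_chol * log(rr)
  m <- make_toy_model(deaths_count = 1000, delta = -1, rr = 1.25,
                      satfat_to_chol = 0.05)
  theta <- 0.05 * log(1.25)
  expected <- 1000 * (1 - exp(theta * -1))
  res <- cra_point_estimate(m)
  expect_equal(res$total, expected, tolerance = 1e-4)
  expect_equal(sum(res$strata$averted), res$total, tolerance = 1e-9)

  # single shifted factor: attribution equals the joint total exactly
  att <- attribute_by_factor(m)
  expect_equal(att$averted[att$factor == "satfat_pcte"], res$total,
               tolerance = 1e-9)
  # factors with no counterfactual shift attribute exactly zero
  expect_equal(att$averted[att$factor != "satfat_pcte"], c(0, 0))

  # near-additivity for small shifts across two pathways
  m2 <- make_toy_model(deaths_count = 1000, delta = -0.5, rr = 1.1,
                       extra_energy = list(mean = 2000, sd = 400,
                                           delta = -30, rr = 1.03,
                                           se_log = 0))
  joint <- cra_point_estimate(m2)$total
  att2 <- attribute_by_factor(m2)
  singles <- sum(att2$averted)
  expect_lt(abs(joint - singles) / joint, 0.02)
})

test_that("full-model conservation, null scenario, and monotonicity", {
  st <- small_study()
  map <- default_food_class_map()
  lib <- scenario_library()
  tabs <- generate_stratum_tables(st$config)
  anthro <- summarize_anthropometrics(st$kept)

  cf1 <- reestimate_counterfactual(st$recalls, lib$S1, map, st$kept,
                                   st$covariates,
                                   baseline_person = st$baseline_person,
                                   lambda_grid = st$lambda_grid)
  m1 <- build_cra_model(st$baseline_person, cf1$person, st$kept, tabs,
                        anthro, params)
  r1 <- cra_point_estimate(m1)
  expect_gt(r1$total, 0)
  # conservation to 1e-9 relative
  expect_equal(sum(r1$strata$averted), r1$total, tolerance = 1e-9)
  expect_equal(sum(r1$by_sex$averted), r1$total, tolerance = 1e-9)
  expect_equal(sum(r1$by_disease$averted), r1$total, tolerance = 1e-9)
  expect_lte(r1$under_75, r1$total)
  # bound: every stratum's averted deaths below its death count
  expect_true(all(r1$strata$averted < pmax(r1$strata$count, 1)))

  # identity counterfactual: exactly zero averted
  m0 <- build_cra_model(st$baseline_person, st$baseline_person, st$kept,
                        tabs, anthro, params)
  expect_equal(cra_point_estimate(m0)$total, 0)

  # S4 dominates S1 for the modeled pathways' net effect
  cf4 <- reestimate_counterfactual(st$recalls, lib$S4, map, st$kept,
                                   st$covariates,
                                   baseline_person = st$baseline_person,
                                   lambda_grid = st$lambda_grid)
  m4 <- build_cra_model(st$baseline_person, cf4$person, st$kept, tabs,
                        anthro, params)
  expect_gte(cra_point_estimate(m4)$total, r1$total)
})

test_that("Monte Carlo intervals: degeneracy, reproducibility, delta-method oracle", {
  # all parameter SEs zero: UI collapses onto the point estimate
  m0 <- make_toy_model(se_log = 0, chol_se = 0)
  mc0 <- monte_carlo_ui(m0, n_iterations = 200, seed = 1)
  expect_equal(mc0$ui_total[1], mc0$point$total, tolerance = 1e-12)
  expect_equal(mc0$ui_total[2], mc0$point$total, tolerance = 1e-12)

  # same seed, same intervals
  m <- make_toy_model(se_log = 0.05)
  a <- monte_carlo_ui(m, n_iterations = 300, seed = 7)
  b <- monte_carlo_ui(m, n_iterations = 300, seed = 7)
  expect_identical(a$ui_total, b$ui_total)

  # delta-method oracle: averted = D (1 - exp(s * delta * log rr)),
  # log rr ~ N(log rr0, se^2); UI endpoints within 5% of the analytic ones
  D <- 1000; s <- 0.05; delta <- -1; rr0 <- 1.25; se <- 0.05
  mdm <- make_toy_model(deaths_count = D, delta = delta, rr = rr0,
                        se_log = se, satfat_to_chol = s)
  mc <- monte_carlo_ui(mdm, n_iterations = 10000, seed = 42)
  f <- function(lr) D * (1 - exp(s * delta * lr))
  grad <- -D * exp(s * delta * log(rr0)) * s * delta
  lo <- f(log(rr0)) - 1.96 * abs(grad) * se
  hi <- f(log(rr0)) + 1.96 * abs(grad) * se
  width <- hi - lo
  expect_lt(abs(mc$ui_total[1] - lo) / width, 0.05)
  expect_lt(abs(mc$ui_total[2] - hi) / width, 0.05)
})
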