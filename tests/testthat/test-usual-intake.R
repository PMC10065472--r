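test_that("sample exclusions tally in order and respect the BMI boundary", {
  # published bookkeeping: 13,919 eligible - 188 breastfeeding - 4 zero
  # consumption - 1,735 underweight/missing anthropometrics = 11,992
  n <- 13919
  roster <- data.frame(id = seq_len(n), bmi = 25, height = 1.7, weight = 72,
                       breastfeeding = FALSE, zero_consumption = FALSE)
  roster$breastfeeding[1:188] <- TRUE
  roster$zero_consumption[189:192] <- TRUE
  roster$bmi[193:1927] <- 17
  fs <- filter_sample(roster, recalls = NULL)
  expect_equal(fs$tally$removed, c(188L, 4L, 1735L))
  expect_equal(fs$tally$rule, c("breastfeeding", "zero_consumption",
                                "underweight_or_missing_anthropometrics"))
  expect_equal(nrow(fs$kept), 11992)

  # all rules disabled: identity
  off <- exclusion_rules(exclude_breastfeeding = FALSE,
                         exclude_zero_consumption = FALSE,
                         min_bmi = 1e-9, require_anthropometrics = FALSE)
  fs0 <- filter_sample(roster, recalls = NULL, rules = off)
  expect_equal(nrow(fs0$kept), n)
  expect_true(all(fs0$tally$removed == 0))

  # strict '<' at the boundary: BMI 18.5 is kept
  tri <- data.frame(id = 1:3, bmi = c(17, 18.5, 25), height = 1.7, weight = 70)
  fs1 <- filter_sample(tri, recalls = NULL)
  expect_equal(fs1$kept$id, c(2L, 3L))

  # respondent with no recall records counts as zero consumption
  two <- data.frame(id = 1:2, bmi = 25, height = 1.7, weight = 70)
  rec <- data.frame(respondent_id = 1, recall_day = 1, weekend = FALSE,
                    item_id = 1, category_code = "bread_cereal",
                    energy = 500, sodium = 800, sugars = 20, satfat = 5)
  fs2 <- filter_sample(two, rec)
  expect_equal(fs2$kept$id, 1L)
  expect_equal(fs2$tally$removed[fs2$tally$rule == "zero_consumption"], 1L)
})

test_that("TEE equation matches a hand calculation and is monotone", {
  cuts <- misreport_cutoffs()
  man <- list(sex = "male", age = 40, weight = 80, height = 1.80)
  hand <- 662 - 9.53 * 40 + 1.11 * (15.91 * 80 + 539.6 * 1.80)
  expect_equal(compute_tee(man, cuts), hand, tolerance = 1e-7)

  woman <- man; woman$sex <- "female"
  expect_false(isTRUE(all.equal(compute_tee(man, cuts),
                                compute_tee(woman, cuts))))

  heavier <- man; heavier$weight <- 90
  expect_gt(compute_tee(heavier, cuts), compute_tee(man, cuts))

  missing_h <- man; missing_h$height <- NA
  expect_error(compute_tee(missing_h, cuts), "missing anthropometrics")
})

test_that("misreporting boundaries are inclusive to plausible", {
  cuts <- misreport_cutoffs(lower = 0.7, upper = 1.42)
  expect_equal(classify_misreporting(0.7 * 2000, 2000, cuts), "plausible")
  expect_equal(classify_misreporting(1.42 * 2000, 2000, cuts), "plausible")
  expect_equal(classify_misreporting(2000, 2000, cuts), "plausible")
  expect_equal(classify_misreporting(0.5 * 2000, 2000, cuts), "under")
  expect_equal(classify_misreporting(1.5 * 2000, 2000, cuts), "over")
  expect_error(classify_misreporting(-1, 2000, cuts), "nonnegative")
})

test_that("implausible-intake filter removes planted outliers only", {
  set.seed(42)
  dt <- data.frame(respondent_id = 1:200, recall_day = 1, weekend = FALSE,
                   sodium = exp(rnorm(200, log(2500), 0.4)))
  out0 <- remove_implausible_intakes(dt, outlier_rules(), "sodium")
  expect_equal(nrow(out0$kept), 200)

  dt$sodium[7] <- 6 * median(dt$sodium)  # below the absolute cap
  out1 <- remove_implausible_intakes(dt, outlier_rules(), "sodium")
  expect_equal(out1$removed$respondent_id, 7)
  expect_equal(out1$removed$rule, "robust_z")
  # direct z computation confirms the planted point is the only |z| > 4
  lx <- log(dt$sodium)
  z <- abs(lx - median(lx)) / mad(lx)
  expect_equal(which(z > 4), 7L)

  dt$sodium[9] <- 30000
  out2 <- remove_implausible_intakes(dt, outlier_rules(), "sodium")
  expect_true(all(c("absolute_cap", "robust_z") %in% out2$removed$rule))
})

test_that("one-part model recovers lambda-1 generative parameters", {
  d <- make_lambda1_data(n = 1200, seed = 4)
  fit <- fit_one_part_model(d$day_totals, d$covariates, nutrient = "y",
                            lambda_grid = 1)
  expect_true(fit$converged)
  expect_equal(fit$sigma_u2, 4, tolerance = 0.15)
  expect_equal(fit$sigma_e2, 1, tolerance = 0.15)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  expect_lt(abs(fit$beta[["age"]] - 2), 2 * se[["age"]])
  expect_lt(abs(fit$beta[["sexmale"]] - 0.5), 2 * se[["sexmale"]])

  # no repeated measures: not identifiable
  one_day <- d$day_totals[d$day_totals$recall_day == 1, ]
  expect_error(fit_one_part_model(one_day, d$covariates, "y", 1),
               "non-identifiable")
})

test_that("degenerate within-variance yields usual intake ~ observed totals", {
  d <- make_lambda1_data(n = 300, sigma_u2 = 4, sigma_e2 = 1e-6, seed = 8)
  fit <- fit_one_part_model(d$day_totals, d$covariates, "y", lambda_grid = 1)
  expect_lt(fit$sigma_e2, 0.01)
  pu <- person_usual_intake(fit)
  day1 <- d$day_totals[d$day_totals$recall_day == 1, ]
  m <- merge(pu, day1, by = "respondent_id")
  expect_equal(m$usual, m$y, tolerance = 0.01)
})

test_that("adding a constant at lambda = 1 shifts only the intercept", {
  d <- make_lambda1_data(n = 400, seed = 6)
  f1 <- fit_one_part_model(d$day_totals, d$covariates, "y", 1)
  d2 <- d$day_totals
  d2$y <- d2$y + 10
  f2 <- fit_one_part_model(d2, d$covariates, "y", 1)
  expect_equal(f2$beta[["(Intercept)"]] - f1$beta[["(Intercept)"]], 10,
               tolerance = 1e-6)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-6)
})

test_that("back-transformation integral matches closed forms", {
  # lambda = 0: Gauss-Hermite E[exp(mu + u)] vs lognormal mean
  for (s in c(0.1, 0.3, 0.5)) {
    gh <- gh_expect(exp, mean = 1.2, sd = s, nodes = 9)
    expect_equal(gh, exp(1.2 + s^2 / 2), tolerance = 1e-3)
  }
  # lambda = 1: identity back-transform, usual = mu + u_hat (+1 for the
  # Box-Cox shift), so the stratum mean equals the mean prediction
  d <- make_lambda1_data(n = 400, seed = 12)
  fit <- fit_one_part_model(d$day_totals, d$covariates, "y", 1)
  pu <- person_usual_intake(fit)
  pp <- foplimpact:::person_predictions(fit)
  expect_equal(pu$usual, pp$mu + pp$u_hat + 1, tolerance = 1e-9)
})

test_that("BRR variance formula matches hand computation and scaling rules", {
  # theta_full = 10, replicates {9, 11, 10, 10}: variance (1+1+0+0)/4 = 0.5
  reps <- matrix(c(1, 2, 3, 4), nrow = 1)  # placeholder weights, one per col
  est <- local({
    vals <- c(9, 11, 10, 10)
    function(w) if (length(w) == 1 && w %in% 1:4) vals[w] else 10
  })
  v <- brr_variance(est, survey_weights = 99, replicate_weights = reps)
  expect_equal(v$se, sqrt(0.5), tolerance = 1e-9)
  expect_equal(v$ci95, 10 + c(-1.96, 1.96) * sqrt(0.5), tolerance = 1e-9)

  # identical replicates: zero variance
  v0 <- brr_variance(function(w) 10, 1, matrix(1, 1, 6))
  expect_equal(v0$se, 0)

  # Fay coefficient 0.5 doubles the SE for identical deviations
  v_fay <- brr_variance(est, 99, reps, fay_coef = 0.5)
  expect_equal(v_fay$se, 2 * v$se, tolerance = 1e-12)

  # failing replicates are dropped with a warning
  est_fail <- function(w) if (length(w) == 1 && w == 2) stop("boom") else 10
  expect_warning(vf <- brr_variance(est_fail, 1, reps), "dropped")
  expect_equal(vf$R_used, 3)
})

test_that("estimates are invariant to a common weight rescaling", {
  st <- small_study()
  pu <- st$baseline_person$sodium
  est1 <- estimate_usual_distribution(pu, st$kept, "sodium")
  kept2 <- st$kept
  kept2$survey_weight <- kept2$survey_weight * 2
  kept2$replicate_weights <- kept2$replicate_weights * 2
  est2 <- estimate_usual_distribution(pu, kept2, "sodium")
  expect_equal(est1$mean, est2$mean, tolerance = 1e-12)
  expect_equal(est1$se, est2$se, tolerance = 1e-12)
  expect_true(all(est1$ci_low <= est1$mean & est1$mean <= est1$ci_high))
})

test_that("anthropometric summary applies corrections and weights", {
  r <- data.frame(id = 1:2, sex = "female", age = 30, dri_group = "19-30 (f)",
                  height = c(1.60, 1.80), weight = c(55, 70),
                  self_reported_flag = FALSE,
                  survey_weight = c(1, 3))
  s <- summarize_anthropometrics(r)
  expect_equal(s$mean_height[s$dri_group == "19-30 (f)"], 1.75)

  # identity correction leaves self-reported values unchanged
  r$self_reported_flag <- TRUE
  s2 <- summarize_anthropometrics(r)
  expect_equal(s2$mean_height, s$mean_height)

  # additive height correction moves the mean by the same amount
  s3 <- summarize_anthropometrics(r, correction_factors = list(
    male = list(height_add = 0, weight_mult = 1),
    female = list(height_add = -0.02, weight_mult = 1.05)))
  expect_equal(s3$mean_height, s$mean_height - 0.02)
})
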