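# Sample construction and usual-intake estimation: exclusion rules,
# EI/TEE-based misreporting classification, implausible-intake filtering, the
# one-part (amount-only) measurement-error model (Box-Cox + person-level
# linear mixed model + back-transformation by Gauss-Hermite quadrature),
# survey-weighted stratum means and balanced-repeated-replication variance.

#' Sample exclusion rules
#'
#' @param min_age minimum age in years (default 19, adults)
#' @param exclude_breastfeeding drop breastfeeding respondents
#' @param exclude_zero_consumption drop respondents with no food reported
#' @param min_bmi minimum BMI; respondents strictly below are dropped
#'   (underweight, for whom predictive energy-expenditure equations do not
#'   apply)
#' @param require_anthropometrics drop respondents missing height or weight
#' @return an `exclusion_rules` list
#' @export
exclusion_rules <- function(min_age = 19, exclude_breastfeeding = TRUE,
                            exclude_zero_consumption = TRUE,
                            min_bmi = 18.5, require_anthropometrics = TRUE) {
  stopifnot(min_age >= 0, min_bmi > 0)
  structure(list(min_age = min_age,
                 exclude_breastfeeding = exclude_breastfeeding,
                 exclude_zero_consumption = exclude_zero_consumption,
                 min_bmi = min_bmi,
                 require_anthropometrics = require_anthropometrics),
            class = "exclusion_rules")
}

#' Apply sample exclusions in sequence
#'
#' Exclusions are applied in a fixed order -- breastfeeding, zero consumption,
#' then underweight/missing anthropometrics -- and tallied per rule, so the
#' bookkeeping `kept = eligible - sum(removed)` is reproducible. A respondent
#' with no recall records counts as a zero-consumption exclusion. BMI exactly
#' at `min_bmi` is kept (strict `<` rule).
#'
#' @param respondents roster; optional logical column `breastfeeding`
#' @param recalls item-level recall records (may be NULL if the roster has a
#'   `zero_consumption` column)
#' @param rules an [exclusion_rules()]
#' @return list with `kept` (filtered roster) and `tally` (data frame of
#'   counts per rule, in application order)
#' @export
filter_sample <- function(respondents, recalls = NULL, rules = exclusion_rules()) {
  df <- respondents
  tally <- data.frame(rule = character(0), removed = integer(0),
                      stringsAsFactors = FALSE)
  note <- function(rule, n) rbind(tally, data.frame(rule = rule, removed = n))

  drop <- rep(FALSE, nrow(df))

  if (rules$exclude_breastfeeding) {
    bf <- if ("breastfeeding" %in% names(df)) df$breastfeeding %in% TRUE else FALSE
    bf <- bf & !drop
    tally <- note("breastfeeding", sum(bf)); drop <- drop | bf
  } else tally <- note("breastfeeding", 0L)

  if (rules$exclude_zero_consumption) {
    if (!is.null(recalls)) {
      zero <- !(df$id %in% recalls$respondent_id)
    } else if ("zero_consumption" %in% names(df)) {
      zero <- df$zero_consumption %in% TRUE
    } else zero <- rep(FALSE, nrow(df))
    zero <- zero & !drop
    tally <- note("zero_consumption", sum(zero)); drop <- drop | zero
  } else tally <- note("zero_consumption", 0L)

  anth_missing <- if (rules$require_anthropometrics) {
    is.na(df$height) | is.na(df$weight)
  } else rep(FALSE, nrow(df))
  under <- (!is.na(df$bmi) & df$bmi < rules$min_bmi) | anth_missing
  under <- under & !drop
  tally <- note("underweight_or_missing_anthropometrics", sum(under))
  drop <- drop | under

  list(kept = df[!drop, , drop = FALSE], tally = tally)
}

#' Misreporting cutoffs and the TEE equation key
#'
#' Goldberg-type cutoffs on the ratio of reported energy intake (EI) to
#' predicted total energy expenditure (TEE). The defaults (0.7, 1.42) are
#' package defaults documented in the vignette, not survey-specific values.
#'
#' @param lower,upper ratio thresholds, `0 < lower < upper`; ratios at or
#'   between the bounds are classified plausible
#' @param tee_equation_id key selecting the predictive TEE equation
#'   (currently `"ier_adult"`, an Institute-of-Medicine-style adult equation)
#' @param pal_male,pal_female physical-activity coefficients (low-active)
#' @return a `misreport_cutoffs` list
#' @export
misreport_cutoffs <- function(lower = 0.7, upper = 1.42,
                              tee_equation_id = "ier_adult",
                              pal_male = 1.11, pal_female = 1.12) {
  stopifnot(lower > 0, lower < upper)
  structure(list(lower = lower, upper = upper,
                 tee_equation_id = tee_equation_id,
                 pal_male = pal_male, pal_female = pal_female),
            class = "misreport_cutoffs")
}

#' Predicted total energy expenditure (kcal/day)
#'
#' Adult predictive equation (Institute-of-Medicine style estimated energy
#' requirement at a configurable activity coefficient):
#' men `662 - 9.53 age + PA (15.91 wt + 539.6 ht)`,
#' women `354 - 6.91 age + PA (9.36 wt + 726 ht)`,
#' with age in years, weight kg, height m.
#'
#' @param respondent list/row with `sex`, `age`, `weight`, `height`
#' @param cutoffs a [misreport_cutoffs()] carrying the equation key and PA
#'   coefficients
#' @return positive TEE in kcal/day
#' @export
compute_tee <- function(respondent, cutoffs = misreport_cutoffs()) {
  if (anyNA(c(respondent$age, respondent$weight, respondent$height)))
    stop("missing anthropometrics: respondent should have been excluded upstream")
  if (cutoffs$tee_equation_id != "ier_adult")
    stop("unknown tee_equation_id: ", cutoffs$tee_equation_id)
  male <- respondent$sex == "male"
  tee <- ifelse(male,
    662 - 9.53 * respondent$age +
      cutoffs$pal_male * (15.91 * respondent$weight + 539.6 * respondent$height),
    354 - 6.91 * respondent$age +
      cutoffs$pal_female * (9.36 * respondent$weight + 726 * respondent$height))
  if (any(!is.finite(tee) | tee <= 0)) stop("non-positive TEE computed")
  tee
}

#' Classify dietary misreporting from the EI/TEE ratio
#'
#' Boundaries are inclusive to plausible: `under` strictly below `lower`,
#' `over` strictly above `upper`.
#'
#' @param mean_ei mean reported energy intake, kcal/day
#' @param tee predicted total energy expenditure, kcal/day
#' @param cutoffs a [misreport_cutoffs()]
#' @return character vector in `{under, plausible, over}`
#' @export
classify_misreporting <- function(mean_ei, tee, cutoffs = misreport_cutoffs()) {
  if (any(mean_ei < 0)) stop("energy intake must be nonnegative")
  if (any(tee <= 0)) stop("TEE must be positive")
  ratio <- mean_ei / tee
  ifelse(ratio < cutoffs$lower, "under",
         ifelse(ratio > cutoffs$upper, "over", "plausible"))
}

#' Per-nutrient implausible-intake rules
#'
#' Each nutrient gets an absolute cap and/or a robust z-score threshold on the
#' log scale (`|log x - median| / MAD > z_max`). Defaults: z 4 on the log
#' scale plus generous physiological caps.
#'
#' @param caps named list of absolute upper caps per nutrient
#' @param z_max robust z threshold (log scale); `Inf` disables
#' @return an `outlier_rules` list
#' @export
outlier_rules <- function(caps = list(energy = 10000, sodium = 20000,
                                      sugars = 800, satfat = 400),
                          z_max = 4) {
  structure(list(caps = caps, z_max = z_max), class = "outlier_rules")
}

#' Remove implausible day-level nutrient totals
#'
#' Filtering is per day-total, not per respondent: a respondent's other recall
#' days survive. Removals are logged with the rule that fired.
#'
#' @param day_totals data frame from [daily_totals()]
#' @param rules an [outlier_rules()]
#' @param nutrient column to screen
#' @return list with `kept` rows and `removed` log (row values + `rule`)
#' @export
remove_implausible_intakes <- function(day_totals, rules = outlier_rules(),
                                       nutrient = "sodium") {
  x <- day_totals[[nutrient]]
  rule <- rep(NA_character_, length(x))
  cap <- rules$caps[[nutrient]]
  if (!is.null(cap)) rule[x > cap] <- "absolute_cap"
  if (is.finite(rules$z_max)) {
    pos <- x > 0
    lx <- log(x[pos])
    md <- stats::median(lx)
    s <- stats::mad(lx)
    if (s > 0) {
      z <- abs(lx - md) / s
      hit <- which(pos)[z > rules$z_max]
      rule[hit][is.na(rule[hit])] <- "robust_z"
    }
  }
  removed <- day_totals[!is.na(rule), , drop = FALSE]
  if (nrow(removed)) removed$rule <- rule[!is.na(rule)]
  list(kept = day_totals[is.na(rule), , drop = FALSE], removed = removed)
}

#' Fit the one-part (amount-only) usual-intake model
#'
#' Box-Cox exponent chosen by profile likelihood over a grid (default 0 to 1
#' by 0.05, ties toward 1); at each grid point a linear mixed model with a
#' person random intercept is fit by maximum likelihood on the transformed
#' scale, with fixed effects for age, sex, misreporting status, weekend and
#' recall sequence. The profile criterion includes the Box-Cox Jacobian
#' `(lambda - 1) * sum(log y)` so likelihoods are comparable across the grid.
#'
#' @param day_totals day-level totals with columns `respondent_id`,
#'   `recall_day`, `weekend` and the nutrient column
#' @param covariates per-respondent data frame with `id`, `age`, `sex` and
#'   optionally `misreporting_status`
#' @param nutrient name of the amount column to model
#' @param lambda_grid Box-Cox grid; a single value fixes the exponent
#' @return a `one_part_fit` with elements `lambda`, `beta`, `sigma_u2`,
#'   `sigma_e2`, `loglik`, `converged`, the fitted `lme4` model and the
#'   modelling frame
#' @export
fit_one_part_model <- function(day_totals, covariates, nutrient = "sodium",
                               lambda_grid = seq(0, 1, by = 0.05)) {
  d <- merge(day_totals, covariates, by.x = "respondent_id", by.y = "id")
  y <- d[[nutrient]]
  if (any(y <= 0)) stop("amounts must be positive after filtering")
  if (!any(duplicated(d$respondent_id)))
    stop("non-identifiable: no respondent has repeated recall days, ",
         "between- and within-person variance cannot be separated")
  d$second_recall <- as.integer(d$recall_day == 2)
  d$weekend_num <- as.integer(d$weekend)
  has_mis <- "misreporting_status" %in% names(d) &&
    length(unique(d$misreporting_status)) > 1
  rhs <- "age + sex + weekend_num + second_recall"
  if (has_mis) rhs <- paste(rhs, "+ misreporting_status")
  slog <- sum(log(y))
  best <- NULL
  for (lam in lambda_grid) {
    d$.y <- box_cox(y, lam)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(paste(".y ~", rhs, "+ (1 | respondent_id)")),
                 data = d, REML = FALSE)))
    ll <- as.numeric(stats::logLik(fit)) + (lam - 1) * slog
    # ties broken toward 1: >= keeps the larger lambda when equal
    if (is.null(best) || ll >= best$ll - 1e-9) best <- list(lam = lam, ll = ll, fit = fit)
  }
  fit <- best$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "respondent_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(lambda = best$lam, beta = lme4::fixef(fit),
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 loglik = best$ll, converged = conv,
                 model = fit, frame = d, nutrient = nutrient,
                 formula_rhs = rhs),
            class = "one_part_fit")
}

# Person-level conditional mean and variance of the random intercept, and the
# linear predictor at reference covariate values (weekend at its design share,
# first recall, observed age/sex/misreporting status).
person_predictions <- function(fit, weekend_share = 2 / 7) {
  d <- fit$frame
  ids <- unique(d$respondent_id)
  per <- d[!duplicated(d$respondent_id), , drop = FALSE]
  per <- per[match(ids, per$respondent_id), , drop = FALSE]
  per$weekend_num <- weekend_share
  per$second_recall <- 0L
  X <- stats::model.matrix(stats::as.formula(paste("~", fit$formula_rhs)), per)
  keep <- intersect(colnames(X), names(fit$beta))  # rank-deficient fits drop terms
  mu <- drop(X[, keep, drop = FALSE] %*% fit$beta[keep])
  re <- lme4::ranef(fit$model, condVar = TRUE)$respondent_id
  u_hat <- re[as.character(ids), 1]
  pv <- drop(attr(re, "postVar"))[match(as.character(ids), rownames(re))]
  data.frame(respondent_id = ids, mu = mu, u_hat = u_hat, u_var = pv)
}

#' Person-level usual intakes from a fitted one-part model
#'
#' For each respondent the usual intake is the expectation of the
#' back-transformed transformed-scale value over the conditional distribution
#' of the person random effect, `u ~ N(u_hat, v_i)`, integrated by
#' Gauss-Hermite quadrature (default 9 nodes), with the within-person-variance
#' adjustment of [back_transform_mean()] applied inside the integrand. At
#' `lambda = 1` this reduces to `mu_i + u_hat_i` (identity scale); at
#' `lambda = 0` to the lognormal mean.
#'
#' @param fit a `one_part_fit`
#' @param weekend_share reference weekend covariate value (default 2/7)
#' @param nodes Gauss-Hermite node count
#' @return data frame `respondent_id`, `usual`
#' @export
person_usual_intake <- function(fit, weekend_share = 2 / 7, nodes = 9) {
  pp <- person_predictions(fit, weekend_share)
  lam <- fit$lambda
  se2 <- fit$sigma_e2
  usual <- gh_expect_many(function(t) back_transform_mean(t, lam, se2),
                          pp$mu + pp$u_hat, sqrt(pmax(pp$u_var, 0)),
                          nodes = nodes)
  data.frame(respondent_id = pp$respondent_id, usual = usual)
}

#' Survey-weighted usual-intake estimates by stratum, with BRR intervals
#'
#' Aggregates person-level usual intakes to survey-weighted means for all
#' adults and each DRI age-sex group, with standard errors and 95% normal
#' intervals from balanced repeated replication over the replicate weights
#' (the weighted-mean aggregation is re-run per replicate).
#'
#' @param person_usual data frame from [person_usual_intake()] (or any
#'   `respondent_id`/`usual` pairing, e.g. counterfactual energy)
#' @param respondents roster with `id`, `dri_group`, `survey_weight` and a
#'   `replicate_weights` matrix column (optional; omit for SE = NA)
#' @param nutrient label recorded on the output
#' @param diet_label baseline or scenario name
#' @param fay_coef Fay coefficient used when the replicate weights were built
#' @return data frame of `usual_intake_estimate` rows: stratum, nutrient,
#'   diet_label, mean, se, ci_low, ci_high
#' @export
estimate_usual_distribution <- function(person_usual, respondents,
                                        nutrient, diet_label = "baseline",
                                        fay_coef = 0) {
  m <- merge(person_usual, respondents, by.x = "respondent_id", by.y = "id")
  strata <- c("all adults", DRI_GROUPS)
  has_reps <- "replicate_weights" %in% names(respondents)
  rw <- if (has_reps) m$replicate_weights else NULL
  out <- lapply(strata, function(s) {
    sel <- if (s == "all adults") rep(TRUE, nrow(m)) else m$dri_group == s
    if (!any(sel)) return(NULL)
    x <- m$usual[sel]
    w <- m$survey_weight[sel]
    est <- wmean(x, w)
    if (has_reps) {
      v <- brr_variance(function(wt) wmean(x, wt), w,
                        rw[sel, , drop = FALSE], fay_coef)
      se <- v$se; ci <- v$ci95
    } else {
      se <- NA_real_; ci <- c(NA_real_, NA_real_)
    }
    data.frame(stratum = s, nutrient = nutrient, diet_label = diet_label,
               mean = est, se = se, ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Balanced repeated replication variance
#'
#' `variance = 1 / (R (1 - fay)^2) * sum_r (theta_r - theta_full)^2`, where
#' `theta_r` re-runs the estimator under replicate weight set `r` (full
#' re-estimation, not a plug-in). Replicates on which the estimator fails are
#' dropped with a warning and `R` adjusted.
#'
#' @param point_estimator function of a weight vector returning a scalar
#' @param survey_weights full-sample weights
#' @param replicate_weights matrix, one column per replicate
#' @param fay_coef Fay coefficient in `[0, 1)`
#' @return list with `estimate`, `se`, `ci95`, `R_used`
#' @export
brr_variance <- function(point_estimator, survey_weights, replicate_weights,
                         fay_coef = 0) {
  R <- ncol(replicate_weights)
  if (R < 2) stop("need at least 2 replicate weight sets")
  theta_full <- point_estimator(survey_weights)
  theta_r <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    theta_r[r] <- tryCatch(point_estimator(replicate_weights[, r]),
                           error = function(e) NA_real_)
  }
  failed <- !is.finite(theta_r)
  if (any(failed)) {
    warning(sum(failed), " replicate(s) failed and were dropped")
    theta_r <- theta_r[!failed]
  }
  R_used <- length(theta_r)
  v <- sum((theta_r - theta_full)^2) / (R_used * (1 - fay_coef)^2)
  se <- sqrt(v)
  list(estimate = theta_full, se = se,
       ci95 = c(theta_full - 1.96 * se, theta_full + 1.96 * se),
       R_used = R_used)
}

#' Survey-weighted anthropometric summary by DRI group
#'
#' Self-reported heights and weights are adjusted by the supplied correction
#' factors (additive for height in m, multiplicative for weight) before
#' averaging; measured values (rows with `self_reported_flag = FALSE`) are
#' used as-is. Means carry BRR confidence intervals when replicate weights are
#' present.
#'
#' @param respondents roster with anthropometrics and weights
#' @param correction_factors list with per-sex `height_add` and `weight_mult`
#' @param fay_coef Fay coefficient for the replicate weights
#' @return data frame per DRI group: mean_bmi, mean_height with CIs
#' @export
summarize_anthropometrics <- function(respondents,
                                      correction_factors = list(
                                        male = list(height_add = 0, weight_mult = 1),
                                        female = list(height_add = 0, weight_mult = 1)),
                                      fay_coef = 0) {
  df <- respondents
  for (s in c("male", "female")) {
    cf <- correction_factors[[s]]
    sel <- df$sex == s & df$self_reported_flag
    df$height[sel] <- df$height[sel] + cf$height_add
    df$weight[sel] <- df$weight[sel] * cf$weight_mult
  }
  df$bmi_used <- df$weight / df$height^2
  has_reps <- "replicate_weights" %in% names(df)
  out <- lapply(DRI_GROUPS, function(g) {
    sel <- df$dri_group == g
    if (!any(sel)) return(NULL)
    w <- df$survey_weight[sel]
    row <- data.frame(dri_group = g,
                      mean_bmi = wmean(df$bmi_used[sel], w),
                      mean_height = wmean(df$height[sel], w))
    if (has_reps) {
      rw <- df$replicate_weights[sel, , drop = FALSE]
      vb <- brr_variance(function(wt) wmean(df$bmi_used[sel], wt), w, rw, fay_coef)
      vh <- brr_variance(function(wt) wmean(df$height[sel], wt), w, rw, fay_coef)
      row$bmi_ci_low <- vb$ci95[1]; row$bmi_ci_high <- vb$ci95[2]
      row$height_ci_low <- vh$ci95[1]; row$height_ci_high <- vh$ci95[2]
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
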