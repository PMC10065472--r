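# Comparative risk assessment: baseline -> counterfactual changes in energy,
# sodium and saturated-fat (%TE) intake are mediated through BMI, systolic
# blood pressure and total cholesterol, and converted into diet-related NCD
# deaths averted or delayed per disease x sex x 5-year age band, with
# per-risk-factor attribution and Monte Carlo uncertainty intervals.

CRA_FACTORS <- c("energy", "sodium", "satfat_pcte")
CRA_DISEASES <- c("CVD", "diabetes", "cancer", "chronic renal failure",
                  "liver disease")

#' Read CRA epidemiological parameters from a YAML config
#'
#' The shipped default (`inst/extdata/cra_params.yaml`) holds illustrative
#' literature-style values for the mediator coefficients (steady-state weight
#' change per kcal/day, blood-pressure response per g salt, cholesterol
#' response per %TE saturated fat) and log-linear relative risks per mediator
#' unit with lognormal uncertainty. All values are editable configuration --
#' users substituting their own meta-analytic estimates simply edit the file.
#'
#' @param path YAML file; default the installed configuration
#' @return a `cra_params` list with `mediators` and `relative_risks`
#' @export
read_cra_params <- function(path = system.file("extdata", "cra_params.yaml",
                                               package = "foplimpact")) {
  raw <- yaml::read_yaml(path)
  rr <- do.call(rbind, lapply(raw$relative_risks, as.data.frame))
  med <- raw$mediators
  structure(list(mediators = med, relative_risks = rr,
                 exposure_forms = raw$exposure_forms),
            class = "cra_params")
}

#' Mediate an energy-intake change into a BMI change
#'
#' `delta_bmi = energy_to_weight * delta_kcal / height^2`, where
#' `energy_to_weight` is the steady-state body-weight change (kg) per unit
#' change in daily energy intake (kcal/day).
#'
#' @param delta_kcal change in energy intake, kcal/day (sign preserved)
#' @param mean_height stratum mean height, m
#' @param params `mediators` list from [read_cra_params()]
#' @return change in BMI, kg/m^2
#' @export
mediate_energy_to_bmi <- function(delta_kcal, mean_height, params) {
  stopifnot(all(mean_height > 0))
  params$energy_to_weight$value * delta_kcal / mean_height^2
}

#' Mediate a sodium-intake change into a systolic blood-pressure change
#'
#' Sodium (mg/day) is converted to salt (g/day) via `sodium_salt_factor`
#' (2.5 g salt per g sodium) and multiplied by the blood-pressure slope
#' (mmHg per g salt). An optional age-dependent slope table
#' (`age_slopes`: rows of `age_low`, `multiplier`) scales the slope.
#'
#' @param delta_sodium change in sodium intake, mg/day
#' @param params `mediators` list
#' @param age stratum age (lower bound of band), for the optional slope table
#' @return change in SBP, mmHg
#' @export
mediate_sodium_to_sbp <- function(delta_sodium, params, age = NULL) {
  slope <- params$sodium_to_sbp$value
  if (!is.null(params$sodium_to_sbp$age_slopes) && !is.null(age)) {
    tab <- params$sodium_to_sbp$age_slopes
    idx <- findInterval(age, tab$age_low)
    if (any(idx == 0)) stop("no blood-pressure slope defined for age ", min(age))
    slope <- slope * tab$multiplier[idx]
  }
  slope * (delta_sodium / 1000) * params$sodium_salt_factor
}

#' Mediate a saturated-fat (%TE) change into a total-cholesterol change
#'
#' @param delta_satfat_pcte change in saturated fat as % of total energy
#' @param params `mediators` list
#' @return change in total cholesterol, mmol/L
#' @export
mediate_satfat_to_chol <- function(delta_satfat_pcte, params) {
  params$satfat_to_chol$value * delta_satfat_pcte
}

#' Risk-factor exposure distribution for one stratum
#'
#' @param factor one of energy, sodium, satfat_pcte
#' @param mean,sd distribution moments on the exposure scale
#' @param form `"normal"` or `"lognormal"`
#' @param trunc length-2 truncation bounds
#' @return a `risk_factor_dist`
#' @export
risk_factor_dist <- function(factor, mean, sd,
                             form = c("normal", "lognormal"),
                             trunc = c(-Inf, Inf)) {
  form <- match.arg(form)
  stopifnot(sd >= 0, trunc[1] < trunc[2])
  if (form == "lognormal" && mean <= 0)
    stop("lognormal distribution requires a positive mean")
  structure(list(factor = factor, mean = mean, sd = sd, form = form,
                 trunc = trunc), class = "risk_factor_dist")
}

#' Shift a risk-factor distribution to a new mean
#'
#' Location-shift convention: the mean moves by `delta_mean`; spread, form and
#' truncation bounds are preserved. Lognormal distributions are re-expressed
#' by moment matching to the shifted mean with the original variance.
#'
#' @param dist a [risk_factor_dist()]
#' @param delta_mean additive change in the mean
#' @return shifted [risk_factor_dist()]
#' @export
shift_distribution <- function(dist, delta_mean) {
  new_mean <- dist$mean + delta_mean
  if (dist$form == "lognormal" && new_mean <= 0)
    stop("shift would take a lognormal distribution to a nonpositive mean")
  out <- dist
  out$mean <- new_mean
  out
}

# lognormal (mu, sigma) from mean m and sd s by moment matching
lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

# E[ rr^((x - ref) * slope) ] over the (truncated) exposure distribution.
# theta = slope * log(rr) is the log-RR per exposure unit.
expected_rr <- function(dist, theta, ref,
                        method = c("adaptive", "gauss"), n_nodes = 60) {
  method <- match.arg(method)
  if (theta == 0) return(1)
  if (dist$sd == 0) return(exp(theta * (dist$mean - ref)))
  if (dist$form == "normal") {
    dens <- function(x) stats::dnorm(x, dist$mean, dist$sd)
    lo <- max(dist$trunc[1], dist$mean - 10 * dist$sd)
    hi <- min(dist$trunc[2], dist$mean + 10 * dist$sd)
  } else {
    p <- lnorm_pars(dist$mean, dist$sd)
    dens <- function(x) stats::dlnorm(x, p$mu, p$sigma)
    lo <- max(dist$trunc[1], stats::qlnorm(1e-10, p$mu, p$sigma))
    hi <- min(dist$trunc[2], stats::qlnorm(1 - 1e-10, p$mu, p$sigma))
  }
  f <- function(x) exp(theta * (x - ref)) * dens(x)
  if (method == "adaptive") {
    num <- stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 0)$value
    den <- stats::integrate(dens, lo, hi, rel.tol = 1e-9, abs.tol = 0)$value
  } else {
    gl <- pracma::gaussLegendre(n_nodes, lo, hi)
    num <- sum(gl$w * f(gl$x))
    den <- sum(gl$w * dens(gl$x))
  }
  if (!is.finite(num) || !is.finite(den) || den <= 0)
    stop("non-finite expectation integral")
  num / den
}

#' Stratum mortality ratio for one risk-factor pathway
#'
#' `ratio = E_cf[RR(x)] / E_base[RR(x)]` with
#' `RR(x) = rr_per_unit^((x - ref) * mediator_slope)`, expectations taken by
#' adaptive numerical integration over the (truncated) baseline and
#' counterfactual exposure distributions. `ref` defaults to the baseline mean
#' (it cancels in the ratio up to distributional shape).
#'
#' @param base,cf baseline and counterfactual [risk_factor_dist()]s
#' @param rr_per_unit log-linear relative risk per mediator unit
#' @param mediator_slope mediator units per exposure unit
#' @param ref reference exposure level
#' @param method `"adaptive"` (default) or `"gauss"` (fixed Gauss-Legendre,
#'   used inside the Monte Carlo loop; agrees with adaptive to ~1e-8)
#' @return positive mortality ratio
#' @export
stratum_mortality_ratio <- function(base, cf, rr_per_unit, mediator_slope,
                                    ref = base$mean,
                                    method = c("adaptive", "gauss")) {
  method <- match.arg(method)
  if (base$factor != cf$factor) stop("base and cf must describe the same factor")
  if (rr_per_unit <= 0) stop("rr_per_unit must be positive")
  theta <- mediator_slope * log(rr_per_unit)
  r <- expected_rr(cf, theta, ref, method) / expected_rr(base, theta, ref, method)
  if (!is.finite(r) || r <= 0) stop("mortality ratio is not finite and positive")
  r
}

#' Deaths averted or delayed from stratum mortality ratios
#'
#' `averted(disease, stratum) = deaths(disease, stratum) * (1 - prod_f ratio_f)`
#' over that disease's risk-factor pathways, then aggregated by summation.
#' The under-75 subtotal sums age bands entirely below 75.
#'
#' @param deaths mortality table (disease, sex, age_low, age_high, count)
#' @param ratios data frame (disease, sex, age_low, factor, ratio)
#' @return list: `strata` (per disease x sex x band with combined ratio and
#'   averted deaths), `total`, `by_sex`, `by_disease`, `under_75`
#' @export
deaths_averted <- function(deaths, ratios) {
  key <- function(d) paste(d$disease, d$sex, d$age_low)
  combined <- stats::aggregate(ratio ~ disease + sex + age_low, data = ratios,
                               FUN = prod)
  m <- merge(deaths, combined, by = c("disease", "sex", "age_low"),
             all.x = TRUE)
  need <- m$count > 0 & is.na(m$ratio)
  if (any(need))
    stop("missing mortality ratio for stratum/strata: ",
         paste(unique(key(m[need, ])), collapse = "; "))
  m$ratio[is.na(m$ratio)] <- 1
  m$averted <- m$count * (1 - m$ratio)
  total <- sum(m$averted)
  by_sex <- stats::aggregate(averted ~ sex, data = m, FUN = sum)
  by_disease <- stats::aggregate(averted ~ disease, data = m, FUN = sum)
  under75 <- sum(m$averted[m$age_high < 75])
  list(strata = m[order(m$disease, m$sex, m$age_low), ],
       total = total, by_sex = by_sex, by_disease = by_disease,
       under_75 = under75)
}

#' Assemble a CRA model from pipeline outputs
#'
#' Bridges DRI-group intake estimates to sex x 5-year mortality strata (each
#' band takes the estimate of the DRI group containing its midpoint),
#' computes per-stratum exposure distributions (lognormal for energy and
#' sodium, truncated normal for saturated-fat %TE), counterfactual mean
#' shifts, and the factor -> mediator slopes.
#'
#' @param baseline_person,cf_person per-nutrient person-level usual intakes
#'   (lists of data frames, as from [person_usual_by_nutrient()])
#' @param respondents roster with survey weights and DRI groups
#' @param stratum_tables list from [generate_stratum_tables()] (or user CSVs)
#' @param anthropometrics output of [summarize_anthropometrics()]
#' @param params a `cra_params` from [read_cra_params()]
#' @return a `cra_model` ready for [cra_point_estimate()] /
#'   [monte_carlo_ui()]
#' @export
build_cra_model <- function(baseline_person, cf_person, respondents,
                            stratum_tables, anthropometrics,
                            params = read_cra_params()) {
  bands <- unique(stratum_tables$population[c("age_low", "age_high")])
  strata <- merge(data.frame(sex = c("male", "female")), bands)
  strata$mid <- (strata$age_low + pmin(strata$age_high, 95)) / 2
  strata$dri_group <- vapply(seq_len(nrow(strata)), function(i) {
    g <- vapply(DRI_GROUPS, function(gr) {
      r <- dri_age_range(gr)
      dri_sex(gr) == strata$sex[i] && strata$mid[i] >= r[1] &&
        (strata$mid[i] <= r[2] || r[1] == 71)
    }, logical(1))
    DRI_GROUPS[which(g)[1]]
  }, character(1))

  # DRI-group weighted moments per factor, baseline and counterfactual
  grp_moments <- function(person, factor) {
    m <- merge(person, respondents, by.x = "respondent_id", by.y = "id")
    do.call(rbind, lapply(DRI_GROUPS, function(g) {
      sel <- m$dri_group == g
      data.frame(dri_group = g, factor = factor,
                 mean = wmean(m$usual[sel], m$survey_weight[sel]),
                 sd = wsd(m$usual[sel], m$survey_weight[sel]))
    }))
  }
  base_mom <- do.call(rbind, lapply(CRA_FACTORS, function(f)
    grp_moments(baseline_person[[f]], f)))
  cf_mom <- do.call(rbind, lapply(CRA_FACTORS, function(f) {
    mm <- grp_moments(cf_person[[f]], f)
    names(mm)[3:4] <- c("cf_mean", "cf_sd")
    mm
  }))
  mom <- merge(base_mom, cf_mom, by = c("dri_group", "factor"))

  heights <- anthropometrics[c("dri_group", "mean_height")]
  model <- list(strata = strata, moments = mom, heights = heights,
                deaths = stratum_tables$deaths,
                population = stratum_tables$population,
                params = params)
  model$quadrature <- cra_quadrature(model)
  class(model) <- "cra_model"
  model
}

# Physiological truncation bounds per factor: the log-linear RR is
# exponential in the exposure, so expectations over an unbounded lognormal
# diverge; bounds keep the integrals finite and the implied risk range
# plausible.
CRA_FORMS <- list(energy = "lognormal", sodium = "lognormal",
                  satfat_pcte = "normal")
CRA_TRUNC <- list(energy = c(500, 6000), sodium = c(200, 12000),
                  satfat_pcte = c(0, 40))
CRA_MEDIATOR_OF <- c(energy = "bmi", sodium = "sbp", satfat_pcte = "chol")

# Precompute Gauss-Legendre nodes and normalized density weights for the
# baseline and counterfactual exposure distribution of every DRI group x
# factor. Distributions do not change across Monte Carlo iterations (only the
# RR exponent does), so ratios reduce to two weighted sums per evaluation.
cra_quadrature <- function(model, n_nodes = 60) {
  mom <- model$moments
  cache <- list()
  for (i in seq_len(nrow(mom))) {
    f <- mom$factor[i]
    if (!is.finite(mom$mean[i])) next
    base <- risk_factor_dist(f, mom$mean[i], mom$sd[i],
                             CRA_FORMS[[f]], CRA_TRUNC[[f]])
    cf <- shift_distribution(base, mom$cf_mean[i] - mom$mean[i])
    nodes <- function(d) {
      if (d$sd == 0) return(list(x = d$mean, w = 1))
      if (d$form == "normal") {
        dens <- function(x) stats::dnorm(x, d$mean, d$sd)
        lo <- max(d$trunc[1], d$mean - 10 * d$sd)
        hi <- min(d$trunc[2], d$mean + 10 * d$sd)
      } else {
        p <- lnorm_pars(d$mean, d$sd)
        dens <- function(x) stats::dlnorm(x, p$mu, p$sigma)
        lo <- max(d$trunc[1], stats::qlnorm(1e-10, p$mu, p$sigma))
        hi <- min(d$trunc[2], stats::qlnorm(1 - 1e-10, p$mu, p$sigma))
      }
      gl <- pracma::gaussLegendre(n_nodes, lo, hi)
      w <- gl$w * dens(gl$x)
      list(x = gl$x, w = w / sum(w))
    }
    cache[[paste(mom$dri_group[i], f)]] <-
      list(base = nodes(base), cf = nodes(cf), ref = base$mean,
           delta = mom$cf_mean[i] - mom$mean[i])
  }
  cache
}

# Per-(disease, stratum, factor) mortality ratios at given parameter values.
# `active` restricts which factors' shifts are applied (others at baseline).
# method = "gauss" uses the cached quadrature; "adaptive" re-integrates with
# stats::integrate (the oracle-tested path).
cra_ratios <- function(model, med = model$params$mediators,
                       rr_tab = model$params$relative_risks,
                       active = CRA_FACTORS, method = "gauss") {
  st <- model$strata
  mom <- model$moments
  heights <- model$heights
  quad <- model$quadrature
  age_dependent_sodium <- !is.null(med$sodium_to_sbp$age_slopes)
  out_disease <- character(0); out_sex <- character(0)
  out_age <- numeric(0); out_factor <- character(0); out_ratio <- numeric(0)
  for (f in CRA_FACTORS) {
    dis_rows <- rr_tab[rr_tab$mediator == CRA_MEDIATOR_OF[[f]], ]
    if (nrow(dis_rows) == 0) next
    log_rr <- log(dis_rows$rr_per_unit)
    for (g in unique(st$dri_group)) {
      mm <- mom[mom$dri_group == g & mom$factor == f, ]
      if (nrow(mm) == 0 || !is.finite(mm$mean)) next
      bands <- st[st$dri_group == g, ]
      delta <- if (f %in% active) mm$cf_mean - mm$mean else 0
      h <- heights$mean_height[heights$dri_group == g]
      # slope is constant within a DRI group unless the sodium pathway uses an
      # age-dependent slope table, in which case it varies by band
      ages <- if (f == "sodium" && age_dependent_sodium) bands$age_low else
        bands$age_low[1]
      for (a in unique(ages)) {
        slope <- switch(f,
          energy = mediate_energy_to_bmi(1, h, med),
          sodium = mediate_sodium_to_sbp(1, med, age = a),
          satfat_pcte = mediate_satfat_to_chol(1, med))
        if (delta == 0) {
          ratio <- rep(1, nrow(dis_rows))
        } else if (method == "gauss") {
          qc <- quad[[paste(g, f)]]
          theta <- slope * log_rr
          num <- colSums(qc$cf$w * exp(outer(qc$cf$x - qc$ref, theta)))
          den <- colSums(qc$base$w * exp(outer(qc$base$x - qc$ref, theta)))
          ratio <- num / den
        } else {
          base <- risk_factor_dist(f, mm$mean, mm$sd,
                                   CRA_FORMS[[f]], CRA_TRUNC[[f]])
          cfd <- shift_distribution(base, delta)
          ratio <- vapply(dis_rows$rr_per_unit, function(rr)
            stratum_mortality_ratio(base, cfd, rr, slope,
                                    method = "adaptive"), numeric(1))
        }
        sel <- if (length(ages) > 1) bands$age_low == a else rep(TRUE, nrow(bands))
        nb <- sum(sel)
        out_disease <- c(out_disease, rep(dis_rows$disease, nb))
        out_sex <- c(out_sex, rep(bands$sex[sel], each = nrow(dis_rows)))
        out_age <- c(out_age, rep(bands$age_low[sel], each = nrow(dis_rows)))
        out_factor <- c(out_factor, rep(f, nb * nrow(dis_rows)))
        out_ratio <- c(out_ratio, rep(ratio, nb))
      }
    }
  }
  data.frame(disease = out_disease, sex = out_sex, age_low = out_age,
             factor = out_factor, ratio = out_ratio, stringsAsFactors = FALSE)
}

#' CRA point estimate at central parameter values
#'
#' @param model a [build_cra_model()] result
#' @param active factors whose counterfactual shifts are applied
#' @param method integration method passed to the ratio computation
#' @return a [deaths_averted()] result
#' @export
cra_point_estimate <- function(model, active = CRA_FACTORS,
                               method = "adaptive") {
  ratios <- cra_ratios(model, active = active, method = method)
  deaths_averted(model$deaths, ratios)
}

#' Per-risk-factor attribution of deaths averted
#'
#' Each factor's attribution re-runs the model with only that factor's
#' counterfactual shift applied (the others held at baseline); percentages
#' are reported against the joint total. Single-factor runs need not sum to
#' the joint total; the interaction residual is returned.
#'
#' @param model a `cra_model`
#' @return data frame (factor, averted, pct_of_joint) plus attributes
#'   `joint_total` and `interaction_residual`
#' @export
attribute_by_factor <- function(model) {
  joint <- cra_point_estimate(model)$total
  rows <- do.call(rbind, lapply(CRA_FACTORS, function(f) {
    data.frame(factor = f,
               averted = cra_point_estimate(model, active = f)$total)
  }))
  rows$pct_of_joint <- if (joint != 0) 100 * rows$averted / joint else 0
  attr(rows, "joint_total") <- joint
  attr(rows, "interaction_residual") <- joint - sum(rows$averted)
  rows
}

#' Monte Carlo uncertainty intervals for the CRA
#'
#' Per iteration the uncertain parameters are redrawn -- relative risks
#' lognormal around their central value, mediator coefficients normal -- and
#' deaths averted recomputed. Uncertainty intervals are empirical 2.5th/97.5th
#' percentiles (linear interpolation between order statistics). The point
#' estimate is computed at central parameter values, not the Monte Carlo mean.
#'
#' @param model a `cra_model`
#' @param n_iterations Monte Carlo iterations (10,000 for production runs;
#'   a warning below 100)
#' @param seed integer seed; same seed reproduces identical intervals
#' @return list: `point` ([deaths_averted()] at central values), `ui_total`,
#'   `ui_by_sex`, `ui_by_disease`, `ui_under_75`, `n_iterations`, `seed`
#' @export
monte_carlo_ui <- function(model, n_iterations = 10000, seed = 1L) {
  if (n_iterations < 100) warning("fewer than 100 Monte Carlo iterations")
  point <- cra_point_estimate(model, method = "adaptive")
  med0 <- model$params$mediators
  rr0 <- model$params$relative_risks
  set.seed(as.integer(seed))
  draw_med <- function() {
    m <- med0
    for (nm in c("energy_to_weight", "sodium_to_sbp", "satfat_to_chol")) {
      se <- m[[nm]]$se %||% 0
      m[[nm]]$value <- stats::rnorm(1, med0[[nm]]$value, se)
    }
    m
  }
  sexes <- sort(unique(model$deaths$sex))
  diseases <- sort(unique(model$deaths$disease))
  tot <- numeric(n_iterations)
  bysex <- matrix(NA_real_, n_iterations, length(sexes),
                  dimnames = list(NULL, sexes))
  bydis <- matrix(NA_real_, n_iterations, length(diseases),
                  dimnames = list(NULL, diseases))
  u75 <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    med <- draw_med()
    rr <- rr0
    se <- if ("se_log" %in% names(rr)) rr$se_log else 0
    rr$rr_per_unit <- exp(stats::rnorm(nrow(rr), log(rr0$rr_per_unit), se))
    res <- tryCatch({
      ratios <- cra_ratios(model, med = med, rr_tab = rr, method = "gauss")
      deaths_averted(model$deaths, ratios)
    }, error = function(e) NULL)
    if (is.null(res)) {  # resample once, then fail
      med <- draw_med()
      rr$rr_per_unit <- exp(stats::rnorm(nrow(rr), log(rr0$rr_per_unit), se))
      ratios <- cra_ratios(model, med = med, rr_tab = rr, method = "gauss")
      res <- deaths_averted(model$deaths, ratios)
    }
    tot[it] <- res$total
    bysex[it, res$by_sex$sex] <- res$by_sex$averted
    bydis[it, res$by_disease$disease] <- res$by_disease$averted
    u75[it] <- res$under_75
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    na.rm = TRUE)
  list(point = point,
       ui_total = qs(tot),
       ui_by_sex = apply(bysex, 2, qs),
       ui_by_disease = apply(bydis, 2, qs),
       ui_under_75 = qs(u75),
       n_iterations = n_iterations, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
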