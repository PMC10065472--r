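# Synthetic survey generator: respondents with survey + BRR replicate weights,
# two-day item-level 24-h recalls with a known between/within-person variance
# structure, and population/mortality stratum tables. Everything downstream is
# testable against the generative parameters set here.

DRI_GROUPS <- c("19-30 (m)", "31-50 (m)", "51-70 (m)", "71+ (m)",
                "19-30 (f)", "31-50 (f)", "51-70 (f)", "71+ (f)")
NUTRIENTS <- c("energy", "sodium", "sugars", "satfat")

dri_age_range <- function(group) {
  band <- sub(" .*", "", group)
  if (band == "71+") c(71, 90) else as.numeric(strsplit(band, "-")[[1]])
}

dri_sex <- function(group) ifelse(grepl("\\(m\\)", group), "male", "female")

#' Configuration for the synthetic survey generator
#'
#' Bundles every generative parameter: roster size, the fraction receiving a
#' second telephone recall (default 0.35, the design fraction of the survey
#' being emulated), DRI age-sex group weights, per-nutrient log-scale means
#' and variance components, weekend and recall-sequence effects, food-category
#' nutrient densities, and the replicate-weight design.
#'
#' Daily nutrient totals are generated on the log scale:
#' `log T = group mean + person effect + weekend effect + sequence effect + day error`,
#' which guarantees positivity and exercises the Box-Cox estimator under mild
#' transformation misspecification.
#'
#' @param n_respondents roster size
#' @param second_recall_fraction proportion sampled for a day-2 recall
#' @param dri_group_weights length-8 proportions over DRI age-sex groups
#' @param nutrients named list per nutrient with elements `mean_log` (length-8,
#'   ordered as `DRI_GROUPS`), `between_sd`, `within_sd`, `weekend_effect`,
#'   `sequence_effect` (all log-scale)
#' @param categories data frame of food categories: `category_code`,
#'   `food_class`, `prob` (sampling probability), and per-nutrient relative
#'   density columns `energy`, `sodium`, `sugars`, `satfat`
#' @param mean_items_per_day Poisson mean for items per recall day (min 1)
#' @param weekend_share probability a recall day falls on a weekend (2/7)
#' @param n_brr_replicates number of replicate weight sets (even, >= 2)
#' @param fay_coef Fay coefficient for replicate construction (0 = classic BRR)
#' @param rng_seed integer seed
#' @return a `synth_config` list, validated
#' @export
synth_config <- function(n_respondents = 2000,
                         second_recall_fraction = 0.35,
                         dri_group_weights = rep(1 / 8, 8),
                         nutrients = default_nutrient_params(),
                         categories = default_categories(),
                         mean_items_per_day = 8,
                         weekend_share = 2 / 7,
                         n_brr_replicates = 500,
                         fay_coef = 0,
                         rng_seed = 1L) {
  cfg <- list(n_respondents = n_respondents,
              second_recall_fraction = second_recall_fraction,
              dri_group_weights = dri_group_weights,
              nutrients = nutrients,
              categories = categories,
              mean_items_per_day = mean_items_per_day,
              weekend_share = weekend_share,
              n_brr_replicates = as.integer(n_brr_replicates),
              fay_coef = fay_coef,
              rng_seed = as.integer(rng_seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_respondents < 0) stop("configuration error: n_respondents must be >= 0")
  if (cfg$second_recall_fraction < 0 || cfg$second_recall_fraction > 1)
    stop("configuration error: second_recall_fraction must be in [0, 1]")
  if (length(cfg$dri_group_weights) != 8 ||
      abs(sum(cfg$dri_group_weights) - 1) > 1e-8 ||
      any(cfg$dri_group_weights < 0))
    stop("configuration error: dri_group_weights must be 8 nonnegative values summing to 1")
  for (nm in NUTRIENTS) {
    p <- cfg$nutrients[[nm]]
    if (is.null(p)) stop("configuration error: missing nutrient params for ", nm)
    if (p$between_sd < 0 || p$within_sd < 0)
      stop("configuration error: SDs must be >= 0 for ", nm)
    if (length(p$mean_log) != 8)
      stop("configuration error: mean_log must have 8 entries for ", nm)
  }
  if (cfg$n_brr_replicates < 2 || cfg$n_brr_replicates %% 2 != 0)
    stop("configuration error: n_brr_replicates must be even and >= 2")
  if (cfg$fay_coef < 0 || cfg$fay_coef >= 1)
    stop("configuration error: fay_coef must be in [0, 1)")
  invisible(cfg)
}

#' Default generative parameters per nutrient
#'
#' Log-scale group means chosen so back-transformed daily means sit at
#' realistic adult levels (energy ~1,900-2,500 kcal, sodium ~2,400-3,200 mg,
#' sugars ~80-95 g, saturated fat ~20-26 g, men above women), with
#' between-person SDs ~0.25-0.35 and within-person (day-to-day) SDs
#' ~0.35-0.45 on the log scale, the magnitudes typical of 24-h recall data.
#' Weekend days run a few percent higher; second recalls a few percent lower
#' (telephone-recall attenuation).
#'
#' @return named list keyed by nutrient
#' @export
default_nutrient_params <- function() {
  mk <- function(male_mean, female_mean, between_sd, within_sd,
                 weekend = 0.05, seq2 = -0.04) {
    # age profile: slight decline after 50
    prof <- c(1.00, 1.00, 0.95, 0.88)
    list(mean_log = log(c(male_mean * prof, female_mean * prof)),
         between_sd = between_sd, within_sd = within_sd,
         weekend_effect = weekend, sequence_effect = seq2)
  }
  list(energy = mk(2500, 1900, 0.25, 0.35),
       sodium = mk(3200, 2400, 0.30, 0.45),
       sugars = mk(95, 80, 0.35, 0.45),
       satfat = mk(26, 20, 0.35, 0.45))
}

#' Default food-category table
#'
#' A small category list spanning the five food classes the scenario engine
#' distinguishes (food, beverage, snack food, alcoholic beverage, meal
#' replacement), with sampling probabilities and relative nutrient densities
#' used to apportion daily totals over items. Not a claim about any real food
#' classification; see the scenario module for the editable class map.
#'
#' @return data frame with columns category_code, food_class, prob and one
#'   relative-density column per nutrient
#' @export
default_categories <- function() {
  tab <- data.frame(
    category_code = c("bread_cereal", "meat_fish", "dairy", "mixed_dish",
                      "fruit_veg", "cookies_crackers", "chips_salty",
                      "confectionery", "soft_drink", "juice", "coffee_tea",
                      "beer", "wine", "meal_replacement_shake"),
    food_class = c("food", "food", "food", "food", "food",
                   "snack_food", "snack_food", "snack_food",
                   "beverage", "beverage", "beverage",
                   "alcoholic_beverage", "alcoholic_beverage",
                   "meal_replacement"),
    prob = c(0.16, 0.14, 0.12, 0.14, 0.12, 0.06, 0.05, 0.04,
             0.05, 0.04, 0.04, 0.02, 0.015, 0.005),
    energy = c(1.2, 1.3, 1.0, 1.4, 0.5, 1.1, 1.1, 1.0,
               0.8, 0.7, 0.1, 0.9, 0.8, 0.9),
    sodium = c(1.3, 1.2, 0.8, 1.6, 0.3, 0.8, 1.8, 0.3,
               0.2, 0.1, 0.1, 0.2, 0.1, 0.5),
    sugars = c(0.6, 0.1, 0.9, 0.5, 1.3, 1.5, 0.3, 2.5,
               2.2, 2.0, 0.3, 0.3, 0.5, 1.0),
    satfat = c(0.7, 1.6, 1.5, 1.4, 0.2, 1.3, 1.0, 1.2,
               0.1, 0.1, 0.1, 0.1, 0.1, 0.5),
    stringsAsFactors = FALSE)
  tab$prob <- tab$prob / sum(tab$prob)
  tab
}

#' Generate a synthetic respondent roster
#'
#' Draws DRI age-sex groups, ages uniform within group, heights and weights at
#' sex-typical levels (BMI lognormal around 27), a survey weight (lognormal,
#' mean ~ the population-to-sample ratio), and BRR replicate weights built by
#' a paired half-sample perturbation: respondents are paired within DRI group
#' and, per replicate, one member of each pair is scaled by `2 - fay` and the
#' other by `fay`.
#'
#' @param config a [synth_config()]
#' @return data frame of respondents; `replicate_weights` is a numeric matrix
#'   column with `n_brr_replicates` columns
#' @export
generate_respondents <- function(config) {
  validate_synth_config(config)
  n <- config$n_respondents
  if (n == 0) {
    out <- data.frame(id = integer(0), sex = character(0), age = numeric(0),
                      dri_group = character(0), height = numeric(0),
                      weight = numeric(0), bmi = numeric(0),
                      self_reported_flag = logical(0),
                      survey_weight = numeric(0))
    out$replicate_weights <- matrix(numeric(0), nrow = 0,
                                    ncol = config$n_brr_replicates)
    return(out)
  }
  set.seed(config$rng_seed)
  grp <- sample(DRI_GROUPS, n, replace = TRUE, prob = config$dri_group_weights)
  age <- vapply(grp, function(g) {
    r <- dri_age_range(g)
    stats::runif(1, r[1], r[2] + 1)
  }, numeric(1))
  sex <- dri_sex(grp)
  height <- stats::rnorm(n, ifelse(sex == "male", 1.75, 1.62), 0.07)
  height <- pmin(pmax(height, 1.40), 2.10)
  bmi <- exp(stats::rnorm(n, log(27), 0.17))
  weight <- bmi * height^2
  w <- exp(stats::rnorm(n, log(1500), 0.5))  # ~ adult population / sample size
  out <- data.frame(id = seq_len(n), sex = sex, age = age, dri_group = grp,
                    height = height, weight = weight, bmi = bmi,
                    self_reported_flag = stats::runif(n) < 0.5,
                    survey_weight = w,
                    stringsAsFactors = FALSE)
  out$replicate_weights <- brr_replicate_weights(
    w, grp, config$n_brr_replicates, config$fay_coef)
  rownames(out) <- NULL
  out
}

# Paired half-sample replicate weights. Pairs are formed within DRI group in
# roster order; an unpaired leftover respondent keeps its full weight in every
# replicate. Per replicate a fair coin decides which member of each pair is
# upweighted, so the expected replicate weight equals the survey weight.
brr_replicate_weights <- function(w, group, R, fay = 0) {
  n <- length(w)
  pair_id <- integer(n)
  next_pair <- 1L
  for (g in unique(group)) {
    idx <- which(group == g)
    np <- floor(length(idx) / 2)
    if (np > 0) {
      pair_id[idx[seq_len(2 * np)]] <- rep(next_pair:(next_pair + np - 1L), each = 2)
      next_pair <- next_pair + np
    }
  }
  half <- logical(n)  # TRUE = first member of its pair
  for (p in unique(pair_id[pair_id > 0])) half[which(pair_id == p)[1]] <- TRUE
  reps <- matrix(w, nrow = n, ncol = R)
  n_pairs <- next_pair - 1L
  if (n_pairs > 0) {
    flips <- matrix(stats::runif(n_pairs * R) < 0.5, nrow = n_pairs)
    sel <- which(pair_id > 0)
    for (r in seq_len(R)) {
      # member is upweighted when its half indicator matches the pair's flip
      upweight <- half[sel] == flips[pair_id[sel], r]
      reps[sel[upweight], r] <- w[sel[upweight]] * (2 - fay)
      reps[sel[!upweight], r] <- w[sel[!upweight]] * fay
    }
  }
  reps
}

#' Generate item-level 24-h recall records
#'
#' Every respondent contributes a day-1 recall; a fraction
#' `second_recall_fraction` contributes a day-2 recall. Daily totals per
#' nutrient follow the log-scale generative model in [synth_config()]; totals
#' are then apportioned over items via a Dirichlet draw across sampled food
#' categories, scaled by each category's relative nutrient density.
#'
#' @param respondents roster from [generate_respondents()]
#' @param config the same [synth_config()]
#' @return data frame of recall records (respondent_id, recall_day, weekend,
#'   item_id, category_code, energy, sodium, sugars, satfat)
#' @export
generate_recalls <- function(respondents, config) {
  validate_synth_config(config)
  if (nrow(respondents) == 0) stop("respondents must be nonempty")
  set.seed(config$rng_seed + 1L)
  n <- nrow(respondents)
  has_day2 <- stats::runif(n) < config$second_recall_fraction
  grp_idx <- match(respondents$dri_group, DRI_GROUPS)

  # person effects per nutrient
  person <- sapply(NUTRIENTS, function(nm)
    stats::rnorm(n, 0, config$nutrients[[nm]]$between_sd))

  rows <- vector("list", 2L)
  for (day in 1:2) {
    ids <- if (day == 1) seq_len(n) else which(has_day2)
    if (length(ids) == 0) next
    weekend <- stats::runif(length(ids)) < config$weekend_share
    totals <- sapply(NUTRIENTS, function(nm) {
      p <- config$nutrients[[nm]]
      mu <- p$mean_log[grp_idx[ids]] + person[ids, nm] +
        weekend * p$weekend_effect + (day == 2) * p$sequence_effect
      exp(mu + stats::rnorm(length(ids), 0, p$within_sd))
    })
    if (length(ids) == 1) totals <- matrix(totals, nrow = 1,
                                           dimnames = list(NULL, NUTRIENTS))
    n_items <- pmax(1L, stats::rpois(length(ids), config$mean_items_per_day))
    cat_tab <- config$categories
    item_rows <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      m <- n_items[j]
      cats <- sample(cat_tab$category_code, m, replace = TRUE, prob = cat_tab$prob)
      ci <- match(cats, cat_tab$category_code)
      gam <- stats::rgamma(m, shape = 1)
      rec <- data.frame(respondent_id = respondents$id[ids[j]],
                        recall_day = day, weekend = weekend[j],
                        item_id = seq_len(m), category_code = cats,
                        stringsAsFactors = FALSE)
      for (nm in NUTRIENTS) {
        share <- gam * cat_tab[[nm]][ci]
        share <- share / sum(share)
        rec[[nm]] <- totals[j, nm] * share
      }
      item_rows[[j]] <- rec
    }
    rows[[day]] <- do.call(rbind, item_rows)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Generate population and mortality stratum tables
#'
#' One population row per sex x 5-year age band over the adult range (19-24,
#' 25-29, ..., 85+) and one death-count row per disease x sex x band. Death
#' counts are Poisson draws around Gompertz-style age-increasing rates per
#' disease, scaled by `mortality_scale`.
#'
#' @param config a [synth_config()]
#' @param population_per_stratum expected population per sex x band
#' @param mortality_scale multiplier on baseline death rates
#' @return list with data frames `population` (sex, age_low, age_high, count)
#'   and `deaths` (disease, sex, age_low, age_high, count)
#' @export
generate_stratum_tables <- function(config, population_per_stratum = 5e5,
                                    mortality_scale = 1) {
  validate_synth_config(config)
  set.seed(config$rng_seed + 2L)
  bands <- rbind(c(19, 24), cbind(seq(25, 85, 5), c(seq(29, 84, 5), 120)))
  diseases <- c("CVD", "diabetes", "cancer", "chronic renal failure",
                "liver disease")
  # baseline annual death rate per 100k at age 50, doubling every ~8 years
  base_rate <- c(CVD = 60, diabetes = 12, cancer = 45,
                 `chronic renal failure` = 5, `liver disease` = 8)
  pop <- expand.grid(sex = c("male", "female"), band = seq_len(nrow(bands)),
                     stringsAsFactors = FALSE)
  pop$age_low <- bands[pop$band, 1]
  pop$age_high <- bands[pop$band, 2]
  # population tapers at older ages
  taper <- exp(-pmax(0, (pop$age_low - 60)) / 15)
  pop$count <- round(population_per_stratum * taper)
  pop$band <- NULL

  dth <- merge(data.frame(disease = diseases, stringsAsFactors = FALSE), pop)
  mid <- (dth$age_low + pmin(dth$age_high, 95)) / 2
  rate <- base_rate[dth$disease] / 1e5 * 2^((mid - 50) / 8) *
    ifelse(dth$sex == "male", 1.3, 1) * mortality_scale
  lam <- rate * dth$count
  dth$count <- stats::rpois(nrow(dth), lam)
  dth <- dth[order(dth$disease, dth$sex, dth$age_low),
             c("disease", "sex", "age_low", "age_high", "count")]
  pop <- pop[order(pop$sex, pop$age_low), c("sex", "age_low", "age_high", "count")]
  rownames(pop) <- rownames(dth) <- NULL
  list(population = pop, deaths = dth)
}

#' Daily nutrient totals from item-level recall records
#'
#' @param recalls item-level records from [generate_recalls()]
#' @return one row per respondent x recall day with summed nutrients and the
#'   day's weekend flag
#' @export
daily_totals <- function(recalls) {
  agg <- stats::aggregate(recalls[NUTRIENTS],
                          by = list(respondent_id = recalls$respondent_id,
                                    recall_day = recalls$recall_day,
                                    weekend = recalls$weekend),
                          FUN = sum)
  agg <- agg[order(agg$respondent_id, agg$recall_day), ]
  rownames(agg) <- NULL
  agg[, c("respondent_id", "recall_day", "weekend", NUTRIENTS)]
}
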