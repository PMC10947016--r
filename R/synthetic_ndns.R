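#' Stratum configuration for the synthetic diary generator
#'
#' One stratum per sex x age-band cell: how many participants to draw, the
#' mean and SD of their total daily fibre intake, the Dirichlet
#' concentration governing how that intake splits across the white-flour,
#' wholemeal and other food categories, and the mean survey weight.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_band One of the five report band labels (see [age_band()]).
#' @param n Number of participants (>= 0).
#' @param intake_mean_g Mean daily fibre intake, g/day (> 0).
#' @param intake_sd_g SD of daily intake, g/day (>= 0; 0 gives every
#'   participant exactly the mean).
#' @param share_alpha Length-3 positive Dirichlet concentration for the
#'   (white_flour, wholemeal, other) intake shares.
#' @param weight_mean Mean survey weight (> 0).
#' @return A list of class `stratum_config`.
#' @export
stratum_config <- function(sex, age_band, n, intake_mean_g, intake_sd_g,
                           share_alpha = c(5, 1, 44), weight_mean = 1.0) {
  sex <- match.arg(sex, SEX_LEVELS)
  age_band <- match.arg(age_band, AGE_BAND_LABELS)
  stopifnot(length(n) == 1, n >= 0,
            length(intake_mean_g) == 1, intake_mean_g > 0,
            length(intake_sd_g) == 1, intake_sd_g >= 0,
            length(share_alpha) == 3, all(share_alpha > 0),
            length(weight_mean) == 1, weight_mean > 0)
  structure(
    list(sex = sex, age_band = age_band, n = as.integer(n),
         intake_mean_g = intake_mean_g, intake_sd_g = intake_sd_g,
         share_alpha = as.numeric(share_alpha), weight_mean = weight_mean),
    class = "stratum_config"
  )
}

#' Generator configuration for synthetic diet diaries
#'
#' Describes a synthetic population with the statistical structure the
#' scenario pipeline assumes: strata with Gamma-distributed total intakes,
#' Dirichlet category shares, multi-day diaries spread over a small food
#' list per category, and positive survey weights.
#'
#' @param strata List of [stratum_config()] objects.
#' @param foods_per_category Foods drawn per category (>= 1).
#' @param diary_days Diary length in days (default 4, the usual multi-day
#'   recall length).
#' @param fibre_density_range Named list of `c(lo, hi)` g/100 g ranges per
#'   category; defaults anchor white flour around its typical 4 g/100 g.
#' @param exact_shares If `TRUE`, every participant uses the expected shares
#'   `alpha / sum(alpha)` instead of a Dirichlet draw (useful with
#'   `intake_sd_g = 0` to make generated intakes exactly invert
#'   [person_daily_intake()]).
#' @param seed Integer seed driving the single pseudo-random stream.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(strata,
                             foods_per_category = 3,
                             diary_days = 4,
                             fibre_density_range = list(
                               white_flour = c(1.0, 4.0),
                               wholemeal = c(5.0, 9.0),
                               other = c(0.5, 8.0)
                             ),
                             exact_shares = FALSE,
                             seed = 1L) {
  if (inherits(strata, "stratum_config")) strata <- list(strata)
  stopifnot(length(strata) > 0,
            all(vapply(strata, inherits, logical(1), "stratum_config")),
            foods_per_category >= 1, diary_days >= 1)
  stopifnot(setequal(names(fibre_density_range), FOOD_CATEGORIES))
  for (cc in FOOD_CATEGORIES) {
    r <- fibre_density_range[[cc]]
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2]) {
      stop("fibre_density_range for ", cc,
           " must be c(lo, hi) with 0 < lo <= hi", call. = FALSE)
    }
  }
  structure(
    list(strata = strata,
         foods_per_category = as.integer(foods_per_category),
         diary_days = as.integer(diary_days),
         fibre_density_range = fibre_density_range,
         exact_shares = isTRUE(exact_shares),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default synthetic population emulating a national diet survey
#'
#' Ten strata (two sexes x five age bands) sized and parameterised to
#' resemble published UK survey margins: 3558 participants in total, band
#' intake means around 10--21 g/day rising with age, males above females
#' within each band, intake SD about 35% of the mean, and category shares
#' with expectation (0.10, 0.02, 0.88) for white flour, wholemeal and
#' other foods.
#'
#' @param seed Integer seed.
#' @param n_total Optional total population size; stratum sizes are scaled
#'   proportionally (default 3558).
#' @return A [generator_config()].
#' @export
default_generator_config <- function(seed = 1L, n_total = NULL) {
  base <- tibble::tribble(
    ~age_band,          ~n_band, ~mean_male, ~mean_female,
    AGE_BAND_LABELS[1],     306,       10.7,         10.1,
    AGE_BAND_LABELS[2],     725,       14.9,         13.9,
    AGE_BAND_LABELS[3],     683,       16.8,         15.2,
    AGE_BAND_LABELS[4],    1392,       21.4,         18.2,
    AGE_BAND_LABELS[5],     452,       19.8,         17.8
  )
  male_frac <- 1636 / 3558
  scale <- if (is.null(n_total)) 1 else n_total / sum(base$n_band)
  strata <- list()
  for (i in seq_len(nrow(base))) {
    n_m <- round(base$n_band[i] * male_frac * scale)
    n_f <- round(base$n_band[i] * scale) - n_m
    strata[[length(strata) + 1]] <- stratum_config(
      "male", base$age_band[i], n_m,
      base$mean_male[i], 0.35 * base$mean_male[i]
    )
    strata[[length(strata) + 1]] <- stratum_config(
      "female", base$age_band[i], n_f,
      base$mean_female[i], 0.35 * base$mean_female[i]
    )
  }
  generator_config(strata, seed = seed)
}

# Dirichlet draws via normalised Gamma variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n)
  x / rowSums(x)
}

# Midpoint ages for each band; Older Adults capped at 90 for realism.
band_age_range <- function(band) {
  i <- match(band, AGE_BAND_LABELS)
  lo <- AGE_BAND_BREAKS[i]
  hi <- min(AGE_BAND_BREAKS[i + 1], 90)
  c(lo, hi)
}

#' Generate a synthetic diet-diary dataset
#'
#' For each participant: a total daily fibre intake `T` is drawn from a
#' Gamma distribution with the stratum's mean and SD (degenerate at the
#' mean when SD is 0); category shares come from a Dirichlet draw (or the
#' exact expected shares when `exact_shares = TRUE`); each category's fibre
#' is then realised as diary entries over all days and the category's
#' foods, with `amount_g = share * T * 100 / (k * fibre_density)` per food
#' per day, so the diary exactly reconstructs `T` through
#' [person_daily_intake()]. Survey weights are Gamma-distributed with the
#' stratum's mean (shape 4). The same seed always yields the identical
#' dataset.
#'
#' @param cfg A [generator_config()].
#' @return A validated [fibre_dataset()] with attribute `"generator_meta"`
#'   (seed and configuration summary).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::local_seed(cfg$seed)

  k <- cfg$foods_per_category
  code_prefix <- c(white_flour = "WF", wholemeal = "WM", other = "OT")
  foods <- dplyr::bind_rows(lapply(FOOD_CATEGORIES, function(cc) {
    r <- cfg$fibre_density_range[[cc]]
    tibble::tibble(
      food_code = sprintf("%s_%02d", code_prefix[[cc]], seq_len(k)),
      description = sprintf("synthetic %s food %d", cc, seq_len(k)),
      fibre_g_per_100g = round(runif(k, r[1], r[2]), 3),
      category = cc,
      custom_factor = NA_real_
    )
  }))

  participants <- list()
  entries <- list()
  pid_offset <- 0L
  for (st in cfg$strata) {
    if (st$n == 0) next
    ids <- sprintf("P%05d", pid_offset + seq_len(st$n))
    pid_offset <- pid_offset + st$n

    ar <- band_age_range(st$age_band)
    ages <- runif(st$n, ar[1], ar[2])
    weights <- rgamma(st$n, shape = 4, rate = 4 / st$weight_mean)

    if (st$intake_sd_g == 0) {
      total <- rep(st$intake_mean_g, st$n)
    } else {
      shape <- (st$intake_mean_g / st$intake_sd_g)^2
      total <- rgamma(st$n, shape = shape,
                      rate = shape / st$intake_mean_g)
    }
    shares <- if (cfg$exact_shares) {
      matrix(st$share_alpha / sum(st$share_alpha), nrow = st$n,
             ncol = 3, byrow = TRUE)
    } else {
      rdirichlet(st$n, st$share_alpha)
    }

    participants[[length(participants) + 1]] <- tibble::tibble(
      participant_id = ids,
      sex = st$sex,
      age_years = round(ages, 2),
      survey_weight = round(weights, 4),
      diary_days = cfg$diary_days
    )

    # One entry per participant x category x food x day; amounts invert
    # person_daily_intake so the realised baseline equals total x share sums.
    grid <- tidyr::expand_grid(
      pi = seq_len(st$n),
      ci = seq_along(FOOD_CATEGORIES),
      fi = seq_len(k),
      day_index = seq_len(cfg$diary_days)
    )
    dens <- matrix(foods$fibre_g_per_100g, nrow = k)  # k x 3, col = category
    entries[[length(entries) + 1]] <- tibble::tibble(
      participant_id = ids[grid$pi],
      day_index = grid$day_index,
      food_code = foods$food_code[(grid$ci - 1L) * k + grid$fi],
      amount_g = shares[cbind(grid$pi, grid$ci)] * total[grid$pi] * 100 /
        (k * dens[cbind(grid$fi, grid$ci)])
    )
  }

  d <- fibre_dataset(
    dplyr::bind_rows(participants),
    dplyr::bind_rows(entries),
    foods
  )
  attr(d, "generator_meta") <- list(
    seed = cfg$seed,
    n_participants = nrow(d$participants),
    n_entries = nrow(d$entries),
    n_foods = nrow(d$foods),
    diary_days = cfg$diary_days,
    foods_per_category = cfg$foods_per_category,
    exact_shares = cfg$exact_shares,
    n_strata = length(cfg$strata)
  )
  d
}

#' Closed-form expected scenario effect per stratum
#'
#' The expected change in daily fibre intake under a scenario, by stratum:
#' `intake_mean_g * sum over categories E[share_c] * (factor_c - 1)` with
#' `E[share_c] = alpha_c / sum(alpha)`. This is the analytic counterpart of
#' running [generate_dataset()] through [compute_intakes()] and averaging
#' the deltas, and is used in parameter-recovery tests.
#'
#' @param cfg A [generator_config()].
#' @param s A [scenario()].
#' @return A tibble with `sex`, `age_band`, `n`, `expected_delta_g_per_day`.
#' @export
expected_delta <- function(cfg, s) {
  stopifnot(inherits(cfg, "generator_config"), inherits(s, "fibre_scenario"))
  fac <- s$factors[FOOD_CATEGORIES]
  dplyr::bind_rows(lapply(cfg$strata, function(st) {
    eshare <- st$share_alpha / sum(st$share_alpha)
    tibble::tibble(
      sex = st$sex,
      age_band = st$age_band,
      n = st$n,
      expected_delta_g_per_day =
        st$intake_mean_g * sum(eshare * (fac - 1))
    )
  }))
}

#' Read a generator configuration from YAML
#'
#' Top-level keys `foods_per_category`, `diary_days`, `seed`,
#' `exact_shares`, `fibre_density_range` (map of category to `[lo, hi]`)
#' and `strata` (list of maps with the [stratum_config()] fields); all but
#' `strata` optional.
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$strata)) stop("generator config needs 'strata'",
                                call. = FALSE)
  strata <- lapply(raw$strata, function(s) {
    # YAML 1.1 resolves a bare `n:` key to boolean FALSE; map it back
    if (is.null(s$n) && !is.null(s[["FALSE"]])) s$n <- s[["FALSE"]]
    stratum_config(
      sex = s$sex, age_band = s$age_band, n = s$n,
      intake_mean_g = s$intake_mean_g, intake_sd_g = s$intake_sd_g,
      share_alpha = if (is.null(s$share_alpha)) c(5, 1, 44)
        else unlist(s$share_alpha),
      weight_mean = if (is.null(s$weight_mean)) 1.0 else s$weight_mean
    )
  })
  args <- list(strata = strata)
  for (k in c("foods_per_category", "diary_days", "exact_shares", "seed")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$fibre_density_range)) {
    args$fibre_density_range <- lapply(raw$fibre_density_range, unlist)
  }
  do.call(generator_config, args)
}
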