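#' Weighted mean and its standard error
#'
#' Design-based estimator: `mean = sum(w*x)/sum(w)` and
#' `se = sqrt(sum(w^2 * (x - mean)^2) / sum(w)^2)`. With unit weights the SE
#' reduces to `sqrt((n-1)/n) * sd(x) / sqrt(n)`. A single observation has
#' SE 0 by convention.
#'
#' @param values Numeric vector, length >= 1.
#' @param weights Positive weights, same length (default: unit weights).
#' @return Named numeric vector `c(mean, se)`.
#' @export
weighted_mean_se <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n == 0) stop("weighted_mean_se requires at least one value",
                   call. = FALSE)
  if (length(weights) != n) stop("values and weights lengths differ",
                                 call. = FALSE)
  if (any(is.na(values)) || any(is.na(weights)) || any(weights <= 0)) {
    stop("weights must be positive and inputs non-missing", call. = FALSE)
  }
  m <- sum(weights * values) / sum(weights)
  se <- if (n == 1) 0 else
    sqrt(sum(weights^2 * (values - m)^2) / sum(weights)^2)
  c(mean = m, se = se)
}

#' Weighted percentage reaching a threshold, with standard error
#'
#' Cut-point estimator: the weighted share of values at or above the
#' threshold (ties count as reaching), expressed in percent, with the
#' binomial-style design SE `100 * sqrt(p*(1-p) * sum(w^2)/sum(w)^2)`.
#'
#' @param values Numeric vector, length >= 1.
#' @param weights Positive weights, same length (default: unit weights).
#' @param threshold Positive cut-point on the same scale as `values`.
#' @return Named numeric vector `c(pct, se)`, `pct` in \[0, 100\].
#' @export
percent_reaching <- function(values, weights = rep(1, length(values)),
                             threshold) {
  n <- length(values)
  if (n == 0) stop("percent_reaching requires at least one value",
                   call. = FALSE)
  if (length(weights) != n) stop("values and weights lengths differ",
                                 call. = FALSE)
  if (any(is.na(values)) || any(is.na(weights)) || any(weights <= 0)) {
    stop("weights must be positive and inputs non-missing", call. = FALSE)
  }
  if (is.na(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  p <- sum(weights * (values >= threshold)) / sum(weights)
  se <- 100 * sqrt(p * (1 - p) * sum(weights^2) / sum(weights)^2)
  c(pct = 100 * p, se = se)
}

#' Assign an age to its report band
#'
#' Five bands with half-open integer-year boundaries:
#' Pre-school \[1.5, 4), Junior School \[4, 11), Adolescents \[11, 19),
#' Adults \[19, 66), Older Adults \[66, Inf).
#'
#' @param age_years Numeric vector of ages, all >= 1.5.
#' @return Factor with the five band labels in report order.
#' @export
#' @examples
#' age_band(c(2, 19, 66))
age_band <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 1.5)) {
    stop("ages below 1.5 years are outside the supported range",
         call. = FALSE)
  }
  cut(age_years, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS,
      right = FALSE)
}

#' Recommended-intake schedule
#'
#' Age-banded daily fibre recommendations used by the cut-point estimator.
#' The default follows UK guidance: 30 g/day from age 16, with lower bands
#' for children (15 g to age 5, 20 g for 5--11, 25 g for 11--16); the first
#' band starts at 1.5 y, the youngest diary age supported. Bands must be
#' ordered, non-overlapping and cover \[1.5, Inf).
#'
#' @param bands Data frame with columns `age_lower` (inclusive), `age_upper`
#'   (exclusive) and `threshold_g_per_day`.
#' @return A tibble of class `recommendation_schedule`.
#' @export
recommendation_schedule <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      age_lower = c(1.5, 5, 11, 16),
      age_upper = c(5, 11, 16, Inf),
      threshold_g_per_day = c(15, 20, 25, 30)
    )
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("age_lower", "age_upper", "threshold_g_per_day") %in%
                  names(bands)))
  bands <- dplyr::arrange(bands, .data$age_lower)
  if (any(bands$threshold_g_per_day <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (nrow(bands) > 1 &&
      any(bands$age_upper[-nrow(bands)] > bands$age_lower[-1])) {
    stop("recommendation bands overlap", call. = FALSE)
  }
  class(bands) <- c("recommendation_schedule", class(bands))
  bands
}

#' Read a recommendation schedule from YAML
#'
#' Expects a top-level list of maps with keys `age_lower`, `age_upper`,
#' `threshold_g_per_day` (use `.inf` for an open upper bound).
#' @param path YAML file path.
#' @return A [recommendation_schedule()].
#' @export
read_recommendations <- function(path) {
  raw <- yaml::read_yaml(path)
  bands <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  recommendation_schedule(bands)
}

#' Threshold applying to each age
#' @param age_years Numeric ages.
#' @param sched A [recommendation_schedule()].
#' @return Numeric thresholds in g/day (NA where no band covers the age).
#' @export
threshold_for_age <- function(age_years, sched = recommendation_schedule()) {
  idx <- findInterval(age_years, sched$age_lower)
  out <- rep(NA_real_, length(age_years))
  ok <- idx >= 1
  ok[ok] <- age_years[ok] < sched$age_upper[idx[ok]]
  out[ok] <- sched$threshold_g_per_day[idx[ok]]
  out
}

#' Population summary by sex and age group
#'
#' Builds the report table: for each of the two sex rows and five age-band
#' rows, the (optionally survey-weighted) mean daily fibre intake with its
#' SE and the percentage of the group at or above its recommended intake
#' with its SE, under both the current and the scenario composition.
#'
#' @param d A [fibre_dataset()].
#' @param intakes Output of [compute_intakes()] covering all participants.
#' @param sched A [recommendation_schedule()].
#' @param weighted Use the `survey_weight` column? Default `FALSE`
#'   (unit weights).
#' @return A tibble with one row per group: `group_type` (`"sex"` or
#'   `"age"`), `group_label`, `n`, then `current_mean`, `current_se`,
#'   `scenario_mean`, `scenario_se`, `current_pct`, `current_pct_se`,
#'   `scenario_pct`, `scenario_pct_se`. Empty groups get `n = 0` and `NA`
#'   statistics, with a warning.
#' @export
summarize_population <- function(d, intakes,
                                 sched = recommendation_schedule(),
                                 weighted = FALSE) {
  stopifnot(inherits(d, "fibre_dataset"))
  p <- d$participants
  if (!all(p$participant_id %in% intakes$participant_id)) {
    stop("intakes must cover every participant", call. = FALSE)
  }

  df <- dplyr::inner_join(p, intakes, by = "participant_id")
  df$w <- if (weighted) df$survey_weight else rep(1, nrow(df))
  df$band <- as.character(age_band(df$age_years))
  df$threshold <- threshold_for_age(df$age_years, sched)
  if (any(is.na(df$threshold))) {
    stop("recommendation schedule does not cover all participant ages",
         call. = FALSE)
  }

  groups <- c(
    lapply(SEX_LEVELS, function(sx) list(
      type = "sex",
      label = c(male = "Male", female = "Female")[[sx]],
      rows = which(df$sex == sx)
    )),
    lapply(AGE_BAND_LABELS, function(b) list(
      type = "age", label = b, rows = which(df$band == b)
    ))
  )

  one <- function(g) {
    sub <- df[g$rows, ]
    if (nrow(sub) == 0) {
      warning("group '", g$label, "' has no members", call. = FALSE)
      return(tibble::tibble(
        group_type = g$type, group_label = g$label, n = 0L,
        current_mean = NA_real_, current_se = NA_real_,
        scenario_mean = NA_real_, scenario_se = NA_real_,
        current_pct = NA_real_, current_pct_se = NA_real_,
        scenario_pct = NA_real_, scenario_pct_se = NA_real_
      ))
    }
    # Cut-point percentages use each member's own age-banded threshold:
    # the weighted share of indicator variables, with the same binomial SE
    # as percent_reaching.
    pct_of <- function(x) {
      reached <- as.numeric(x >= sub$threshold)
      pr <- sum(sub$w * reached) / sum(sub$w)
      c(100 * pr,
        100 * sqrt(pr * (1 - pr) * sum(sub$w^2) / sum(sub$w)^2))
    }
    cm <- weighted_mean_se(sub$baseline_g_per_day, sub$w)
    sm <- weighted_mean_se(sub$scenario_g_per_day, sub$w)
    cp <- pct_of(sub$baseline_g_per_day)
    sp <- pct_of(sub$scenario_g_per_day)
    tibble::tibble(
      group_type = g$type, group_label = g$label, n = nrow(sub),
      current_mean = cm[["mean"]], current_se = cm[["se"]],
      scenario_mean = sm[["mean"]], scenario_se = sm[["se"]],
      current_pct = cp[1], current_pct_se = cp[2],
      scenario_pct = sp[1], scenario_pct_se = sp[2]
    )
  }

  dplyr::bind_rows(lapply(groups, one))
}

#' Render a population summary as a fixed-width report table
#'
#' Text rendering with the report's layout: a Gender block then an Age
#' block, columns "mean (SE)" for intake and for the percentage reaching
#' the recommended intake, current vs scenario, rounded to 1 decimal.
#'
#' @param summary Output of [summarize_population()].
#' @param scenario_label Column label for the scenario diet.
#' @return A character vector of lines (invisible when printed via `cat`).
#' @export
render_summary <- function(summary, scenario_label = "Higher fibre") {
  fmt <- function(m, se) {
    ifelse(is.na(m), "-", sprintf("%.1f (%.1f)", m, se))
  }
  rows <- tibble::tibble(
    label = summary$group_label,
    n = as.character(summary$n),
    cur_int = fmt(summary$current_mean, summary$current_se),
    scen_int = fmt(summary$scenario_mean, summary$scenario_se),
    cur_pct = fmt(summary$current_pct, summary$current_pct_se),
    scen_pct = fmt(summary$scenario_pct, summary$scenario_pct_se)
  )
  widths <- c(
    label = max(nchar(c(rows$label, "Older Adults (>65 years)"))),
    n = max(nchar(c(rows$n, "n"))),
    cur_int = max(nchar(c(rows$cur_int, "Current"))),
    scen_int = max(nchar(c(rows$scen_int, scenario_label))),
    cur_pct = max(nchar(c(rows$cur_pct, "Current"))),
    scen_pct = max(nchar(c(rows$scen_pct, scenario_label)))
  )
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  line <- function(label, n, a, b, c2, d) {
    paste(pad(label, widths["label"]), pad(n, widths["n"]),
          pad(a, widths["cur_int"]), pad(b, widths["scen_int"]),
          pad(c2, widths["cur_pct"]), pad(d, widths["scen_pct"]),
          sep = "  ")
  }
  span1 <- "Fibre intake (g/day) mean (SE)"
  span2 <- "Reaching recommended (%) mean (SE)"
  out <- c(
    line("", "", span1, "", span2, ""),
    line("", "n", "Current", scenario_label, "Current", scenario_label),
    line("Gender", "", "", "", "", "")
  )
  sex_rows <- which(summary$group_type == "sex")
  age_rows <- which(summary$group_type == "age")
  for (i in sex_rows) {
    out <- c(out, line(rows$label[i], rows$n[i], rows$cur_int[i],
                       rows$scen_int[i], rows$cur_pct[i], rows$scen_pct[i]))
  }
  out <- c(out, line("Age", "", "", "", "", ""))
  for (i in age_rows) {
    out <- c(out, line(rows$label[i], rows$n[i], rows$cur_int[i],
                       rows$scen_int[i], rows$cur_pct[i], rows$scen_pct[i]))
  }
  trimws(out, which = "right")
}
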