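# Fixture builders shared across the suite. All data is constructed in code.

# Two participants, three foods (one per category), six entries.
make_toy_dataset <- function() {
  fibre_dataset(
    participants = tibble::tibble(
      participant_id = c("p1", "p2"),
      sex = c("male", "female"),
      age_years = c(34, 7),
      survey_weight = c(1.2, 0.8),
      diary_days = c(4L, 3L)
    ),
    entries = tibble::tibble(
      participant_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
      day_index = c(1L, 2L, 4L, 1L, 2L, 3L),
      food_code = c("WB", "WM", "AP", "WB", "AP", "AP"),
      amount_g = c(80, 60, 150, 40, 100, 120)
    ),
    foods = tibble::tibble(
      food_code = c("WB", "WM", "AP"),
      description = c("white bread", "wholemeal bread", "apple"),
      fibre_g_per_100g = c(4.0, 7.0, 1.2),
      category = c("white_flour", "wholemeal", "other"),
      custom_factor = NA_real_
    )
  )
}

# Random valid dataset with n participants over a small food list.
make_random_dataset <- function(n = 20, n_entries_per = 5, seed = 42) {
  withr::local_seed(seed)
  foods <- tibble::tibble(
    food_code = sprintf("F%02d", 1:9),
    description = paste("food", 1:9),
    fibre_g_per_100g = round(runif(9, 0.5, 8), 2),
    category = rep(c("white_flour", "wholemeal", "other"), each = 3),
    custom_factor = NA_real_
  )
  participants <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = round(runif(n, 1.5, 90), 1),
    survey_weight = round(runif(n, 0.3, 2.5), 3),
    diary_days = sample(3:4, n, replace = TRUE)
  )
  entries <- tibble::tibble(
    participant_id = rep(participants$participant_id, each = n_entries_per),
    day_index = unlist(lapply(participants$diary_days, function(dd) {
      sample(seq_len(dd), n_entries_per, replace = TRUE)
    })),
    food_code = sample(foods$food_code, n * n_entries_per, replace = TRUE),
    amount_g = round(runif(n * n_entries_per, 0, 300), 1)
  )
  fibre_dataset(participants, entries, foods)
}

# Write a dataset's four CSVs to a temp dir, returning the paths.
write_toy_csvs <- function(d, dir = withr::local_tempdir(.local_envir =
                                                           parent.frame())) {
  write_dataset(d, dir)
}

# Independent naive oracle: per-entry loop, no dplyr, no package internals.
naive_intakes <- function(d, s) {
  fac <- s$factors
  out <- data.frame(participant_id = d$participants$participant_id,
                    baseline = 0, scenario = 0,
                    white = 0, wholemeal = 0, other = 0)
  for (i in seq_len(nrow(d$entries))) {
    e <- d$entries[i, ]
    f <- d$foods[d$foods$food_code == e$food_code, ]
    p_row <- which(out$participant_id == e$participant_id)
    days <- d$participants$diary_days[p_row]
    base <- e$amount_g * f$fibre_g_per_100g / 100 / days
    factor_i <- if (!is.na(f$custom_factor)) f$custom_factor
      else fac[[f$category]]
    out$baseline[p_row] <- out$baseline[p_row] + base
    out$scenario[p_row] <- out$scenario[p_row] + base * factor_i
    col <- c(white_flour = "white", wholemeal = "wholemeal",
             other = "other")[[f$category]]
    out[[col]][p_row] <- out[[col]][p_row] + base
  }
  out
}
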