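#' Construct a diet-diary dataset
#'
#' Bundles the three tables the scenario pipeline operates on: a participant
#' roster, multi-day diary entries, and a food composition table carrying a
#' reformulation category per food. Input tables are coerced to tibbles and
#' column types are checked; referential integrity is checked unless
#' `validate = FALSE`.
#'
#' @param participants Data frame with columns `participant_id`, `sex`
#'   (`"male"`/`"female"`), `age_years`, `survey_weight`, `diary_days`.
#' @param entries Data frame with columns `participant_id`, `day_index`,
#'   `food_code`, `amount_g`.
#' @param foods Data frame with columns `food_code`, `description`,
#'   `fibre_g_per_100g`, `category` and optionally `custom_factor`
#'   (`NA` = use the category factor).
#' @param validate If `TRUE` (default), stop on any integrity violation.
#'
#' @return An object of class `fibre_dataset`: a list with tibbles
#'   `participants`, `entries`, `foods`.
#' @export
#' @examples
#' fibre_dataset(
#'   participants = data.frame(participant_id = "p1", sex = "female",
#'     age_years = 34, survey_weight = 1, diary_days = 4),
#'   entries = data.frame(participant_id = "p1", day_index = 1,
#'     food_code = "WB", amount_g = 80),
#'   foods = data.frame(food_code = "WB", description = "white bread",
#'     fibre_g_per_100g = 4, category = "white_flour")
#' )
fibre_dataset <- function(participants, entries, foods, validate = TRUE) {
  participants <- tibble::as_tibble(participants)
  entries <- tibble::as_tibble(entries)
  foods <- tibble::as_tibble(foods)

  req_cols <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      stop(sprintf("%s table is missing column(s): %s",
                   what, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  req_cols(participants,
           c("participant_id", "sex", "age_years", "survey_weight",
             "diary_days"), "participants")
  req_cols(entries,
           c("participant_id", "day_index", "food_code", "amount_g"),
           "entries")
  req_cols(foods,
           c("food_code", "description", "fibre_g_per_100g", "category"),
           "foods")

  participants <- dplyr::mutate(
    participants,
    participant_id = as.character(.data$participant_id),
    sex = tolower(as.character(.data$sex)),
    age_years = as.numeric(.data$age_years),
    survey_weight = as.numeric(.data$survey_weight),
    diary_days = as.integer(.data$diary_days)
  )
  entries <- dplyr::mutate(
    entries,
    participant_id = as.character(.data$participant_id),
    day_index = as.integer(.data$day_index),
    food_code = as.character(.data$food_code),
    amount_g = as.numeric(.data$amount_g)
  )
  if (!"custom_factor" %in% names(foods)) {
    foods$custom_factor <- NA_real_
  }
  foods <- dplyr::mutate(
    foods,
    food_code = as.character(.data$food_code),
    description = as.character(.data$description),
    fibre_g_per_100g = as.numeric(.data$fibre_g_per_100g),
    category = as.character(.data$category),
    custom_factor = as.numeric(.data$custom_factor)
  )
  foods <- foods[, c("food_code", "description", "fibre_g_per_100g",
                     "category", "custom_factor")]

  dup_p <- unique(participants$participant_id[duplicated(participants$participant_id)])
  if (length(dup_p) > 0) {
    stop("duplicate participant_id: ", paste(dup_p, collapse = ", "),
         call. = FALSE)
  }
  dup_f <- unique(foods$food_code[duplicated(foods$food_code)])
  if (length(dup_f) > 0) {
    stop("duplicate food_code: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }

  d <- structure(
    list(participants = participants, entries = entries, foods = foods),
    class = "fibre_dataset"
  )
  if (validate) {
    v <- validate_dataset(d)
    if (nrow(v) > 0) {
      stop("dataset integrity violations:\n",
           paste(utils::head(v$message, 10), collapse = "\n"),
           if (nrow(v) > 10) sprintf("\n... and %d more", nrow(v) - 10) else "",
           call. = FALSE)
    }
  }
  d
}

#' @export
print.fibre_dataset <- function(x, ...) {
  cat(sprintf(
    "<fibre_dataset> %d participants, %d diary entries, %d foods\n",
    nrow(x$participants), nrow(x$entries), nrow(x$foods)
  ))
  invisible(x)
}

#' Load a diet-diary dataset from CSV files
#'
#' Reads the four-file CSV interchange format: participant roster, diary
#' entries, food composition table and a category map assigning each food to
#' `white_flour`, `wholemeal` or `other` (optionally with a per-food
#' `custom_factor` override). Foods absent from the category map default to
#' `other`, with a message naming them.
#'
#' @param participants_path CSV with header
#'   `participant_id,sex,age_years,survey_weight,diary_days`.
#' @param entries_path CSV with header
#'   `participant_id,day_index,food_code,amount_g`.
#' @param foods_path CSV with header
#'   `food_code,description,fibre_g_per_100g`.
#' @param category_map_path CSV with header
#'   `food_code,category[,custom_factor]`.
#'
#' @return A validated [fibre_dataset()].
#' @export
load_dataset <- function(participants_path, entries_path, foods_path,
                         category_map_path) {
  read_one <- function(path, what) {
    if (!file.exists(path)) {
      stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
    }
    out <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) {
        stop(sprintf("could not parse %s file %s: %s",
                     what, path, conditionMessage(e)), call. = FALSE)
      }
    )
    probs <- readr::problems(out)
    if (nrow(probs) > 0) {
      stop(sprintf("malformed %s file %s at line %d: expected %s, got %s",
                   what, path, probs$row[1] + 1L,
                   probs$expected[1], probs$actual[1]), call. = FALSE)
    }
    out
  }

  participants <- read_one(participants_path, "participants")
  entries <- read_one(entries_path, "entries")
  foods <- read_one(foods_path, "foods")
  cmap <- read_one(category_map_path, "category map")

  if (!all(c("food_code", "category") %in% names(cmap))) {
    stop("category map must have columns food_code,category", call. = FALSE)
  }
  cmap$food_code <- as.character(cmap$food_code)
  if (!"custom_factor" %in% names(cmap)) cmap$custom_factor <- NA_real_
  dup_c <- unique(cmap$food_code[duplicated(cmap$food_code)])
  if (length(dup_c) > 0) {
    stop("duplicate food_code in category map: ",
         paste(dup_c, collapse = ", "), call. = FALSE)
  }

  foods$food_code <- as.character(foods$food_code)
  foods <- dplyr::left_join(foods, cmap, by = "food_code")
  unmapped <- foods$food_code[is.na(foods$category)]
  if (length(unmapped) > 0) {
    message(length(unmapped),
            " food(s) absent from category map; defaulting to 'other': ",
            paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ..." else "")
    foods$category[is.na(foods$category)] <- "other"
  }

  fibre_dataset(participants, entries, foods)
}

#' Write a dataset to the four-file CSV format
#'
#' Inverse of [load_dataset()]: writes `participants.csv`, `entries.csv`,
#' `foods.csv` and `category_map.csv` under `dir`. A dataset survives a
#' write/reload round trip unchanged.
#'
#' @param d A [fibre_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "fibre_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    entries = file.path(dir, "entries.csv"),
    foods = file.path(dir, "foods.csv"),
    category_map = file.path(dir, "category_map.csv")
  )
  readr::write_csv(d$participants, paths[["participants"]], progress = FALSE)
  readr::write_csv(d$entries, paths[["entries"]], progress = FALSE)
  readr::write_csv(
    d$foods[, c("food_code", "description", "fibre_g_per_100g")],
    paths[["foods"]], progress = FALSE
  )
  readr::write_csv(
    d$foods[, c("food_code", "category", "custom_factor")],
    paths[["category_map"]], progress = FALSE
  )
  invisible(paths)
}

#' Check dataset invariants
#'
#' Pure validation: returns violations as data rather than raising them, one
#' row per violated rule, so callers can report all problems at once.
#' Checked rules: category values; non-negative fibre densities and amounts;
#' positive survey weights; ages within 1.5--120 years; `diary_days >= 1`;
#' entry references resolving to a participant and a food; `day_index`
#' within the participant's diary length.
#'
#' @param d A [fibre_dataset()].
#' @return A tibble with columns `table`, `record`, `rule`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "fibre_dataset"))
  v <- list()
  add <- function(table, record, rule, message) {
    tibble::tibble(table = table, record = as.character(record),
                   rule = rule, message = message)
  }

  p <- d$participants
  bad <- p$participant_id[!p$sex %in% SEX_LEVELS]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("participants", bad, "sex-level",
      sprintf("participant %s: sex must be one of %s", bad,
              paste(SEX_LEVELS, collapse = "/")))
  }
  bad <- p$participant_id[is.na(p$age_years) | p$age_years < 1.5 |
                            p$age_years > 120]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("participants", bad, "age-range",
      sprintf("participant %s: age_years must lie in [1.5, 120]", bad))
  }
  bad <- p$participant_id[is.na(p$survey_weight) | p$survey_weight <= 0]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("participants", bad, "positive-weight",
      sprintf("participant %s: survey_weight must be > 0", bad))
  }
  bad <- p$participant_id[is.na(p$diary_days) | p$diary_days < 1]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("participants", bad, "diary-days",
      sprintf("participant %s: diary_days must be >= 1", bad))
  }

  f <- d$foods
  bad <- f$food_code[!f$category %in% FOOD_CATEGORIES]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("foods", bad, "category-level",
      sprintf("food %s: category must be one of %s", bad,
              paste(FOOD_CATEGORIES, collapse = "/")))
  }
  bad <- f$food_code[is.na(f$fibre_g_per_100g) | f$fibre_g_per_100g < 0]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("foods", bad, "non-negative-fibre",
      sprintf("food %s: fibre_g_per_100g must be >= 0", bad))
  }
  bad <- f$food_code[!is.na(f$custom_factor) & f$custom_factor < 0]
  if (length(bad) > 0) {
    v[[length(v) + 1]] <- add("foods", bad, "non-negative-factor",
      sprintf("food %s: custom_factor must be >= 0", bad))
  }

  e <- d$entries
  if (nrow(e) > 0) {
    rec <- paste0("entry#", seq_len(nrow(e)))
    miss_p <- !e$participant_id %in% p$participant_id
    if (any(miss_p)) {
      v[[length(v) + 1]] <- add("entries", rec[miss_p], "participant-ref",
        sprintf("entry %s: unknown participant_id '%s'",
                rec[miss_p], e$participant_id[miss_p]))
    }
    miss_f <- !e$food_code %in% f$food_code
    if (any(miss_f)) {
      v[[length(v) + 1]] <- add("entries", rec[miss_f], "food-ref",
        sprintf("entry %s: unknown food_code '%s'",
                rec[miss_f], e$food_code[miss_f]))
    }
    bad_amt <- is.na(e$amount_g) | e$amount_g < 0
    if (any(bad_amt)) {
      v[[length(v) + 1]] <- add("entries", rec[bad_amt], "non-negative-amount",
        sprintf("entry %s: amount_g must be >= 0", rec[bad_amt]))
    }
    days <- setNames(p$diary_days, p$participant_id)
    known <- !miss_p
    bad_day <- known & (is.na(e$day_index) | e$day_index < 1 |
                          e$day_index > days[e$participant_id])
    if (any(bad_day)) {
      v[[length(v) + 1]] <- add("entries", rec[bad_day], "day-range",
        sprintf("entry %s: day_index %d outside [1, %d] for participant '%s'",
                rec[bad_day], e$day_index[bad_day],
                days[e$participant_id[bad_day]], e$participant_id[bad_day]))
    }
  }

  if (length(v) == 0) {
    tibble::tibble(table = character(), record = character(),
                   rule = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}
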