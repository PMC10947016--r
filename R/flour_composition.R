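#' White-flour fibre composition profile
#'
#' Quantitative model of the dietary fibre fraction of white wheat flour.
#' Five components are tracked — arabinoxylan (AX), beta-glucan, fructans,
#' cellulose and arabinogalactan peptide (AGP) — each with a content in %
#' dry weight and a water-soluble fraction in \[0, 1\]. Where the literature
#' reports a range rather than a point (fructans content, cellulose content,
#' AX solubility), the profile stores the `(lo, hi)` interval and every
#' downstream computation takes an evaluation point: `"lo"`, `"mid"`
#' (default) or `"hi"`.
#'
#' Defaults reflect typical white flour: AX 1.9% dw (varietal range
#' 1.35--2.75) with 25--50% water-soluble, beta-glucan 0.2% (30% soluble),
#' fructans 1.5--1.7% (fully soluble), cellulose below 0.1% (insoluble) and
#' AGP 0.3% (fully soluble). Resistant starch (about 1% DM in white bread)
#' is deliberately excluded from the profile.
#'
#' @param arabinoxylan,beta_glucan,fructans,cellulose,agp Content in % dry
#'   weight: a single value or a `c(lo, hi)` range.
#' @param sol_arabinoxylan,sol_beta_glucan,sol_fructans,sol_cellulose,sol_agp
#'   Water-soluble fraction in \[0, 1\]: a single value or a range.
#' @return A tibble of class `flour_fibre_profile` with one row per
#'   component and columns `component`, `content_lo`, `content_hi`,
#'   `soluble_lo`, `soluble_hi`.
#' @export
#' @examples
#' p <- flour_fibre_profile()
#' total_fibre(p)            # about 4% dry weight
#' soluble_fraction(p)       # percent of total fibre that is soluble
flour_fibre_profile <- function(arabinoxylan = 1.9,
                                beta_glucan = 0.2,
                                fructans = c(1.5, 1.7),
                                cellulose = c(0, 0.1),
                                agp = 0.3,
                                sol_arabinoxylan = c(0.25, 0.50),
                                sol_beta_glucan = 0.30,
                                sol_fructans = 1.0,
                                sol_cellulose = 0.0,
                                sol_agp = 1.0) {
  as_range <- function(x, what, upper = Inf) {
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || any(is.na(x)) || x[1] > x[2] ||
        x[1] < 0 || x[2] > upper) {
      stop(what, " must be a value or c(lo, hi) within [0, ",
           upper, "]", call. = FALSE)
    }
    x
  }
  comp <- c("arabinoxylan", "beta_glucan", "fructans", "cellulose", "agp")
  contents <- list(as_range(arabinoxylan, "arabinoxylan"),
                   as_range(beta_glucan, "beta_glucan"),
                   as_range(fructans, "fructans"),
                   as_range(cellulose, "cellulose"),
                   as_range(agp, "agp"))
  sols <- list(as_range(sol_arabinoxylan, "sol_arabinoxylan", 1),
               as_range(sol_beta_glucan, "sol_beta_glucan", 1),
               as_range(sol_fructans, "sol_fructans", 1),
               as_range(sol_cellulose, "sol_cellulose", 1),
               as_range(sol_agp, "sol_agp", 1))
  p <- tibble::tibble(
    component = comp,
    content_lo = vapply(contents, `[`, numeric(1), 1),
    content_hi = vapply(contents, `[`, numeric(1), 2),
    soluble_lo = vapply(sols, `[`, numeric(1), 1),
    soluble_hi = vapply(sols, `[`, numeric(1), 2)
  )
  class(p) <- c("flour_fibre_profile", class(p))
  p
}

eval_point <- function(lo, hi, point = c("mid", "lo", "hi")) {
  point <- match.arg(point)
  switch(point, lo = lo, hi = hi, mid = (lo + hi) / 2)
}

#' Component contents of a profile at an evaluation point
#' @param p A [flour_fibre_profile()].
#' @param point `"lo"`, `"mid"` (default) or `"hi"` for range-valued entries.
#' @return Named numeric vector of contents in % dry weight.
#' @export
component_contents <- function(p, point = "mid") {
  stopifnot(inherits(p, "flour_fibre_profile"))
  setNames(eval_point(p$content_lo, p$content_hi, point), p$component)
}

#' Total dietary fibre of a flour profile
#'
#' Sum of the five component contents, in % dry weight.
#' @inheritParams component_contents
#' @return Total fibre, % dry weight.
#' @export
total_fibre <- function(p, point = "mid") {
  sum(component_contents(p, point))
}

#' Soluble share of total flour fibre
#'
#' `100 * sum(content_i * soluble_i) / total`, i.e. the percentage of the
#' total fibre that is water-soluble. `ax_solubility` selects the
#' evaluation point for the arabinoxylan solubility range independently of
#' `point`, since AX solubility is the dominant and most uncertain term.
#'
#' @inheritParams component_contents
#' @param ax_solubility Evaluation point for the AX solubility range;
#'   defaults to `point`.
#' @return Percentage of total fibre that is soluble, in \[0, 100\].
#' @export
soluble_fraction <- function(p, point = "mid", ax_solubility = point) {
  stopifnot(inherits(p, "flour_fibre_profile"))
  contents <- component_contents(p, point)
  total <- sum(contents)
  if (total <= 0) stop("total fibre must be positive", call. = FALSE)
  sol <- setNames(eval_point(p$soluble_lo, p$soluble_hi, point), p$component)
  sol["arabinoxylan"] <- eval_point(
    p$soluble_lo[p$component == "arabinoxylan"],
    p$soluble_hi[p$component == "arabinoxylan"],
    ax_solubility
  )
  100 * sum(contents * sol) / total
}

#' Substitute the arabinoxylan content of a profile
#'
#' Replaces the AX content with a target value (the breeding target raises
#' it from below 2% to about 4% dry weight), leaving every other component
#' unchanged, so total fibre changes by exactly `ax_target - ax_current`.
#'
#' @param p A [flour_fibre_profile()].
#' @param ax_target Target AX content, % dry weight (>= 0).
#' @param point Evaluation point used to report totals.
#' @return A list with `profile` (the new profile), `old_total`,
#'   `new_total` (% dry weight at `point`).
#' @export
#' @examples
#' p <- flour_fibre_profile(arabinoxylan = 2.0, fructans = 1.5,
#'                          cellulose = 0)  # total 4.0
#' apply_ax_scenario(p, ax_target = 4.0)$new_total  # 6.0
apply_ax_scenario <- function(p, ax_target, point = "mid") {
  stopifnot(inherits(p, "flour_fibre_profile"))
  if (is.na(ax_target) || ax_target < 0) {
    stop("ax_target must be >= 0", call. = FALSE)
  }
  old_total <- total_fibre(p, point)
  ax_current <- component_contents(p, point)[["arabinoxylan"]]
  new <- p
  new$content_lo[new$component == "arabinoxylan"] <- ax_target
  new$content_hi[new$component == "arabinoxylan"] <- ax_target
  list(
    profile = new,
    old_total = old_total,
    new_total = old_total + (ax_target - ax_current)
  )
}

#' Water absorbed by arabinoxylan fractions
#'
#' Arabinoxylan binds about 10 times its own dry weight of water for the
#' water-insoluble fraction and 11 times for the water-soluble fraction;
#' this matters for bakers because it drives flour water absorption.
#'
#' @param ax_insoluble_g,ax_soluble_g Dry weights in grams (>= 0).
#' @return Grams of water absorbed.
#' @export
water_absorption <- function(ax_insoluble_g, ax_soluble_g) {
  if (any(is.na(c(ax_insoluble_g, ax_soluble_g))) ||
      any(c(ax_insoluble_g, ax_soluble_g) < 0)) {
    stop("arabinoxylan fractions must be >= 0", call. = FALSE)
  }
  10 * ax_insoluble_g + 11 * ax_soluble_g
}
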