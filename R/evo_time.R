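# Back-of-the-envelope comparison of evolutionary opportunity: reproductive
# events of the gut microbiota of one person versus reproductive events of
# the whole pre-agricultural human population, plus hunter-gatherer vs
# modern-US dietary-fiber ratios.

#' Parameters for the reproductive-events comparison
#'
#' Defaults: ~1.1e13 bacterial cells produced per day in one human gut, a
#' 79-year human lifespan, and a pre-agricultural human population of about
#' 5 million females bearing 4.4 offspring over a 27-year generation.  The
#' year is fixed at 365 days by default.
#'
#' @param daily_bacterial_cells Bacterial cells produced per gut per day.
#' @param lifespan_years Human lifespan in years.
#' @param days_per_year Days per year (365 by default).
#' @param n_females Number of reproducing females in the reference
#'   population.
#' @param offspring_per_female Offspring per female per generation.
#' @param generation_years Generation time in years.
#' @param universe_age_years Age of the universe in years.
#' @return A list of class `repro_params`.
#' @export
repro_params <- function(daily_bacterial_cells = 1.1e13,
                         lifespan_years = 79,
                         days_per_year = 365,
                         n_females = 5e6,
                         offspring_per_female = 4.4,
                         generation_years = 27,
                         universe_age_years = 13.8e9) {
  p <- as.list(environment())
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  TRUE)))
    stop("all parameters must be single positive numbers")
  structure(p, class = "repro_params")
}

#' Human births per day in the reference population
#'
#' `n_females * offspring_per_female / (generation_years * days_per_year)`.
#' At the defaults this is about 2232 births/day.
#'
#' @param params A [repro_params()].
#' @return Births per day.
#' @export
human_births_per_day <- function(params = repro_params()) {
  with(params, n_females * offspring_per_female /
         (generation_years * days_per_year))
}

#' Bacterial reproductive events over one human lifetime
#'
#' `daily_bacterial_cells * days_per_year * lifespan_years`; about
#' 3.17e17 at the defaults.
#'
#' @inheritParams human_births_per_day
#' @return Event count.
#' @export
lifetime_bacterial_events <- function(params = repro_params()) {
  with(params, daily_bacterial_cells * days_per_year * lifespan_years)
}

#' Years of human reproduction matching one lifetime of gut bacteria
#'
#' The time the reference human population would need to accumulate as
#' many reproductive events as one person's gut microbiota accumulates in
#' one lifetime: about 3.9e11 years at the defaults.
#'
#' @inheritParams human_births_per_day
#' @return Years.
#' @export
years_for_equal_events <- function(params = repro_params()) {
  b <- human_births_per_day(params)
  if (b <= 0) stop("zero human birth rate")
  lifetime_bacterial_events(params) / (b * params$days_per_year)
}

#' Equivalent reproduction time as a multiple of the universe's age
#' @inheritParams human_births_per_day
#' @return Dimensionless multiple (about 28 at the defaults).
#' @export
universe_age_multiple <- function(params = repro_params()) {
  years_for_equal_events(params) / params$universe_age_years
}

#' Full reproductive-events comparison
#'
#' @inheritParams human_births_per_day
#' @return A list of class `repro_comparison` with
#'   `lifetime_bacterial_events`, `human_births_per_day`,
#'   `years_equivalent`, and `universe_age_multiple`.  These satisfy
#'   `years_equivalent * human_births_per_day * days_per_year =
#'   lifetime_bacterial_events` to relative 1e-12.
#' @export
repro_comparison <- function(params = repro_params()) {
  structure(list(lifetime_bacterial_events = lifetime_bacterial_events(params),
                 human_births_per_day = human_births_per_day(params),
                 years_equivalent = years_for_equal_events(params),
                 universe_age_multiple = universe_age_multiple(params),
                 params = params),
            class = "repro_comparison")
}

#' @export
print.repro_comparison <- function(x, ...) {
  cat("Reproductive-events comparison\n")
  cat(sprintf("  gut bacterial events per lifetime : %.4g\n",
              x$lifetime_bacterial_events))
  cat(sprintf("  human births per day              : %.0f\n",
              x$human_births_per_day))
  cat(sprintf("  years for equal human events      : %.4g\n",
              x$years_equivalent))
  cat(sprintf("  multiples of the universe's age   : %.1f\n",
              x$universe_age_multiple))
  invisible(x)
}

#' Hunter-gatherer versus US dietary-fiber parameters
#'
#' Defaults: 80-150 g/day for hunter-gatherer diets against 20 g/day for
#' the average US diet.
#'
#' @param hg_fiber_low,hg_fiber_high Hunter-gatherer daily fiber intake
#'   bounds (g/day).
#' @param us_fiber US daily fiber intake (g/day).
#' @return A list of class `fiber_params`.
#' @export
fiber_params <- function(hg_fiber_low = 80, hg_fiber_high = 150,
                         us_fiber = 20) {
  stopifnot(hg_fiber_low > 0, hg_fiber_high >= hg_fiber_low, us_fiber > 0)
  structure(list(hg_fiber_low = hg_fiber_low, hg_fiber_high = hg_fiber_high,
                 us_fiber = us_fiber), class = "fiber_params")
}

#' Fiber intake ratios and loss percentages
#'
#' Ratios of hunter-gatherer to US fiber intake at both bounds, and the
#' corresponding percentage losses `100 * (1 - us / hg)`.  At the defaults
#' the ratios are 4.0 and 7.5 and the losses 75% and 86.7%; note that both
#' loss figures are computed from the same three intake values, with no
#' additional inputs.
#'
#' @param params A [fiber_params()].
#' @return A list with `ratio_low`, `ratio_high`, `loss_low_pct`,
#'   `loss_high_pct`.
#' @export
fiber_ratios <- function(params = fiber_params()) {
  with(params, list(ratio_low = hg_fiber_low / us_fiber,
                    ratio_high = hg_fiber_high / us_fiber,
                    loss_low_pct = 100 * (1 - us_fiber / hg_fiber_low),
                    loss_high_pct = 100 * (1 - us_fiber / hg_fiber_high)))
}
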