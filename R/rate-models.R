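#' Leaf rate models
#'
#' Every basic factor of a non-adherence tree carries a rate model describing
#' how often the factor fires, in events per day. Four forms are supported:
#'
#' \describe{
#'   \item{constant}{a fixed hazard \code{rate} per day (the usual case for a
#'     pooled WNAR).}
#'   \item{linear_decay}{a hazard that starts at \code{initial_rate} and loses
#'     \code{decay_fraction_per_day} of the initial value for every whole
#'     elapsed day, floored at zero. Used for factors that fade as a study
#'     team learns, e.g. lack of prior adherence knowledge.}
#'   \item{repairable}{an alternating up/down subsystem: exponential time to
#'     failure at \code{failure_rate} per day, then down for a fixed
#'     \code{mean_repair_time} (hours). Such leaves are resolved by the
#'     simulator's availability process, not by a single hazard.}
#'   \item{age_stratified}{a per-band hazard with cohort band weights; the
#'     population-averaged hazard is the weight-weighted mean.}
#' }
#'
#' @param rate,initial_rate,failure_rate hazards in events per day, `>= 0`.
#' @param decay_fraction_per_day fraction of the initial rate lost per elapsed
#'   day, in `[0, 1]`.
#' @param mean_repair_time repair duration in hours, `> 0`.
#' @param bands a data frame with columns `label`, `rate` (per day) and
#'   `weight`; weights must be non-negative and sum to 1 (within 1e-9).
#' @return an object of class `nata_rate`.
#' @examples
#' rate_constant(0.006)
#' rate_linear_decay(1.5e-4, 0.08)
#' rate_repairable(8.12e-5, 4)
#' rate_age_stratified(data.frame(
#'   label = c("<25", "25-45", ">45"),
#'   rate = c(4.138e-4, 1.379e-4, 2.069e-4),
#'   weight = rep(1 / 3, 3)))
#' @name rate_models
NULL

new_rate <- function(form, ...) {
  structure(list(form = form, ...), class = "nata_rate")
}

#' @rdname rate_models
#' @export
rate_constant <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 0) stop("constant rate must be >= 0", call. = FALSE)
  new_rate("constant", rate = as.numeric(rate))
}

#' @rdname rate_models
#' @export
rate_linear_decay <- function(initial_rate, decay_fraction_per_day) {
  stopifnot(is.numeric(initial_rate), is.numeric(decay_fraction_per_day))
  if (initial_rate < 0) stop("initial_rate must be >= 0", call. = FALSE)
  if (decay_fraction_per_day < 0 || decay_fraction_per_day > 1)
    stop("decay_fraction_per_day must lie in [0, 1]", call. = FALSE)
  new_rate("linear_decay",
           initial_rate = as.numeric(initial_rate),
           decay_fraction_per_day = as.numeric(decay_fraction_per_day))
}

#' @rdname rate_models
#' @export
rate_repairable <- function(failure_rate, mean_repair_time) {
  stopifnot(is.numeric(failure_rate), is.numeric(mean_repair_time))
  if (failure_rate < 0) stop("failure_rate must be >= 0", call. = FALSE)
  if (mean_repair_time <= 0) stop("mean_repair_time must be > 0", call. = FALSE)
  new_rate("repairable",
           failure_rate = as.numeric(failure_rate),
           mean_repair_time = as.numeric(mean_repair_time))
}

#' @rdname rate_models
#' @export
rate_age_stratified <- function(bands) {
  bands <- as.data.frame(bands)
  need <- c("label", "rate", "weight")
  if (!all(need %in% names(bands)))
    stop("age_stratified bands need columns label, rate, weight", call. = FALSE)
  if (any(bands$rate < 0)) stop("band rates must be >= 0", call. = FALSE)
  if (any(bands$weight < 0)) stop("band weights must be >= 0", call. = FALSE)
  if (abs(sum(bands$weight) - 1) > 1e-9)
    stop("band weights must sum to 1", call. = FALSE)
  bands$label <- as.character(bands$label)
  new_rate("age_stratified", bands = bands)
}

#' Effective per-day hazard of a rate model at a given elapsed time
#'
#' Reduces a rate model to a single per-day hazard at elapsed time `day`
#' (days since regimen start, day 0 covering the first dosing day).
#' Constant models return their rate; linear-decay models return
#' `max(0, initial_rate * (1 - decay_fraction_per_day * floor(day)))`;
#' age-stratified models return the population-averaged hazard
#' `sum(weight * rate)`. Repairable models have no single-hazard reduction
#' (their behaviour is an availability process handled by
#' [simulate_cohort()]): for them the failure rate is returned with
#' attribute `availability_caveat = TRUE`.
#'
#' @param model a `nata_rate`.
#' @param day elapsed time in days, `>= 0`.
#' @return hazard in events per day.
#' @examples
#' effective_rate(rate_constant(0.006), 7)
#' effective_rate(rate_linear_decay(1.5e-4, 0.08), 20)  # floored at 0
#' @export
effective_rate <- function(model, day) {
  stopifnot(inherits(model, "nata_rate"), is.numeric(day), length(day) == 1L)
  if (day < 0) stop("day must be >= 0", call. = FALSE)
  switch(model$form,
    constant = model$rate,
    linear_decay = max(0, model$initial_rate *
                         (1 - model$decay_fraction_per_day * floor(day))),
    age_stratified = sum(model$bands$weight * model$bands$rate),
    repairable = structure(model$failure_rate, availability_caveat = TRUE),
    stop("unknown rate model form: ", model$form, call. = FALSE))
}

#' @export
print.nata_rate <- function(x, ...) {
  p <- switch(x$form,
    constant = sprintf("rate = %g/day", x$rate),
    linear_decay = sprintf("initial = %g/day, decay = %g of initial per day",
                           x$initial_rate, x$decay_fraction_per_day),
    repairable = sprintf("failure = %g/day, repair = %g h",
                         x$failure_rate, x$mean_repair_time),
    age_stratified = paste(sprintf("%s: %g/day (w=%.3g)", x$bands$label,
                                   x$bands$rate, x$bands$weight),
                           collapse = "; "))
  cat(sprintf("<nata_rate %s> %s\n", x$form, p))
  invisible(x)
}
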