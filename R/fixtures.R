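#' Bundled example inputs
#'
#' Three inputs ship with the package:
#' \describe{
#'   \item{`"scenario"`}{a three-factor illustrative tree (forgetfulness,
#'     side effects, other under a single OR gate) with per-day rates
#'     0.006 / 0.004 / 0.010.}
#'   \item{`"covid_tree"`}{the COVID-19 antiviral case-study tree: the top
#'     event over the five WHO adherence dimensions, twelve basic factors
#'     including an AND-gated pair of repairable medicine-delivery
#'     subsystems, a decaying prior-knowledge factor and an age-stratified
#'     social-support factor.}
#'   \item{`"six_studies"`}{raw per-factor non-adherent counts from six
#'     oseltamivir adherence studies (NoP 201, 33, 331, 313, 326, 246),
#'     stored as integers so every derived rate is genuinely recomputed.}
#' }
#'
#' @param name which fixture.
#' @return path to the installed file.
#' @examples
#' nat_read(nata_example("scenario"))
#' @export
nata_example <- function(name = c("scenario", "covid_tree", "six_studies")) {
  name <- match.arg(name)
  file <- c(scenario = "scenario.yaml", covid_tree = "covid_tree.yaml",
            six_studies = "six_studies.csv")[[name]]
  path <- system.file("extdata", file, package = "natar")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Generate synthetic study tables with known true rates
#'
#' Draws per-study non-adherent counts from the same generative model the
#' rate estimators assume: a factor with true per-day hazard `r` observed
#' over `DoM` days yields `Binomial(NoP, 1 - exp(-r * DoM))` non-adherent
#' participants. Used for parameter-recovery and property tests: WNAR
#' estimated from large synthetic studies converges to the generating rate.
#'
#' @param n_studies number of studies to draw.
#' @param nop_range integer range (length 2) for participants per study.
#' @param dom_range integer range (length 2) for regimen length in days.
#' @param true_rates named per-day hazard vector, factor id -> rate.
#' @param seed integer seed.
#' @return a `nata_studies` table.
#' @details If a draw would exceed the study's NoP (infeasible with the
#'   moderate hazards this model targets), counts are trimmed from the
#'   largest factor down until the total fits; rates for which the expected
#'   total exceeds NoP are rejected up front.
#' @examples
#' syn <- generate_synthetic_studies(3, c(200, 400), c(5, 10),
#'                                   c(SidEff = 8e-3, Forgot = 5e-3), seed = 1)
#' wnar(syn, "SidEff")
#' @export
generate_synthetic_studies <- function(n_studies, nop_range, dom_range,
                                       true_rates, seed = 1L) {
  stopifnot(n_studies >= 1, length(nop_range) == 2, length(dom_range) == 2,
            is.numeric(true_rates), length(true_rates) >= 1)
  if (is.null(names(true_rates)))
    stop("true_rates must be a named vector", call. = FALSE)
  if (any(true_rates < 0)) stop("rates must be >= 0", call. = FALSE)
  p_max <- sum(1 - exp(-true_rates * max(dom_range)))
  if (p_max > 1)
    stop("infeasible rates: expected non-adherent fraction ", round(p_max, 3),
         " exceeds 1", call. = FALSE)
  set.seed(seed)
  pick <- function(lo, hi) if (lo == hi) as.integer(lo)
                           else sample(lo:hi, 1L)
  rows <- list()
  for (i in seq_len(n_studies)) {
    nop <- pick(nop_range[1], nop_range[2])
    dom <- pick(dom_range[1], dom_range[2])
    p <- 1 - exp(-true_rates * dom)
    counts <- stats::rbinom(length(p), nop, p)
    while (sum(counts) > nop) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
    rows[[i]] <- data.frame(study_id = sprintf("SYN%d", i), NoP = nop,
                            DoM = dom, factor = names(true_rates),
                            count = counts)
  }
  as_studies(do.call(rbind, rows))
}
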