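#' Closed-form factor and gate probabilities
#'
#' For an exponentially distributed non-adherence factor with per-day hazard
#' `rate`, the probability of occurrence within `d` days is
#' `1 - exp(-rate * d)`. Gate combinations assume independent factors:
#' an OR gate has probability `1 - prod(1 - p_i)`, an AND gate `prod(p_i)`.
#'
#' @param rate per-day hazard, `>= 0`. Vectorised.
#' @param d duration in days, `>= 0`.
#' @param probs numeric vector of probabilities in `[0, 1]`.
#' @return a probability in `[0, 1]`.
#' @examples
#' p_naf_exponential(0.006, 10)              # 0.058235
#' p_or(p_naf_exponential(c(0.006, 0.004, 0.010), 10))  # 0.18127
#' @name gate_probabilities
NULL

#' @rdname gate_probabilities
#' @export
p_naf_exponential <- function(rate, d) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(d < 0)) stop("duration must be >= 0", call. = FALSE)
  -expm1(-rate * d)
}

check_probs <- function(probs) {
  if (!length(probs)) stop("need at least one probability", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  probs
}

#' @rdname gate_probabilities
#' @export
p_or <- function(probs) 1 - prod(1 - check_probs(probs))

#' @rdname gate_probabilities
#' @export
p_and <- function(probs) prod(check_probs(probs))

#' Priority-AND probability for exponential events
#'
#' Probability that `n` independent exponentially distributed events all
#' occur within `t` days *in the given order* (first element of `rates`
#' first). Uses the classical closed form for ordered exponential
#' occurrence: with partial hazard sums `a_0 = 0`,
#' `a_m = -(lambda_1 + ... + lambda_m)` taken over the events from last to
#' first,
#' \deqn{P = \prod_i \lambda_i \sum_{k=0}^{n}
#'       \frac{e^{a_k t}}{\prod_{j \ne k} (a_k - a_j)}.}
#' The form degenerates when two partial sums coincide; such inputs raise an
#' error suggesting a tiny rate perturbation.
#'
#' @param rates per-day hazards in required occurrence order; all `> 0`.
#' @param t duration in days, `>= 0`.
#' @return probability in `[0, 1]`; always `<=` [p_and()] of the same
#'   marginals (ordering restricts the joint event).
#' @examples
#' p_pand_exponential(0.006, 10)           # single event: exponential CDF
#' p_pand_exponential(c(0.01, 0.02), 10)   # 0.01-event first, then 0.02
#' @export
p_pand_exponential <- function(rates, t) {
  if (any(rates <= 0)) stop("all PAND rates must be > 0", call. = FALSE)
  if (t < 0) stop("duration must be >= 0", call. = FALSE)
  lambda <- rev(as.numeric(rates))  # closed form indexes last event first
  a <- c(0, -cumsum(lambda))
  if (min(abs(outer(a, a, "-")[lower.tri(diag(length(a)))])) < 1e-12)
    stop("degenerate PAND: coincident partial hazard sums; ",
         "perturb one rate slightly", call. = FALSE)
  terms <- vapply(seq_along(a), function(k) {
    exp(a[k] * t) / prod(a[k] - a[-k])
  }, 0)
  p <- prod(lambda) * sum(terms)
  if (p < -1e-9 || p > 1 + 1e-9)
    stop("numerical instability: PAND probability ", format(p),
         " outside [0, 1]", call. = FALSE)
  min(max(p, 0), 1)
}

#' Analytic top-event probability of a constant-rate tree
#'
#' Bottom-up closed-form evaluation: basic leaves via the exponential CDF
#' [p_naf_exponential()], OR/AND gates via [p_or()]/[p_and()], and PAND
#' gates (whose children must all be basic) via [p_pand_exponential()].
#' Exact for trees (no shared basic events) with independent,
#' constant-hazard leaves. Decaying, age-stratified or repairable leaves
#' have no closed form here and are rejected — use [simulate_cohort()] for
#' those.
#'
#' @param tree a `nat_tree` whose basic leaves are all `constant` rate
#'   models.
#' @param d duration in days, `>= 0`.
#' @return probability in `[0, 1]`, non-decreasing in `d` and in every leaf
#'   rate.
#' @examples
#' tr <- nat_read(nata_example("scenario"))
#' analytic_top_probability(tr, 10)  # 0.18127
#' @export
analytic_top_probability <- function(tree, d) {
  stopifnot(inherits(tree, "nat_tree"))
  if (d < 0) stop("duration must be >= 0", call. = FALSE)
  leaf_rate <- function(id) {
    r <- tree$nodes[[id]]$rate
    if (r$form != "constant")
      stop("analytic evaluation supports constant-rate leaves only; leaf '",
           id, "' has form '", r$form, "' - use simulate_cohort() instead",
           call. = FALSE)
    r$rate
  }
  eval_node <- function(id) {
    n <- tree$nodes[[id]]
    if (n$kind == "basic") return(p_naf_exponential(leaf_rate(id), d))
    if (n$gate == "PAND") {
      non_basic <- n$children[vapply(n$children, function(c_)
        tree$nodes[[c_]]$kind != "basic", TRUE)]
      if (length(non_basic))
        stop("PAND gate '", id, "' must have basic children for analytic ",
             "evaluation", call. = FALSE)
      return(p_pand_exponential(vapply(n$children, leaf_rate, 0), d))
    }
    probs <- vapply(n$children, eval_node, 0)
    if (n$gate == "OR") p_or(probs) else p_and(probs)
  }
  eval_node(tree$top)
}
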