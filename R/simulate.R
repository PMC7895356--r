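#' Simulation configuration
#'
#' @param patients cohort size (one simulated trajectory per patient).
#' @param days regimen length in days; one pill per day is assumed, and
#'   missing at least one pill makes a patient non-adherent.
#' @param timestep step length in hours; must divide 24.
#' @param seed integer seed; a run is fully reproducible from it.
#' @param replicates number of independent cohort runs (seeds
#'   `seed, seed + 1, ...`); use `> 1` for tolerance bands on stochastic
#'   summaries.
#' @return a `nata_sim_config`.
#' @export
sim_config <- function(patients = 1000, days = 10, timestep = 1, seed = 1L,
                       replicates = 1L) {
  stopifnot(patients >= 1, days >= 1, timestep > 0, replicates >= 1)
  if (abs(24 / timestep - round(24 / timestep)) > 1e-9)
    stop("timestep (hours) must divide 24", call. = FALSE)
  structure(list(patients = as.integer(patients), days = as.integer(days),
                 timestep = timestep, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "nata_sim_config")
}

# vectorised bottom-up truth evaluation over an occurrence matrix
eval_top_matrix <- function(tree, occ) {
  eval_node <- function(id) {
    n <- tree$nodes[[id]]
    if (n$kind == "basic") return(occ[, id])
    vals <- lapply(n$children, eval_node)
    if (n$gate == "OR") Reduce(`|`, vals) else Reduce(`&`, vals)
  }
  eval_node(tree$top)
}

run_cohort <- function(tree, patients, days, timestep, seed) {
  set.seed(seed)
  spd <- as.integer(round(24 / timestep))      # steps per day
  n_steps <- days * spd
  dt <- timestep / 24                          # step length in days
  basics <- basic_ids(tree)
  models <- lapply(basics, function(id) tree$nodes[[id]]$rate)
  names(models) <- basics
  forms <- vapply(models, `[[`, "", "form")
  haz_ids <- basics[forms != "repairable"]
  rep_ids <- basics[forms == "repairable"]
  nh <- length(haz_ids)
  nr <- length(rep_ids)

  # --- all stochastic inputs are drawn up front, in a fixed order, so two
  # runs with the same seed but scaled leaf rates share the same uniforms
  # per (patient, leaf, step): common random numbers for paired scenarios.

  # 1. per-patient hazards for age-stratified leaves (band membership)
  pat_rate <- vector("list", nh); names(pat_rate) <- haz_ids
  for (id in haz_ids) {
    m <- models[[id]]
    if (m$form == "age_stratified") {
      band <- sample.int(nrow(m$bands), patients, replace = TRUE,
                         prob = m$bands$weight)
      pat_rate[[id]] <- m$bands$rate[band]
    }
  }

  # 2. availability trajectories of repairable subsystems (system-level
  # alternating renewal: exponential time to failure, fixed repair duration)
  mids <- (seq_len(n_steps) - 0.5) * dt        # step midpoints, days
  down <- matrix(FALSE, n_steps, nr, dimnames = list(NULL, rep_ids))
  for (id in rep_ids) {
    m <- models[[id]]
    repair_days <- m$mean_repair_time / 24
    t_now <- 0
    while (m$failure_rate > 0) {
      fail_at <- t_now + stats::rexp(1L, m$failure_rate)
      if (fail_at >= days) break
      up_at <- fail_at + repair_days
      down[mids >= fail_at & mids < up_at, id] <- TRUE
      t_now <- up_at
    }
  }

  # 3. each patient's dosing step, uniform within each day
  dose_step <- matrix(sample.int(spd, patients * days, replace = TRUE),
                      patients, days)

  # 4. firing uniforms for every (patient, hazard leaf, step)
  U <- if (nh) array(stats::runif(patients * nh * n_steps),
                     dim = c(patients, nh, n_steps))

  # per-day firing probability matrix (patients x hazard leaves)
  day_probs <- function(d0) {
    P <- matrix(0, patients, nh, dimnames = list(NULL, haz_ids))
    for (id in haz_ids) {
      r <- if (!is.null(pat_rate[[id]])) pat_rate[[id]]
           else effective_rate(models[[id]], d0)
      P[, id] <- -expm1(-r * dt)
    }
    P
  }

  alive <- rep(TRUE, patients)
  occ <- matrix(FALSE, patients, length(basics),
                dimnames = list(NULL, basics))
  attributed <- rep(NA_character_, patients)
  disc_day <- rep(NA_integer_, patients)
  nac_by_day <- integer(days)
  cur_day <- -1L
  P <- NULL

  for (s in seq_len(n_steps)) {
    d0 <- (s - 1L) %/% spd                     # elapsed whole days
    if (d0 != cur_day) { P <- day_probs(d0); cur_day <- d0 }
    step_in_day <- (s - 1L) %% spd + 1L

    if (any(alive)) {
      fired <- if (nh) matrix(U[, , s] < P, patients, nh,
                              dimnames = list(NULL, haz_ids))
               else matrix(FALSE, patients, 0)
      # transient repairable occurrence: down at this patient's dosing step
      rep_now <- matrix(FALSE, patients, nr, dimnames = list(NULL, rep_ids))
      if (nr) {
        dosing <- alive & dose_step[, d0 + 1L] == step_in_day
        for (id in rep_ids) rep_now[dosing, id] <- down[s, id]
      }
      cand <- which(alive & (rowSums(fired) > 0 | rowSums(rep_now) > 0))
      if (length(cand)) {
        occ[cand, haz_ids] <- occ[cand, haz_ids, drop = FALSE] |
          fired[cand, , drop = FALSE]
        occ_now <- occ[cand, , drop = FALSE]
        if (nr) occ_now[, rep_ids] <- rep_now[cand, , drop = FALSE]
        hit <- eval_top_matrix(tree, occ_now)
        new_na <- cand[hit]
        for (i in new_na) {
          ids <- c(haz_ids[fired[i, ]], rep_ids[rep_now[i, ]])
          attributed[i] <- if (length(ids) == 1L) ids
                           else ids[sample.int(length(ids), 1L)]
        }
        alive[new_na] <- FALSE
        disc_day[new_na] <- d0 + 1L
      }
    }
    if (step_in_day == spd) nac_by_day[d0 + 1L] <- sum(!alive)
  }

  non_adherent <- sum(!alive)
  structure(list(
    patients = patients, days = days, timestep = timestep, seed = seed,
    nac_by_day = nac_by_day,
    p_na_by_day = nac_by_day / patients,
    non_adherent = non_adherent,
    adherent = patients - non_adherent,
    final_mean = non_adherent / patients,
    attributed = attributed,
    discontinuation_day = disc_day,
    dimension = dimension_map(tree)),
    class = "nata_sim")
}

#' Monte Carlo cohort simulation of a non-adherence tree
#'
#' Simulates one Bernoulli trajectory per patient over the regimen, stepping
#' hourly (or as configured). In each step an active constant, decaying or
#' age-stratified leaf fires with probability `1 - exp(-r(d) * dt)` (`dt` in
#' days), so the marginal occurrence distribution is exactly exponential and
#' results are step-size robust. Repairable leaves evolve as system-level
#' alternating renewal processes (exponential failures, fixed repair time);
#' they count as occurred for a patient only when down at that patient's
#' dosing step (assigned uniformly at random within each day). The first
#' step in which the tree's top event evaluates true absorbs the patient:
#' they are counted non-adherent, attributed to the leaf that fired in that
#' step (uniform tie-break if several), and no further events are sampled
#' for them.
#'
#' @param tree a `nat_tree` whose basic nodes all carry rate models.
#' @param config a [sim_config()].
#' @return with `replicates = 1`, a `nata_sim` with the daily cumulative
#'   non-adherent count (`nac_by_day`), the daily non-adherence probability
#'   (`p_na_by_day`, non-decreasing), totals, and per-patient attribution;
#'   with `replicates > 1`, a `nata_sim_ensemble` holding the individual
#'   runs and pooled summaries. Identical tree + config give bit-identical
#'   results.
#' @examples
#' tr <- nat_read(nata_example("scenario"))
#' sim <- simulate_cohort(tr, sim_config(patients = 500, seed = 42))
#' sim$final_mean
#' @export
simulate_cohort <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "nat_tree"), inherits(config, "nata_sim_config"))
  nat_validate(tree)
  if (config$replicates == 1L)
    return(run_cohort(tree, config$patients, config$days, config$timestep,
                      config$seed))
  runs <- lapply(seq_len(config$replicates) - 1L, function(k)
    run_cohort(tree, config$patients, config$days, config$timestep,
               config$seed + k))
  means <- vapply(runs, `[[`, 0, "final_mean")
  structure(list(
    runs = runs, patients = config$patients, days = config$days,
    replicates = config$replicates,
    final_mean = mean(means),
    final_mean_by_run = means,
    non_adherent = mean(vapply(runs, `[[`, 0, "non_adherent")),
    nac_by_day = Reduce(`+`, lapply(runs, `[[`, "nac_by_day")) /
      length(runs),
    p_na_by_day = Reduce(`+`, lapply(runs, `[[`, "p_na_by_day")) /
      length(runs),
    attributed = unlist(lapply(runs, `[[`, "attributed")),
    dimension = runs[[1L]]$dimension),
    class = "nata_sim_ensemble")
}

#' Uncertainty summary of a simulated cohort
#'
#' Treats each patient as a Bernoulli trial: `mean` is the non-adherent
#' fraction p, `sd` the per-patient standard deviation `sqrt(p(1-p))`, and
#' `ci5`/`ci95` the normal-approximation 5%/95% bounds of the cohort mean,
#' `p +/- 1.645 * sqrt(p(1-p)/n)`, clamped to `[0, 1]`.
#'
#' @param result a `nata_sim` or `nata_sim_ensemble`.
#' @return list with `mean`, `sd`, `ci5`, `ci95`.
#' @export
summarize_uncertainty <- function(result) {
  stopifnot(inherits(result, c("nata_sim", "nata_sim_ensemble")))
  n <- result$patients
  if (n < 1) stop("no patients simulated", call. = FALSE)
  p <- result$final_mean
  sd_b <- sqrt(p * (1 - p))
  half <- 1.645 * sd_b / sqrt(n)
  list(mean = p, sd = sd_b,
       ci5 = max(0, p - half), ci95 = min(1, p + half))
}

#' Factor contributions to discontinuation
#'
#' Shares of discontinuations attributed to each basic factor (the first
#' leaf that fired for each non-adherent patient), in percent, plus a
#' rollup to the top-level branches of the tree (the WHO adherence
#' dimensions in the bundled case study).
#'
#' @param result a `nata_sim` or `nata_sim_ensemble` with at least one
#'   discontinuation.
#' @return a `nata_contrib` list: `factor` (named percentage vector, summing
#'   to 100, sorted decreasing), `dimension` (rollup by top-level branch),
#'   `n_events`.
#' @export
contributions <- function(result) {
  stopifnot(inherits(result, c("nata_sim", "nata_sim_ensemble")))
  att <- result$attributed[!is.na(result$attributed)]
  if (!length(att))
    stop("contributions are undefined: no discontinuations occurred",
         call. = FALSE)
  shares <- sort(100 * table(att) / length(att), decreasing = TRUE)
  fac <- stats::setNames(as.numeric(shares), names(shares))
  dim_of <- result$dimension[att]
  dshares <- sort(100 * table(dim_of) / length(att), decreasing = TRUE)
  structure(list(factor = fac,
                 dimension = stats::setNames(as.numeric(dshares),
                                             names(dshares)),
                 n_events = length(att)),
            class = "nata_contrib")
}

#' Apply an intervention scenario to a tree
#'
#' Returns a copy of the tree with the named basic factors' rate parameters
#' scaled by `1 - reduction` — e.g. a 20% reduction in forgetfulness after
#' introducing a pillbox. Constant rates, decay initial rates, repairable
#' failure rates and all age-band rates are scaled; the original tree is
#' untouched.
#'
#' @param tree a `nat_tree`.
#' @param reductions named numeric vector, factor id -> fractional reduction
#'   in `[0, 1]`.
#' @return a new `nat_tree`.
#' @examples
#' tr <- nat_read(nata_example("covid_tree"))
#' better <- apply_improvement(tr, c(SidEff = 0.2, Forgot = 0.2))
#' @export
apply_improvement <- function(tree, reductions) {
  stopifnot(inherits(tree, "nat_tree"), is.numeric(reductions))
  if (is.null(names(reductions)) || any(!nzchar(names(reductions))))
    stop("reductions must be a named vector", call. = FALSE)
  if (any(reductions < 0 | reductions > 1))
    stop("reductions must lie in [0, 1]", call. = FALSE)
  for (id in names(reductions)) {
    n <- tree$nodes[[id]]
    if (is.null(n)) stop("unknown factor id: '", id, "'", call. = FALSE)
    if (n$kind != "basic")
      stop("'", id, "' is not a basic factor", call. = FALSE)
    keep <- 1 - reductions[[id]]
    r <- n$rate
    r <- switch(r$form,
      constant = { r$rate <- r$rate * keep; r },
      linear_decay = { r$initial_rate <- r$initial_rate * keep; r },
      repairable = { r$failure_rate <- r$failure_rate * keep; r },
      age_stratified = { r$bands$rate <- r$bands$rate * keep; r })
    tree$nodes[[id]]$rate <- r
  }
  tree
}

#' @export
print.nata_sim <- function(x, ...) {
  s <- summarize_uncertainty(x)
  cat(sprintf(paste0("<nata_sim> %d patients, %d days, %g h steps, seed %d\n",
                     "  P(NA) day %d: %.4f (sd %.3f, 5%%-95%% %.3f-%.3f); ",
                     "%d non-adherent\n"),
              x$patients, x$days, x$timestep, x$seed, x$days, s$mean, s$sd,
              s$ci5, s$ci95, x$non_adherent))
  invisible(x)
}

#' @export
print.nata_sim_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<nata_sim_ensemble> %d replicates x %d patients, ",
                     "%d days\n  pooled P(NA): %.4f ",
                     "(per-run range %.4f-%.4f)\n"),
              x$replicates, x$patients, x$days, x$final_mean,
              min(x$final_mean_by_run), max(x$final_mean_by_run)))
  invisible(x)
}

#' @export
print.nata_contrib <- function(x, ...) {
  cat(sprintf("<nata_contrib> %d discontinuations\n", x$n_events))
  for (f in names(x$factor))
    cat(sprintf("  %-8s %6.2f%%\n", f, x$factor[[f]]))
  cat("  by dimension:\n")
  for (d in names(x$dimension))
    cat(sprintf("  %-8s %6.2f%%\n", d, x$dimension[[d]]))
  invisible(x)
}
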