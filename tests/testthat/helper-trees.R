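# Builders and oracles shared across test files. All fixtures are built in
# code; the only on-disk inputs are the package's own extdata files.

# flat tree: basic leaves with constant rates under a single gate
flat_tree <- function(rates, gate = "OR", name = "flat") {
  ids <- names(rates)
  nodes <- c(list(nat_node("TOP", "top", gate = gate, children = ids)),
             lapply(ids, function(id)
               nat_node(id, "basic", rate = rate_constant(rates[[id]]))))
  nat_tree(nodes, name = name)
}

# random nested AND/OR tree over n constant-rate leaves (binary splits)
random_constant_tree <- function(n_leaves, rate_range = c(0.01, 0.08)) {
  leaf_rates <- stats::runif(n_leaves, rate_range[1], rate_range[2])
  ids <- sprintf("L%d", seq_len(n_leaves))
  nodes <- list()
  counter <- 0L
  build <- function(leaf_idx) {
    if (length(leaf_idx) == 1L) {
      id <- ids[leaf_idx]
      nodes[[id]] <<- nat_node(id, "basic",
                               rate = rate_constant(leaf_rates[leaf_idx]))
      return(id)
    }
    counter <<- counter + 1L
    gid <- sprintf("G%d", counter)
    cut <- sample(seq_len(length(leaf_idx) - 1L), 1L)
    kids <- c(build(leaf_idx[seq_len(cut)]),
              build(leaf_idx[-seq_len(cut)]))
    gate <- sample(c("OR", "OR", "AND"), 1L)  # OR-leaning, like real NATs
    nodes[[gid]] <<- nat_node(gid, "intermediate", gate = gate,
                              children = kids)
    gid
  }
  root <- build(seq_len(n_leaves))
  nodes[[root]]$kind <- "top"
  nat_tree(unname(nodes), name = "random")
}

# sampling oracle for ordered exponential occurrence: draws each event time
# directly and counts trajectories where all events fall in the given order
# within t. Never touches the analytic code.
mc_pand_oracle <- function(rates, t, n_draws = 1e5) {
  times <- vapply(rates, function(r) stats::rexp(n_draws, r),
                  numeric(n_draws))
  ordered <- rep(TRUE, n_draws)
  for (j in seq_len(length(rates) - 1L))
    ordered <- ordered & times[, j] < times[, j + 1L]
  hits <- ordered & times[, length(rates)] <= t
  list(p = mean(hits), se = stats::sd(hits) / sqrt(n_draws))
}

# DNF evaluation of a cut-set report under one Boolean assignment
mcs_predicts <- function(report, assignment) {
  any(vapply(report$cut_sets, function(s)
    all(assignment[s$members]), TRUE))
}

# all 2^n assignments over the given basic ids, as a logical matrix
all_assignments <- function(ids) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(ids))))
  colnames(m) <- ids
  m
}

scenario_tree <- function() nat_read(nata_example("scenario"))
covid_tree <- function() nat_read(nata_example("covid_tree"))
six_studies <- function() read_studies(nata_example("six_studies"))
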