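#' Minimal cut sets of a non-adherence tree
#'
#' A cut set is a set of basic factors whose joint occurrence triggers the
#' top event; a *minimal* cut set (MCS) is one from which no member can be
#' removed. Singleton cut sets are the single points of failure of the
#' regimen. Derivation is exact symbolic top-down expansion: an OR gate
#' concatenates its children's cut-set lists, an AND (or PAND) gate takes
#' pairwise unions across children, and the result is minimised under the
#' absorption law. PAND gates are treated as AND for minimality (the
#' sequence constraint only tightens probability, not logic); cut sets that
#' passed through a PAND are flagged `ordered` and keep their member order.
#'
#' @param tree a `nat_tree`.
#' @param max_products guard against combinatorial blow-up: expansion stops
#'   with an error if an intermediate product list exceeds this size.
#' @return a `nata_mcs` list: `cut_sets` — a list of
#'   `list(members, ordered)`, sorted by size then lexicographically;
#'   `single_points` — character vector of singleton cut-set members.
#' @examples
#' tr <- nat_read(nata_example("covid_tree"))
#' minimal_cut_sets(tr)
#' @export
minimal_cut_sets <- function(tree, max_products = 2^20) {
  stopifnot(inherits(tree, "nat_tree"))
  expand <- function(id) {
    n <- tree$nodes[[id]]
    if (n$kind == "basic")
      return(list(list(members = id, ordered = FALSE)))
    kid_sets <- lapply(n$children, expand)
    if (n$gate == "OR") {
      out <- do.call(c, kid_sets)
    } else {  # AND / PAND: cross-product unions
      out <- kid_sets[[1L]]
      for (ks in kid_sets[-1L]) {
        if (length(out) * length(ks) > max_products)
          stop("cut-set expansion exceeds ", max_products,
               " intermediate products", call. = FALSE)
        out <- unlist(lapply(out, function(a) lapply(ks, function(b)
          list(members = unique(c(a$members, b$members)),
               ordered = a$ordered || b$ordered))), recursive = FALSE)
      }
      if (n$gate == "PAND")
        out <- lapply(out, function(s) { s$ordered <- TRUE; s })
    }
    if (length(out) > max_products)
      stop("cut-set expansion exceeds ", max_products,
           " intermediate products", call. = FALSE)
    out
  }
  sets <- expand(tree$top)
  # absorption: drop any set that contains another as a subset
  sizes <- vapply(sets, function(s) length(s$members), 0L)
  sets <- sets[order(sizes)]
  kept <- list()
  for (s in sets) {
    absorbed <- any(vapply(kept, function(k)
      all(k$members %in% s$members), TRUE))
    if (!absorbed) kept[[length(kept) + 1L]] <- s
  }
  keyed <- vapply(kept, function(s)
    sprintf("%06d|%s", length(s$members),
            paste(sort(s$members), collapse = ",")), "")
  kept <- kept[order(keyed)]
  singles <- unlist(lapply(kept, function(s)
    if (length(s$members) == 1L) s$members))
  structure(list(cut_sets = kept,
                 single_points = as.character(singles)),
            class = "nata_mcs")
}

#' Evaluate the top event under a Boolean assignment
#'
#' Bottom-up Boolean evaluation of the tree: basic nodes take their assigned
#' truth value, OR/AND gates combine children, and PAND is evaluated as AND
#' (occurrence, not order). Used as the truth-table oracle for cut-set
#' derivations.
#'
#' @param tree a `nat_tree`.
#' @param assignment named logical vector covering every basic id.
#' @return logical: is the top event triggered?
#' @export
evaluate_truth <- function(tree, assignment) {
  stopifnot(inherits(tree, "nat_tree"))
  basics <- basic_ids(tree)
  missing <- setdiff(basics, names(assignment))
  if (length(missing))
    stop("assignment missing basic id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  eval_node <- function(id) {
    n <- tree$nodes[[id]]
    if (n$kind == "basic") return(isTRUE(as.logical(assignment[[id]])))
    vals <- vapply(n$children, eval_node, TRUE)
    if (n$gate == "OR") any(vals) else all(vals)
  }
  eval_node(tree$top)
}

#' @export
print.nata_mcs <- function(x, ...) {
  cat(sprintf("<nata_mcs> %d minimal cut sets, %d single points of failure\n",
              length(x$cut_sets), length(x$single_points)))
  for (s in x$cut_sets)
    cat("  {", paste(s$members, collapse = if (s$ordered) " < " else ", "),
        "}\n", sep = "")
  invisible(x)
}
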