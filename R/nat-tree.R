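#' Build a non-adherence tree node
#'
#' A non-adherence tree (NAT) is a fault-tree-style hierarchy: the top event
#' is discontinuation of the medication regimen, intermediate nodes group
#' factors (typically the five WHO adherence dimensions), and basic nodes are
#' the non-adherence factors (NAFs) that can actually fire. Gates are `AND`,
#' `OR` or `PAND` (Priority-AND: all children in the listed order).
#'
#' @param id short unique token, e.g. `"SidEff"`. Case-sensitive.
#' @param kind one of `"basic"`, `"intermediate"`, `"top"`.
#' @param label free-text description; defaults to the id.
#' @param gate gate kind for non-basic nodes (`"AND"`, `"OR"`, `"PAND"`).
#' @param children character vector of child ids (ordered; order is
#'   significant under a PAND gate).
#' @param rate a [rate_models] object; required for basic nodes.
#' @return a `nata_node` list.
#' @seealso [nat_tree()], [nat_read()]
#' @export
nat_node <- function(id, kind, label = id, gate = NULL, children = NULL,
                     rate = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, c("basic", "intermediate", "top"))
  if (!is.null(gate)) gate <- match.arg(gate, c("AND", "OR", "PAND"))
  structure(list(id = id, label = label, kind = kind, gate = gate,
                 children = as.character(children), rate = rate),
            class = "nata_node")
}

#' Assemble and validate a non-adherence tree
#'
#' @param nodes list of [nat_node()] objects.
#' @param name free-text name for the tree.
#' @return a validated `nat_tree`: a list with `nodes` (id-keyed list),
#'   `top` (id of the top event) and `name`.
#' @details Validation enforces: exactly one `top` node; every referenced
#'   child exists; each non-top node has exactly one parent; all nodes are
#'   reachable from the top (so the id graph is a tree); basic nodes have a
#'   rate model and no children; non-basic nodes have at least one child, a
#'   gate, and no rate model.
#' @export
nat_tree <- function(nodes, name = "") {
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("structural error: repeated node id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(nodes) <- ids
  tops <- ids[vapply(nodes, function(n) n$kind == "top", TRUE)]
  if (length(tops) != 1L)
    stop("validation error: exactly one node must have kind = 'top' (found ",
         length(tops), ")", call. = FALSE)
  tree <- structure(list(nodes = nodes, top = tops, name = name),
                    class = "nat_tree")
  nat_validate(tree)
  tree
}

nat_validate <- function(tree) {
  nodes <- tree$nodes
  ids <- names(nodes)
  all_children <- unlist(lapply(nodes, `[[`, "children"), use.names = FALSE)
  missing <- setdiff(all_children, ids)
  if (length(missing))
    stop("structural error: child id(s) not defined: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(all_children))
    stop("structural error: node(s) with more than one parent: ",
         paste(unique(all_children[duplicated(all_children)]), collapse = ", "),
         call. = FALSE)
  if (tree$top %in% all_children)
    stop("structural error: top node '", tree$top, "' appears as a child",
         call. = FALSE)
  for (n in nodes) {
    if (n$kind == "basic") {
      if (length(n$children))
        stop("validation error: basic node '", n$id, "' has children",
             call. = FALSE)
      if (!inherits(n$rate, "nata_rate"))
        stop("validation error: basic node '", n$id, "' is missing a rate ",
             "model", call. = FALSE)
    } else {
      if (!length(n$children))
        stop("validation error: node '", n$id, "' has no children",
             call. = FALSE)
      if (is.null(n$gate))
        stop("validation error: node '", n$id, "' has no gate", call. = FALSE)
      if (!is.null(n$rate))
        stop("validation error: non-basic node '", n$id,
             "' carries a rate model", call. = FALSE)
    }
  }
  # reachability from top (single-parent + full coverage => acyclic tree)
  seen <- character(0)
  stack <- tree$top
  while (length(stack)) {
    id <- stack[[1L]]; stack <- stack[-1L]
    if (id %in% seen)
      stop("structural error: cycle detected at node '", id, "'",
           call. = FALSE)
    seen <- c(seen, id)
    stack <- c(nodes[[id]]$children, stack)
  }
  unreached <- setdiff(ids, seen)
  if (length(unreached))
    stop("structural error: node(s) unreachable from top: ",
         paste(unreached, collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Basic-factor ids of a tree
#' @param tree a `nat_tree`.
#' @return character vector of basic node ids, in depth-first order from the
#'   top event.
#' @export
basic_ids <- function(tree) {
  out <- character(0)
  walk <- function(id) {
    n <- tree$nodes[[id]]
    if (n$kind == "basic") out[[length(out) + 1L]] <<- id
    else for (c_ in n$children) walk(c_)
  }
  walk(tree$top)
  out
}

# id of the top-level branch (e.g. WHO dimension) each basic factor sits under
dimension_map <- function(tree) {
  top_children <- tree$nodes[[tree$top]]$children
  map <- character(0)
  for (dim_id in top_children) {
    walk <- function(id) {
      n <- tree$nodes[[id]]
      if (n$kind == "basic") map[[id]] <<- dim_id
      else for (c_ in n$children) walk(c_)
    }
    walk(dim_id)
  }
  map
}

node_to_spec <- function(n) {
  out <- list(id = n$id, label = n$label, kind = n$kind)
  if (!is.null(n$gate)) out$gate <- n$gate
  if (length(n$children)) out$children <- as.list(n$children)
  if (!is.null(n$rate)) {
    r <- n$rate
    out$rate <- switch(r$form,
      constant = list(form = "constant", rate = r$rate),
      linear_decay = list(form = "linear_decay", initial_rate = r$initial_rate,
                          decay_fraction_per_day = r$decay_fraction_per_day),
      repairable = list(form = "repairable", failure_rate = r$failure_rate,
                        mean_repair_time = r$mean_repair_time),
      age_stratified = list(form = "age_stratified",
        bands = lapply(seq_len(nrow(r$bands)), function(i)
          list(label = r$bands$label[i], rate = r$bands$rate[i],
               weight = r$bands$weight[i]))))
  }
  out
}

spec_to_rate <- function(spec, id) {
  if (is.null(spec$form))
    stop("validation error: node '", id, "': rate model has no 'form'",
         call. = FALSE)
  tryCatch(switch(spec$form,
    constant = rate_constant(spec$rate),
    linear_decay = rate_linear_decay(spec$initial_rate,
                                     spec$decay_fraction_per_day),
    repairable = rate_repairable(spec$failure_rate, spec$mean_repair_time),
    age_stratified = rate_age_stratified(data.frame(
      label = vapply(spec$bands, function(b) as.character(b$label), ""),
      rate = vapply(spec$bands, function(b) as.numeric(b$rate), 0),
      weight = vapply(spec$bands, function(b) as.numeric(b$weight), 0))),
    stop("unknown rate form '", spec$form, "'", call. = FALSE)),
    error = function(e) stop("validation error: node '", id, "': ",
                             conditionMessage(e), call. = FALSE))
}

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
}

#' Read / write a non-adherence tree specification file
#'
#' Trees are stored in a small YAML (or isomorphic JSON) schema: top-level
#' keys `name`, `top`, and `nodes`, the latter a list of
#' `{id, label, kind, gate, children, rate}` maps where `rate` is
#' `{form, ...parameters}` (see [rate_models]). The writer emits keys in
#' that order, so files diff cleanly.
#'
#' @param path file path.
#' @param format `"yaml"`, `"json"`, or `"auto"` (by file extension).
#' @param tree a `nat_tree`.
#' @return `nat_read` returns a validated `nat_tree`; `nat_write` returns
#'   `path` invisibly. A round trip reproduces the tree node for node.
#' @examples
#' tr <- nat_read(nata_example("scenario"))
#' basic_ids(tr)
#' @export
nat_read <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- guess_format(path, format)
  spec <- if (fmt == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$nodes) || is.null(spec$top))
    stop("validation error: tree file needs 'top' and 'nodes' keys",
         call. = FALSE)
  nodes <- lapply(spec$nodes, function(ns) {
    if (is.null(ns$id)) stop("validation error: node without an id",
                             call. = FALSE)
    nat_node(id = as.character(ns$id),
             kind = if (is.null(ns$kind)) "basic" else ns$kind,
             label = if (is.null(ns$label)) as.character(ns$id) else ns$label,
             gate = ns$gate,
             children = unlist(ns$children),
             rate = if (!is.null(ns$rate)) spec_to_rate(ns$rate, ns$id))
  })
  tree <- nat_tree(nodes, name = if (is.null(spec$name)) "" else spec$name)
  if (tree$top != as.character(spec$top))
    stop("validation error: 'top' key (", spec$top,
         ") does not match the node with kind = 'top' (", tree$top, ")",
         call. = FALSE)
  tree
}

#' @rdname nat_read
#' @export
nat_write <- function(tree, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(tree, "nat_tree"))
  format <- match.arg(format)
  fmt <- guess_format(path, format)
  spec <- list(name = tree$name, top = tree$top,
               nodes = lapply(tree$nodes, node_to_spec))
  names(spec$nodes) <- NULL
  if (fmt == "json") {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path, precision = 12L)
  }
  invisible(path)
}

#' @export
print.nat_tree <- function(x, ...) {
  nb <- length(basic_ids(x))
  cat(sprintf("<nat_tree> %s\n  top: %s | %d nodes (%d basic factors)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$top, length(x$nodes), nb))
  walk <- function(id, depth) {
    n <- x$nodes[[id]]
    tag <- if (n$kind == "basic") n$rate$form else n$gate
    cat(sprintf("  %s%s [%s]\n", strrep("  ", depth), id, tag))
    for (c_ in n$children) walk(c_, depth + 1L)
  }
  walk(x$top, 0L)
  invisible(x)
}
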