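#' Construct a specific directed path
#'
#' A specific path is an ordered node sequence `X1 -> X2 -> ... -> XK -> Y`
#' through the DAG, together with a per-edge adjustment plan (the back-door
#' covariates used when estimating each edge's average causal effect).
#'
#' @param dag a `causal_dag`.
#' @param nodes character vector of at least two distinct node names forming
#'   consecutive edges of `dag`.
#' @param adjustment optional per-edge covariate plan; computed with
#'   [adjustment_sets()] when `NULL`.
#' @return An object of class `specific_path` with components `nodes`,
#'   `edges` (list of `c(parent, child)` pairs) and `adjustment` (named list,
#'   one sorted covariate vector per edge, named `"A->B"`).
#' @export
specific_path <- function(dag, nodes, adjustment = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 2L) stop2("a path needs at least two nodes")
  if (anyDuplicated(nodes)) stop2("path nodes must be distinct")
  for (nd in nodes) check_node(dag, nd)
  edges <- Map(c, nodes[-length(nodes)], nodes[-1L])
  names(edges) <- vapply(edges, function(e) paste(e, collapse = "->"),
                         character(1L))
  for (e in edges)
    if (!has_edge(dag, e[[1L]], e[[2L]]))
      stop2(sprintf("%s -> %s is not an edge of the DAG", e[[1L]], e[[2L]]))
  p <- structure(list(nodes = nodes, edges = edges, adjustment = NULL),
                 class = "specific_path")
  p$adjustment <- adjustment %||% adjustment_sets(dag, p)
  p
}

#' @export
print.specific_path <- function(x, ...) {
  cat("specific_path:", paste(x$nodes, collapse = " -> "), "\n")
  for (nm in names(x$adjustment)) {
    adj <- x$adjustment[[nm]]
    cat(sprintf("  %s adjusted for {%s}\n", nm,
                paste(adj, collapse = ", ")))
  }
  invisible(x)
}

#' @export
format.specific_path <- function(x, ...) paste(x$nodes, collapse = " -> ")

#' Per-edge back-door adjustment sets for a path
#'
#' For each edge `A -> B` of the path the covariate set is the parents of the
#' child `B` other than `A` itself: conditioning on a node's remaining parents
#' blocks every back-door route into that edge, by the local Markov property.
#'
#' @param dag a `causal_dag`.
#' @param path a `specific_path` (or bare character vector of path nodes).
#' @return Named list, one sorted character vector per path edge; the
#'   attribute `"confounders"` holds the union of all per-edge sets.
#' @examples
#' g <- three_path_network()
#' p <- specific_path(g, c("X1", "X2", "Y"))
#' adjustment_sets(g, p)   # X2 -> Y adjusted for X3
#' @export
adjustment_sets <- function(dag, path) {
  if (is.character(path)) path <- specific_path(dag, path)
  plan <- lapply(path$edges, function(e)
    setdiff(dag_parents(dag, e[[2L]]), e[[1L]]))
  names(plan) <- names(path$edges)
  attr(plan, "confounders") <- sort(unique(unlist(plan)))
  plan
}

#' Enumerate all directed paths between two variables
#'
#' Exhaustive search for simple directed paths from `source` to `sink`, each
#' returned with its adjustment plan attached.  Ordering is deterministic:
#' shortest paths first, ties broken lexicographically on the node sequence.
#'
#' @param dag a `causal_dag`.
#' @param source,sink node names, `source != sink`.
#' @param max_paths safety ceiling on the number of paths; exceeded search
#'   raises an error rather than truncating silently.
#' @return List of `specific_path` objects (possibly empty).
#' @examples
#' g <- three_path_network()
#' length(enumerate_paths(g, "X1", "Y"))   # 3
#' @export
enumerate_paths <- function(dag, source, sink, max_paths = 10000L) {
  check_node(dag, source)
  check_node(dag, sink)
  if (identical(source, sink)) stop2("source and sink must differ")
  vp <- igraph::all_simple_paths(dag$graph, from = source, to = sink,
                                 mode = "out")
  if (length(vp) > max_paths)
    stop2(sprintf("%d paths exceed max_paths = %d; raise the ceiling explicitly",
                  length(vp), max_paths))
  seqs <- lapply(vp, igraph::as_ids)
  ord <- order(lengths(seqs),
               vapply(seqs, paste, character(1L), collapse = "\r"))
  lapply(seqs[ord], function(s) specific_path(dag, s))
}

#' Simplify a causal network around a specific path
#'
#' Removes every variable that has no directed route into any node of the
#' path and no directed route into any node of the path's adjustment sets.
#' Such variables cannot open a back-door route into any on-path edge, so
#' dropping them leaves every per-edge estimand unchanged; in particular all
#' descendants of the outcome are removed.
#'
#' @param dag a `causal_dag`.
#' @param path a `specific_path` in `dag`.
#' @return A `causal_dag` on the retained nodes (the path's ancestors,
#'   including the path and adjustment nodes themselves).
#' @export
simplify_dag <- function(dag, path) {
  if (is.character(path)) path <- specific_path(dag, path)
  core <- unique(c(path$nodes, unlist(path$adjustment)))
  keep <- unique(unlist(lapply(core, function(nd)
    igraph::as_ids(igraph::subcomponent(dag$graph, nd, mode = "in")))))
  keep <- sort(keep)
  sub <- dag$edges[dag$edges$parent %in% keep & dag$edges$child %in% keep, ,
                   drop = FALSE]
  parse_graph(sub, var_kind = dag$var_kind[keep],
              levels = dag$levels[keep])
}
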