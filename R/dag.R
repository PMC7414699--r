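#' Construct a causal DAG from an edge list
#'
#' Builds a validated directed acyclic graph over named variables.  Each
#' variable carries a kind (`"binary"`, `"discrete"` or `"continuous"`) that
#' determines which average-causal-effect estimator is used for edges into it.
#'
#' @param edges a two-column data frame or matrix of `(parent, child)` name
#'   pairs, or a list of length-2 character vectors.
#' @param var_kind optional named character vector mapping node names to
#'   `"binary"`, `"discrete"` or `"continuous"`.  Nodes not mentioned default
#'   to `"continuous"`.
#' @param levels optional named list giving the ordered level set of each
#'   discrete node (defaults to `0:1` for binary nodes).
#'
#' @return An object of class `causal_dag` with components `nodes` (sorted
#'   names), `edges` (data frame with columns `parent`, `child`),
#'   `var_kind`, `levels` and `graph` (the backing igraph object).
#'
#' @details Validation rejects self-loops, duplicate edges and cycles (the
#'   error names one offending cycle).  Node order is deterministic:
#'   lexicographic for `nodes`, and a lexicographically tie-broken topological
#'   order is available through [topo_order()].
#'
#' @examples
#' g <- parse_graph(rbind(c("A", "B"), c("B", "C")),
#'                  var_kind = c(A = "binary", B = "binary", C = "binary"))
#' dag_parents(g, "C")
#' @export
parse_graph <- function(edges, var_kind = NULL, levels = NULL) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2L) stop2("each edge record must have exactly 2 names")
      as.character(e)
    }))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop2("edge list must have two columns (parent, child)")
  edges <- data.frame(parent = as.character(edges[[1L]]),
                      child  = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop2("edge list is empty")
  if (any(!nzchar(edges$parent)) || any(!nzchar(edges$child)))
    stop2("node names must be non-empty strings")
  if (any(edges$parent == edges$child))
    stop2("self-loops are not allowed: ",
          paste(unique(edges$parent[edges$parent == edges$child]),
                collapse = ", "))
  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key))
    stop2("duplicate edge(s): ",
          paste(unique(sub("\r", " -> ", key[duplicated(key)])), collapse = ", "))

  nodes <- sort(unique(c(edges$parent, edges$child)))
  kind <- rep("continuous", length(nodes))
  names(kind) <- nodes
  if (!is.null(var_kind)) {
    if (is.null(names(var_kind))) stop2("var_kind must be a named vector")
    unknown <- setdiff(names(var_kind), nodes)
    if (length(unknown))
      stop2("var_kind names not in the graph: ", paste(unknown, collapse = ", "))
    bad <- setdiff(unique(var_kind), VAR_KINDS)
    if (length(bad))
      stop2("unknown variable kind(s): ", paste(bad, collapse = ", "))
    kind[names(var_kind)] <- var_kind
  }

  lv <- lapply(nodes, function(nd) {
    if (!is.null(levels[[nd]])) sort(levels[[nd]])
    else if (kind[[nd]] %in% c("binary", "discrete")) c(0, 1)
    else NULL
  })
  names(lv) <- nodes

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(g, edges)
    stop2("graph is not acyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }

  structure(list(nodes = nodes, edges = edges, var_kind = kind,
                 levels = lv, graph = g),
            class = "causal_dag")
}

## locate one directed cycle for the acyclicity error message
find_cycle <- function(g, edges) {
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]; ch <- edges$child[i]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = ch, to = p, mode = "out")$vpath[[1L]])
    if (length(sp)) return(c(igraph::as_ids(sp), ch))
  }
  "<cycle not located>"
}

#' Read a causal DAG from an edge-list file
#'
#' Reads a two-column TSV/CSV edge list (`parent<sep>child`, one edge per
#' line).  Lines starting with `#` are comments; a header line naming the
#' columns `parent`/`child` (any case) is detected and skipped.  Variable
#' kinds can be supplied through a sidecar JSON file mapping node names to
#' kinds.
#'
#' @param file path to the edge-list file.
#' @param kinds_file optional path to a JSON file `{"node": "kind", ...}`.
#' @param sep field separator; guessed from the first data line when `NULL`
#'   (tab if present, otherwise comma).
#' @return A [parse_graph()] `causal_dag`.
#' @export
read_graph <- function(file, kinds_file = NULL, sep = NULL) {
  if (!file.exists(file)) stop2("graph file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop2("graph file contains no edges: ", file)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop2("malformed edge line(s): ", paste(lines[bad], collapse = "; "))
  m <- t(vapply(parts, function(p) trimws(p[1:2]), character(2L)))
  if (tolower(m[1L, 1L]) %in% c("parent", "from", "source") ||
      tolower(m[1L, 2L]) %in% c("child", "to", "target"))
    m <- m[-1L, , drop = FALSE]
  var_kind <- NULL
  if (!is.null(kinds_file)) {
    kl <- jsonlite::read_json(kinds_file, simplifyVector = TRUE)
    var_kind <- unlist(kl)
  }
  parse_graph(m, var_kind = var_kind)
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("causal_dag: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  kinds <- table(factor(x$var_kind, levels = VAR_KINDS))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = " "),
      "\n")
  ord <- topo_order(x)
  cat("  topological order:", paste(ord, collapse = " "), "\n")
  invisible(x)
}

#' DAG accessors
#'
#' @param dag a `causal_dag`.
#' @param node a node name.
#' @return `dag_nodes()`/`topo_order()` return character vectors of node
#'   names; `dag_edges()` the edge data frame; `dag_parents()`/
#'   `dag_children()` the sorted parent/child names of `node`; `var_kinds()`
#'   the named kind vector.
#' @name dag-accessors
NULL

#' @rdname dag-accessors
#' @export
dag_nodes <- function(dag) dag$nodes

#' @rdname dag-accessors
#' @export
dag_edges <- function(dag) dag$edges

#' @rdname dag-accessors
#' @export
var_kinds <- function(dag) dag$var_kind

#' @rdname dag-accessors
#' @export
dag_parents <- function(dag, node) {
  check_node(dag, node)
  sort(dag$edges$parent[dag$edges$child == node])
}

#' @rdname dag-accessors
#' @export
dag_children <- function(dag, node) {
  check_node(dag, node)
  sort(dag$edges$child[dag$edges$parent == node])
}

#' @rdname dag-accessors
#' @export
topo_order <- function(dag) {
  ## Kahn's algorithm with a lexicographic frontier so the order is unique
  nodes <- dag$nodes
  indeg <- vapply(nodes, function(nd)
    sum(dag$edges$child == nd), integer(1L))
  names(indeg) <- nodes
  out <- character(0L)
  avail <- sort(nodes[indeg == 0L])
  while (length(avail)) {
    nd <- avail[[1L]]
    avail <- avail[-1L]
    out <- c(out, nd)
    kids <- dag$edges$child[dag$edges$parent == nd]
    for (k in kids) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) avail <- sort(c(avail, k))
    }
  }
  out
}

check_node <- function(dag, node) {
  if (!(is.character(node) && length(node) == 1L && node %in% dag$nodes))
    stop2("unknown node: ", paste(node, collapse = ", "))
  invisible(node)
}

has_edge <- function(dag, parent, child) {
  any(dag$edges$parent == parent & dag$edges$child == child)
}
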