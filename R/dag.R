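#' Construct a causal DAG
#'
#' A directed acyclic graph over named variables. The order of `nodes` is part
#' of the object: it is the canonical variable order used to orient
#' d-separation claims deterministically, mirroring how path-analysis software
#' records the variable layout of each candidate model.
#'
#' @param nodes Character vector of variable names, in canonical order.
#' @param edges Two-column character matrix (or data.frame) of directed edges,
#'   `from` -> `to`. May have zero rows.
#' @param id Optional model identifier string.
#' @return An object of class `causal_dag`.
#' @export
causal_dag <- function(nodes, edges = NULL, id = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (from, to)")
    colnames(edges) <- c("from", "to")
  }
  if (!all(edges %in% nodes)) {
    stop("edge endpoints not in node set: ",
         paste(setdiff(unique(as.vector(edges)), nodes), collapse = ", "))
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  key <- paste(edges[, 1], edges[, 2])
  if (anyDuplicated(key)) stop("duplicate edges")
  dag <- structure(list(nodes = nodes, edges = edges, id = id),
                   class = "causal_dag")
  if (is.null(topo_order(dag))) stop("graph is cyclic; a DAG is required")
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal_dag", if (!is.null(x$id)) paste0("'", x$id, "'"), ":",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste(x$edges[, 1], "->", x$edges[, 2]), sep = "\n")
  }
  invisible(x)
}

# Stable topological order: Kahn's algorithm taking, at each step, the
# first zero-indegree node in the DAG's stored node order. For a node order
# that is already topologically valid this returns that order unchanged.
# Returns NULL on cycles.
topo_order <- function(dag) {
  nodes <- dag$nodes
  n <- length(nodes)
  indeg <- setNames(integer(n), nodes)
  if (nrow(dag$edges)) {
    tab <- table(dag$edges[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    avail <- remaining[indeg[remaining] == 0]
    if (!length(avail)) return(NULL)
    v <- avail[1]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    if (nrow(dag$edges)) {
      ch <- dag$edges[dag$edges[, 1] == v, 2]
      indeg[ch] <- indeg[ch] - 1L
    }
  }
  out
}

dag_parents <- function(dag) {
  pa <- setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) pa[[v]] <- character(0)
  if (nrow(dag$edges)) {
    for (i in seq_len(nrow(dag$edges))) {
      pa[[dag$edges[i, 2]]] <- c(pa[[dag$edges[i, 2]]], dag$edges[i, 1])
    }
  }
  pa
}

#' d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent pair of variables,
#' conditioned on the union of the two variables' parents (Shipley's basis).
#' Claims are oriented deterministically: the pair is ordered by the DAG's
#' topological order (ties broken by the stored node order) and the later
#' variable is the regression response; the conditioning variables are listed
#' in the order parents-of-earlier then parents-of-later. The `formula` column
#' is the regression `response ~ Z... + x`, whose final term carries the
#' tested coefficient.
#'
#' @param dag A [causal_dag()].
#' @return A data.frame with columns `x`, `response`, `conditioning`
#'   (comma-joined string, `""` if empty) and `formula` (string). Zero rows
#'   for a complete DAG.
#' @export
basis_set <- function(dag) {
  ord <- topo_order(dag)
  if (is.null(ord)) stop("graph is cyclic")
  pos <- setNames(seq_along(ord), ord)
  pa <- dag_parents(dag)
  # order each parent list by topological position
  pa <- lapply(pa, function(p) p[order(pos[p])])
  adj <- character(0)
  if (nrow(dag$edges)) {
    adj <- c(paste(dag$edges[, 1], dag$edges[, 2]),
             paste(dag$edges[, 2], dag$edges[, 1]))
  }
  rows <- list()
  n <- length(ord)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        x <- ord[i]; y <- ord[j]
        if (paste(x, y) %in% adj) next
        z <- unique(c(pa[[x]], pa[[y]]))
        z <- setdiff(z, c(x, y))
        rows[[length(rows) + 1L]] <- data.frame(
          x = x, response = y,
          conditioning = paste(z, collapse = ","),
          formula = paste0(y, " ~ ", paste(c(z, x), collapse = " + ")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(x = character(0), response = character(0),
                      conditioning = character(0), formula = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export a DAG in DOT format
#'
#' @param dag A [causal_dag()].
#' @param path Optional file to write to.
#' @return The DOT text, invisibly if written to file.
#' @export
dag_to_dot <- function(dag, path = NULL) {
  lines <- c(paste0("digraph \"", if (is.null(dag$id)) "model" else dag$id, "\" {"),
             paste0("  ", dag$nodes, ";"),
             if (nrow(dag$edges)) paste0("  ", dag$edges[, 1], " -> ", dag$edges[, 2], ";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# brute-force d-separation check used nowhere in the fitting path; exported
# for verification of basis sets on small graphs.

#' Test d-separation by exhaustive path checking
#'
#' Checks whether `x` and `y` are d-separated given `z` by enumerating all
#' undirected paths and applying the collider rules directly. Exponential in
#' graph size; intended for verification on small DAGs.
#'
#' @param dag A [causal_dag()].
#' @param x,y Variable names.
#' @param z Character vector of conditioning variables (possibly empty).
#' @return `TRUE` if every path is blocked.
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  nodes <- dag$nodes
  edges <- dag$edges
  # descendants map for collider openings
  children <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) children[[v]] <- character(0)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      children[[edges[i, 1]]] <- c(children[[edges[i, 1]]], edges[i, 2])
    }
  }
  descendants <- function(v) {
    out <- character(0); stack <- children[[v]]
    while (length(stack)) {
      w <- stack[1]; stack <- stack[-1]
      if (!(w %in% out)) { out <- c(out, w); stack <- c(stack, children[[w]]) }
    }
    out
  }
  desc <- lapply(setNames(nodes, nodes), descendants)
  # enumerate simple undirected paths x..y
  nbrs <- function(v) {
    c(if (nrow(edges)) edges[edges[, 1] == v, 2], if (nrow(edges)) edges[edges[, 2] == v, 1])
  }
  blocked_path <- function(path) {
    # path is a vector of nodes; check each interior triple
    if (length(path) == 2) return(FALSE)  # direct edge, never blocked
    for (k in 2:(length(path) - 1)) {
      a <- path[k - 1]; b <- path[k]; c <- path[k + 1]
      into_b_from_a <- any(edges[, 1] == a & edges[, 2] == b)
      into_b_from_c <- any(edges[, 1] == c & edges[, 2] == b)
      collider <- into_b_from_a && into_b_from_c
      if (collider) {
        opened <- b %in% z || length(intersect(desc[[b]], z)) > 0
        if (!opened) return(TRUE)
      } else {
        if (b %in% z) return(TRUE)
      }
    }
    FALSE
  }
  all_blocked <- TRUE
  walk <- function(path) {
    if (!all_blocked) return()
    v <- path[length(path)]
    if (v == y) {
      if (!blocked_path(path)) all_blocked <<- FALSE
      return()
    }
    for (w in nbrs(v)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(x)
  all_blocked
}
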