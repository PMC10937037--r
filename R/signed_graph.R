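#' Signed directed graphs of excitatory and inhibitory nodes
#'
#' A `signed_digraph` represents a network whose nodes are excitatory (`"E"`)
#' or inhibitory (`"I"`) populations and whose directed edges inherit their
#' sign from the source node: every edge leaving an inhibitory node is
#' inhibitory, every edge leaving an excitatory node is excitatory. This is
#' the natural convention for neural circuits, where a population releases a
#' single transmitter type, and it is the structural object on which the odd
#' inhibitory cycle rule operates.
#'
#' @param nodes character vector of node names, or a two-column data frame
#'   with columns `node` and `sign`.
#' @param signs character vector of `"E"`/`"I"`, one per node (ignored when
#'   `nodes` is a data frame).
#' @param edges two-column data frame (or matrix) of `source`, `target` node
#'   names. Duplicate directed edges are rejected; self-loops are allowed.
#' @param weights optional numeric vector of positive weight magnitudes, one
#'   per edge.
#'
#' @return An object of class `signed_digraph` with elements `nodes`,
#'   `sign` (named character vector), and `edges` (data frame with columns
#'   `source`, `target`, `weight`, `sign`).
#' @examples
#' g <- signed_digraph(c("E1", "I1"), c("E", "I"),
#'                     data.frame(source = c("E1", "I1"),
#'                                target = c("I1", "E1")))
#' network_oscillation_potential(g)$overall
#' @export
signed_digraph <- function(nodes, signs = NULL, edges, weights = NULL) {
  if (is.data.frame(nodes)) {
    signs <- as.character(nodes$sign)
    nodes <- as.character(nodes$node)
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  signs <- toupper(as.character(signs))
  if (length(signs) != length(nodes) || !all(signs %in% c("E", "I")))
    stop("each node needs a sign 'E' or 'I' (a node is purely excitatory or purely inhibitory)")
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edges must have columns source, target")
  names(edges)[1:2] <- c("source", "target")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  unknown <- setdiff(c(edges$source, edges$target), nodes)
  if (length(unknown)) stop("edge refers to unknown node(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\r")))
    stop("duplicate directed edges are not allowed")
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (length(weights) != nrow(edges) || any(weights <= 0))
    stop("weights must be positive, one per edge")
  names(signs) <- nodes
  sgn <- signs
  edges$weight <- as.numeric(weights)
  edges$sign <- ifelse(sgn[edges$source] == "I", "inhibitory", "excitatory")
  structure(list(nodes = nodes, sign = signs, edges = edges),
            class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("signed_digraph: %d nodes (%d excitatory, %d inhibitory), %d edges\n",
              length(x$nodes), sum(x$sign == "E"), sum(x$sign == "I"), nrow(x$edges)))
  invisible(x)
}

# integer adjacency list (by node index), self-loops split out
.adj_list <- function(g) {
  idx <- stats::setNames(seq_along(g$nodes), g$nodes)
  src <- idx[g$edges$source]; tgt <- idx[g$edges$target]
  self <- src == tgt
  adj <- lapply(seq_along(g$nodes), function(i) sort(unname(tgt[src == i & !self])))
  list(adj = adj, self = sort(unname(src[self])))
}

.make_cycle_record <- function(g, seq_idx) {
  nodes <- g$nodes[seq_idx]
  # rotation-canonical: start at the lexicographically smallest node name
  k <- which(nodes == min(nodes))[1L]
  if (k > 1L) nodes <- c(nodes[k:length(nodes)], nodes[seq_len(k - 1L)])
  n_inh <- sum(g$sign[nodes] == "I")
  structure(list(nodes = nodes, length = length(nodes), n_inhibitory = n_inh,
                 parity = if (n_inh %% 2L == 1L) "negative" else "positive"),
            class = "cycle_record")
}

#' @export
print.cycle_record <- function(x, ...) {
  cat(sprintf("cycle [%s] length %d, %d inhibitory edge(s), %s loop\n",
              paste(x$nodes, collapse = " -> "), x$length, x$n_inhibitory, x$parity))
  invisible(x)
}

#' Enumerate all simple directed cycles of a signed digraph
#'
#' Johnson-style search: for each start node `s` in increasing order, simple
#' cycles through `s` within the subgraph of nodes `>= s` are found by a
#' blocked depth-first search, so every cycle is produced exactly once.
#' Length-1 self-loops are included. Each cycle is returned in
#' rotation-canonical form (lexicographically smallest node name first);
#' directed cycles are not identified with their reversals.
#'
#' @param g a [signed_digraph()].
#' @param max_nodes guard against combinatorial explosion (default 20).
#' @return list of `cycle_record` objects, each with `nodes`,
#'   `length`, `n_inhibitory` and `parity` (`"negative"` for an odd number of
#'   inhibitory edges, `"positive"` for even).
#' @export
enumerate_simple_cycles <- function(g, max_nodes = 20L) {
  stopifnot(inherits(g, "signed_digraph"))
  n <- length(g$nodes)
  if (n > max_nodes)
    stop("graph has ", n, " nodes; cycle enumeration is guarded at ", max_nodes)
  al <- .adj_list(g)
  cycles <- lapply(al$self, function(i) .make_cycle_record(g, i))

  blocked <- logical(n)
  Bsets <- vector("list", n)
  path <- integer(0)
  out <- list()
  s <- 0L

  unblock <- function(u) {
    blocked[u] <<- FALSE
    for (w in Bsets[[u]]) if (blocked[w]) unblock(w)
    Bsets[[u]] <<- integer(0)
  }
  circuit <- function(v) {
    found <- FALSE
    path <<- c(path, v)
    blocked[v] <<- TRUE
    for (w in al$adj[[v]]) {
      if (w < s) next
      if (w == s) {
        out[[length(out) + 1L]] <<- path
        found <- TRUE
      } else if (!blocked[w]) {
        if (circuit(w)) found <- TRUE
      }
    }
    if (found) unblock(v)
    else for (w in al$adj[[v]]) {
      if (w < s) next
      if (!(v %in% Bsets[[w]])) Bsets[[w]] <<- c(Bsets[[w]], v)
    }
    path <<- path[-length(path)]
    found
  }
  for (s_i in seq_len(n)) {
    s <- s_i
    blocked[] <- FALSE
    Bsets <- rep(list(integer(0)), n)
    path <- integer(0)
    circuit(s)
  }
  c(cycles, lapply(out, function(p) .make_cycle_record(g, p)))
}

#' Apply the odd inhibitory cycle rule to one cycle
#'
#' A directed cycle can support oscillations only if it is a negative loop,
#' i.e. contains an odd number of inhibitory edges; cycles with an even count
#' settle into synchrony or winner-take-all dynamics instead.
#'
#' @param cycle a `cycle_record` from [enumerate_simple_cycles()].
#' @return `"oscillation-capable"` or `"not-capable"`.
#' @export
classify_cycle <- function(cycle) {
  stopifnot(inherits(cycle, "cycle_record"))
  if (cycle$n_inhibitory %% 2L == 1L) "oscillation-capable" else "not-capable"
}

#' Oscillation potential of a whole network
#'
#' Enumerates every simple directed cycle, classifies each by the odd
#' inhibitory cycle rule, and reports whether the network as a whole admits a
#' negative loop (the structural requirement for oscillations). Length-1
#' self-loops are negative loops when the node is inhibitory and are reported
#' with `self_loop = TRUE`, since the single-cycle stability theory applies
#' to cycles of length two and more.
#'
#' @param g a [signed_digraph()].
#' @return list with `cycles` (data frame: cycle string, length,
#'   inhibitory count, parity, classification, self_loop flag), `records`
#'   (the `cycle_record` list) and `overall` (`TRUE` iff at least one
#'   negative cycle exists).
#' @export
network_oscillation_potential <- function(g) {
  recs <- enumerate_simple_cycles(g)
  if (!length(recs)) {
    return(list(cycles = data.frame(cycle = character(0), length = integer(0),
                                    n_inhibitory = integer(0), parity = character(0),
                                    classification = character(0), self_loop = logical(0)),
                records = recs, overall = FALSE))
  }
  df <- data.frame(
    cycle = vapply(recs, function(r) paste(r$nodes, collapse = "->"), ""),
    length = vapply(recs, `[[`, 0L, "length"),
    n_inhibitory = vapply(recs, `[[`, 0L, "n_inhibitory"),
    parity = vapply(recs, `[[`, "", "parity"),
    classification = vapply(recs, classify_cycle, ""),
    stringsAsFactors = FALSE)
  df$self_loop <- df$length == 1L
  list(cycles = df, records = recs, overall = any(df$parity == "negative"))
}

#' Enumerate induced node subsets of a graph
#'
#' Yields every node subset with size between `kmin` and `kmax`, each exactly
#' once; the number of subsets equals the corresponding sum of binomial
#' coefficients.
#'
#' @param g a [signed_digraph()].
#' @param kmin,kmax inclusive size bounds, `1 <= kmin <= kmax <= n`.
#' @return list of character vectors of node names.
#' @export
enumerate_subnetworks <- function(g, kmin, kmax) {
  stopifnot(inherits(g, "signed_digraph"))
  n <- length(g$nodes)
  if (!(kmin >= 1 && kmin <= kmax && kmax <= n))
    stop("require 1 <= kmin <= kmax <= number of nodes (", n, ")")
  out <- list()
  for (k in kmin:kmax) {
    cmb <- utils::combn(g$nodes, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Coverage of node subsets by oscillatory loops
#'
#' Counts how many induced subnetworks (node subsets of sizes `kmin..kmax`)
#' contain at least one of the given loops in full, i.e. how many motifs
#' inherit oscillation potential from a listed negative loop. Optionally also
#' counts how many of the loops avoid a named node and how many feature at
#' least one node from a named set (e.g. pallidal populations).
#'
#' @param g a [signed_digraph()].
#' @param loops list of character vectors: the node set of each loop.
#' @param kmin,kmax subset size bounds.
#' @param without_node optional node name: count loops whose node set
#'   excludes it.
#' @param featuring_any optional character vector: count loops whose node set
#'   intersects it.
#' @return `coverage_report` list with `total`, `covered`, `loops`,
#'   `n_loops_without`, `n_loops_featuring` and per-subset-size tallies.
#' @export
loop_coverage <- function(g, loops, kmin, kmax,
                          without_node = NULL, featuring_any = NULL) {
  stopifnot(inherits(g, "signed_digraph"))
  loops <- lapply(loops, as.character)
  bad <- unlist(lapply(loops, function(l) setdiff(l, g$nodes)))
  if (length(bad)) stop("loop node(s) not in graph: ", paste(unique(bad), collapse = ", "))
  subsets <- enumerate_subnetworks(g, kmin, kmax)
  contains_loop <- vapply(subsets, function(s)
    any(vapply(loops, function(l) all(l %in% s), NA)), NA)
  sizes <- vapply(subsets, length, 0L)
  by_size <- tapply(contains_loop, sizes, sum)
  n_without <- if (is.null(without_node)) NA_integer_ else
    sum(vapply(loops, function(l) !(without_node %in% l), NA))
  n_feat <- if (is.null(featuring_any)) NA_integer_ else
    sum(vapply(loops, function(l) length(intersect(l, featuring_any)) > 0, NA))
  structure(list(total = length(subsets), covered = sum(contains_loop),
                 loops = loops, covered_by_size = by_size,
                 n_loops_without = n_without, n_loops_featuring = n_feat),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %d of %d subnetworks contain at least one of %d loops\n",
              x$covered, x$total, length(x$loops)))
  invisible(x)
}

#' Topological order of a signed digraph
#'
#' Kahn's algorithm; errors (naming one directed cycle) when the graph is not
#' acyclic. Self-loops count as cycles.
#'
#' @param g a [signed_digraph()].
#' @return integer vector: node indices in topological order.
#' @export
topological_order <- function(g) {
  al <- .adj_list(g)
  if (length(al$self))
    stop("graph is not acyclic: self-loop at ", g$nodes[al$self[1]])
  n <- length(g$nodes)
  indeg <- integer(n)
  for (i in seq_len(n)) for (j in al$adj[[i]]) indeg[j] <- indeg[j] + 1L
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (j in al$adj[[v]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(order) < n) {
    cyc <- enumerate_simple_cycles(g)[[1]]
    stop("graph is not acyclic: found cycle ", paste(cyc$nodes, collapse = "->"))
  }
  order
}
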