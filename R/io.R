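# File interfaces: edge-list CSV / JSON graphs, TLN JSON, trajectory CSV,
# DOT export.

#' Read a signed digraph from CSV edge and node tables
#'
#' @param edge_file CSV with columns `source,target` (optional `weight`).
#' @param node_file CSV with columns `node,sign`.
#' @return a [signed_digraph()].
#' @export
read_graph_csv <- function(edge_file, node_file) {
  edges <- utils::read.csv(edge_file, stringsAsFactors = FALSE)
  nodes <- utils::read.csv(node_file, stringsAsFactors = FALSE)
  signed_digraph(nodes, edges = edges[, c("source", "target")],
                 weights = if ("weight" %in% names(edges)) edges$weight)
}

#' Read or write a signed digraph as a single JSON document
#'
#' The document has fields `nodes` (list of `{name, sign}`) and `edges`
#' (list of `{source, target, weight}`).
#'
#' @param file path.
#' @return [read_graph_json()]: a [signed_digraph()];
#'   [write_graph_json()]: the path, invisibly.
#' @export
read_graph_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  signed_digraph(doc$nodes$name, doc$nodes$sign,
                 edges = doc$edges[, c("source", "target")],
                 weights = if ("weight" %in% names(doc$edges)) doc$edges$weight)
}

#' @rdname read_graph_json
#' @param g a [signed_digraph()].
#' @export
write_graph_json <- function(g, file) {
  jsonlite::write_json(
    list(nodes = data.frame(name = g$nodes, sign = unname(g$sign)),
         edges = g$edges[, c("source", "target", "weight")]),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Export a signed digraph to Graphviz DOT
#'
#' Inhibitory nodes are drawn solid, inhibitory edges red.
#'
#' @param g a [signed_digraph()].
#' @param file optional path; when `NULL` the DOT text is returned.
#' @export
graph_to_dot <- function(g, file = NULL) {
  lines <- c("digraph G {",
             sprintf("  \"%s\" [style=%s];", g$nodes,
                     ifelse(g$sign == "I", "filled", "solid")),
             sprintf("  \"%s\" -> \"%s\" [color=%s];",
                     g$edges$source, g$edges$target,
                     ifelse(g$edges$sign == "inhibitory", "red", "black")),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read or write a threshold-linear network as JSON
#'
#' Fields: `W` (dense row-major), `b`, optional `signs`.
#'
#' @param file path.
#' @export
read_tln_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  n <- length(doc$b)
  W <- if (is.matrix(doc$W)) doc$W
       else matrix(unlist(doc$W), n, n, byrow = TRUE)
  tln_network(W, doc$b, signs = doc$signs)
}

#' @rdname read_tln_json
#' @param net a [tln_network()].
#' @export
write_tln_json <- function(net, file) {
  jsonlite::write_json(
    list(W = apply(net$W, 1, function(r) r, simplify = FALSE),
         b = net$b, signs = net$signs),
    file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' Write a trajectory as CSV (time, one column per node)
#'
#' @param traj a `tln_trajectory` or `wc_trajectory`.
#' @param file path.
#' @export
write_trajectory_csv <- function(traj, file) {
  m <- if (inherits(traj, "wc_trajectory")) traj$r else traj$x
  df <- data.frame(time = traj$time, m)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
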