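#' Built-in network motifs and the cortico-basal-ganglia graph
#'
#' Named signed-digraph fixtures used throughout the package:
#' \describe{
#'   \item{`EI`}{two mutually connected nodes, one excitatory and one
#'     inhibitory — the smallest negative loop.}
#'   \item{`EEI`}{three-node ring with one inhibitory edge (negative loop).}
#'   \item{`EII`}{three-node ring with two inhibitory edges (positive loop;
#'     winner-take-all, not oscillation-capable).}
#'   \item{`III`}{three mutually inhibiting nodes in a ring (negative loop;
#'     winner-less competition).}
#'   \item{`CBG-core`}{eight-population cortico-basal-ganglia graph (Cortex,
#'     D2-SPN, FSN, Proto- and Arky-pallidal GPe, STN, GPi, thalamus)
#'     containing exactly the edges of the six oscillation-capable loops
#'     listed by [cbg_loops()] plus the Proto self-inhibition.}
#'   \item{`CBG-extended`}{`CBG-core` plus additional anatomically motivated
#'     (reconstructed, non-canonical) projections: Cortex to FSN, Cortex to
#'     thalamus, Arky to FSN. Counts reported by [reproduce_counts()] use
#'     `CBG-core` only.}
#' }
#'
#' @param name fixture name (see above).
#' @return a [signed_digraph()].
#' @export
graph_fixture <- function(name = c("EI", "EEI", "EII", "III",
                                   "CBG-core", "CBG-extended")) {
  name <- match.arg(name)
  ring <- function(nodes, signs) {
    n <- length(nodes)
    signed_digraph(nodes, signs,
                   data.frame(source = nodes, target = nodes[c(2:n, 1)]))
  }
  switch(name,
    "EI"  = signed_digraph(c("E1", "I1"), c("E", "I"),
                           data.frame(source = c("E1", "I1"),
                                      target = c("I1", "E1"))),
    "EEI" = ring(c("E1", "E2", "I1"), c("E", "E", "I")),
    "EII" = ring(c("E1", "I1", "I2"), c("E", "I", "I")),
    "III" = ring(c("I1", "I2", "I3"), c("I", "I", "I")),
    "CBG-core" = .cbg_graph(extended = FALSE),
    "CBG-extended" = .cbg_graph(extended = TRUE))
}

.cbg_nodes <- data.frame(
  node = c("Cortex", "D2",  "FSN", "Proto", "Arky", "STN", "GPi", "Th"),
  sign = c("E",      "I",   "I",   "I",     "I",    "E",   "I",   "E"),
  stringsAsFactors = FALSE)

.cbg_edges_core <- data.frame(rbind(
  # Proto-STN reciprocal loop
  c("Proto", "STN"), c("STN", "Proto"),
  # hyperdirect loop STN-GPi-Th-Cortex
  c("STN", "GPi"), c("GPi", "Th"), c("Th", "Cortex"), c("Cortex", "STN"),
  # STN-Arky-D2-Proto loop
  c("STN", "Arky"), c("Arky", "D2"), c("D2", "Proto"),
  # Proto-Arky-D2 loop (adds the pallido-pallidal edge)
  c("Proto", "Arky"),
  # Proto-FSN-D2 loop
  c("Proto", "FSN"), c("FSN", "D2"),
  # Proto-GPi-Th-Cortex-D2 loop (adds Proto->GPi, Cortex->D2)
  c("Proto", "GPi"), c("Cortex", "D2"),
  # Proto self-inhibition (recurrent collaterals)
  c("Proto", "Proto")), stringsAsFactors = FALSE)

.cbg_graph <- function(extended = FALSE) {
  edges <- .cbg_edges_core
  names(edges) <- c("source", "target")
  if (extended) {
    extra <- data.frame(source = c("Cortex", "Cortex", "Arky"),
                        target = c("FSN", "Th", "FSN"),
                        stringsAsFactors = FALSE)
    edges <- rbind(edges, extra)
  }
  signed_digraph(.cbg_nodes, edges = edges)
}

#' The six oscillation-capable loops of the cortico-basal-ganglia graph
#'
#' Node sets of the six directed cycles in the cortico-basal-ganglia network
#' that satisfy the odd inhibitory cycle rule (one or three inhibitory
#' projections): Proto-STN, STN-GPi-Th-Cortex, STN-Arky-D2-Proto,
#' Proto-Arky-D2, Proto-FSN-D2, and Proto-GPi-Th-Cortex-D2.
#'
#' @return named list of character vectors.
#' @export
cbg_loops <- function() {
  list(
    `Proto-STN`              = c("Proto", "STN"),
    `STN-GPi-Th-Cortex`      = c("STN", "GPi", "Th", "Cortex"),
    `STN-Arky-D2-Proto`      = c("STN", "Arky", "D2", "Proto"),
    `Proto-Arky-D2`          = c("Proto", "Arky", "D2"),
    `Proto-FSN-D2`           = c("Proto", "FSN", "D2"),
    `Proto-GPi-Th-Cortex-D2` = c("Proto", "GPi", "Th", "Cortex", "D2"))
}

#' Motif-coverage counts for the cortico-basal-ganglia network
#'
#' Recomputes, from the built-in `CBG-core` fixture and the six loops of
#' [cbg_loops()], the combinatorial summary of where beta-band oscillations
#' can arise in the cortico-basal-ganglia circuit: the number of induced
#' subnetworks with 2 to 7 of the 8 populations, how many of them contain at
#' least one oscillation-capable loop, how many of the six loops avoid the
#' STN, and how many feature the GPe (Proto or Arky).
#'
#' @return list with `total`, `covered`, `loops_without_stn`,
#'   `loops_featuring_gpe`, and the underlying `coverage_report`.
#' @export
reproduce_counts <- function() {
  g <- graph_fixture("CBG-core")
  rep <- loop_coverage(g, cbg_loops(), kmin = 2, kmax = 7,
                       without_node = "STN",
                       featuring_any = c("Proto", "Arky"))
  list(total = rep$total, covered = rep$covered,
       loops_without_stn = rep$n_loops_without,
       loops_featuring_gpe = rep$n_loops_featuring,
       report = rep)
}
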