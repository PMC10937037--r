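# Independent oracles and random-input generators for property tests.

# Brute-force simple-cycle enumeration: for every node subset and every
# permutation starting at the subset's smallest element, check that all
# consecutive edges (and the closing edge) exist. Only feasible for small n;
# deliberately unrelated to the package's blocked-DFS search.
oracle_cycles <- function(g) {
  n <- length(g$nodes)
  has_edge <- matrix(FALSE, n, n)
  idx <- stats::setNames(seq_len(n), g$nodes)
  for (k in seq_len(nrow(g$edges)))
    has_edge[idx[g$edges$source[k]], idx[g$edges$target[k]]] <- TRUE
  found <- character(0)
  for (i in seq_len(n)) if (has_edge[i, i]) found <- c(found, g$nodes[i])
  for (size in 2:max(2, n)) {
    if (size > n) break
    for (subset in utils::combn(n, size, simplify = FALSE)) {
      first <- subset[1]
      rest <- subset[-1]
      perms <- if (length(rest) == 1) list(rest) else all_perms(rest)
      for (p in perms) {
        cyc <- c(first, p)
        edges_ok <- all(has_edge[cbind(cyc, c(cyc[-1], first))])
        if (edges_ok)
          found <- c(found, paste(g$nodes[cyc], collapse = "->"))
      }
    }
  }
  sort(found)
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# canonical strings for the package's cycle records (min-first rotation is
# already applied by the package; oracle_cycles starts at the smallest index,
# which coincides because fixture node names sort like their indices)
cycle_strings <- function(records)
  sort(vapply(records, function(r) paste(r$nodes, collapse = "->"), ""))

# Inclusion-exclusion count of subsets (sizes kmin..kmax of n nodes)
# containing at least one loop node set.
oracle_coverage <- function(n_nodes, loops, kmin, kmax) {
  m <- length(loops)
  total <- 0
  for (mask in 1:(2^m - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0)
    u <- length(unique(unlist(loops[sel])))
    cnt <- 0
    for (k in kmin:kmax)
      if (k >= u) cnt <- cnt + choose(n_nodes - u, k - u)
    total <- total + (-1)^(length(sel) + 1) * cnt
  }
  total
}

# Random signed digraph (no duplicate edges, self-loops allowed).
random_signed_graph <- function(n, p_edge = 0.35, p_inh = 0.5,
                                p_self = 0.1) {
  nodes <- sprintf("n%02d", seq_len(n))
  signs <- ifelse(stats::runif(n) < p_inh, "I", "E")
  src <- tgt <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- if (i == j) p_self else p_edge
    if (stats::runif(1) < p) { src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j]) }
  }
  if (!length(src)) { src <- nodes[1]; tgt <- nodes[min(2, n)] }
  signed_digraph(nodes, signs, data.frame(source = src, target = tgt))
}

# Random acyclic TLN: edges only from lower to higher topological position.
random_dag_tln <- function(n, p_edge = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n))
  signs <- ifelse(stats::runif(n) < 0.5, "I", "E")
  src <- tgt <- character(0)
  w <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) {
      src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j])
      w <- c(w, stats::runif(1, 0.2, 1.5))
    }
  if (!length(src)) { src <- nodes[1]; tgt <- nodes[2]; w <- 1 }
  g <- signed_digraph(nodes, signs, data.frame(source = src, target = tgt),
                      weights = w)
  list(g = g, net = tln_from_graph(g, b = stats::runif(n, 0, 1)))
}

# Random cycle TLN away from the classification boundaries (relative margin
# on every evaluated inequality).
boundary_safe_cycle <- function(n, nI, margin = 0.02, seed = NULL) {
  c <- generate_random_cycle_tln(n, nI, seed = seed)
  rg <- classify_regime(c)
  if (rg$label %in% c("INDETERMINATE_GAP", "OUT_OF_SCOPE")) return(NULL)
  if (length(rg$segment_products) &&
      any(abs(rg$segment_products / rg$input_ratios - 1) < margin))
    return(NULL)
  if (abs(rg$geometric_mean / rg$threshold - 1) < margin) return(NULL)
  list(cycle = c, regime = rg$label)
}
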