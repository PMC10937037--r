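# Numerical experiments that confront the structural theory with simulated
# dynamics. These are the package's standing validation protocols; the
# acceptance script and the test suite both run them.

#' Regime classification versus simulated dynamics
#'
#' Draws random single-cycle networks (ring length 2-6), discards those
#' within `margin` relative distance of a classification boundary (where the
#' theory is silent), and confronts the two decisive labels with simulation:
#' `ODD_UNSTABLE_OSCILLATORY` must produce a sustained oscillation, and
#' `WEAK_GLOBAL_STABLE` must converge to a common fixed point from
#' `n_starts` random admissible initial states.
#'
#' @param n_networks number of boundary-safe networks to test (default 200).
#' @param seed integer seed.
#' @param margin relative boundary-exclusion margin (default 0.02).
#' @param n_starts initial states per weak-coupling network (default 5).
#' @param T_osc,T_weak simulation horizons (time units).
#' @return list with counts (`n_networks`, `n_oscillatory`, `n_weak`,
#'   `n_other`) and `contradictions` (0 when theory and dynamics agree).
#' @export
regime_concordance <- function(n_networks = 200, seed = 1, margin = 0.02,
                               n_starts = 5, T_osc = 400, T_weak = 250) {
  set.seed(seed)
  done <- 0; tried <- 0
  n_osc <- 0; n_weak <- 0; contradictions <- 0
  while (done < n_networks && tried < 100 * n_networks) {
    tried <- tried + 1
    n <- sample(2:6, 1)
    nI <- sample(n, 1)
    if (n == 2 && nI == 1) nI <- 2
    c <- generate_random_cycle_tln(n, nI)
    rg <- classify_regime(c)
    if (rg$label %in% c("INDETERMINATE_GAP", "OUT_OF_SCOPE")) next
    if (length(rg$segment_products) &&
        any(abs(rg$segment_products / rg$input_ratios - 1) < margin)) next
    if (abs(rg$geometric_mean / rg$threshold - 1) < margin) next
    done <- done + 1
    if (rg$label == "ODD_UNSTABLE_OSCILLATORY") {
      n_osc <- n_osc + 1
      tr <- simulate_tln(c, T = T_osc, thin = 10)
      if (classify_trajectory(tr) != "sustained-oscillation")
        contradictions <- contradictions + 1
    } else if (rg$label == "WEAK_GLOBAL_STABLE") {
      n_weak <- n_weak + 1
      finals <- vapply(seq_len(n_starts), function(i) {
        tr <- simulate_tln(c, T = T_weak, thin = 100)
        tr$x[nrow(tr$x), ]
      }, numeric(n))
      finals <- matrix(finals, ncol = n_starts)
      dev <- max(apply(finals, 1, function(r)
        diff(range(r)) / max(1, abs(mean(r)))))
      if (dev > 1e-6) contradictions <- contradictions + 1
    }
  }
  list(n_networks = done, n_oscillatory = n_osc, n_weak = n_weak,
       n_other = done - n_osc - n_weak, contradictions = contradictions)
}

#' Bisect the critical coupling of a uniform all-inhibitory ring
#'
#' For the uniform ring of `n` inhibitory nodes with unit inputs, the
#' full-support fixed point loses stability at `w = 1/cos(pi/n)` (2 for
#' `n = 3`). This experiment locates the boundary purely dynamically:
#' bisection on `w` over whether a long simulation sustains an oscillation.
#'
#' @param n ring length (default 3).
#' @param lo,hi initial bracket (must classify as non-oscillating /
#'   oscillating respectively).
#' @param iters bisection iterations (default 6).
#' @param seed seed for initial states; `T` horizon per probe.
#' @return list with `estimate` (bracket midpoint), `bracket`, and the
#'   analytic `threshold`.
#' @export
critical_coupling <- function(n = 3, lo = 1, hi = 4, iters = 6, seed = 1,
                              T = 400) {
  oscillates <- function(w) {
    c <- cycle_tln(rep("I", n), rep(w, n), rep(1, n))
    set.seed(seed)
    tr <- simulate_tln(c, T = T, thin = 10)
    classify_trajectory(tr) == "sustained-oscillation"
  }
  if (oscillates(lo) || !oscillates(hi))
    stop("bracket does not straddle the oscillation boundary")
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oscillates(mid)) hi <- mid else lo <- mid
  }
  list(estimate = (lo + hi) / 2, bracket = c(lo, hi),
       threshold = 1 / cos(pi / n))
}

#' Multi-start convergence on random acyclic networks
#'
#' Generates random acyclic signed TLNs, computes the forward-propagated
#' fixed point, and verifies convergence there from random initial states —
#' the global-stability claim for cycle-free interaction graphs.
#'
#' @param n_graphs number of random acyclic networks (default 50).
#' @param max_nodes maximum node count (default 8).
#' @param n_starts initial states per network (default 3).
#' @param seed integer seed; `T` horizon.
#' @return list with `n_graphs` and `max_deviation` (worst final distance
#'   from the propagated fixed point).
#' @export
dag_convergence <- function(n_graphs = 50, max_nodes = 8, n_starts = 3,
                            seed = 1, T = 60) {
  set.seed(seed)
  worst <- 0
  for (g_i in seq_len(n_graphs)) {
    n <- sample(2:max_nodes, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    signs <- ifelse(stats::runif(n) < 0.5, "I", "E")
    src <- tgt <- character(0); w <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < 0.4) {
        src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j])
        w <- c(w, stats::runif(1, 0.2, 1.5))
      }
    if (!length(src)) { src <- nodes[1]; tgt <- nodes[2]; w <- 1 }
    g <- signed_digraph(nodes, signs, data.frame(source = src, target = tgt),
                        weights = w)
    net <- tln_from_graph(g, b = stats::runif(n, 0, 1))
    fp <- dag_fixed_point(net, g)
    for (s in seq_len(n_starts)) {
      tr <- simulate_tln(net, x0 = stats::runif(n, 0, 2), T = T, thin = 100)
      worst <- max(worst, max(abs(tr$x[nrow(tr$x), ] - fp$x)))
    }
  }
  list(n_graphs = n_graphs, max_deviation = worst)
}

#' Quench predictions versus simulation on random weak cycles
#'
#' On random weak-coupling cycles (whose full-support fixed point is
#' globally stable, so every node is active), injects extra input into an
#' excited node at two levels: one above the silencing bound
#' (`b_extra * prod(w) > b_target`, predicted to pin the downstream
#' inhibited node at zero forever) and one inside the guaranteed-survival
#' zone (total propagated drive below `b_target`). Each prediction is
#' checked against a simulation.
#'
#' @param n_cycles number of cycles (default 20).
#' @param seed integer seed; `T` horizon.
#' @return list with `n_cycles`, `n_checks` and `disagreements`.
#' @export
quench_check <- function(n_cycles = 20, seed = 1, T = 200) {
  set.seed(seed)
  done <- 0; tried <- 0; checks <- 0; bad <- 0
  while (done < n_cycles && tried < 200 * n_cycles) {
    tried <- tried + 1
    n <- sample(3:6, 1)
    nI <- sample(n - 1, 1)
    c <- generate_random_cycle_tln(n, nI, weight_range = c(0.3, 0.95))
    if (classify_regime(c)$label != "WEAK_GLOBAL_STABLE") next
    excited <- setdiff(seq_len(c$n), c$A)
    node <- excited[sample(length(excited), 1)]
    probe <- quench_condition(c, node, 1)
    gain <- probe$lhs; b_t <- probe$rhs
    upstream <- quench_condition(c, node, -1e-12)$lhs  # b_{a_k} * P_k
    bex_keep <- 0.9 * (0.95 * b_t - upstream) / gain
    if (bex_keep <= 0) next
    done <- done + 1
    for (bex in c(1.5 * b_t / gain, bex_keep)) {
      q <- quench_condition(c, node, bex)
      net <- as_tln(c)
      net$b[node] <- net$b[node] + bex
      tr <- simulate_tln(tln_network(net$W, net$b),
                         x0 = random_initial_state(c), T = T, thin = 10)
      lastmax <- max(tr$x[((nrow(tr$x) * 3) %/% 4):nrow(tr$x), q$target])
      checks <- checks + 1
      ok <- if (q$prediction == "oscillation-destroyed") lastmax < 1e-8
            else lastmax > 1e-4
      if (!ok) bad <- bad + 1
    }
  }
  list(n_cycles = done, n_checks = checks, disagreements = bad)
}
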