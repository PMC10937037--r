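# Regime classification and spectral analysis of single-cycle TLNs.

.cycle_segments <- function(c) {
  # per inhibited node a_k: the cyclic product of weights from a_k up to the
  # node before the next inhibited node, and the matching input ratio
  n <- c$n; A <- c$A
  nI <- length(A)
  P <- R <- numeric(nI)
  for (k in seq_len(nI)) {
    a <- A[k]
    a_next <- A[if (k < nI) k + 1 else 1]
    seg_len <- ((a_next - a - 1) %% n) + 1
    idx <- ((a - 1 + seq_len(seg_len) - 1) %% n) + 1
    P[k] <- prod(c$w[idx])
    R[k] <- c$b[a_next] / c$b[a]
  }
  list(P = P, R = R)
}

#' Coupling-regime classification of a single-cycle TLN
#'
#' Determines the long-term behavior of a directed-ring threshold-linear
#' network from its weights and inputs alone. With inhibited nodes
#' `a_1 < ... < a_nI`, segment products `P_k = prod(w_i, i = a_k ..
#' a_{k+1}-1)` and input ratios `R_k = b_{a_{k+1}} / b_{a_k}`:
#' \itemize{
#'   \item all `P_k < R_k` (weak coupling): a unique globally asymptotically
#'     stable fixed point with full support — `WEAK_GLOBAL_STABLE`;
#'   \item all `P_k > R_k` (strong coupling) and `nI` even: two
#'     asymptotically stable fixed points with strictly complementary
#'     supports — `EVEN_BISTABLE` (winner-take-all);
#'   \item all `P_k > R_k`, `nI` odd and geometric mean
#'     `rho = (prod w_i)^(1/n) < 1/cos(pi/n)`: a unique asymptotically (not
#'     globally) stable full-support fixed point — `ODD_STABLE`;
#'   \item all `P_k > R_k`, `nI` odd and `rho > 1/cos(pi/n)`: the unique
#'     full-support fixed point is unstable and the bounded dynamics must
#'     oscillate (limit cycle, quasi-periodic or chaotic) —
#'     `ODD_UNSTABLE_OSCILLATORY`.
#' }
#' Mixed segment comparisons, or any comparison within relative tolerance of
#' its bound, fall into the gap the theory leaves open and return
#' `INDETERMINATE_GAP`. Purely excitatory rings (`nI = 0`) and the two-node
#' EI pair (which always converges; see [cycle_eigenvalues()]) return
#' `OUT_OF_SCOPE`.
#'
#' @param c a [cycle_tln()].
#' @param tol relative tolerance for inequality evaluation (default 1e-9);
#'   within-tolerance equality is never resolved by guessing.
#' @return object of class `regime_classification`: `label` plus the
#'   evaluated quantities (`segment_products`, `input_ratios`,
#'   `geometric_mean`, `threshold`).
#' @export
classify_regime <- function(c, tol = 1e-9) {
  stopifnot(inherits(c, "cycle_tln"))
  n <- c$n
  rho <- exp(mean(log(c$w)))
  thr <- 1 / cos(pi / n)
  res <- function(label, P = numeric(0), R = numeric(0)) {
    structure(list(label = label, segment_products = P, input_ratios = R,
                   geometric_mean = rho, threshold = thr, n = n, nI = c$nI),
              class = "regime_classification")
  }
  if (c$nI == 0) return(res("OUT_OF_SCOPE"))
  if (c$n == 2 && c$nI == 1) return(res("OUT_OF_SCOPE"))
  sg <- .cycle_segments(c)
  cmp <- function(x, y) {                     # -1 below, +1 above, 0 within tol
    ifelse(abs(x - y) <= tol * pmax(abs(x), abs(y), 1), 0L, ifelse(x < y, -1L, 1L))
  }
  seg_cmp <- cmp(sg$P, sg$R)
  if (any(seg_cmp == 0L)) return(res("INDETERMINATE_GAP", sg$P, sg$R))
  if (all(seg_cmp < 0L)) return(res("WEAK_GLOBAL_STABLE", sg$P, sg$R))
  if (!all(seg_cmp > 0L)) return(res("INDETERMINATE_GAP", sg$P, sg$R))
  if (c$nI %% 2 == 0) return(res("EVEN_BISTABLE", sg$P, sg$R))
  rc <- cmp(rho, thr)
  if (rc == 0L) return(res("INDETERMINATE_GAP", sg$P, sg$R))
  if (rc < 0L) res("ODD_STABLE", sg$P, sg$R)
  else res("ODD_UNSTABLE_OSCILLATORY", sg$P, sg$R)
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("regime: %s (n = %d, nI = %d, geometric mean %.4g, threshold 1/cos(pi/n) = %.4g)\n",
              x$label, x$n, x$nI, x$geometric_mean, x$threshold))
  invisible(x)
}

#' Closed-form spectrum of the full-support Jacobian of a cycle
#'
#' On its full support the linearization of a directed-ring TLN is
#' `-I + W`, whose eigenvalues have the closed form `-1 + rho * zeta`, where
#' `rho = (prod w_i)^(1/n)` and `zeta` ranges over the n-th roots of
#' `(-1)^nI`. For odd `nI` the largest real part is
#' `-1 + rho cos(pi/n)`, which crosses zero exactly at the coupling
#' threshold `rho = 1/cos(pi/n)`. For the EI pair with `w1 = w2 = 1` the
#' spectrum is `-1 +/- i`.
#'
#' @param c a [cycle_tln()].
#' @return complex vector of the `n` eigenvalues, ordered by decreasing
#'   real part.
#' @export
cycle_eigenvalues <- function(c) {
  stopifnot(inherits(c, "cycle_tln"))
  n <- c$n
  rho <- exp(mean(log(c$w)))
  k <- 0:(n - 1)
  zeta <- exp(1i * pi * (c$nI + 2 * k) / n)
  ev <- -1 + rho * zeta
  ev[order(-Re(ev), Im(ev))]
}

#' Effect of extra input to an excited node of a cycle
#'
#' In the single-cycle theory, excited nodes (those between inhibited nodes
#' in cyclic order) carry no external input. Injecting a constant extra
#' input `b_extra` into excited node `i` changes the picture:
#' \itemize{
#'   \item `b_extra > 0`: node `i`'s activity exceeds `b_extra`, so the next
#'     inhibited node `a_{k+1}` is silenced forever once
#'     `b_extra * prod(w_j, j = i .. a_{k+1}-1) > b_{a_{k+1}}` — the cycle is
#'     structurally broken and oscillations are prevented
#'     (`"oscillation-destroyed"`); otherwise the prediction is
#'     `"not-destroyed"`.
#'   \item `b_extra < 0`: the weak-coupling inequality of the segment is
#'     modified to `b_{a_k} * P_k + b_extra * prod(w_j, j = i ..
#'     a_{k+1}-1) < b_{a_{k+1}}` (the negative drive propagates down the
#'     segment with the same weight product), returned as
#'     `"modified-threshold"` with the evaluated bound.
#'   \item `b_extra = 0`: `"unchanged"`.
#' }
#'
#' @param c a [cycle_tln()].
#' @param node index of an excited node (error if the node is inhibited).
#' @param b_extra constant extra input.
#' @return list with `prediction`, the silenced/affected node `target`
#'   (`a_{k+1}`), and the evaluated `lhs`/`rhs` of the relevant inequality.
#' @export
quench_condition <- function(c, node, b_extra) {
  stopifnot(inherits(c, "cycle_tln"))
  if (c$nI == 0) stop("cycle has no inhibited node")
  if (node %in% c$A) stop("node ", node, " is an inhibited node, not an excited one")
  stopifnot(node >= 1, node <= c$n)
  n <- c$n
  # segment containing `node`: inhibited node a_k at or before it, a_{k+1} after
  dist_after <- ((c$A - node) %% n)
  dist_after[dist_after == 0] <- n
  a_next <- c$A[which.min(dist_after)]
  seg_len <- ((a_next - node - 1) %% n) + 1
  idx <- ((node - 1 + seq_len(seg_len) - 1) %% n) + 1
  gain <- prod(c$w[idx])                  # prod of w from node to a_{k+1}-1
  if (b_extra == 0)
    return(list(prediction = "unchanged", target = a_next,
                lhs = 0, rhs = c$b[a_next]))
  if (b_extra > 0) {
    lhs <- b_extra * gain
    pred <- if (lhs > c$b[a_next]) "oscillation-destroyed" else "not-destroyed"
    return(list(prediction = pred, target = a_next, lhs = lhs,
                rhs = c$b[a_next]))
  }
  # negative extra input: modified weak-coupling bound for the segment
  dist_before <- ((node - c$A) %% n)
  dist_before[dist_before == 0] <- n
  a_prev <- c$A[which.min(dist_before)]
  seg_len0 <- ((a_next - a_prev - 1) %% n) + 1
  idx0 <- ((a_prev - 1 + seq_len(seg_len0) - 1) %% n) + 1
  lhs <- c$b[a_prev] * prod(c$w[idx0]) + b_extra * gain
  list(prediction = "modified-threshold", target = a_next,
       lhs = lhs, rhs = c$b[a_next], weak_condition_satisfied = lhs < c$b[a_next])
}
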