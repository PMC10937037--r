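#' Threshold-linear network TLN(W, b)
#'
#' A threshold-linear network couples `n` nodes through
#' `dx_i/dt = -x_i + [sum_j W_ij x_j + b_i]_+`, where `[u]_+ = max(u, 0)`,
#' `W_ij` is the connection strength from node `j` to node `i` and `b` is a
#' constant external input. When node signs are supplied, every nonzero
#' entry of column `j` must carry the sign of node `j` (negative for
#' inhibitory nodes), mirroring the signed-digraph convention.
#'
#' @param W numeric `n x n` matrix, `W[i, j]` = strength from `j` to `i`.
#' @param b numeric length-`n` input vector.
#' @param signs optional character vector of `"E"`/`"I"` per node; enforces
#'   column-sign consistency.
#' @param names optional node names.
#' @return object of class `tln_network`.
#' @export
tln_network <- function(W, b, signs = NULL, names = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, length(b) == n)
  if (!is.null(signs)) {
    signs <- toupper(signs)
    stopifnot(length(signs) == n, all(signs %in% c("E", "I")))
    for (j in seq_len(n)) {
      col <- W[, j][W[, j] != 0]
      want <- if (signs[j] == "I") -1 else 1
      if (length(col) && any(sign(col) != want))
        stop("column ", j, " has entries inconsistent with node sign ", signs[j])
    }
  }
  if (is.null(names)) names <- paste0("x", seq_len(n))
  structure(list(n = n, W = W, b = as.numeric(b), signs = signs,
                 names = names),
            class = "tln_network")
}

#' @export
print.tln_network <- function(x, ...) {
  cat(sprintf("tln_network: %d nodes\n", x$n))
  invisible(x)
}

#' Build a threshold-linear network from a signed digraph
#'
#' Edge weight magnitudes of the graph become `|W_ij|`; signs follow the
#' source node (`-` for inhibitory).
#'
#' @param g a [signed_digraph()].
#' @param b input vector (default 0).
#' @return a [tln_network()].
#' @export
tln_from_graph <- function(g, b = NULL) {
  n <- length(g$nodes)
  W <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$target[k]; j <- g$edges$source[k]
    W[i, j] <- g$edges$weight[k] * if (g$sign[j] == "I") -1 else 1
  }
  if (is.null(b)) b <- rep(0, n)
  tln_network(W, b, signs = unname(g$sign), names = g$nodes)
}

#' Single-cycle threshold-linear network
#'
#' The object of the single-cycle stability theory: `n` nodes arranged in a
#' directed ring, node `i` projecting to node `i + 1` (cyclically) with
#' positive weight magnitude `w[i]` and sign given by node `i`'s type.
#' The *inhibited* nodes `A = {a_1 < ... < a_nI}` are those whose cyclic
#' predecessor is inhibitory; exactly these receive a positive constant
#' external input, which keeps them active when their inhibitory afferent
#' falls silent. Inputs on excited nodes must be zero (see
#' [quench_condition()] for the effect of relaxing this).
#'
#' The ring must have at least two nodes, and at least three when only one
#' node is inhibitory; the two-node EI pair is still constructible because
#' its full-support linearization (eigenvalues `-1 +/- i sqrt(w1 w2)`) is a
#' useful reference case, but [classify_regime()] reports it as out of scope
#' of the regime classification: it always converges to a unique globally
#' stable fixed point.
#'
#' @param signs character vector of `"E"`/`"I"`, length `n >= 2`.
#' @param w positive weight magnitudes; `w[i]` sits on the edge
#'   `i -> i + 1` (cyclically, so `w[n]` on `n -> 1`).
#' @param b external inputs; positive exactly on inhibited nodes. If `NULL`,
#'   set to 1 on inhibited nodes and 0 elsewhere.
#' @return object of class `cycle_tln` with derived fields `nI`, `nE` and
#'   `A` (sorted inhibited-node indices).
#' @export
cycle_tln <- function(signs, w, b = NULL) {
  signs <- toupper(signs)
  n <- length(signs)
  stopifnot(n >= 2, all(signs %in% c("E", "I")), length(w) == n, all(w > 0))
  nI <- sum(signs == "I")
  # n = 2, nI = 1 (the EI pair) is constructible as a reference case but
  # sits outside the regime classification (it always converges)
  pred <- c(n, seq_len(n - 1L))          # cyclic predecessor of each node
  A <- which(signs[pred] == "I")
  if (is.null(b)) b <- ifelse(seq_len(n) %in% A, 1, 0)
  stopifnot(length(b) == n)
  if (any(b[A] <= 0)) stop("inhibited nodes must receive positive input b")
  if (any(b[-A] != 0) && length(A) < n)
    stop("excited nodes must have zero input b (see quench_condition)")
  structure(list(n = n, signs = signs, w = as.numeric(w), b = as.numeric(b),
                 nI = nI, nE = n - nI, A = A),
            class = "cycle_tln")
}

#' @export
print.cycle_tln <- function(x, ...) {
  cat(sprintf("cycle_tln: n = %d (%d inhibitory), inhibited nodes {%s}\n",
              x$n, x$nI, paste(x$A, collapse = ", ")))
  invisible(x)
}

#' Convert a single-cycle network to a full TLN
#' @param c a [cycle_tln()].
#' @return a [tln_network()].
#' @export
as_tln <- function(c) {
  stopifnot(inherits(c, "cycle_tln"))
  n <- c$n
  W <- matrix(0, n, n)
  succ <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n))
    W[succ[i], i] <- c$w[i] * if (c$signs[i] == "I") -1 else 1
  tln_network(W, c$b, signs = c$signs)
}

#' Admissible random initial state
#'
#' For a single-cycle network, draws uniformly inside the invariant box used
#' by the stability analysis: within the segment starting at inhibited node
#' `a_k`, node `j` lies in `[0, b_{a_k} * prod(w_{a_k..j-1})]`. For a general
#' network, draws uniformly in `[0, max(|b|, 1)]` per node.
#'
#' @param net a [cycle_tln()] or [tln_network()].
#' @return numeric state vector.
#' @export
random_initial_state <- function(net) {
  if (inherits(net, "cycle_tln")) {
    n <- net$n
    hi <- numeric(n)
    A <- net$A
    if (length(A) == 0) {
      hi[] <- max(net$b, 1)
    } else {
      for (k in seq_along(A)) {
        a <- A[k]
        a_next <- A[if (k < length(A)) k + 1 else 1]
        seg_len <- ((a_next - a - 1) %% n) + 1   # whole ring when nI = 1
        j <- a; cum <- 1
        for (m in seq_len(seg_len)) {
          hi[j] <- net$b[a] * cum
          cum <- cum * net$w[j]
          j <- if (j == n) 1L else j + 1L
        }
      }
    }
    return(stats::runif(n, 0, hi))
  }
  stopifnot(inherits(net, "tln_network"))
  stats::runif(net$n, 0, max(abs(net$b), 1))
}

#' Simulate threshold-linear dynamics
#'
#' Forward-Euler integration of `dx/dt = -x + [W x + b]_+`. With the leak
#' rate fixed at 1, time is measured in units of the node time constant.
#'
#' @param net a [tln_network()] or [cycle_tln()].
#' @param x0 initial state (componentwise nonnegative). Default: a
#'   [random_initial_state()] draw.
#' @param T duration (time units), `dt` step (default 0.01), `thin` record
#'   every `thin`-th step.
#' @return object of class `tln_trajectory`: list with `time` and matrix
#'   `x` (time points by nodes).
#' @export
simulate_tln <- function(net, x0 = NULL, T = 100, dt = 0.01, thin = 1L) {
  cyc <- NULL
  if (inherits(net, "cycle_tln")) { cyc <- net; net <- as_tln(net) }
  stopifnot(inherits(net, "tln_network"), T > 0, dt > 0)
  if (is.null(x0)) x0 <- random_initial_state(if (is.null(cyc)) net else cyc)
  stopifnot(length(x0) == net$n, all(x0 >= 0))
  xm <- tln_euler_cpp(net$W, net$b, as.numeric(x0), T, dt, as.integer(thin))
  structure(list(time = seq(0, by = dt * thin, length.out = nrow(xm)),
                 x = xm, dt = dt * thin),
            class = "tln_trajectory")
}

#' Fixed point of an acyclic threshold-linear network
#'
#' When the interaction graph has no directed cycle, the unique globally
#' asymptotically stable fixed point is obtained exactly by forward
#' propagation in topological order: `x*_i = [sum_j W_ij x*_j + b_i]_+`.
#'
#' @param net a [tln_network()] consistent with `g`.
#' @param g the acyclic [signed_digraph()] of the interactions.
#' @return list with `x` (the fixed point) and `stability`
#'   (`"globally-stable-claimed"`).
#' @export
dag_fixed_point <- function(net, g) {
  stopifnot(inherits(net, "tln_network"), inherits(g, "signed_digraph"))
  ord <- topological_order(g)            # errors on a cyclic graph
  x <- numeric(net$n)
  for (i in ord) x[i] <- max(sum(net$W[i, ] * x) + net$b[i], 0)
  list(x = x, stability = "globally-stable-claimed")
}

#' Enumerate all fixed points of a threshold-linear network
#'
#' Support enumeration: for every candidate support `sigma` the linear
#' system `(I - W_ss) x_s = b_s` is solved; the solution is a fixed point of
#' the full dynamics iff `x_s > 0` and every off-support node receives net
#' input `<= 0`. Linear stability on the support follows from the
#' eigenvalues of `-I + W_ss`. The search is exhaustive over the `2^n`
#' supports, so `n` is guarded at 20.
#'
#' @param net a [tln_network()] (or [cycle_tln()]).
#' @param tol acceptance tolerance for positivity/negativity checks.
#' @return object of class `fixed_point_set`: list of entries with `x`,
#'   `support`, `stability` (`"linearly-stable"`, `"unstable"`,
#'   `"undetermined"`), `eigenvalues`; degenerate (singular) supports are
#'   listed in attribute `"degenerate"`.
#' @export
enumerate_fixed_points <- function(net, tol = 1e-9) {
  if (inherits(net, "cycle_tln")) net <- as_tln(net)
  stopifnot(inherits(net, "tln_network"))
  n <- net$n
  if (n > 20) stop("support enumeration is guarded at 20 nodes")
  out <- list()
  degen <- list()
  for (mask in 0:(2^n - 1)) {
    supp <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0)
    x <- numeric(n)
    if (length(supp)) {
      M <- diag(length(supp)) - net$W[supp, supp, drop = FALSE]
      xs <- tryCatch(solve(M, net$b[supp]), error = function(e) NULL)
      if (is.null(xs)) { degen[[length(degen) + 1]] <- supp; next }
      if (any(xs <= tol)) next
      x[supp] <- xs
    }
    off <- setdiff(seq_len(n), supp)
    if (length(off)) {
      drive <- as.numeric(net$W[off, , drop = FALSE] %*% x) + net$b[off]
      if (any(drive > tol)) next
    }
    if (length(supp)) {
      ev <- eigen(-diag(length(supp)) + net$W[supp, supp, drop = FALSE],
                  only.values = TRUE)$values
      mre <- max(Re(ev))
      stab <- if (mre < -tol) "linearly-stable"
              else if (mre > tol) "unstable" else "undetermined"
    } else {
      ev <- complex(0)
      stab <- "linearly-stable"          # all nodes leak to zero
    }
    out[[length(out) + 1]] <- list(x = x, support = supp, stability = stab,
                                   eigenvalues = ev)
  }
  structure(out, degenerate = degen, class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("fixed_point_set: %d fixed point(s)\n", length(x)))
  for (fp in x)
    cat(sprintf("  support {%s} %s\n", paste(fp$support, collapse = ","),
                fp$stability))
  invisible(x)
}
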