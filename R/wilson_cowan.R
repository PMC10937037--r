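# Delayed Wilson-Cowan rate model of basal-ganglia motifs.

#' Sigmoidal activation of the Wilson-Cowan model
#'
#' `F(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`. The offset
#' makes `F(0) = 0`, so a silent network stays silent; `F` is strictly
#' increasing with slope `a/4` at the inflection point `theta`, and is
#' bounded above by `1 - 1/(1 + exp(a theta))`.
#'
#' @param x input (drive).
#' @param a slope parameter (default 3).
#' @param theta inflection point (default 1.5).
#' @return activation value(s).
#' @export
wc_activation <- function(x, a = 3, theta = 1.5) {
  1 / (1 + exp(-a * (x - theta))) - 1 / (1 + exp(a * theta))
}

#' Delayed Wilson-Cowan network
#'
#' Populations coupled through
#' `tau dr_i/dt = -r_i + F(sum_j w_ij r_j(t - d_ij) + I_i)`, with
#' [wc_activation()] as gain function, per-edge transmission delays and
#' constant external inputs. Time is in milliseconds; with the default
#' `tau = 20` ms the model operates on cortical population timescales and
#' oscillation frequencies come out in Hz.
#'
#' @param names population names.
#' @param W signed weight matrix (`W[i, j]` from `j` to `i`).
#' @param delays per-edge delay matrix (ms), or a scalar applied to all
#'   edges; entries for absent edges are ignored.
#' @param I_ext external input per population.
#' @param tau,a,theta model constants (defaults 20 ms, 3, 1.5).
#' @return object of class `wc_network`.
#' @export
wc_network <- function(names, W, delays = 0, I_ext, tau = 20, a = 3,
                       theta = 1.5) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, length(I_ext) == n, length(names) == n,
            tau > 0, a > 0)
  if (length(delays) == 1) delays <- matrix(delays, n, n)
  delays <- as.matrix(delays)
  stopifnot(all(dim(delays) == n), all(delays >= 0))
  dimnames(W) <- dimnames(delays) <- list(names, names)
  structure(list(names = names, W = W, delays = delays,
                 I_ext = stats::setNames(as.numeric(I_ext), names),
                 tau = tau, a = a, theta = theta),
            class = "wc_network")
}

#' @export
print.wc_network <- function(x, ...) {
  cat(sprintf("wc_network: %d populations (%s), tau = %g ms\n",
              length(x$names), paste(x$names, collapse = ", "), x$tau))
  invisible(x)
}

#' Simulate a delayed Wilson-Cowan network
#'
#' Euler integration with per-edge delay buffers; rates before `t = 0` are
#' held at the initial state. Delays are rounded to integer multiples of
#' `dt` (the rounded values are attached as attribute `"delay_steps"`).
#'
#' @param net a [wc_network()].
#' @param r0 initial rate(s), in `[0, 1)`. A scalar `r0` is expanded to the
#'   graded vector `r0 + 0.01 * (0:(n-1))`: homogeneous motifs have an exact
#'   permutation symmetry, and a perfectly symmetric start would trap the
#'   (symmetry-preserving) integrator on the non-oscillating symmetric
#'   manifold forever.
#' @param T duration (ms, default 5000), `dt` Euler step (ms, default 0.01),
#'   `thin` record every `thin`-th step (default 100, i.e. 1 kHz sampling).
#' @return object of class `wc_trajectory`: `time` (ms), matrix `r`, `fs`
#'   (sampling rate of the record in Hz).
#' @export
simulate_wc <- function(net, r0 = 0.1, T = 5000, dt = 0.01, thin = 100L) {
  stopifnot(inherits(net, "wc_network"), T > 0, dt > 0)
  n <- length(net$names)
  if (length(r0) == 1) r0 <- r0 + 0.01 * (seq_len(n) - 1)
  stopifnot(length(r0) == n, all(r0 >= 0), all(r0 < 1))
  dsteps <- matrix(as.integer(round(net$delays / dt)), n, n)
  r <- wc_euler_cpp(net$W, dsteps, unname(net$I_ext), net$tau, net$a,
                    net$theta, as.numeric(r0), T, dt, as.integer(thin))
  colnames(r) <- net$names
  structure(list(time = seq(0, by = dt * thin, length.out = nrow(r)),
                 r = r, fs = 1000 / (dt * thin)),
            class = "wc_trajectory", delay_steps = dsteps)
}

#' Remove connections and override inputs (lesion experiment)
#'
#' Returns a modified copy of the network with the named projections set to
#' zero weight and external inputs overridden; the original is unchanged.
#' Edges are given as `"Source->Target"` strings; `"Source->*"` removes all
#' outgoing projections of a population.
#'
#' @param net a [wc_network()].
#' @param edges_to_remove character vector of `"Source->Target"` edges
#'   (must exist, i.e. have nonzero weight).
#' @param input_overrides named numeric vector of replacement external
#'   inputs.
#' @return the lesioned [wc_network()].
#' @export
lesion <- function(net, edges_to_remove = character(0),
                   input_overrides = NULL) {
  stopifnot(inherits(net, "wc_network"))
  out <- net
  for (e in edges_to_remove) {
    parts <- strsplit(e, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("edge must be 'Source->Target': ", e)
    src <- trimws(parts[1]); tgt <- trimws(parts[2])
    if (!(src %in% net$names)) stop("unknown population: ", src)
    if (tgt == "*") {
      out$W[, src] <- 0
      next
    }
    if (!(tgt %in% net$names)) stop("unknown population: ", tgt)
    if (net$W[tgt, src] == 0) stop("no such edge: ", e)
    out$W[tgt, src] <- 0
  }
  if (!is.null(input_overrides)) {
    bad <- setdiff(names(input_overrides), net$names)
    if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
    out$I_ext[names(input_overrides)] <- input_overrides
  }
  out
}

# classify a Wilson-Cowan trajectory after discarding the settle-in window;
# frequency comes from the population with the largest amplitude
.wc_oscillation <- function(traj, settle = 0.5, floor = 1e-3) {
  keep <- traj$time >= settle * max(traj$time)
  r <- traj$r[keep, , drop = FALSE]
  amps <- apply(r, 2, function(col) diff(range(col)))
  lead <- which.max(amps)
  oc <- oscillation_class(r[, lead], traj$fs, floor = floor)
  oc$population <- colnames(traj$r)[lead]
  oc
}

#' Parameter sweep of oscillation frequency
#'
#' Re-simulates the network over a grid of one homogeneous parameter and
#' reports the dominant oscillation frequency at each value (0 when the
#' network does not sustain an oscillation). In each run the parameter is
#' applied to all relevant entries at once:
#' \describe{
#'   \item{`delay`}{all existing synapses get the given delay (ms).}
#'   \item{`weight`}{all off-diagonal nonzero weights get the given
#'     magnitude, signs preserved.}
#'   \item{`input`}{all external inputs set to the value.}
#'   \item{`self-connection`}{all diagonal entries set to the (signed)
#'     value.}
#' }
#'
#' @param net a [wc_network()].
#' @param parameter one of `"delay"`, `"weight"`, `"input"`,
#'   `"self-connection"`.
#' @param grid numeric grid of parameter values (non-empty).
#' @param T,dt simulation duration and step (ms); the first half of each run
#'   is discarded as transient.
#' @return `sweep_result` data frame: `value`, `frequency` (Hz, 0 when not
#'   sustained), `class`.
#' @export
frequency_sweep <- function(net, parameter = c("delay", "weight", "input",
                                               "self-connection"),
                            grid, T = 3000, dt = 0.01) {
  stopifnot(inherits(net, "wc_network"))
  parameter <- match.arg(parameter)
  if (!length(grid)) stop("empty parameter grid")
  rows <- lapply(grid, function(v) {
    m <- net
    switch(parameter,
      "delay" = { m$delays[m$W != 0] <- v },
      "weight" = {
        off <- m$W != 0 & row(m$W) != col(m$W)
        m$W[off] <- sign(m$W[off]) * v
      },
      "input" = { m$I_ext[] <- v },
      "self-connection" = { diag(m$W) <- v })
    traj <- simulate_wc(m, T = T, dt = dt)
    oc <- .wc_oscillation(traj)
    data.frame(value = v,
               frequency = if (oc$class == "sustained") oc$frequency else 0,
               class = oc$class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}
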