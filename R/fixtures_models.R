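#' Built-in Wilson-Cowan parameter sets
#'
#' Named rate-model fixtures:
#' \describe{
#'   \item{`III`}{three mutually inhibiting populations in a ring,
#'     cross-inhibition -15, external input 6, zero delay — the canonical
#'     odd-inhibitory (winner-less competition) oscillator.}
#'   \item{`EII`}{ring E1 -> I1 -> I2 -> E1 with excitatory weight +15,
#'     inhibitory weights -15, inputs 6, zero delay — an even-inhibitory
#'     (positive) loop capable of transient ringing only.}
#'   \item{`EI`}{reciprocal excitatory-inhibitory pair (+15/-15, inputs 6,
#'     zero delay); without delays this pair converges, delays can make it
#'     ring.}
#'   \item{`BG4`}{four-population basal-ganglia subnetwork D2, Arky, Proto,
#'     STN: Arky -> D2 (-15), Proto -> Arky (-15), STN -> Arky (+15),
#'     D2 -> Proto (-15), Proto self-inhibition (-8), STN -> Proto (+15),
#'     Proto -> STN (-15), STN self-excitation (+5), delays 2 ms, inputs
#'     (D2, Arky, Proto, STN) = (4, 3, `proto_input`, 4). It contains the
#'     Proto-STN pair and the Proto-Arky-D2 triangle as competing
#'     oscillators.}
#' }
#'
#' @param name fixture name.
#' @param proto_input external input to Proto in `BG4` (1 in the intact and
#'   D2-lesion settings; 4 when STN output is removed, to restore Proto
#'   baseline activity).
#' @param stn_self keep the printed STN self-excitation of +5 (`TRUE`,
#'   default) or zero it.
#' @return a [wc_network()].
#' @export
wc_fixture <- function(name = c("III", "EII", "EI", "BG4"),
                       proto_input = 1, stn_self = TRUE) {
  name <- match.arg(name)
  switch(name,
    "III" = wc_network(c("I1", "I2", "I3"),
                       W = rbind(c(0, 0, -15),
                                 c(-15, 0, 0),
                                 c(0, -15, 0)),
                       delays = 0, I_ext = c(6, 6, 6)),
    "EII" = wc_network(c("E1", "I1", "I2"),
                       W = rbind(c(0, 0, -15),
                                 c(15, 0, 0),
                                 c(0, -15, 0)),
                       delays = 0, I_ext = c(6, 6, 6)),
    "EI" = wc_network(c("E1", "I1"),
                      W = rbind(c(0, -15),
                                c(15, 0)),
                      delays = 0, I_ext = c(6, 6)),
    "BG4" = wc_network(c("D2", "Arky", "Proto", "STN"),
                       W = rbind(c(0, -15, 0, 0),
                                 c(0, 0, -15, 15),
                                 c(-15, 0, -8, 15),
                                 c(0, 0, -15, if (stn_self) 5 else 0)),
                       delays = 2,
                       I_ext = c(4, 3, proto_input, 4)))
}

#' Random single-cycle TLN generator
#'
#' Draws a valid [cycle_tln()]: `nI` inhibitory nodes placed uniformly at
#' random among the `n` ring positions, weights log-uniform in
#' `weight_range`, inputs uniform in `input_range` on the inhibited nodes
#' and zero elsewhere. Deterministic for a given seed.
#'
#' @param n ring length (`>= 2`; `>= 3` when `nI = 1`).
#' @param nI number of inhibitory nodes, `1 <= nI <= n`.
#' @param weight_range positive range for the log-uniform weight draw.
#' @param input_range positive range for the uniform input draw.
#' @param seed optional integer seed.
#' @return a [cycle_tln()].
#' @export
generate_random_cycle_tln <- function(n, nI, weight_range = c(0.2, 5),
                                      input_range = c(0.5, 2), seed = NULL) {
  stopifnot(n >= 2, nI >= 1, nI <= n,
            all(weight_range > 0), all(input_range > 0))
  if (nI == 1 && n < 3)
    stop("a cycle with one inhibitory node needs at least 3 nodes")
  if (!is.null(seed)) set.seed(seed)
  signs <- rep("E", n)
  signs[sample.int(n, nI)] <- "I"
  w <- exp(stats::runif(n, log(weight_range[1]), log(weight_range[2])))
  pred <- c(n, seq_len(n - 1L))
  A <- which(signs[pred] == "I")
  b <- numeric(n)
  b[A] <- stats::runif(length(A), input_range[1], input_range[2])
  cycle_tln(signs, w, b)
}
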