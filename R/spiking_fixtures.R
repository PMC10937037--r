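#' Built-in spiking basal-ganglia motif configurations
#'
#' Named spiking-network fixtures at desk scale (default 300 neurons per
#' population). Neuron and synapse parameters are the package's documented,
#' non-canonical defaults (see the methods vignette); connection structure
#' follows the basal-ganglia motifs:
#' \describe{
#'   \item{`proto-fsn-d2`}{the Proto -> FSN -> D2 -> Proto inhibitory
#'     triangle (three inhibitory projections, a negative loop).}
#'   \item{`proto-arky-d2`}{the Proto -> Arky -> D2 -> Proto inhibitory
#'     triangle.}
#'   \item{`proto-d2-arky-stn`}{the Proto-Arky-D2 triangle with the STN
#'     attached (Proto -> STN inhibitory, STN -> Proto weakly excitatory):
#'     the triangle is the dominant oscillator, so STN inhibition should
#'     spare the Proto rhythm.}
#'   \item{`proto-stn`}{the reciprocal Proto-STN loop as dominant oscillator
#'     (strong mutual coupling, D2 and Arky present but weakly driven):
#'     silencing the STN removes the only negative loop.}
#' }
#'
#' @param name fixture name.
#' @param n_per_pop neurons per population (default 300).
#' @return a [spiking_config()].
#' @export
spiking_fixture <- function(name = c("proto-fsn-d2", "proto-arky-d2",
                                     "proto-d2-arky-stn", "proto-stn"),
                            n_per_pop = 300) {
  name <- match.arg(name)
  nd <- .bg_neuron_defaults()
  pop <- function(nm, rate_ext, J_ext = 1, I_dc = 0)
    spiking_population(nm, n_per_pop, .bg_signs[[nm]], nd[[nm]],
                       tau_inh = 4, rate_ext = rate_ext, J_ext = J_ext,
                       I_dc = I_dc)
  con <- function(source, target, J, delay, p = 0.2)
    data.frame(source = source, target = target, J = J, delay = delay, p = p)
  triangle <- function(second) rbind(                  # Proto -> second -> D2 -> Proto
    con("Proto", second, J = 0.8, delay = 2),
    con(second, "D2", J = 0.6, delay = 4),
    con("D2", "Proto", J = 0.8, delay = 4))
  switch(name,
    "proto-fsn-d2" = spiking_config(
      list(pop("Proto", rate_ext = 675), pop("FSN", rate_ext = 400),
           pop("D2", rate_ext = 700)),
      triangle("FSN")),
    "proto-arky-d2" = spiking_config(
      list(pop("Proto", rate_ext = 675), pop("Arky", rate_ext = 480),
           pop("D2", rate_ext = 700)),
      triangle("Arky")),
    "proto-d2-arky-stn" = spiking_config(
      list(pop("Proto", rate_ext = 675), pop("Arky", rate_ext = 480),
           pop("D2", rate_ext = 700), pop("STN", rate_ext = 250, I_dc = 1)),
      rbind(triangle("Arky"),
            con("Proto", "STN", J = 0.8, delay = 4),
            con("STN", "Proto", J = 0.2, delay = 2, p = 0.1))),
    "proto-stn" = spiking_config(
      list(pop("Proto", rate_ext = 250), pop("Arky", rate_ext = 250),
           pop("D2", rate_ext = 300), pop("STN", rate_ext = 280, I_dc = 30)),
      rbind(con("Proto", "Arky", J = 0.8, delay = 2),
            con("Arky", "D2", J = 0.6, delay = 4),
            con("D2", "Proto", J = 0.2, delay = 4),
            con("Proto", "STN", J = 0.1, delay = 4),
            con("STN", "Proto", J = 0.5, delay = 2))))
}

#' STN-inhibition experiment
#'
#' Reproduces, at desk scale, the optogenetics-motivated in-silico
#' experiment: progressively inhibit STN neurons (via their DC bias
#' current) while either the Proto-Arky-D2 triangle or the Proto-STN loop is
#' the dominant beta oscillator, and track beta-band (13-30 Hz) power of the
#' Proto and STN population rates. When the triangle drives the rhythm,
#' Proto beta power should survive even complete STN silencing; when the
#' Proto-STN loop drives it, STN inhibition destroys the only negative loop
#' and beta power collapses in both populations.
#'
#' @param mode `"proto-d2-arky"` (triangle oscillator) or `"proto-stn"`
#'   (reciprocal loop oscillator).
#' @param currents grid of STN bias currents (pA); defaults follow the mode
#'   (1 down to -99 pA for the triangle mode, 30 down to -50 pA for the
#'   loop mode). Must be non-empty.
#' @param seed integer seed; `T` simulation length per grid point (ms).
#' @param n_per_pop neurons per population.
#' @return data frame with one row per current: beta-band power and
#'   dominant frequency of Proto and STN, and mean firing rates.
#' @export
stn_inhibition_experiment <- function(mode = c("proto-d2-arky", "proto-stn"),
                                      currents = NULL, seed = 1, T = 2000,
                                      n_per_pop = 300) {
  mode <- match.arg(mode)
  if (!is.null(currents) && !length(currents)) stop("empty current grid")
  if (is.null(currents))
    currents <- if (mode == "proto-d2-arky") seq(1, -99, by = -25)
                else seq(30, -50, by = -20)
  fixture <- if (mode == "proto-d2-arky") "proto-d2-arky-stn" else "proto-stn"
  rows <- lapply(seq_along(currents), function(k) {
    cfg <- spiking_fixture(fixture, n_per_pop = n_per_pop)
    cfg$populations$STN$I_dc <- currents[k]
    sd <- simulate_spiking(cfg, T = T, seed = seed + k - 1L)
    rate <- function(p) {
      pr <- population_rate(sd, p, bin_width = 1, discard = 500)
      sp <- welch_psd(pr$rate, pr$fs)
      c(beta = band_power(sp, c(13, 30)), freq = sp$dominant_frequency,
        mean = mean(pr$rate))
    }
    pr <- rate("Proto"); st <- rate("STN")
    data.frame(current = currents[k],
               proto_beta = pr["beta"], proto_freq = pr["freq"],
               proto_rate = pr["mean"],
               stn_beta = st["beta"], stn_freq = st["freq"],
               stn_rate = st["mean"], row.names = NULL)
  })
  do.call(rbind, rows)
}
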