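# Desk-scale spiking network of basal-ganglia motifs: conductance-based LIF
# neurons (D2-SPN, FSN, STN) and AdEx neurons (Proto, Arky) with
# alpha-conductance synapses and Poisson external drive.

#' Alpha-function synaptic conductance
#'
#' `g(t) = J * (t/tau) * exp(-(t - tau)/tau)` for `t >= 0` (0 before the
#' spike): rises from zero, peaks at exactly `J` at `t = tau`, then decays.
#'
#' @param t time since the presynaptic spike (ms); vectorized.
#' @param J peak conductance (nS).
#' @param tau synaptic time constant (ms).
#' @return conductance (nS).
#' @export
alpha_conductance <- function(t, J, tau) {
  ifelse(t >= 0, J * (t / tau) * exp(-(t - tau) / tau), 0)
}

#' Neuron model specification
#'
#' @param kind `"LIF"` or `"AdEx"`.
#' @param Cm capacitance (pF); `gL` leak conductance (nS); `Vreset` reset
#'   and leak-reversal potential (mV); `Vth` spike threshold/detection (mV);
#'   `tref` refractory period (ms, default 2).
#' @param DeltaT,VT,a,b,tau_w AdEx extras: slope factor (mV), exponential
#'   threshold (mV), subthreshold adaptation coupling (nS), spike-triggered
#'   adaptation increment (pA), adaptation time constant (ms).
#' @return `neuron_spec` list.
#' @export
neuron_spec <- function(kind = c("LIF", "AdEx"), Cm, gL, Vreset, Vth,
                        tref = 2, DeltaT = 2, VT = NA, a = 0, b = 0,
                        tau_w = 20) {
  kind <- match.arg(kind)
  stopifnot(tref >= 0, Vreset < Vth, Cm > 0, gL > 0)
  if (kind == "AdEx") stopifnot(DeltaT > 0, is.finite(VT), tau_w > 0)
  structure(list(kind = kind, Cm = Cm, gL = gL, Vreset = Vreset, Vth = Vth,
                 tref = tref, DeltaT = DeltaT, VT = VT, a = a, b = b,
                 tau_w = tau_w),
            class = "neuron_spec")
}

# Default neuron and synapse parameters for the basal-ganglia populations.
# The values are adapted from the conductance-based LIF/AdEx basal-ganglia
# modelling lineage and are NON-CANONICAL defaults: the qualitative
# behaviors exercised here (beta-band loop oscillations, their persistence
# or abolition under STN inhibition) are robust to their exact values, and
# every entry can be overridden in the config.
.bg_neuron_defaults <- function() {
  list(
    D2    = neuron_spec("LIF",  Cm = 100, gL = 10, Vreset = -80, Vth = -50),
    FSN   = neuron_spec("LIF",  Cm = 80,  gL = 10, Vreset = -70, Vth = -50),
    STN   = neuron_spec("LIF",  Cm = 100, gL = 10, Vreset = -70, Vth = -50),
    Proto = neuron_spec("AdEx", Cm = 100, gL = 10, Vreset = -70, Vth = -40,
                        DeltaT = 2, VT = -52, a = 2.5, b = 20, tau_w = 20),
    Arky  = neuron_spec("AdEx", Cm = 100, gL = 10, Vreset = -70, Vth = -40,
                        DeltaT = 2, VT = -52, a = 2.5, b = 20, tau_w = 20))
}

.bg_signs <- c(D2 = "I", FSN = "I", STN = "E", Proto = "I", Arky = "I")

#' Population entry of a spiking network configuration
#'
#' @param name population name; `n` number of neurons; `sign` `"E"`/`"I"`
#'   (sign of the transmitter the population releases).
#' @param neuron a [neuron_spec()].
#' @param tau_exc,tau_inh alpha-synapse time constants of the incoming
#'   excitatory/inhibitory channels (ms).
#' @param E_exc,E_inh reversal potentials (mV).
#' @param rate_ext Poisson external input rate per neuron (Hz, onto the
#'   excitatory channel); `J_ext` its peak conductance (nS); `I_dc` constant
#'   bias current (pA).
#' @return `spiking_population` list.
#' @export
spiking_population <- function(name, n, sign, neuron, tau_exc = 5,
                               tau_inh = 10, E_exc = 0, E_inh = -90,
                               rate_ext = 0, J_ext = 1, I_dc = 0) {
  stopifnot(n >= 1, sign %in% c("E", "I"), inherits(neuron, "neuron_spec"),
            tau_exc > 0, tau_inh > 0)
  structure(list(name = name, n = as.integer(n), sign = sign,
                 neuron = neuron, tau_exc = tau_exc, tau_inh = tau_inh,
                 E_exc = E_exc, E_inh = E_inh, rate_ext = rate_ext,
                 J_ext = J_ext, I_dc = I_dc),
            class = "spiking_population")
}

#' Spiking network configuration
#'
#' @param populations list of [spiking_population()] entries.
#' @param connections data frame with columns `source`, `target` (population
#'   names), `J` (peak conductance magnitude, nS), `delay` (ms), `p`
#'   (connection probability). The channel (excitatory or inhibitory) is
#'   derived from the source population's sign.
#' @return `spiking_config` list.
#' @export
spiking_config <- function(populations, connections) {
  names(populations) <- vapply(populations, `[[`, "", "name")
  connections <- as.data.frame(connections)
  stopifnot(all(c("source", "target", "J", "delay", "p") %in%
                  names(connections)))
  bad <- setdiff(c(connections$source, connections$target),
                 names(populations))
  if (length(bad)) stop("unknown population(s): ", paste(unique(bad), collapse = ", "))
  stopifnot(all(connections$J >= 0), all(connections$delay > 0),
            all(connections$p >= 0 & connections$p <= 1))
  structure(list(populations = populations, connections = connections),
            class = "spiking_config")
}

#' Simulate a spiking basal-ganglia network
#'
#' Fixed-step integration (RK4 on the membrane equations, dt = 0.1 ms by
#' default) of conductance-based LIF and AdEx neurons with alpha-function
#' synapses, transmission delays, per-neuron independent Poisson external
#' drive and a refractory clamp. Connectivity is realized at random
#' (probability `p` per source-target pair) from the seed, so identical
#' seeds give identical spike data.
#'
#' @param config a [spiking_config()].
#' @param T duration (ms); `dt` step (ms, default 0.1).
#' @param seed integer seed for connectivity, initial potentials and the
#'   Poisson drive.
#' @return object of class `spike_data`: data frame `spikes` (`id`, `time`),
#'   per-neuron `population` factor, `T`, `dt`.
#' @export
simulate_spiking <- function(config, T = 2000, dt = 0.1, seed = 1) {
  stopifnot(inherits(config, "spiking_config"), T > 0, dt > 0)
  pops <- config$populations
  pn <- names(pops)
  num <- function(field, sub = NULL)
    vapply(pops, function(p) {
      v <- if (is.null(sub)) p[[field]] else p[[sub]][[field]]
      if (is.null(v) || is.na(v)) 0 else as.numeric(v)
    }, 0)
  con <- config$connections
  set.seed(seed)
  res <- spiking_sim_cpp(
    pop_size = vapply(pops, `[[`, 1L, "n"),
    kind = ifelse(vapply(pops, function(p) p$neuron$kind, "") == "AdEx", 1L, 0L),
    Cm = num("Cm", "neuron"), gL = num("gL", "neuron"),
    Vreset = num("Vreset", "neuron"), Vth = num("Vth", "neuron"),
    tref = num("tref", "neuron"),
    DeltaT = num("DeltaT", "neuron"), VT = num("VT", "neuron"),
    a_w = num("a", "neuron"), b_w = num("b", "neuron"),
    tau_w = num("tau_w", "neuron"),
    tau_exc = num("tau_exc"), tau_inh = num("tau_inh"),
    E_exc = num("E_exc"), E_inh = num("E_inh"),
    rate_ext = num("rate_ext"), J_ext = num("J_ext"), I_dc = num("I_dc"),
    con_src = match(con$source, pn) - 1L,
    con_tgt = match(con$target, pn) - 1L,
    con_J = con$J, con_delay = con$delay, con_p = con$p,
    con_inh = vapply(con$source, function(s) pops[[s]]$sign == "I", NA),
    T = T, dt = dt)
  sizes <- vapply(pops, `[[`, 1L, "n")
  population <- factor(rep(pn, sizes), levels = pn)
  structure(list(spikes = data.frame(id = res$id, time = res$time),
                 population = population, n_neurons = res$n_neurons,
                 T = T, dt = dt),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  rates <- table(x$population[x$spikes$id]) /
    (as.numeric(table(x$population)) * x$T / 1000)
  cat(sprintf("spike_data: %d spikes from %d neurons over %g ms\n",
              nrow(x$spikes), x$n_neurons, x$T))
  cat("  mean rates (Hz):",
      paste(sprintf("%s %.1f", names(rates), rates), collapse = ", "), "\n")
  invisible(x)
}

#' Peristimulus time histogram
#'
#' Pooled spike counts of each population in rectangular time bins.
#'
#' @param spikes a `spike_data` object.
#' @param bin_width bin width (ms, default 0.1).
#' @return list with `time` (bin midpoints, ms) and matrix `counts`
#'   (bins by populations); total counts equal the number of spikes.
#' @export
psth <- function(spikes, bin_width = 0.1) {
  stopifnot(inherits(spikes, "spike_data"))
  if (bin_width <= 0) stop("bin width must be positive")
  nbin <- ceiling(spikes$T / bin_width)
  pops <- levels(spikes$population)
  spike_pop <- spikes$population[spikes$spikes$id]
  counts <- vapply(pops, function(p) {
    tt <- spikes$spikes$time[spike_pop == p]
    tabulate(pmin(floor(tt / bin_width) + 1L, nbin), nbins = nbin)
  }, integer(nbin))
  list(time = (seq_len(nbin) - 0.5) * bin_width,
       counts = matrix(counts, ncol = length(pops),
                       dimnames = list(NULL, pops)),
       bin_width = bin_width)
}

#' Population rate series for spectral analysis
#'
#' Pools and bins a population's spikes (PSTH at `bin_width`), converts to a
#' rate in spikes/s per neuron, and discards an initial settle-in window.
#'
#' @param spikes a `spike_data` object.
#' @param population population name.
#' @param bin_width bin (ms, default 1, i.e. 1 kHz sampling).
#' @param discard initial window to drop (ms, default 500).
#' @return list with `rate` (Hz), `fs` (Hz).
#' @export
population_rate <- function(spikes, population, bin_width = 1,
                            discard = 500) {
  ps <- psth(spikes, bin_width = bin_width)
  keep <- ps$time >= discard
  n <- sum(spikes$population == population)
  list(rate = ps$counts[keep, population] / n / (bin_width / 1000),
       fs = 1000 / bin_width)
}
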