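single_neuron_config <- function(I_dc = 0, rate_ext = 0, n = 1) {
  spiking_config(
    list(spiking_population("STN", n, "E",
                            neuron_spec("LIF", Cm = 100, gL = 10,
                                        Vreset = -70, Vth = -50),
                            rate_ext = rate_ext, I_dc = I_dc)),
    data.frame(source = character(0), target = character(0), J = numeric(0),
               delay = numeric(0), p = numeric(0)))
}

test_that("alpha conductance peaks at exactly J at t = tau", {
  expect_equal(alpha_conductance(6, J = 2.5, tau = 6), 2.5)
  expect_equal(alpha_conductance(0, J = 2.5, tau = 6), 0)
  expect_equal(alpha_conductance(-1, J = 2.5, tau = 6), 0)
  tt <- seq(0, 60, by = 0.001)
  expect_equal(tt[which.max(alpha_conductance(tt, 1, 6))], 6,
               tolerance = 1e-3)
})

test_that("a LIF neuron above rheobase fires at the closed-form interval", {
  I <- 400   # pA; rheobase = gL (Vth - Vreset) = 200 pA
  sd <- simulate_spiking(single_neuron_config(I_dc = I), T = 500, seed = 1)
  isi <- diff(sd$spikes$time)
  isi_theory <- 2 + (100 / 10) * log(I / (I - 10 * (-50 - -70)))
  expect_gt(length(isi), 10)
  expect_lt(max(abs(isi - isi_theory)), 0.15)  # one integration step
})

test_that("a LIF neuron without input stays silent", {
  sd <- simulate_spiking(single_neuron_config(I_dc = 0), T = 200, seed = 1)
  expect_equal(nrow(sd$spikes), 0L)
})

test_that("no interspike interval violates the refractory period", {
  cfg <- spiking_fixture("proto-arky-d2", n_per_pop = 100)
  sd <- simulate_spiking(cfg, T = 500, seed = 3)
  isi_min <- min(vapply(split(sd$spikes$time, sd$spikes$id),
                        function(tt) if (length(tt) > 1) min(diff(tt)) else Inf,
                        0))
  expect_gte(isi_min, 2)
})

test_that("identical seeds reproduce identical spike data", {
  cfg <- spiking_fixture("proto-arky-d2", n_per_pop = 50)
  s1 <- simulate_spiking(cfg, T = 300, seed = 7)
  s2 <- simulate_spiking(cfg, T = 300, seed = 7)
  s3 <- simulate_spiking(cfg, T = 300, seed = 8)
  expect_identical(s1$spikes, s2$spikes)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("psth pools counts conservatively", {
  fake <- structure(list(spikes = data.frame(id = c(1L, 1L),
                                             time = c(0.05, 0.15)),
                         population = factor("P"), n_neurons = 1L,
                         T = 0.2, dt = 0.1),
                    class = "spike_data")
  ps <- psth(fake, bin_width = 0.1)
  expect_equal(as.integer(ps$counts[, "P"]), c(1L, 1L))
  empty <- structure(list(spikes = data.frame(id = integer(0),
                                              time = numeric(0)),
                          population = factor(character(0), levels = "P"),
                          n_neurons = 1L, T = 1, dt = 0.1),
                     class = "spike_data")
  expect_true(all(psth(empty)$counts == 0))
  cfg <- spiking_fixture("proto-arky-d2", n_per_pop = 30)
  sd <- simulate_spiking(cfg, T = 300, seed = 2)
  expect_equal(sum(psth(sd, 0.5)$counts), nrow(sd$spikes))
  expect_error(psth(sd, 0), "positive")
})

test_that("with synapses off, population rates match the isolated f-I rates", {
  cfg <- spiking_fixture("proto-arky-d2", n_per_pop = 150)
  cfg$connections$J[] <- 0
  sd <- simulate_spiking(cfg, T = 1000, seed = 4)
  for (p in names(cfg$populations)) {
    iso <- cfg
    iso$populations <- cfg$populations[p]
    iso$connections <- cfg$connections[0, ]
    si <- simulate_spiking(iso, T = 1000, seed = 5)
    r_net <- sum(sd$population[sd$spikes$id] == p) / 150
    r_iso <- nrow(si$spikes) / 150
    expect_lt(abs(r_net - r_iso), 0.2 * max(r_iso, 5))
  }
})

test_that("configuration errors are caught before the run", {
  expect_error(spiking_config(list(), data.frame(source = "A", target = "B",
                                                 J = 1, delay = 1, p = 0.1)),
               "unknown population")
  expect_error(stn_inhibition_experiment("proto-stn", currents = numeric(0)),
               "empty")
})
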