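test_that("half-life to time-constant conversion is exact", {
  expect_equal(half_life_to_tau(log(2)), 1.0)
  expect_equal(half_life_to_tau(7.5), 7.5 / log(2), tolerance = 1e-12)
  expect_equal(half_life_to_tau(7.5), 10.8202, tolerance = 1e-4)
  # decaying for exactly lambda ms with this tau halves the value
  tau <- half_life_to_tau(13)
  expect_equal(exp(-13 / tau), 0.5, tolerance = 1e-12)
  expect_error(half_life_to_tau(0), "positive")
  expect_error(half_life_to_tau(-3), "positive")
})

test_that("parameter validation rejects invalid neuron settings", {
  expect_error(neuron_params(lambda_HAP = 0), "half-life")
  expect_error(neuron_params(k_HAP = -1), ">= 0")
  expect_error(neuron_params(i_h = 2), "i_h")
  expect_error(neuron_params(I_re = -10), "rates")
  expect_error(neuron_params(dt = 0), "dt")
})

test_that("external input has the Poisson expectation and zero-rate limit", {
  p0 <- neuron_params(I_re = 0)
  expect_true(all(external_input_step(p0, n = 1000) == 0))

  set.seed(11)
  # balanced drive: expectation 0 per step
  p <- neuron_params(I_re = 300, I_ratio = 1)
  x <- external_input_step(p, n = 1e6)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x)), 4 * se)

  # asymmetric drive: 3*0.2 - 3*0.1 = +0.3 mV per step
  p2 <- neuron_params(I_re = 200, I_ratio = 0.5)
  y <- external_input_step(p2, n = 1e6)
  expect_equal(mean(y), 0.3, tolerance = 4 * sd(y) / sqrt(length(y)) / 0.3)
})

test_that("quiescent neuron stays at rest and never spikes", {
  p <- neuron_params(I_re = 0, k_HAP = 0, k_AHP = 0, k_DAP = 0)
  st <- simulate_single(p, 5000, seed = 1, record_v = TRUE)
  expect_length(st$times, 0)
  expect_true(all(attr(st, "v") == -62))
})

test_that("post-spike decay is exact under exact integration", {
  # no input, potentials initialised at k: V(t) = V_rest - k * 2^(-t/lambda)
  p <- neuron_params(I_re = 0, k_HAP = 30, lambda_HAP = 8)
  st <- simulate_single(p, 200, seed = 1, record_v = TRUE,
                        integration = "exact")
  v <- attr(st, "v")
  k <- seq_along(v)
  expect_equal(v, -62 - 30 * 2^(-k / 8), tolerance = 1e-9)
})

test_that("absolute refractory period bounds every ISI", {
  # resting potential above threshold: fires as fast as allowed
  p <- neuron_params(I_re = 0, V_rest = -40, k_HAP = 0, k_AHP = 0,
                     k_DAP = 0)
  st <- simulate_single(p, 2000, seed = 1)
  expect_gt(length(st$times), 100)
  expect_true(all(diff(st$times) > 2))

  # and under strong stochastic drive too
  p2 <- neuron_params(I_re = 2000, I_ratio = 0)
  st2 <- simulate_single(p2, 20000, seed = 2)
  expect_true(all(diff(st2$times) > 2))
})

test_that("simulation is deterministic per seed and varies across seeds", {
  p <- neuron_params()
  a <- simulate_single(p, 30000, seed = 7)
  b <- simulate_single(p, 30000, seed = 7)
  c <- simulate_single(p, 30000, seed = 8)
  expect_identical(a$times, b$times)
  expect_false(identical(a$times, c$times))
})

test_that("default neuron fires in the observed range for random cells", {
  st <- simulate_single(neuron_params(), 1000000, seed = 3)
  expect_gt(length(st$times), 0)
  expect_true(all(diff(st$times) > 2))
  r <- mean_rate(st)
  expect_gt(r, 1)
  expect_lt(r, 10)
})

test_that("a spike drops V by ~k_HAP which then recovers with its half-life", {
  p <- neuron_params(I_re = 0, V_rest = -49, V_thresh = -50, k_HAP = 30,
                     lambda_HAP = 8, k_AHP = 0, k_DAP = 0)
  # start potentials at zero: V = -49 >= -50 fires immediately, then the
  # 30-mV HAP holds it down until it has decayed to ~1 mV (~39 ms)
  st <- simulate_single(p, 400, seed = 1, record_v = TRUE,
                        integration = "exact", init_at_k = FALSE)
  v <- attr(st, "v")
  expect_gt(length(st$times), 1)
  i0 <- round(st$times[1])
  expect_equal(v[i0], -49)            # at spike threshold crossing
  expect_equal(v[i0 + 1], -49 - 30 * 2^(-1 / 8), tolerance = 1e-9)
  # half-life: 8 ms later the deviation from rest has halved
  expect_equal(-49 - v[i0 + 9], (-49 - v[i0 + 1]) / 2, tolerance = 1e-9)
  # next spike only once the HAP has decayed below 1 mV
  expect_gt(st$times[2] - st$times[1], 8 * log2(30) - 1)
})

test_that("HAP-free excitatory drive gives Poisson-like output", {
  p <- neuron_params(I_re = 1000, I_ratio = 0, e_h = 3, lambda_syn = 1,
                     k_HAP = 0, k_AHP = 0, k_DAP = 0)
  st <- simulate_single(p, 2e6, seed = 1)
  iods <- iod_range(st)
  expect_true(all(iods > 0.85 & iods < 1.15))
  expect_gt(mean(iods), 0.9)
  expect_lt(mean(iods), 1.05)
  # ISIs beyond the refractory period are near-exponential: compare the
  # hazard flatness (memorylessness) over well-populated bins
  h <- hazard_fn(isi_histogram(st, 5))
  ok <- which(h$survivors > 2000 & h$mids > 10)
  expect_lt(max(h$hazard[ok]) - min(h$hazard[ok]), 0.5 * mean(h$hazard[ok]))
})

test_that("pacemaker configuration produces regular low-IoD spiking", {
  # resting potential above threshold with a slow HAP acting as pacemaker
  p <- neuron_params(I_re = 0, V_rest = -48, V_thresh = -50, k_HAP = 20,
                     lambda_HAP = 60, k_AHP = 0, k_DAP = 0)
  st <- simulate_single(p, 300000, seed = 1)
  isi <- diff(st$times)
  expect_lt(sd(isi) / mean(isi), 0.05)
  expect_lt(iod(st, 2), 0.1)
})

test_that("AHP lowers the IoD at long binwidths while a slow DAP raises it", {
  base <- neuron_params(I_re = 300, k_HAP = 20, lambda_HAP = 40)
  with_ahp <- neuron_params(I_re = 300, k_HAP = 20, lambda_HAP = 40,
                            k_AHP = 2, lambda_AHP = 500)
  with_dap <- neuron_params(I_re = 300, k_HAP = 20, lambda_HAP = 40,
                            k_DAP = 0.75, lambda_DAP = 1000)
  for (s in 1:2) {
    i_base <- iod_range(simulate_single(base, 5e5, seed = s))
    i_ahp <- iod_range(simulate_single(with_ahp, 5e5, seed = s))
    i_dap <- iod_range(simulate_single(with_dap, 5e5, seed = s))
    expect_lt(i_ahp["10s"], i_base["10s"])      # negative feedback
    expect_gt(i_dap["10s"], i_base["10s"])      # positive feedback
    expect_gt(i_dap["10s"], i_dap["0.5s"])      # and grows with binwidth
    expect_lt(i_ahp["10s"], i_ahp["0.5s"])
  }
})

test_that("relative refractory period matches its closed form", {
  expect_equal(relative_refractory_estimate(neuron_params(k_HAP = 1)), 0)
  expect_equal(
    relative_refractory_estimate(neuron_params(k_HAP = 30, lambda_HAP = 8)),
    8 * log2(30), tolerance = 1e-3)
  # 'broad'-cell parameters: ~95-96 ms
  est <- relative_refractory_estimate(neuron_params(k_HAP = 20,
                                                    lambda_HAP = 22))
  expect_equal(est, 22 * log2(20), tolerance = 1e-3)
  expect_lt(abs(est - 96), 5)
  expect_equal(
    relative_refractory_estimate(neuron_params(k_HAP = 0, k_AHP = 0,
                                               k_DAP = 0)), 0)
})

test_that("spike trains validate ordering and window membership", {
  expect_error(spike_train(c(3, 2, 5)), "increasing")
  expect_error(spike_train(c(1, 5), duration = 4), "within")
  st <- spike_train(c(10, 30), duration = 100)
  expect_equal(mean_rate(st), 2 / 0.1)
  expect_equal(isis(st), 20)
})
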