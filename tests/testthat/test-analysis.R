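test_that("ISI histogram bins, counts and normalisation behave", {
  st <- spike_train(seq(0, 1000, by = 10), duration = 1000)
  h <- isi_histogram(st, binwidth = 5, normalise = TRUE)
  expect_equal(h$n_intervals, 100)
  expect_equal(sum(h$counts), length(st$times) - 1)
  # all mass in the bin covering 10 ms
  expect_equal(h$counts[3], 100)
  expect_equal(h$norm_counts[3], 10000)
  expect_equal(sum(h$norm_counts), 10000, tolerance = 1e-6)
  expect_error(isi_histogram(spike_train(5, duration = 10)), "2 spikes")
})

test_that("ISI histogram of exponential intervals matches the analytic form", {
  st <- synthetic_train("poisson", rate_hz = 10, duration_s = 1100, seed = 8)
  isi <- isis(st)
  expect_gt(length(isi), 1e4)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 10 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard is the conditional firing probability", {
  # single-bin ISI distribution: hazard 1 in that bin
  st <- spike_train(seq(0, 1000, by = 10), duration = 1000)
  hz <- hazard_fn(isi_histogram(st, 5))
  expect_equal(hz$hazard[3], 1)
  # always within [0, 1]
  st2 <- fixture_100_spikes()
  hz2 <- hazard_fn(isi_histogram(st2, 5))
  expect_true(all(hz2$hazard >= 0 & hz2$hazard <= 1, na.rm = TRUE))
  # exponential ISIs: flat hazard ~ 1 - exp(-r * 0.005)
  stp <- synthetic_train("poisson", rate_hz = 8, duration_s = 2000, seed = 9)
  hzp <- hazard_fn(isi_histogram(stp, 5))
  ok <- which(hzp$survivors > 1000)
  expect_equal(mean(hzp$hazard[ok]), 1 - exp(-8 * 0.005), tolerance = 0.05)
  expect_lt(diff(range(hzp$hazard[ok])), 0.1)
})

test_that("hazard and survivor counts reconstruct the histogram exactly", {
  st <- fixture_100_spikes()
  h <- isi_histogram(st, 5)
  hz <- hazard_fn(h)
  expect_equal(hz$hazard * hz$survivors, as.numeric(h$counts))
})

test_that("analysis statistics agree with naive oracles on small instances", {
  st <- fixture_100_spikes()
  expect_gte(length(st$times), 90)

  h <- isi_histogram(st, 5)
  expect_equal(h$counts, oracle_isi_counts(st$times, 5))

  hz <- hazard_fn(h)
  expect_equal(hz$hazard, oracle_hazard(st$times, 5))

  expect_equal(iod(st, 2), oracle_iod(st$times, st$t0, st$duration, 2000))

  ps <- postsynaptic_signal(list(st), amplitude = 3, half_life = 7.5)
  # recursive filter vs brute-force convolution (euler-free, exact kernel)
  oracle <- oracle_psp_convolution(st$times, st$duration, 3, 7.5)
  expect_equal(ps, oracle, tolerance = 1e-9)

  cc <- crosscorrelogram(st, st, lag_ms = 50, binwidth_ms = 5)
  expect_equal(cc$counts, oracle_xcorr(st$times, st$times, 50, 5))
})

test_that("IoD separates random, regular and clustered spiking", {
  # per-binwidth IoD averaged over independent trains (single-train IoD at
  # 6-10-s binwidths has SD ~0.1, so averaging controls the test's error rate)
  irs <- sapply(1:3, function(s) {
    iod_range(synthetic_train("poisson", rate_hz = 5, duration_s = 1000,
                              seed = s))
  })
  expect_true(all(rowMeans(irs) > 0.85 & rowMeans(irs) < 1.15))

  reg <- synthetic_train("regular", rate_hz = 5, duration_s = 1000)
  expect_lt(iod(reg, 2), 0.1)
  expect_lt(iod(reg, 10), 0.1)

  burst <- synthetic_train("burst", rate_hz = 10, duration_s = 1000,
                           seed = 2, epoch_s = 5)
  ib <- iod_range(burst)
  expect_gt(ib["1s"], 1)
  expect_gt(ib["4s"], ib["0.5s"])  # grows with binwidth up to the epoch scale
})

test_that("IoD is invariant to shifting the whole train and window", {
  st <- fixture_100_spikes()
  sh <- shift_train(st, 1234.5)
  expect_equal(iod_range(st), iod_range(sh))
})

test_that("population rate sums and conserves spike counts", {
  t1 <- spike_train(c(10.5, 20.5), duration = 100)
  t2 <- spike_train(c(10.7, 50.2), duration = 100)
  pc <- population_rate(list(t1, t2), 1)
  expect_length(pc, 100)
  expect_equal(sum(pc), 4)
  expect_equal(pc[11], 2)
  # single train: equals its own binned counts; empty: all zero
  expect_equal(sum(population_rate(list(t1), 1)), 2)
  empty <- spike_train(numeric(0), duration = 100)
  expect_true(all(population_rate(list(empty), 1) == 0))
})

test_that("postsynaptic signal is an exponentially decaying EPSP per spike", {
  st <- spike_train(50.2, duration = 200)
  ps <- postsynaptic_signal(list(st), amplitude = 3, half_life = 7.5)
  expect_true(all(ps[1:50] == 0))
  expect_equal(ps[51], 3)
  expect_equal(ps[51 + 15], 3 * 2^(-15 / 7.5), tolerance = 1e-9)
  empty <- spike_train(numeric(0), duration = 200)
  expect_true(all(postsynaptic_signal(list(empty)) == 0))
})

test_that("spike-triggered average recovers constants and the mean", {
  st <- synthetic_train("poisson", rate_hz = 10, duration_s = 50, seed = 3)
  flat <- rep(2.5, 50000)
  sta <- spike_triggered_average(flat, st, window_ms = 100)
  expect_true(all(sta$mean == 2.5))
  expect_equal(length(sta$mean), 201)

  set.seed(4)
  noise <- rnorm(50000)
  sta2 <- spike_triggered_average(noise, st, window_ms = 50)
  se <- 1 / sqrt(sta2$n_used)
  expect_true(all(abs(sta2$mean) < 4 * se + 0.02))
})

test_that("cross-correlogram locates identity and shift lags", {
  st <- synthetic_train("poisson", rate_hz = 5, duration_s = 200, seed = 5)
  cc <- crosscorrelogram(st, st, lag_ms = 50, binwidth_ms = 2)
  expect_equal(cc$lag[which.max(cc$counts)], 1)  # zero-lag bin (0, 2]

  shifted <- spike_train(st$times + 5, duration = st$duration + 5)
  cc2 <- crosscorrelogram(st, shifted, lag_ms = 50, binwidth_ms = 2)
  expect_equal(cc2$lag[which.max(cc2$counts)], 5)

  indep <- synthetic_train("poisson", rate_hz = 5, duration_s = 200, seed = 6)
  cc3 <- crosscorrelogram(st, indep, lag_ms = 100, binwidth_ms = 5)
  expected <- mean(cc3$counts)
  expect_true(all(abs(cc3$counts - expected) < 4 * sqrt(expected) + 4))
})

test_that("oscillation frequency finds constructed rhythms and flags noise", {
  mod <- synthetic_train("sinusoid", rate_hz = 40, duration_s = 200,
                         seed = 7, depth = 0.8, f_hz = 3)
  of <- oscillation_frequency(population_rate(list(mod), 1))
  expect_equal(of$frequency, 3, tolerance = 0.1 / 3)
  expect_true(of$significant)

  flat <- synthetic_train("poisson", rate_hz = 40, duration_s = 200, seed = 8)
  of2 <- oscillation_frequency(population_rate(list(flat), 1))
  expect_false(of2$significant)
})

test_that("bistable-state segmentation handles constructed series", {
  # constant fast / constant slow -> one interval each
  n <- 100  # neurons
  fast <- rep(6 * n / 1000, 200000)   # 6 spikes/s per neuron in 1-ms bins
  seg <- segment_bistable_states(fast, n_neurons = n)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "fast")

  slow <- rep(0.85 * n / 1000, 200000)
  seg2 <- segment_bistable_states(slow, n_neurons = n)
  expect_equal(seg2$state, "slow")

  # step at 100 s: two intervals with the boundary within the smoothing window
  step <- c(rep(0.85 * n / 1000, 100000), rep(6 * n / 1000, 100000))
  seg3 <- segment_bistable_states(step, n_neurons = n)
  expect_equal(seg3$state, c("slow", "fast"))
  expect_lt(abs(seg3$end_s[1] - 100), 10)
})

test_that("pattern summary bundles consistent components", {
  st <- synthetic_train("poisson", rate_hz = 5, duration_s = 300, seed = 9)
  ps <- pattern_summary(st)
  expect_s3_class(ps, "pattern_summary")
  expect_equal(sum(ps$isi$norm_counts), 10000, tolerance = 1e-6)
  expect_equal(ps$rate, mean_rate(window_train(st, 5000)), tolerance = 1e-12)
  expect_length(ps$iod, 7)
})
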