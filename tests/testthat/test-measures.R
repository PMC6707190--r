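test_that("percept state arithmetic and window classification", {
  alt <- alternating_two_pool_raster(n_per_pool = 40, epoch_shape = Inf,
                                     epoch_mean = 1000, duration = 6000,
                                     seed = 1)
  tr <- percept_trace(alt$raster)
  w <- tr$windows
  ok <- w$u_a + w$u_b > 0
  expect_equal(w$p[ok], (w$u_a[ok] - w$u_b[ok]) / (w$u_a[ok] + w$u_b[ok]))
  expect_true(all(w$p[ok] >= -1 & w$p[ok] <= 1))
  expect_true(all(w$label[!ok] == "neither"))
  expect_true(all(w$label[!is.na(w$p) & w$p > 1 / 3] == "A"))
  expect_true(all(w$label[!is.na(w$p) & w$p < -1 / 3] == "B"))
  # u_a = 30, u_b = 10 -> P = 0.5 -> A; equal counts -> neither
  expect_equal((30 - 10) / (30 + 10), 0.5)
})

test_that("report-threshold filtering follows the absorb policy hand-trace", {
  # [A x10, neither x2, B x8] at 50 ms, threshold 300:
  # A epoch runs until the reported change at 600 ms, B until trace end
  tr <- trace_from_labels(c(rep("A", 10), rep("neither", 2), rep("B", 8)))
  d <- dominance_durations(tr, 300)
  expect_equal(d$epochs$label, c("A", "B"))
  expect_equal(d$epochs$duration, c(600, 400))
  expect_true(all(d$epochs$censored))  # first and last epochs are censored
  expect_false(d$stats$defined)
})

test_that("an all-A trace yields one censored epoch and undefined stats", {
  tr <- trace_from_labels(rep("A", 20))
  d <- dominance_durations(tr, 300)
  expect_equal(nrow(d$epochs), 1L)
  expect_true(d$epochs$censored)
  expect_false(d$stats$defined)
  expect_true(is.na(d$stats$cv))
})

test_that("threshold 0 reports every labeled epoch unchanged", {
  lab <- c(rep("A", 4), rep("B", 3), rep("A", 5), rep("B", 2))
  tr <- trace_from_labels(lab)
  d <- dominance_durations(tr, 0)
  expect_equal(d$epochs$label, c("A", "B", "A", "B"))
  expect_equal(d$epochs$duration, c(200, 150, 250, 100))
  expect_equal(d$stats$n, 2L)  # interior epochs only
  # drop policy agrees when there are no sub-threshold events
  dd <- dominance_durations(tr, 0, policy = "drop")
  expect_equal(dd$epochs$duration, d$epochs$duration)
})

test_that("drop policy discards sub-threshold runs instead of absorbing", {
  tr <- trace_from_labels(c(rep("A", 10), rep("neither", 2), rep("B", 3),
                            rep("A", 8), rep("B", 7)))
  d <- dominance_durations(tr, 300, policy = "drop")
  # the 150 ms B run is not reported; durations are the runs' own lengths
  expect_equal(d$epochs$label, c("A", "A", "B"))
  expect_equal(d$epochs$duration, c(500, 400, 350))
})

test_that("duration moments recover known distribution shapes", {
  set.seed(10)
  x <- rgamma(1e5, shape = 4, scale = 500)
  mo <- duration_moments(x)
  expect_equal(mo$cv, 0.5, tolerance = 0.02)        # 1/sqrt(shape)
  expect_equal(mo$skewness, 1, tolerance = 0.05)    # 2/sqrt(shape)
  expect_equal(mo$skew_cv, 2, tolerance = 0.1)
  e <- rexp(1e5, rate = 1 / 800)
  expect_equal(duration_moments(e)$cv, 1, tolerance = 0.02)
  cm <- duration_moments(rep(700, 50))
  expect_equal(cm$cv, 0)
  expect_true(is.na(cm$skewness))
  expect_error(duration_moments(1), "at least 2")
})

test_that("gamma MLE recovers shape and scale on synthetic draws", {
  set.seed(11)
  x <- rgamma(1e4, shape = 3.5, scale = 600)
  gf <- rivalnet:::gamma_fit(x)
  expect_equal(gf$shape, 3.5, tolerance = 0.05 * 3.5)
  expect_equal(gf$scale, 600, tolerance = 0.05 * 600)
})

test_that("sigma-mu regression through the origin returns the exact slope", {
  mu <- c(1000, 1500, 2200, 3000)
  fit <- sigma_mu_regression(mu, 0.65 * mu)
  expect_equal(fit$slope, 0.65, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-6)
  expect_error(sigma_mu_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("state mask partitions reported windows without overlap", {
  lab <- c(rep("A", 8), rep("B", 9), rep("A", 7))
  tr <- trace_from_labels(lab)
  m <- state_mask(tr, 300)
  expect_equal(nrow(m), 24)
  expect_equal(m$state, lab)  # all runs reportable here
  blocks_d <- rivalnet:::mask_blocks(dominance_durations(tr, 300), 1,
                                     "dominant")
  blocks_s <- rivalnet:::mask_blocks(dominance_durations(tr, 300), 1,
                                     "suppressed")
  expect_equal(nrow(blocks_d), 2)
  expect_equal(nrow(blocks_s), 1)
  # all-A trace: pool 1 all-dominant, pool 2 all-suppressed
  tra <- trace_from_labels(rep("A", 10))
  da <- dominance_durations(tra, 300)
  expect_equal(rivalnet:::mask_blocks(da, 1, "dominant")[1, ], c(0, 500))
  expect_equal(rivalnet:::mask_blocks(da, 2, "suppressed")[1, ], c(0, 500))
  expect_equal(nrow(rivalnet:::mask_blocks(da, 1, "suppressed")), 0)
})

test_that("CV_ISI is 0 for periodic and 1 for Poisson trains", {
  per <- periodic_raster(5, rate_hz = 20, duration = 30000, pools = TRUE)
  tr <- trace_from_labels(rep("A", 600))
  d <- dominance_durations(tr, 300)
  cv_p <- cv_isi(per, d, pool = 1, state = "dominant")
  expect_equal(nrow(cv_p), 3L)  # pool 1 holds neurons 1-3
  expect_true(all(cv_p$cv < 1e-9))
  # one Poisson neuron with ~1e4 spikes
  poi <- poisson_raster(1, rate_hz = 100, duration = 1e5, seed = 2, pools = TRUE)
  trp <- trace_from_labels(rep("A", 2000))
  dp <- dominance_durations(trp, 300)
  cv <- cv_isi(poi, dp, pool = 1, state = "dominant")
  expect_equal(cv$cv, 1, tolerance = 0.02)
})

test_that("ISIs spanning a state change are discarded", {
  # one neuron spiking every 400 ms; states alternate every 1000 ms
  r <- periodic_raster(1, rate_hz = 2.5, duration = 12000, pools = TRUE)
  tr <- trace_from_labels(rep(rep(c("A", "B"), each = 20), 6))
  d <- dominance_durations(tr, 300)
  cv <- cv_isi(d = d, raster = r, pool = 1, state = "dominant",
               min_isis = 1)
  # within each 1000 ms A-epoch only 2-3 spikes fit: ISIs all 400 ms
  expect_true(all(abs(diff(r$events$time) - 400) < 1e-9))
  expect_true(all(cv$cv < 1e-9))
})

test_that("Fano factor separates Poisson from periodic counts", {
  poi <- poisson_raster(30, rate_hz = 40, duration = 60000, seed = 3, pools = TRUE)
  tr <- trace_from_labels(rep("A", 1200))
  d <- dominance_durations(tr, 300)
  f <- fano_factor(poi, d, pool = 1, state = "dominant")
  expect_equal(nrow(f), 15L)  # the 15 pool-1 neurons
  expect_equal(mean(f$fano), 1, tolerance = 0.05)
  per <- periodic_raster(10, rate_hz = 50, duration = 60000, pools = TRUE)
  fp <- fano_factor(per, d, pool = 1, state = "dominant")
  expect_true(all(fp$fano < 1))
  # empty trains are excluded, not reported as zero
  silent <- spike_raster(integer(0), numeric(0), 3, 60000,
                         layout = rivalnet:::fixture_layout(3, pools = TRUE))
  fe <- fano_factor(silent, d, pool = 1, state = "dominant")
  expect_equal(nrow(fe), 0L)
})

test_that("spike-count correlations: identical trains 1, independent near 0", {
  poi <- poisson_raster(2, rate_hz = 50, duration = 1.2e5, seed = 4)
  # duplicate neuron 1's train onto neuron 2 to make identical trains
  ev <- poi$events[poi$events$neuron == 1, ]
  twin <- spike_raster(c(ev$neuron, rep(2L, nrow(ev))),
                       c(ev$time, ev$time), 2, 1.2e5,
                       layout = rivalnet:::fixture_layout(2, pools = TRUE))
  twin$layout$pool <- c(1L, 1L)
  tr <- trace_from_labels(rep("A", 2400))
  d <- dominance_durations(tr, 300)
  r1 <- spike_count_correlations(twin, d, pool = 1, state = "dominant",
                                 n_pairs = 10, seed = 1)
  expect_equal(r1$r, rep(1, nrow(r1)), tolerance = 1e-9)
  # independent Poisson pair over >= 1e3 windows: 95% CI about 0
  poi2 <- poisson_raster(2, rate_hz = 50, duration = 1.2e5, seed = 5)
  poi2$layout$pool <- c(1L, 1L)
  r0 <- spike_count_correlations(poi2, d, pool = 1, state = "dominant",
                                 n_pairs = 5, seed = 1)
  expect_lt(abs(mean(r0$r)), 2 / sqrt(1200) + 0.02)
})

test_that("threshold robustness distinguishes stable from unstable traces", {
  set.seed(12)
  # gamma-distributed alternation: CV_D stable across thresholds
  alt <- alternating_two_pool_raster(n_per_pool = 40, rate_dominant = 30,
                                     epoch_shape = 4, epoch_mean = 2000,
                                     duration = 3e5, seed = 6)
  tr <- percept_trace(alt$raster)
  rob <- threshold_robustness(tr)
  expect_lt(rob$ratio, 1.5)
})

test_that("levelt checks respond to constructed scan summaries", {
  # durations proportional to 1/drive -> proposition 4 holds
  sym <- data.frame(drive = c(3, 4, 5, 6, 7),
                    mean_duration = 6000 / c(3, 4, 5, 6, 7))
  lv <- levelt_checks(symmetric = sym)
  expect_true(lv$levelt4$pass)
  expect_equal(lv$levelt4$rho, -1)
  # synthetic predominance 'X' crossing at 0.5 with peaked alternation
  pa <- data.frame(drive_a = 1:7,
                   pred_a = c(0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.9),
                   pred_b = c(0.9, 0.8, 0.65, 0.5, 0.35, 0.2, 0.1),
                   alternation_rate_hz = c(0.2, 0.4, 0.7, 0.9, 0.7, 0.4,
                                           0.2))
  lv2 <- levelt_checks(pool_a = pa)
  expect_true(lv2$levelt2_classic$pass)
  expect_true(lv2$levelt2_modified$pass)
  expect_true(lv2$max_alternation$pass)
  expect_error(levelt_checks(symmetric = sym[1:3, ]), ">= 4")
  expect_error(levelt_checks(), "at least one")
})
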