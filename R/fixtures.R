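# Synthetic spike-train generators with known ground truth. Fixture rasters
# use the same spike_raster container (and file format) as the simulator so
# the measures pipeline is format-agnostic. Rates are in Hz, times in ms.

fixture_layout <- function(n, pools = FALSE) {
  data.frame(id = seq_len(n), class = "E",
             pool = if (pools) rep(c(1L, 2L), each = ceiling(n / 2))[1:n]
             else NA_integer_,
             angle = NA_real_)
}

#' Homogeneous Poisson raster
#'
#' Independent homogeneous Poisson trains, one per neuron.
#'
#' @param n_neurons number of neurons.
#' @param rate_hz firing rate (Hz), >= 0.
#' @param duration duration (ms).
#' @param seed integer seed.
#' @param pools label neurons with two pool ids (default FALSE).
#' @return A `spike_raster`.
#' @export
poisson_raster <- function(n_neurons, rate_hz, duration, seed = 1,
                           pools = FALSE) {
  stopifnot(rate_hz >= 0, duration > 0)
  ev <- with_seed(seed, {
    counts <- stats::rpois(n_neurons, rate_hz * duration / 1000)
    data.frame(neuron = rep(seq_len(n_neurons), counts),
               time = runif(sum(counts), 0, duration))
  })
  spike_raster(ev$neuron, ev$time, n_neurons, duration,
               layout = fixture_layout(n_neurons, pools),
               meta = list(fixture = "poisson", rate_hz = rate_hz,
                           seed = seed))
}

#' Periodic raster
#'
#' Deterministic periodic trains at a fixed rate, with per-neuron phase.
#'
#' @inheritParams poisson_raster
#' @param phase spike-time offset (ms) or vector per neuron.
#' @return A `spike_raster`.
#' @export
periodic_raster <- function(n_neurons, rate_hz, duration, phase = 0,
                            pools = FALSE) {
  stopifnot(rate_hz > 0)
  period <- 1000 / rate_hz
  phase <- rep_len(phase, n_neurons)
  ev <- do.call(rbind, lapply(seq_len(n_neurons), function(i) {
    t <- seq(phase[i] %% period, duration, by = period)
    t <- t[t > 0 & t <= duration]
    data.frame(neuron = i, time = t)
  }))
  spike_raster(ev$neuron, ev$time, n_neurons, duration,
               layout = fixture_layout(n_neurons, pools),
               meta = list(fixture = "periodic", rate_hz = rate_hz))
}

#' Gamma-renewal raster
#'
#' Renewal trains with gamma-distributed interspike intervals
#' (`shape = shape`, mean interval `1000/rate_hz` ms), so the ISI CV is
#' `1/sqrt(shape)`.
#'
#' @inheritParams poisson_raster
#' @param shape gamma shape of the interval distribution.
#' @return A `spike_raster`.
#' @export
gamma_renewal_raster <- function(n_neurons, rate_hz, shape, duration,
                                 seed = 1) {
  stopifnot(rate_hz > 0, shape > 0)
  mean_isi <- 1000 / rate_hz
  ev <- with_seed(seed, {
    out <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      n_draw <- ceiling(duration / mean_isi * 1.5 + 20)
      t <- cumsum(rgamma(n_draw, shape = shape, scale = mean_isi / shape))
      while (length(t) && t[length(t)] < duration)
        t <- c(t, t[length(t)] +
                 cumsum(rgamma(n_draw, shape = shape,
                               scale = mean_isi / shape)))
      t <- t[t <= duration]
      out[[i]] <- data.frame(neuron = i, time = t)
    }
    do.call(rbind, out)
  })
  spike_raster(ev$neuron, ev$time, n_neurons, duration,
               layout = fixture_layout(n_neurons),
               meta = list(fixture = "gamma_renewal", rate_hz = rate_hz,
                           shape = shape, seed = seed))
}

#' Alternating two-pool raster with known epochs
#'
#' Ground truth for the dominance pipeline: epoch durations are drawn from a
#' gamma distribution (`shape = epoch_shape`, mean `epoch_mean` ms) and the
#' two pools alternate dominance; the dominant pool fires as a Poisson
#' process at `rate_dominant`, the suppressed pool at `rate_suppressed`.
#'
#' @param n_per_pool excitatory neurons per pool.
#' @param rate_dominant,rate_suppressed firing rates (Hz).
#' @param epoch_shape gamma shape of epoch durations (use `Inf` for
#'   deterministic epochs of length `epoch_mean`).
#' @param epoch_mean mean epoch duration (ms).
#' @param duration total duration (ms).
#' @param seed integer seed.
#' @return A list with the `spike_raster` and the true `epochs` table
#'   (`label`, `start`, `end`, `duration`).
#' @export
alternating_two_pool_raster <- function(n_per_pool = 50, rate_dominant = 20,
                                        rate_suppressed = 2,
                                        epoch_shape = 4, epoch_mean = 2000,
                                        duration = 60000, seed = 1) {
  stopifnot(epoch_mean > 0, duration > 0)
  n <- 2L * n_per_pool
  res <- with_seed(seed, {
    durs <- numeric(0)
    while (sum(durs) < duration) {
      add <- if (is.finite(epoch_shape))
        rgamma(64, shape = epoch_shape, scale = epoch_mean / epoch_shape)
      else rep(epoch_mean, 64)
      durs <- c(durs, add)
    }
    cut_at <- which(cumsum(durs) >= duration)[1]
    durs <- durs[seq_len(cut_at)]
    ends <- pmin(cumsum(durs), duration)
    starts <- c(0, head(ends, -1))
    epochs <- data.frame(label = rep(c("A", "B"),
                                     length.out = length(durs)),
                         start = starts, end = ends,
                         duration = ends - starts)
    ev <- vector("list", nrow(epochs) * 2L)
    m <- 0L
    for (e in seq_len(nrow(epochs))) {
      for (pl in 1:2) {
        rate <- if ((pl == 1L) == (epochs$label[e] == "A"))
          rate_dominant else rate_suppressed
        ids <- if (pl == 1L) seq_len(n_per_pool)
        else n_per_pool + seq_len(n_per_pool)
        counts <- stats::rpois(n_per_pool,
                               rate * epochs$duration[e] / 1000)
        if (sum(counts)) {
          m <- m + 1L
          ev[[m]] <- data.frame(
            neuron = rep(ids, counts),
            time = runif(sum(counts), epochs$start[e], epochs$end[e]))
        }
      }
    }
    list(events = do.call(rbind, ev[seq_len(m)]), epochs = epochs)
  })
  raster <- spike_raster(res$events$neuron, res$events$time, n, duration,
                         layout = fixture_layout(n, pools = TRUE),
                         meta = list(fixture = "alternating_two_pool",
                                     seed = seed,
                                     rate_dominant = rate_dominant,
                                     rate_suppressed = rate_suppressed,
                                     epoch_shape = epoch_shape,
                                     epoch_mean = epoch_mean))
  list(raster = raster, epochs = res$epochs)
}
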