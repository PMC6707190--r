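# Network simulation driver and the spike_raster container.

#' Construct a spike raster
#'
#' @param neuron integer neuron ids of the spike events.
#' @param time spike times (ms), will be sorted.
#' @param n_neurons number of neurons.
#' @param duration simulated time (ms).
#' @param layout optional per-neuron label table (`id`, `class`, `pool`,
#'   `angle`).
#' @param burn_in initial interval (ms) excluded from statistics.
#' @param meta free-form metadata list (architecture, drive, seeds, params).
#' @return A `spike_raster` object.
#' @export
spike_raster <- function(neuron, time, n_neurons, duration, layout = NULL,
                         burn_in = 0, meta = list()) {
  stopifnot(length(neuron) == length(time))
  ord <- order(time, neuron)
  events <- data.frame(neuron = as.integer(neuron[ord]), time = time[ord])
  if (nrow(events) && (events$time[1] < 0 ||
                       events$time[nrow(events)] > duration))
    stop("spike times outside [0, duration]")
  structure(list(events = events, n_neurons = as.integer(n_neurons),
                 duration = duration, burn_in = burn_in,
                 layout = layout, meta = meta),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("spike_raster:", nrow(x$events), "spikes,", x$n_neurons, "neurons,",
      x$duration / 1000, "s",
      if (!is.null(x$meta$architecture)) paste0("(", x$meta$architecture, ")"),
      "\n")
  invisible(x)
}

#' Validate spike-raster invariants
#'
#' Checks that events are time-sorted within `[0, duration]` and that every
#' per-neuron interspike interval is strictly positive.
#'
#' @param raster a `spike_raster`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_raster <- function(raster) {
  ev <- raster$events
  if (is.unsorted(ev$time)) stop("events not sorted by time")
  if (nrow(ev) && (min(ev$time) < 0 || max(ev$time) > raster$duration))
    stop("spike times outside [0, duration]")
  if (any(ev$neuron < 1L | ev$neuron > raster$n_neurons))
    stop("neuron ids outside 1..n_neurons")
  ord <- order(ev$neuron, ev$time)
  same <- diff(ev$neuron[ord]) == 0L
  if (any(diff(ev$time[ord])[same] <= 0))
    stop("non-positive interspike interval")
  invisible(TRUE)
}

#' Simulate a network
#'
#' Integrates the adapting leaky integrate-and-fire equations for the given
#' connectivity and drive with a two-stage (modified Euler) scheme at step
#' `params$h`. Threshold crossings are timed by linear interpolation within
#' the step; the reset (`v -> v - theta`), the adaptation increment and the
#' postsynaptic increments are applied at the end of the step. Initial
#' voltages are uniform on `[0, theta)` (policy `"random"`) or zero; synaptic
#' and adaptation traces start at zero. A fixed `seed` makes the run
#' bit-identical (initial state and any OU drive realization are drawn from
#' it).
#'
#' @param conn a `connectivity` object.
#' @param params a `neuron_params` object.
#' @param drive a `drive_spec`.
#' @param duration simulated time (ms); must be at least `10 * tau_m`.
#' @param seed integer seed.
#' @param burn_in interval (ms) excluded from downstream statistics
#'   (default 2000).
#' @param init initial-voltage policy, `"random"` or `"zero"`.
#' @param sync_weighted weight postsynaptic increments by the residual
#'   exponential decay between the interpolated spike time and the step end
#'   (default `TRUE`); `FALSE` applies raw increments, for sensitivity
#'   checks.
#' @return A `spike_raster`.
#' @export
simulate_network <- function(conn, params, drive, duration, seed = 1,
                             burn_in = 2000, init = c("random", "zero"),
                             sync_weighted = TRUE) {
  stopifnot(inherits(conn, "connectivity"), inherits(params, "neuron_params"),
            inherits(drive, "drive_spec"))
  init <- match.arg(init)
  if (duration < 10 * params$tau_m)
    stop("duration must be at least 10 * tau_m = ", 10 * params$tau_m, " ms")
  if (burn_in >= duration) stop("burn_in must be below duration")
  n <- nrow(conn$layout)
  n_steps <- as.integer(round(duration / params$h))
  res <- with_seed(seed, {
    v0 <- if (init == "random") runif(n, 0, params$theta) else numeric(n)
    dr <- realize_drive(drive, n, n_steps, params$h)
    lif_run_cpp(v0, conn$W@p, conn$W@i, conn$W@x,
                params$theta, params$tau_m, params$tau_s, params$tau_a,
                params$gamma, params$h,
                dr$mat, dr$group, n_steps, sync_weighted,
                numeric(n), numeric(n))
  })
  spike_raster(res$id, res$time, n, duration, layout = conn$layout,
               burn_in = burn_in,
               meta = list(architecture = conn$architecture,
                           params = params, seed = seed,
                           drive = summary_of_drive(drive),
                           sync_weighted = sync_weighted))
}

summary_of_drive <- function(drive) {
  lapply(drive$groups, function(g)
    list(name = g$name, n_targets = length(g$targets), mu = g$mu,
         sigma = g$sigma, tau = g$tau))
}

#' Population firing rates
#'
#' Mean firing rate (Hz) per synaptic class and pool over the post-burn-in
#' interval, or over an explicit set of time windows.
#'
#' @param raster a `spike_raster` with a layout.
#' @param windows optional two-column matrix of `[start, end)` times (ms);
#'   default is the single post-burn-in interval.
#' @return A data frame with columns `class`, `pool`, `rate_hz`.
#' @export
population_rates <- function(raster, windows = NULL) {
  stopifnot(!is.null(raster$layout))
  if (is.null(windows))
    windows <- matrix(c(raster$burn_in, raster$duration), ncol = 2)
  total_t <- sum(windows[, 2] - windows[, 1]) / 1000  # s
  ev <- raster$events
  keep <- rep(FALSE, nrow(ev))
  for (r in seq_len(nrow(windows)))
    keep <- keep | (ev$time >= windows[r, 1] & ev$time < windows[r, 2])
  ev <- ev[keep, ]
  lay <- raster$layout
  key <- interaction(lay$class, ifelse(is.na(lay$pool), 0L, lay$pool),
                     drop = FALSE)
  cnt <- tapply(tabulate(ev$neuron, raster$n_neurons), key, sum)
  siz <- tapply(rep(1L, nrow(lay)), key, sum)
  out <- data.frame(group = names(cnt),
                    rate_hz = as.numeric(cnt) / (as.numeric(siz) * total_t))
  out[!is.na(out$rate_hz), ]
}

#' Write / read a raster as plain text
#'
#' The raster is written as a two-column tab-separated table
#' (`neuron_id`, `time_ms`) with a YAML sidecar (`<path>.meta.yaml`) holding
#' dimensions, burn-in and run metadata, and a label sidecar
#' (`<path>.labels.tsv`) holding the per-neuron layout.
#'
#' @param raster a `spike_raster`.
#' @param path output file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns the
#'   `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  write.table(raster$events, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = c("neuron_id", "time_ms"))
  yaml::write_yaml(list(n_neurons = raster$n_neurons,
                        duration = raster$duration,
                        burn_in = raster$burn_in, meta = raster$meta),
                   paste0(path, ".meta.yaml"))
  if (!is.null(raster$layout))
    write.table(raster$layout, paste0(path, ".labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  lab_path <- paste0(path, ".labels.tsv")
  layout <- if (file.exists(lab_path))
    read.table(lab_path, sep = "\t", header = TRUE,
               colClasses = c("integer", "character", "integer", "numeric"))
  spike_raster(ev$neuron_id, ev$time_ms, meta$n_neurons, meta$duration,
               layout = layout, burn_in = meta$burn_in,
               meta = if (is.null(meta$meta)) list() else meta$meta)
}
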