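# Shared fixtures and cached case-example runs. Simulations are memoised so
# several test files can share one run.

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .case_cache)) assign(key, force(expr), .case_cache)
  get(key, .case_cache)
}

# a connectivity wrapping a single unconnected neuron, for closed-form checks
single_neuron_conn <- function() {
  lay <- data.frame(id = 1L, class = "E", pool = 1L, angle = NA_real_)
  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  rivalnet:::new_connectivity(lay, W, "unstructured", list())
}

# small discrete network for fast structural/dynamical tests
small_discrete <- function(seed = 1)
  cached(paste0("small_discrete_", seed),
         build_discrete(n = 400, k = 20, seed = seed))

# the discrete case example at reference parameters (expensive; shared)
case_discrete_run <- function() {
  cached("case_discrete_run", {
    conn <- build_discrete(seed = 7)
    params <- case_neuron_params("discrete")
    drive <- stimulus_drive(conn$layout, 5)
    raster <- simulate_network(conn, params, drive, 62000, seed = 1)
    trace <- percept_trace(raster)
    dom <- dominance_durations(trace, 300)
    list(conn = conn, params = params, raster = raster, trace = trace,
         dom = dom, spk = spike_stats(raster, dom, seed = 1))
  })
}

# the unstructured network under the reference heterogeneous OU protocol
case_unstructured_ou_run <- function() {
  cached("case_unstructured_ou_run", {
    conn <- build_unstructured(seed = 5)
    params <- case_neuron_params("unstructured")
    drive <- heterogeneous_ou_drive(conn$layout)
    raster <- simulate_network(conn, params, drive, 152000, seed = 2)
    list(conn = conn, raster = raster, trace = percept_trace(raster))
  })
}

# closed-form LIF interspike interval for constant suprathreshold drive
lif_isi <- function(f, theta = 20, tau_m = 20) -tau_m * log(1 - theta / (f * tau_m))

# build a percept_trace directly from a window label sequence (50 ms windows)
trace_from_labels <- function(labels, window = 50) {
  n <- length(labels)
  u_a <- ifelse(labels == "A", 30L, ifelse(labels == "B", 10L, 0L))
  u_b <- ifelse(labels == "B", 30L, ifelse(labels == "A", 10L, 0L))
  structure(list(windows = data.frame(
    t_start = (seq_len(n) - 1L) * window,
    u_a = u_a, u_b = u_b,
    p = ifelse(u_a + u_b > 0, (u_a - u_b) / (u_a + u_b), NA_real_),
    label = labels),
    window = window, burn_in = 0, t_end = n * window),
    class = "percept_trace")
}
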