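# Feedforward drive protocols. A drive_spec is a list of target groups; each
# group is a disjoint set of neurons sharing one drive time course, either
# constant or an Ornstein-Uhlenbeck (OU) process. Drive values are currents
# in mV ms^-1. Neurons in no group receive zero drive.

new_drive_group <- function(targets, mu, sigma = 0, tau = NULL, name = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma > 0 && (is.null(tau) || tau <= 0))
    stop("an OU group needs a positive correlation time tau")
  list(targets = as.integer(targets), mu = mu, sigma = sigma,
       tau = tau, name = name)
}

#' Assemble a drive specification from target groups
#'
#' @param groups list of groups as returned by [constant_drive()] or
#'   [ou_drive()] (their `$groups` elements are spliced in, so specs can be
#'   combined: `drive_spec(c(spec1$groups, spec2$groups))`).
#' @param clip_zero clip negative excursions of fluctuating drive at zero
#'   (off by default; the model equations accept negative currents).
#' @return A `drive_spec` object.
#' @export
drive_spec <- function(groups, clip_zero = FALSE) {
  all_t <- unlist(lapply(groups, `[[`, "targets"))
  if (!length(all_t)) stop("drive targets an empty neuron set")
  if (anyDuplicated(all_t))
    stop("drive group target sets must be disjoint")
  structure(list(groups = groups, clip_zero = clip_zero),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  for (g in x$groups)
    cat(sprintf("  %-12s %5d neurons  mu = %g%s\n",
                if (is.null(g$name)) "group" else g$name,
                length(g$targets), g$mu,
                if (g$sigma > 0)
                  sprintf("  OU(sd = %g, tau = %g ms)", g$sigma, g$tau)
                else ""))
  invisible(x)
}

#' Select neurons by class, pool or ring arc
#'
#' @param layout a connectivity layout (`conn$layout`).
#' @param class optional synaptic class, `"E"` or `"I"`.
#' @param pool optional pool id.
#' @param arc_center,arc_halfwidth optional ring arc (radians) for continuum
#'   layouts.
#' @return Integer neuron ids.
#' @export
select_neurons <- function(layout, class = NULL, pool = NULL,
                           arc_center = NULL, arc_halfwidth = NULL) {
  keep <- rep(TRUE, nrow(layout))
  if (!is.null(class)) keep <- keep & layout$class %in% class
  if (!is.null(pool)) keep <- keep & !is.na(layout$pool) &
      layout$pool %in% pool
  if (!is.null(arc_center)) {
    stopifnot(!is.null(arc_halfwidth))
    d <- abs((layout$angle - arc_center) %% (2 * pi))
    d <- pmin(d, 2 * pi - d)
    keep <- keep & !is.na(d) & d <= arc_halfwidth
  }
  layout$id[keep]
}

#' Constant drive to a target set
#'
#' @param targets integer neuron ids.
#' @param value drive current (mV ms^-1).
#' @param name optional group label.
#' @return A `drive_spec` with one constant group.
#' @export
constant_drive <- function(targets, value, name = "constant") {
  drive_spec(list(new_drive_group(targets, value, name = name)))
}

#' Ornstein-Uhlenbeck drive to a target set
#'
#' One OU process shared by all targeted neurons, with stationary mean `mu`,
#' stationary standard deviation `sigma` and correlation time `tau`. The
#' process is sampled exactly on the integration grid:
#' `x(t+h) = mu + (x(t)-mu) e^(-h/tau) + sigma sqrt(1-e^(-2h/tau)) xi`.
#'
#' @param targets integer neuron ids.
#' @param mu stationary mean (mV ms^-1).
#' @param sigma stationary standard deviation.
#' @param tau correlation time (ms).
#' @param name optional group label.
#' @return A `drive_spec` with one OU group.
#' @export
ou_drive <- function(targets, mu, sigma = 1, tau = 500, name = "ou") {
  drive_spec(list(new_drive_group(targets, mu, sigma, tau, name = name)))
}

#' Case-example drive protocols
#'
#' `stimulus_drive()` builds the standard nonfluctuating stimulus: value
#' `d_a` to pool-1 excitatory neurons and `d_b` to pool-2 excitatory neurons
#' (for the discrete network the two pools tile the whole excitatory
#' population; for the continuum network they are the stimulated arcs).
#' `heterogeneous_ou_drive()` builds the unstructured-network fluctuating
#' protocol: independent OU processes to the two excitatory pools (mean
#' `mu_e`) and one OU process to all inhibitory neurons (mean `mu_i`).
#' `homogeneous_drive()` gives constant drive to all E and all I neurons
#' (E slightly above I by convention).
#'
#' @param layout a connectivity layout.
#' @param d_a,d_b stimulus strengths for pools 1 and 2 (mV ms^-1).
#' @param mu_e,mu_i,sigma,tau OU parameters (defaults 0.2, 0.1, 1, 500 ms).
#' @param e_value,i_value homogeneous constant values (defaults 0.2, 0.1).
#' @return A `drive_spec`.
#' @export
stimulus_drive <- function(layout, d_a, d_b = d_a) {
  drive_spec(list(
    new_drive_group(select_neurons(layout, "E", pool = 1L), d_a, name = "E pool 1"),
    new_drive_group(select_neurons(layout, "E", pool = 2L), d_b, name = "E pool 2")))
}

#' @rdname stimulus_drive
#' @export
heterogeneous_ou_drive <- function(layout, mu_e = 0.2, mu_i = 0.1,
                                   sigma = 1, tau = 500) {
  drive_spec(list(
    new_drive_group(select_neurons(layout, "E", pool = 1L), mu_e, sigma, tau,
                    "E pool 1 OU"),
    new_drive_group(select_neurons(layout, "E", pool = 2L), mu_e, sigma, tau,
                    "E pool 2 OU"),
    new_drive_group(select_neurons(layout, "I"), mu_i, sigma, tau, "I OU")))
}

#' @rdname stimulus_drive
#' @export
homogeneous_drive <- function(layout, e_value = 0.2, i_value = 0.1) {
  drive_spec(list(
    new_drive_group(select_neurons(layout, "E"), e_value, name = "E"),
    new_drive_group(select_neurons(layout, "I"), i_value, name = "I")))
}

#' Drive sequences for Levelt scans
#'
#' Builds one stimulus drive per grid value: either symmetric (both pools
#' follow the grid) or pool-A-only (pool 1 follows the grid, pool 2 is held
#' at `base`).
#'
#' @param layout a connectivity layout.
#' @param grid numeric vector of drive strengths, all >= 0.
#' @param axis `"symmetric"` or `"pool_a"`.
#' @param base pool-2 drive for the `pool_a` axis.
#' @return A list of `drive_spec`s, named by grid value.
#' @export
levelt_scan <- function(layout, grid, axis = c("symmetric", "pool_a"),
                        base = 5) {
  axis <- match.arg(axis)
  if (!length(grid)) stop("empty drive grid")
  if (any(grid < 0)) stop("drive strengths must be non-negative")
  specs <- lapply(grid, function(d)
    if (axis == "symmetric") stimulus_drive(layout, d)
    else stimulus_drive(layout, d, base))
  names(specs) <- format(grid)
  specs
}

# Realize a drive_spec on the integration grid. Returns the per-group trace
# matrix (one column per grid time for OU specs, a single column for purely
# constant specs) and the per-neuron 0-based group row index (background
# zero-drive group is row 1). OU randomness is drawn from the current RNG
# stream, so callers seed before realizing.
realize_drive <- function(spec, n_neurons, n_steps, h) {
  ngrp <- length(spec$groups)
  group <- integer(n_neurons)  # 0 = background zero drive
  for (g in seq_len(ngrp)) {
    tg <- spec$groups[[g]]$targets
    if (any(tg < 1L | tg > n_neurons))
      stop("drive targets outside the network")
    group[tg] <- g
  }
  has_ou <- any(vapply(spec$groups, function(g) g$sigma > 0, logical(1)))
  if (!has_ou) {
    mat <- matrix(c(0, vapply(spec$groups, `[[`, numeric(1), "mu")),
                  ncol = 1L)
  } else {
    mat <- matrix(0, nrow = ngrp + 1L, ncol = n_steps + 1L)
    for (g in seq_len(ngrp)) {
      gr <- spec$groups[[g]]
      if (gr$sigma == 0) {
        mat[g + 1L, ] <- gr$mu
      } else {
        mat[g + 1L, ] <- ou_trace(n_steps + 1L, gr$mu, gr$sigma, gr$tau, h)
      }
    }
    if (spec$clip_zero) mat[mat < 0] <- 0
  }
  list(mat = mat, group = group)
}

# exact stationary OU discretization; length n values at spacing h
ou_trace <- function(n, mu, sigma, tau, h) {
  e <- exp(-h / tau)
  # first innovation is the stationary draw, so the trace starts in the
  # stationary distribution
  innov <- c(rnorm(1, 0, sigma),
             rnorm(n - 1L, 0, sigma * sqrt(1 - e^2)))
  mu + as.numeric(stats::filter(innov, e, method = "recursive", init = 0))
}
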