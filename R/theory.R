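# Balanced-state mean-field theory for the two-pool (four population) and
# single-pool (two population) systems.
#
# In the balanced state the mean input to every population sits at threshold,
# which to leading order gives the linear condition W r + f = 0 where r holds
# the population rates, f the external drives and W the effective coupling
# matrix. For the discrete architecture the pools interact only through the
# long-range excitatory-to-inhibitory coupling, so W has the sparsity
#
#   input(e1) = w_ee r_e1 - w_ei r_i1
#   input(i1) = w_ie r_e1 - w_ii r_i1 + w_long r_e2
#
# (pool 2 mirrored). Effective population weights are obtained from the
# microscopic amplitudes as w_XY = sqrt(k) * A_XY * tau_s, with rates in
# spikes per ms, since each of the k afferents of class Y contributes
# A_XY/sqrt(k) per spike integrated over the synaptic time constant.

MF_POPS <- c("e1", "i1", "e2", "i2")

#' Construct a two-pool mean-field system
#'
#' @param w_ee,w_ei,w_ie,w_ii within-pool effective weights (positive
#'   magnitudes; inhibitory columns are negated internally).
#' @param w_long cross-pool excitatory-to-inhibitory weight (default 0).
#' @param f external drive vector, length 4 in population order
#'   `e1, i1, e2, i2` (a length-2 vector `c(f_e, f_i)` is mirrored).
#' @return A `meanfield_system`.
#' @export
meanfield_system <- function(w_ee, w_ei, w_ie, w_ii, w_long = 0, f = c(0, 0)) {
  if (length(f) == 2) f <- rep(f, 2)
  stopifnot(length(f) == 4)
  W <- rbind(c(w_ee, -w_ei, 0, 0),
             c(w_ie, -w_ii, w_long, 0),
             c(0, 0, w_ee, -w_ei),
             c(w_long, 0, w_ie, -w_ii))
  dimnames(W) <- list(MF_POPS, MF_POPS)
  names(f) <- MF_POPS
  structure(list(W = W, f = f, populations = MF_POPS,
                 weights = c(w_ee = w_ee, w_ei = w_ei, w_ie = w_ie,
                             w_ii = w_ii, w_long = w_long)),
            class = "meanfield_system")
}

#' @export
print.meanfield_system <- function(x, ...) {
  cat("meanfield_system (populations e1, i1, e2, i2)\n")
  print(round(x$W, 4))
  cat("f =", paste(signif(x$f, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Mean-field system from a network architecture
#'
#' Maps the microscopic connectivity (amplitudes `A_XY`, in-degree `k`) and
#' a drive specification to population-level effective weights
#' `w_XY = sqrt(k) * A_XY * tau_s` and mean external drives. Supported for
#' the unstructured and discrete architectures; the continuum architecture
#' has no discrete-pool mean-field reduction here.
#'
#' @param conn a `connectivity` (unstructured or discrete).
#' @param drive a `drive_spec`; group means are averaged onto populations.
#' @param params a `neuron_params` (supplies `tau_s`).
#' @return A `meanfield_system`.
#' @export
meanfield_from_architecture <- function(conn, drive,
                                        params = neuron_params()) {
  if (conn$architecture == "continuum")
    stop("continuum architecture is not supported by the discrete-pool ",
         "mean-field theory")
  A <- conn$params$amplitudes
  k <- conn$params$k
  ts <- params$tau_s
  w_long <- if (conn$architecture == "discrete")
    sqrt(k) * A[["ie_long"]] * ts else 0
  # mean drive per population from the spec's group means
  lay <- conn$layout
  f <- numeric(4)
  pop_of <- function(id) {
    cls <- lay$class[id]; pl <- lay$pool[id]
    ifelse(cls == "E", ifelse(!is.na(pl) & pl == 2L, 3L, 1L),
           ifelse(!is.na(pl) & pl == 2L, 4L, 2L))
  }
  acc <- matrix(0, nrow = 4, ncol = 2)  # sum mu, count
  for (g in drive$groups) {
    p <- pop_of(g$targets)
    for (q in 1:4) {
      m <- sum(p == q)
      acc[q, 1] <- acc[q, 1] + m * g$mu
      acc[q, 2] <- acc[q, 2] + m
    }
  }
  sizes <- tabulate(pop_of(lay$id), 4)
  f <- ifelse(sizes > 0, acc[, 1] / sizes, 0)
  meanfield_system(sqrt(k) * A[["ee"]] * ts, sqrt(k) * A[["ei"]] * ts,
                   sqrt(k) * A[["ie"]] * ts, sqrt(k) * A[["ii"]] * ts,
                   w_long = w_long, f = f)
}

new_balanced_solution <- function(rates, feasible, singular, residual,
                                  reason = NA_character_,
                                  populations = MF_POPS) {
  names(rates) <- populations[seq_along(rates)]
  structure(list(rates = rates, rates_hz = rates * 1000,
                 feasible = feasible, singular = singular,
                 residual = residual, reason = reason),
            class = "balanced_solution")
}

#' @export
print.balanced_solution <- function(x, ...) {
  cat("balanced_solution:",
      if (x$feasible) "feasible" else paste("infeasible:", x$reason), "\n")
  if (!any(is.na(x$rates)))
    cat("  rates (Hz):", paste(names(x$rates), signif(x$rates_hz, 4),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Solve the balanced-state condition W r + f = 0
#'
#' Rates are the solution of `W r = -f`. A near-singular coupling matrix
#' (`|det W| / ||W||^dim < tol_singular`) is handled by an explicit
#' column-space membership test via least squares: if the residual of the
#' projection of `-f` onto the column space exceeds tolerance, no balanced
#' state exists. Negative rate components mark the solution infeasible. All
#' pathologies are reported states, never errors.
#'
#' @param system a `meanfield_system` (or a list with square matrix `W` and
#'   vector `f`).
#' @param tol_singular relative determinant threshold declaring singularity
#'   (default 1e-12).
#' @return A `balanced_solution` with rates (spikes/ms and Hz), `feasible`,
#'   `singular` and `residual` of `W r + f`.
#' @export
solve_balanced <- function(system, tol_singular = 1e-12) {
  W <- system$W
  f <- system$f
  d <- nrow(W)
  pops <- if (!is.null(system$populations)) system$populations else
    paste0("p", seq_len(d))
  scale <- norm(W, "F") / sqrt(d)
  singular <- scale == 0 ||
    abs(det(W)) / scale^d < tol_singular
  if (!singular) {
    r <- drop(solve(W, -f))
    resid <- max(abs(W %*% r + f))
  } else {
    qrW <- qr(W)
    r <- qr.coef(qrW, -f)
    r[is.na(r)] <- 0
    resid <- max(abs(W %*% r + f))
    if (resid > 1e-8 * max(1, max(abs(f))))
      return(new_balanced_solution(rep(NA_real_, d), FALSE, TRUE, resid,
                                   "drive outside the column space of W",
                                   pops))
  }
  if (any(r < -1e-10))
    return(new_balanced_solution(r, FALSE, singular, resid,
                                 "negative rate component", pops))
  new_balanced_solution(pmax(r, 0), TRUE, singular, resid,
                        populations = pops)
}

#' Single-pool (classic) balanced-state solution
#'
#' Restricts the system to one pool's 2x2 within-pool block and solves the
#' classic two-population balanced-state condition.
#'
#' @param system a `meanfield_system`.
#' @param pool pool id (1 or 2).
#' @inheritParams solve_balanced
#' @return A `balanced_solution` for populations `(e, i)` of the pool.
#' @export
solve_single_pool <- function(system, pool = 1L, tol_singular = 1e-12) {
  idx <- if (pool == 1L) 1:2 else 3:4
  sub <- list(W = system$W[idx, idx], f = system$f[idx],
              populations = c("e", "i"))
  solve_balanced(sub, tol_singular)
}

#' Sweep the mutual-inhibition coupling
#'
#' Solves the two-pool balanced state along a grid of long-range
#' excitatory-to-inhibitory weights and locates the singularity of the
#' theory (the zero of `det W(w_long)`) by bisection between grid points
#' where the determinant changes sign.
#'
#' @param system a `meanfield_system` (its `w_long` is replaced).
#' @param w_long_grid increasing grid of cross-pool weights.
#' @param tol bisection tolerance on `w_long`.
#' @return A list with the per-grid solutions table (`w_long`, `det`, the
#'   four rates in Hz, `feasible`) and `singular_w` (NA when no sign change
#'   occurs in the range).
#' @export
sweep_mutual_inhibition <- function(system, w_long_grid, tol = 1e-9) {
  if (is.unsorted(w_long_grid, strictly = TRUE))
    stop("w_long grid must be strictly increasing")
  ws <- system$weights
  sys_at <- function(w) meanfield_system(ws[["w_ee"]], ws[["w_ei"]],
                                         ws[["w_ie"]], ws[["w_ii"]],
                                         w_long = w, f = system$f)
  det_at <- function(w) det(sys_at(w)$W)
  sols <- lapply(w_long_grid, function(w) solve_balanced(sys_at(w)))
  tab <- data.frame(
    w_long = w_long_grid,
    det = vapply(w_long_grid, det_at, numeric(1)),
    t(vapply(sols, function(s) s$rates_hz, numeric(4))),
    feasible = vapply(sols, `[[`, logical(1), "feasible"))
  names(tab)[3:6] <- paste0("r_", MF_POPS, "_hz")
  singular_w <- NA_real_
  sgn <- sign(tab$det)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip)) {
    i <- flip[1]
    lo <- w_long_grid[i]; hi <- w_long_grid[i + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(det_at(mid)) == sgn[i]) lo <- mid else hi <- mid
    }
    singular_w <- (lo + hi) / 2
  } else if (any(sgn == 0)) {
    singular_w <- w_long_grid[which(sgn == 0)[1]]
  }
  list(table = tab, solutions = sols, singular_w = singular_w)
}

#' Compare mean-field predictions with simulated rates
#'
#' Joins theory solutions and simulated population rates on a shared grid,
#' fits one global scale factor between theory and simulation on the
#' symmetric branch (then freezes it), labels each grid point's regime from
#' the simulated excitatory rate asymmetry, and reports per-population
#' relative errors of the calibrated two-pool theory and of the single-pool
#' theory applied to the dominant pool.
#'
#' @param sweep result of [sweep_mutual_inhibition()].
#' @param sim data frame with `w_long` and simulated rates (Hz)
#'   `r_e1_hz`, `r_i1_hz`, `r_e2_hz`, `r_i2_hz`; the grid must match the
#'   sweep's.
#' @param single_pool optional per-grid single-pool solutions (list of
#'   `balanced_solution`), e.g. the within-pool theory.
#' @param asym_threshold relative excitatory-rate asymmetry above which a
#'   point is labeled winner-take-all (default 0.2).
#' @return A list with the comparison table, the frozen calibration scale
#'   and the regime labels.
#' @export
compare_theory_simulation <- function(sweep, sim, single_pool = NULL,
                                      asym_threshold = 0.2) {
  th <- sweep$table
  if (nrow(th) != nrow(sim) ||
      any(abs(th$w_long - sim$w_long) > 1e-9))
    stop("theory and simulation grids do not match")
  rate_cols <- paste0("r_", MF_POPS, "_hz")
  asym <- abs(sim$r_e1_hz - sim$r_e2_hz) /
    pmax(sim$r_e1_hz + sim$r_e2_hz, .Machine$double.eps)
  regime <- ifelse(asym > asym_threshold, "asymmetric", "symmetric")
  sym <- regime == "symmetric" & th$feasible
  if (!any(sym)) stop("no feasible symmetric-branch points to calibrate on")
  x <- unlist(th[sym, rate_cols])
  y <- unlist(sim[sym, rate_cols])
  scale <- sum(x * y) / sum(x * x)
  rel_err <- abs(as.matrix(th[, rate_cols]) * scale -
                   as.matrix(sim[, rate_cols])) /
    pmax(as.matrix(sim[, rate_cols]), .Machine$double.eps)
  colnames(rel_err) <- paste0("err_", MF_POPS)
  out <- cbind(th[, c("w_long", rate_cols, "feasible")],
               sim_e1 = sim$r_e1_hz, sim_i1 = sim$r_i1_hz,
               sim_e2 = sim$r_e2_hz, sim_i2 = sim$r_i2_hz,
               regime = regime, as.data.frame(rel_err))
  if (!is.null(single_pool)) {
    sp <- t(vapply(single_pool, function(s) s$rates_hz, numeric(2)))
    dom_e <- pmax(sim$r_e1_hz, sim$r_e2_hz)
    dom_i <- ifelse(sim$r_e1_hz >= sim$r_e2_hz, sim$r_i1_hz, sim$r_i2_hz)
    out$err_single_dom_e <- abs(sp[, 1] * scale - dom_e) /
      pmax(dom_e, .Machine$double.eps)
    out$err_single_dom_i <- abs(sp[, 2] * scale - dom_i) /
      pmax(dom_i, .Machine$double.eps)
  }
  list(table = out, scale = scale, regime = regime)
}
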