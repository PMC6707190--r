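test_that("solve_balanced satisfies W r + f = 0 on the worked 2x2 system", {
  sys <- list(W = rbind(c(1, -2), c(1, -1)), f = c(1, 0),
              populations = c("e", "i"))
  sol <- solve_balanced(sys)
  expect_true(sol$feasible)
  expect_equal(unname(sol$rates), c(1, 1))
  expect_lt(sol$residual, 1e-12)
  # zero drive with invertible W gives zero rates
  sol0 <- solve_balanced(list(W = rbind(c(1, -2), c(1, -1)), f = c(0, 0)))
  expect_true(sol0$feasible)
  expect_equal(unname(sol0$rates), c(0, 0))
})

test_that("symmetric coupling with asymmetric drive has no balanced state", {
  w <- meanfield_system(2, 3, 4, 5)$W
  Wsym <- w
  Wsym[1:2, 3:4] <- Wsym[1:2, 1:2]  # pools coupled identically
  Wsym[3:4, 1:2] <- Wsym[3:4, 3:4]
  f_asym <- c(1, 0, 2, 0)
  sol <- solve_balanced(list(W = Wsym, f = f_asym))
  expect_true(sol$singular)
  expect_false(sol$feasible)
  expect_match(sol$reason, "column space")
  # symmetric drive on the same singular coupling is solvable
  sol2 <- solve_balanced(list(W = Wsym, f = c(1, 0, 1, 0)))
  expect_true(sol2$singular)
  expect_lt(sol2$residual, 1e-8)
})

test_that("solver agrees with the dense linear-algebra oracle", {
  set.seed(20)
  n_bad <- 0
  for (i in 1:10000) {
    W <- matrix(rnorm(16), 4)
    f <- rnorm(4)
    sol <- solve_balanced(list(W = W, f = f))
    if (sol$singular) { n_bad <- n_bad + 1; next }
    oracle <- solve(W, -f)
    if (any(oracle < 0)) {
      expect_false(sol$feasible)
    } else {
      expect_lt(max(abs(sol$rates - oracle)) / max(1, max(abs(oracle))),
                1e-10)
    }
  }
  expect_lt(n_bad, 50)  # random Gaussian matrices are almost never singular
})

test_that("mean-field construction mirrors the discrete architecture", {
  conn <- build_discrete(n = 400, k = 20, seed = 1)
  params <- case_neuron_params("discrete")
  drive <- stimulus_drive(conn$layout, 5)
  sys <- meanfield_from_architecture(conn, drive, params)
  k <- 20; ts <- params$tau_s
  expect_equal(sys$W["e1", "e1"], sqrt(k) * 10.5 * ts)
  expect_equal(sys$W["e1", "i1"], -sqrt(k) * 20 * ts)
  expect_equal(sys$W["i1", "e2"], sqrt(k) * 30 * ts)
  # Eq.-1 sparsity: pools couple only through long-range E -> I
  expect_equal(sys$W["e1", "e2"], 0)
  expect_equal(sys$W["e1", "i2"], 0)
  expect_equal(sys$W["i1", "i2"], 0)
  expect_equal(sys$W["e2", "e1"], 0)
  # drive only to excitatory populations
  expect_equal(unname(sys$f), c(5, 0, 5, 0))
  # pool-swap symmetry: permuting pools permutes the solution
  sol <- solve_balanced(sys)
  perm <- c(3, 4, 1, 2)
  sol_p <- solve_balanced(list(W = sys$W[perm, perm], f = sys$f[perm]))
  expect_equal(unname(sol_p$rates), unname(sol$rates[perm]))
  expect_error(
    meanfield_from_architecture(build_continuum(n = 300, seed = 1), drive),
    "continuum")
})

test_that("zero long-range coupling reduces to the single-pool theory", {
  sys <- meanfield_system(297, 566, 849, 1273, w_long = 0, f = c(5, 0))
  sol4 <- solve_balanced(sys)
  sol2 <- solve_single_pool(sys, pool = 1)
  expect_equal(unname(sol4$rates[1:2]), unname(sol2$rates), tolerance = 1e-12)
  expect_equal(unname(sol4$rates[3:4]), unname(sol2$rates), tolerance = 1e-12)
})

test_that("determinant-root bisection locates the singularity", {
  sys <- meanfield_system(297, 566, 849, 1273, f = c(5, 0))
  grid <- seq(0, 400, by = 25)
  sw <- sweep_mutual_inhibition(sys, grid)
  # oracle: the antisymmetric block [w_ee, -w_ei; w_ie - w, -w_ii] loses
  # rank at w = (w_ee*w_ii - w_ei*w_ie... solve det directly by polyroot
  det_fun <- function(w) {
    W <- meanfield_system(297, 566, 849, 1273, w_long = w)$W
    det(W)
  }
  # det is quadratic in w: fit exactly through three points
  dmat <- cbind(1, grid, grid^2)
  beta <- solve(t(dmat[1:3, ]) %*% dmat[1:3, ],
                t(dmat[1:3, ]) %*% vapply(grid[1:3], det_fun, numeric(1)))
  roots <- polyroot(beta)
  real_roots <- Re(roots[abs(Im(roots)) < 1e-6])
  target <- real_roots[real_roots >= 0 & real_roots <= 400][1]
  expect_equal(sw$singular_w, target, tolerance = 1e-6)
  # continuity away from the singularity, divergence near it
  below <- sw$table[sw$table$w_long < sw$singular_w - 50, ]
  expect_true(all(abs(diff(below$r_e1_hz)) <
                    0.5 * max(abs(below$r_e1_hz))))
  expect_error(sweep_mutual_inhibition(sys, c(3, 2, 1)), "increasing")
})

test_that("rates fall with mutual inhibition, E faster than I", {
  sys <- meanfield_system(297, 566, 849, 1273, f = c(5, 0))
  sw <- sweep_mutual_inhibition(sys, seq(0, 150, by = 25))
  tab <- sw$table[sw$table$feasible, ]
  expect_true(all(diff(tab$r_e1_hz) < 0))
  rel_e <- tab$r_e1_hz / tab$r_e1_hz[1]
  rel_i <- tab$r_i1_hz / tab$r_i1_hz[1]
  expect_true(all(rel_e[-1] < rel_i[-1]))
})

test_that("theory-simulation comparison calibrates once and reports errors", {
  sys <- meanfield_system(297, 566, 849, 1273, f = c(5, 0))
  grid <- seq(0, 100, by = 25)
  sw <- sweep_mutual_inhibition(sys, grid)
  # identical inputs (theory scaled by 2) -> zero error after calibration
  sim <- sw$table[, c("w_long", paste0("r_", c("e1", "i1", "e2", "i2"),
                                       "_hz"))]
  sim[, -1] <- sim[, -1] * 2
  cmp <- compare_theory_simulation(sw, sim)
  expect_equal(cmp$scale, 2, tolerance = 1e-10)
  expect_true(all(as.matrix(cmp$table[, paste0("err_", c("e1", "i1", "e2",
                                                         "i2"))]) < 1e-9))
  expect_true(all(cmp$regime == "symmetric"))
  sim_bad <- sim; sim_bad$w_long <- sim_bad$w_long + 1
  expect_error(compare_theory_simulation(sw, sim_bad), "grids")
})
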