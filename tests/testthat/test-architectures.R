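test_that("unstructured in-degree is a point mass at k per afferent class", {
  conn <- build_unstructured(n = 400, k = 30, seed = 1)
  deg <- in_degree(conn)
  expect_true(all(deg$from_e == 30))
  expect_true(all(deg$from_i == 30))
  expect_true(all(Matrix::diag(conn$W) == 0))
})

test_that("unstructured weights equal +/- A_XY / sqrt(k) by presynaptic class", {
  k <- 30
  conn <- build_unstructured(n = 400, k = k, seed = 1)
  tw <- Matrix::summary(conn$W)
  cls_pre <- conn$layout$class[tw$j]
  cls_post <- conn$layout$class[tw$i]
  expect_equal(unique(tw$x[cls_pre == "E" & cls_post == "E"]), 12.5 / sqrt(k))
  expect_equal(unique(tw$x[cls_pre == "E" & cls_post == "I"]), 20 / sqrt(k))
  expect_equal(unique(tw$x[cls_pre == "I" & cls_post == "E"]), -50 / sqrt(k))
  expect_equal(unique(tw$x[cls_pre == "I" & cls_post == "I"]), -50 / sqrt(k))
  # case-example magnitude quoted in the construction: 12.5/sqrt(600)
  conn2 <- build_unstructured(n = 4000, k = 600, seed = 1)
  tw2 <- Matrix::summary(conn2$W)
  w_ee <- tw2$x[conn2$layout$class[tw2$j] == "E" &
                  conn2$layout$class[tw2$i] == "E"][1]
  expect_equal(w_ee, 12.5 / sqrt(600), tolerance = 1e-12)
  expect_equal(w_ee, 0.5103, tolerance = 1e-3)
})

test_that("k = 1 on four neurons gives one E and one I in-synapse, no self", {
  conn <- build_unstructured(n = 4, k = 1, seed = 1)
  deg <- in_degree(conn)
  expect_true(all(deg$from_e == 1))
  expect_true(all(deg$from_i == 1))
  expect_true(all(Matrix::diag(conn$W) == 0))
})

test_that("discrete cross-pool wiring is exactly k E->I and nothing else", {
  conn <- build_discrete(n = 400, k = 20, seed = 2)
  lay <- conn$layout
  tw <- Matrix::summary(conn$W)
  cross <- lay$pool[tw$j] != lay$pool[tw$i]
  # all cross-pool synapses are excitatory-to-inhibitory
  expect_true(all(lay$class[tw$j[cross]] == "E"))
  expect_true(all(lay$class[tw$i[cross]] == "I"))
  cross_in <- tabulate(tw$i[cross], nrow(lay))
  expect_true(all(cross_in[lay$class == "I"] == 20))
  expect_true(all(cross_in[lay$class == "E"] == 0))
  # within-pool in-degrees are k per class
  deg <- in_degree(conn)
  expect_true(all(deg$from_e[lay$class == "E"] == 20))
  expect_true(all(deg$from_e[lay$class == "I"] == 40))  # own pool + long range
  expect_true(all(deg$from_i == 20))
})

test_that("discrete network with zero long-range weight splits into two components", {
  amp <- c(ee = 10.5, ei = 20, ie = 30, ie_long = 0, ii = 45)
  conn <- build_discrete(n = 400, k = 20, amplitudes = amp, seed = 2)
  tw <- Matrix::summary(conn$W)
  tw <- tw[tw$x != 0, ]
  lay <- conn$layout
  expect_true(all(lay$pool[tw$j] == lay$pool[tw$i]))
})

test_that("wiring is seed-deterministic", {
  a <- build_discrete(n = 400, k = 20, seed = 9)
  b <- build_discrete(n = 400, k = 20, seed = 9)
  expect_identical(Matrix::summary(a$W), Matrix::summary(b$W))
  c <- build_discrete(n = 400, k = 20, seed = 10)
  expect_false(identical(Matrix::summary(a$W), Matrix::summary(c$W)))
})

test_that("all afferents of an inhibitory neuron are negative", {
  for (conn in list(build_unstructured(n = 400, k = 30, seed = 1),
                    build_discrete(n = 400, k = 20, seed = 1),
                    build_continuum(n = 300, seed = 1))) {
    tw <- Matrix::summary(conn$W)
    pre_i <- conn$layout$class[tw$j] == "I"
    expect_true(all(tw$x[pre_i] < 0))
    expect_true(all(tw$x[!pre_i] > 0))
  }
})

test_that("von Mises weight has the reference normalisation and shape", {
  # kappa = 0: uniform weight A/(p N 2 pi)
  expect_equal(von_mises_weight(0.3, 2.2, A = 84, kappa = 0, p = 0.34,
                                N = 100),
               84 / (0.34 * 100 * 2 * pi))
  # maximal at theta_i = theta_j, periodic
  th <- seq(0, 2 * pi, length.out = 200)
  w <- von_mises_weight(th, 1, A = 84, kappa = 0.9, p = 0.34, N = 100)
  expect_equal(th[which.max(w)], 1, tolerance = 0.05)
  expect_equal(von_mises_weight(0.2, 5, 84, 0.9, 0.34, 100),
               von_mises_weight(0.2 + 2 * pi, 5, 84, 0.9, 0.34, 100))
  # expected total outgoing weight is A/(2 pi), independent of kappa:
  # p * N * mean over postsynaptic angles == A/(2 pi) by quadrature
  for (kap in c(0, 0.26, 0.97, 3)) {
    integrand <- function(x) von_mises_weight(x, 0, 1, kap, 0.5, 200)
    total <- 0.5 * 200 * integrate(integrand, 0, 2 * pi)$value / (2 * pi)
    expect_equal(total, 1 / (2 * pi), tolerance = 1e-6)
  }
})

test_that("continuum realized connectivity matches Bernoulli(p) counts", {
  conn <- build_continuum(n = 500, p = 0.34, seed = 3)
  n_syn <- length(conn$W@x)
  expected <- 0.34 * (500 * 499)
  expect_lt(abs(n_syn - expected), 3 * sqrt(expected * 0.66))
  # 80/20 class split and evenly spaced angles per class
  expect_equal(sum(conn$layout$class == "E"), 400)
  expect_equal(sum(conn$layout$class == "I"), 100)
  ang_e <- conn$layout$angle[conn$layout$class == "E"]
  expect_equal(diff(ang_e)[1], 2 * pi / 400, tolerance = 1e-12)
})

test_that("continuum E-E weight decreases with ring distance for kappa > 0", {
  conn <- build_continuum(n = 500, p = 0.5, seed = 4)
  tw <- Matrix::summary(conn$W)
  lay <- conn$layout
  ee <- lay$class[tw$j] == "E" & lay$class[tw$i] == "E"
  d <- abs((lay$angle[tw$i[ee]] - lay$angle[tw$j[ee]]) %% (2 * pi))
  d <- pmin(d, 2 * pi - d)
  w <- tw$x[ee]
  bins <- cut(d, seq(0, pi, length.out = 8))
  mw <- tapply(w, bins, mean)
  expect_true(all(diff(mw) < 0))
})

test_that("p = 1, kappa = 0 continuum is all-to-all with uniform weights", {
  amp <- c(ee = 10, ei = 10, ie = 10, ii = 10)
  kap <- c(ee = 0, ei = 0, ie = 0, ii = 0)
  conn <- build_continuum(n = 100, p = 1, amplitudes = amp, kappas = kap,
                          seed = 1)
  expect_equal(length(conn$W@x), 100 * 99)
  tw <- Matrix::summary(conn$W)
  w_to_e <- abs(tw$x[conn$layout$class[tw$i] == "E"])
  expect_true(all(abs(w_to_e - 10 / (80 * 2 * pi)) < 1e-12))
})

test_that("builder preconditions are enforced", {
  expect_error(build_unstructured(n = 100, k = 60), "k must be below")
  expect_error(build_discrete(n = 100, k = 30), "k must be below")
  expect_error(build_continuum(n = 100, amplitudes = c(ee = 1)), "classes")
  expect_error(von_mises_weight(0, 0, 1, kappa = -1, p = 0.3, N = 10))
  expect_error(von_mises_weight(0, 0, 1, kappa = 1, p = 0, N = 10))
})

test_that("connectivity exports round-trip the synapse table", {
  conn <- build_discrete(n = 400, k = 20, seed = 2)
  tabs <- connectivity_tables(conn)
  expect_equal(nrow(tabs$synapses), length(conn$W@x))
  expect_named(tabs$synapses, c("pre", "post", "weight"))
  W2 <- Matrix::sparseMatrix(i = tabs$synapses$post, j = tabs$synapses$pre,
                             x = tabs$synapses$weight, dims = dim(conn$W))
  expect_equal(W2, conn$W)
})
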