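# Connectivity constructors for the three network architectures.
#
# Amplitude naming follows the "post <- pre" convention: an amplitude named
# "ie" scales synapses from excitatory (pre) onto inhibitory (post) neurons.
# Weights are signed by the presynaptic class: excitatory afferents are
# positive, inhibitory afferents negative. Weights are stored in a sparse
# matrix W with W[i, j] = synaptic strength from neuron j onto neuron i
# (mV ms^-1 per presynaptic spike).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

new_connectivity <- function(layout, W, architecture, params) {
  structure(list(layout = layout, W = W, architecture = architecture,
                 params = params),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("connectivity:", x$architecture, "network,",
      nrow(x$layout), "neurons,",
      length(x$W@x), "synapses\n")
  cat("  classes:", sum(x$layout$class == "E"), "E /",
      sum(x$layout$class == "I"), "I;",
      "pools:", paste(unique(stats::na.omit(x$layout$pool)), collapse = ", "),
      "\n")
  invisible(x)
}

# sample k distinct in-synapses for every postsynaptic neuron from a fixed
# presynaptic index set, excluding self-connections
sample_in_synapses <- function(post_ids, pre_ids, k) {
  n_pre <- length(pre_ids)
  if (k >= n_pre) stop("in-degree k = ", k, " must be below the afferent ",
                       "class size (", n_pre, ")")
  pre <- integer(length(post_ids) * k)
  for (m in seq_along(post_ids)) {
    pool <- pre_ids
    self <- match(post_ids[m], pool)
    if (!is.na(self)) pool <- pool[-self]
    pre[((m - 1L) * k + 1L):(m * k)] <- pool[sample.int(length(pool), k)]
  }
  data.frame(pre = pre, post = rep(post_ids, each = k))
}

unstructured_layout <- function(n) {
  n_e <- n %/% 2L
  data.frame(id = seq_len(n),
             class = rep(c("E", "I"), c(n_e, n - n_e)),
             pool = c(rep(c(1L, 2L), each = n_e %/% 2L,
                          length.out = n_e), rep(NA_integer_, n - n_e)),
             angle = NA_real_)
}

#' Build an unstructured balanced network
#'
#' Half the neurons are excitatory, half inhibitory. Every neuron receives
#' exactly `k` randomly chosen in-synapses from each synaptic class, with
#' weight `A_XY / sqrt(k)` (negated for inhibitory afferents). The excitatory
#' population carries two pool labels (an even split) used only by the drive
#' and percept-readout machinery; the wiring itself is pool-blind.
#'
#' @param n total number of neurons (default 4000).
#' @param k in-degree per afferent class (default 600).
#' @param amplitudes named vector with entries `ee`, `ie`, `ei`, `ii`
#'   (post <- pre); defaults are the case-example values 12.5, 20, 50, 50.
#' @param seed integer seed for the wiring.
#' @return A `connectivity` object.
#' @export
build_unstructured <- function(n = 4000, k = 600,
                               amplitudes = c(ee = 12.5, ie = 20,
                                              ei = 50, ii = 50),
                               seed = 1) {
  stopifnot(all(c("ee", "ie", "ei", "ii") %in% names(amplitudes)))
  if (k >= n / 2) stop("k must be below the class size n/2")
  layout <- unstructured_layout(n)
  W <- with_seed(seed, wire_unstructured(layout, k, amplitudes))
  new_connectivity(layout, W, "unstructured",
                   list(n = n, k = k, amplitudes = amplitudes, seed = seed))
}

wire_unstructured <- function(layout, k, amplitudes, subset = NULL) {
  ids <- if (is.null(subset)) layout$id else subset
  e_ids <- ids[layout$class[ids] == "E"]
  i_ids <- ids[layout$class[ids] == "I"]
  sk <- sqrt(k)
  tri <- list(
    cbind(sample_in_synapses(e_ids, e_ids, k), w = amplitudes[["ee"]] / sk),
    cbind(sample_in_synapses(i_ids, e_ids, k), w = amplitudes[["ie"]] / sk),
    cbind(sample_in_synapses(e_ids, i_ids, k), w = -amplitudes[["ei"]] / sk),
    cbind(sample_in_synapses(i_ids, i_ids, k), w = -amplitudes[["ii"]] / sk))
  tri <- do.call(rbind, tri)
  Matrix::sparseMatrix(i = tri$post, j = tri$pre, x = tri$w,
                       dims = c(nrow(layout), nrow(layout)))
}

#' Build the discrete mutual-inhibition network
#'
#' Two percept pools of `n/2` neurons each (evenly split E/I), wired
#' internally as independent unstructured networks with in-degree `k`. The
#' pools compete through long-range mutual inhibition: every inhibitory
#' neuron additionally receives exactly `k` excitatory in-synapses from the
#' opposite pool with weight `A_ieLONG / sqrt(k)`. No other cross-pool
#' synapses exist. Excitatory neurons are indexed first (pool 1 then pool 2)
#' so rasters display the two competing excitatory populations contiguously.
#'
#' @param n total number of neurons (default 4000, i.e. 1000 E + 1000 I per
#'   pool).
#' @param k in-degree per afferent class (default 200).
#' @param amplitudes named vector `ee`, `ei`, `ie`, `ie_long`, `ii`;
#'   defaults are the case-example values 10.5, 20, 30, 30, 45.
#' @param seed integer seed for the wiring.
#' @return A `connectivity` object.
#' @export
build_discrete <- function(n = 4000, k = 200,
                           amplitudes = c(ee = 10.5, ei = 20, ie = 30,
                                          ie_long = 30, ii = 45),
                           seed = 1) {
  stopifnot(all(c("ee", "ei", "ie", "ie_long", "ii") %in% names(amplitudes)))
  if (n %% 4 != 0) stop("n must be divisible by 4")
  q <- n %/% 4L
  if (k >= q) stop("k must be below the per-pool class size n/4")
  # order: E pool1, E pool2, I pool1, I pool2
  layout <- data.frame(
    id = seq_len(n),
    class = rep(c("E", "I"), each = 2L * q),
    pool = rep(c(1L, 2L, 1L, 2L), each = q),
    angle = NA_real_)
  W <- with_seed(seed, {
    e1 <- 1:q; e2 <- (q + 1L):(2L * q)
    i1 <- (2L * q + 1L):(3L * q); i2 <- (3L * q + 1L):(4L * q)
    sk <- sqrt(k)
    blocks <- function(e_ids, i_ids, e_opp) {
      list(
        cbind(sample_in_synapses(e_ids, e_ids, k), w = amplitudes[["ee"]] / sk),
        cbind(sample_in_synapses(i_ids, e_ids, k), w = amplitudes[["ie"]] / sk),
        cbind(sample_in_synapses(e_ids, i_ids, k), w = -amplitudes[["ei"]] / sk),
        cbind(sample_in_synapses(i_ids, i_ids, k), w = -amplitudes[["ii"]] / sk),
        cbind(sample_in_synapses(i_ids, e_opp, k),
              w = amplitudes[["ie_long"]] / sk))
    }
    tri <- do.call(rbind, c(blocks(e1, i1, e2), blocks(e2, i2, e1)))
    Matrix::sparseMatrix(i = tri$post, j = tri$pre, x = tri$w,
                         dims = c(n, n))
  })
  new_connectivity(layout, W, "discrete",
                   list(n = n, k = k, amplitudes = amplitudes, seed = seed))
}

#' Von Mises synaptic weight profile
#'
#' Weight magnitude between ring positions `theta_i` (postsynaptic) and
#' `theta_j` (presynaptic):
#' `A * exp(kappa * cos(theta_i - theta_j)) / (p * N * 2 * pi * I0(kappa))`,
#' where `I0` is the modified Bessel function of order 0. The profile is
#' positive, periodic in the angle difference and maximal at
#' `theta_i == theta_j`; the normalisation makes the expected total synaptic
#' weight delivered by one presynaptic neuron equal `A / (2 * pi)`,
#' independent of `kappa`.
#'
#' @param theta_i,theta_j ring angles in radians (vectorised).
#' @param A class amplitude.
#' @param kappa von Mises concentration, >= 0.
#' @param p connection probability in (0, 1].
#' @param N number of postsynaptic neurons (class size).
#' @return Weight magnitudes.
#' @export
von_mises_weight <- function(theta_i, theta_j, A, kappa, p, N) {
  stopifnot(kappa >= 0, p > 0, p <= 1, N > 0)
  A * exp(kappa * cos(theta_i - theta_j)) /
    (p * N * 2 * pi * besselI(kappa, 0))
}

#' Build the continuum ring network
#'
#' 80% excitatory and 20% inhibitory neurons arranged evenly on a ring
#' (angles interleaved by class). Every ordered pair is connected
#' independently with probability `p`; connected weights follow the von Mises
#' profile of [von_mises_weight()] with class-specific amplitude and
#' concentration, negated for inhibitory afferents. Excitatory neurons whose
#' angle lies within `arc_halfwidth` of 0 (pool 1) or of pi (pool 2) carry
#' pool labels; these arcs are the stimulated percept populations.
#'
#' @param n total number of neurons (default 4000).
#' @param p connection probability (default 0.34).
#' @param amplitudes named vector `ee`, `ei`, `ie`, `ii`; defaults
#'   84, 314, 1319, 689.
#' @param kappas named vector `ee`, `ei`, `ie`, `ii`; defaults
#'   0.26, 0.93, 0.97, 0.5.
#' @param frac_e excitatory fraction (default 0.8).
#' @param arc_halfwidth half-width (radians) of the two stimulated arcs
#'   (default `pi/4`, i.e. 45 degrees).
#' @param seed integer seed for the wiring.
#' @return A `connectivity` object.
#' @export
build_continuum <- function(n = 4000, p = 0.34,
                            amplitudes = c(ee = 84, ei = 314,
                                           ie = 1319, ii = 689),
                            kappas = c(ee = 0.26, ei = 0.93,
                                       ie = 0.97, ii = 0.5),
                            frac_e = 0.8, arc_halfwidth = pi / 4,
                            seed = 1) {
  need <- c("ee", "ei", "ie", "ii")
  if (!all(need %in% names(amplitudes)) || !all(need %in% names(kappas)))
    stop("amplitudes and kappas must name all four synapse classes ",
         "(ee, ei, ie, ii)")
  n_e <- round(n * frac_e)
  n_i <- n - n_e
  # evenly spaced per class on [0, 2pi)
  angle_e <- 2 * pi * (seq_len(n_e) - 1L) / n_e
  angle_i <- 2 * pi * (seq_len(n_i) - 1L) / n_i
  ang_dist <- function(x, centre) {
    d <- abs((x - centre) %% (2 * pi))
    pmin(d, 2 * pi - d)
  }
  pool_e <- ifelse(ang_dist(angle_e, 0) <= arc_halfwidth, 1L,
                   ifelse(ang_dist(angle_e, pi) <= arc_halfwidth,
                          2L, NA_integer_))
  layout <- data.frame(
    id = seq_len(n),
    class = rep(c("E", "I"), c(n_e, n_i)),
    pool = c(pool_e, rep(NA_integer_, n_i)),
    angle = c(angle_e, angle_i))

  W <- with_seed(seed, {
    cls <- layout$class
    idx_by <- split(layout$id, cls)
    pre_l <- list(); post_l <- list(); w_l <- list()
    m <- 0L
    for (pre_cls in c("E", "I")) {
      for (post_cls in c("E", "I")) {
        key <- paste0(tolower(post_cls), tolower(pre_cls))
        A <- amplitudes[[key]]; kap <- kappas[[key]]
        posts <- idx_by[[post_cls]]
        npost <- length(posts)
        norm <- A / (p * npost * 2 * pi * besselI(kap, 0))
        sgn <- if (pre_cls == "I") -1 else 1
        for (j in idx_by[[pre_cls]]) {
          hit <- posts[runif(npost) < p]
          hit <- hit[hit != j]
          if (!length(hit)) next
          m <- m + 1L
          pre_l[[m]] <- rep.int(j, length(hit))
          post_l[[m]] <- hit
          w_l[[m]] <- sgn * norm *
            exp(kap * cos(layout$angle[hit] - layout$angle[j]))
        }
      }
    }
    Matrix::sparseMatrix(i = unlist(post_l), j = unlist(pre_l),
                         x = unlist(w_l), dims = c(n, n))
  })
  new_connectivity(layout, W, "continuum",
                   list(n = n, p = p, amplitudes = amplitudes,
                        kappas = kappas, frac_e = frac_e,
                        arc_halfwidth = arc_halfwidth, seed = seed))
}

#' Export connectivity as plain tables
#'
#' @param conn a `connectivity` object.
#' @return A list with a sparse synapse triplet table
#'   (`pre`, `post`, `weight`) and the per-neuron label table.
#' @export
connectivity_tables <- function(conn) {
  tw <- Matrix::summary(conn$W)
  list(synapses = data.frame(pre = tw$j, post = tw$i, weight = tw$x),
       labels = conn$layout)
}

#' Per-neuron in-degree by afferent class
#'
#' @param conn a `connectivity` object.
#' @return A data frame with columns `id`, `from_e`, `from_i`.
#' @export
in_degree <- function(conn) {
  tw <- Matrix::summary(conn$W)
  pre_cls <- conn$layout$class[tw$j]
  n <- nrow(conn$layout)
  data.frame(id = seq_len(n),
             from_e = tabulate(tw$i[pre_cls == "E"], n),
             from_i = tabulate(tw$i[pre_cls == "I"], n))
}
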