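# Perceptual and spiking variability measures.
#
# The percept readout converts pooled excitatory spike counts in 50 ms
# windows into the percept state variable P = (u_A - u_B)/(u_A + u_B) and
# classifies each window as percept A (P > 1/3), percept B (P < -1/3) or
# neither (including |P| = 1/3 exactly and empty windows). Dominance epochs
# are intervals between changes of the *reported* percept: a labeled run
# shorter than the report threshold (and any "neither" run) is absorbed into
# the ongoing epoch, so the duration clock runs until the next reportable
# percept change.

#' Percept state trace
#'
#' @param raster a `spike_raster` whose layout labels two excitatory pools.
#' @param window window length (ms, default 50).
#' @return A `percept_trace`: per-window pooled counts `u_a`, `u_b`, percept
#'   state `p` and label (`"A"`, `"B"`, `"neither"`). Windows tile
#'   `[burn_in, duration)`.
#' @export
percept_trace <- function(raster, window = 50) {
  lay <- raster$layout
  if (is.null(lay)) stop("raster has no layout with pool labels")
  ids_a <- lay$id[lay$class == "E" & !is.na(lay$pool) & lay$pool == 1L]
  ids_b <- lay$id[lay$class == "E" & !is.na(lay$pool) & lay$pool == 2L]
  if (!length(ids_a) || !length(ids_b))
    stop("layout must label excitatory neurons of two pools")
  n_win <- floor((raster$duration - raster$burn_in) / window)
  if (n_win < 1) stop("no complete windows after burn-in")
  ev <- raster$events
  keep <- ev$time >= raster$burn_in &
    ev$time < raster$burn_in + n_win * window
  ev <- ev[keep, ]
  win <- floor((ev$time - raster$burn_in) / window) + 1L
  u_a <- tabulate(win[ev$neuron %in% ids_a], n_win)
  u_b <- tabulate(win[ev$neuron %in% ids_b], n_win)
  tot <- u_a + u_b
  p <- ifelse(tot > 0, (u_a - u_b) / tot, NA_real_)
  label <- rep("neither", n_win)
  label[!is.na(p) & p > 1 / 3] <- "A"
  label[!is.na(p) & p < -1 / 3] <- "B"
  structure(list(windows = data.frame(
    t_start = raster$burn_in + (seq_len(n_win) - 1L) * window,
    u_a = u_a, u_b = u_b, p = p, label = label),
    window = window, burn_in = raster$burn_in,
    t_end = raster$burn_in + n_win * window),
    class = "percept_trace")
}

#' @export
print.percept_trace <- function(x, ...) {
  tab <- table(x$windows$label)
  cat("percept_trace:", nrow(x$windows), "windows of", x$window, "ms (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Dominance durations and their statistics
#'
#' Applies the report-threshold filter to the percept trace and measures
#' dominance epochs as intervals between reported percept changes. Labeled
#' runs at least as long as `report_threshold` are reportable; shorter runs
#' and "neither" runs are absorbed into the ongoing epoch. The first and
#' last epochs are flagged censored and excluded from the summary statistics.
#'
#' @param trace a `percept_trace`.
#' @param report_threshold minimum reportable event duration (ms, default
#'   300); a multiple of the window length is recommended.
#' @param policy sub-threshold-event handling. `"absorb"` (default): the
#'   duration clock runs until the next reportable percept change, so short
#'   interruptions extend the ongoing epoch. `"drop"`: a duration is a
#'   maximal same-label run; runs below threshold (and "neither" runs) are
#'   simply not reported.
#' @return A `dominance_stats` object: `epochs` (label, start, end, duration,
#'   censored), summary `stats` (n, mean, sd, cv_d, skewness, skew_cv,
#'   gamma shape/scale by maximum likelihood, per-pool predominance,
#'   alternation rate in Hz, `defined` flag), and the per-window state
#'   assignment used for state-conditioned spiking statistics.
#' @export
dominance_durations <- function(trace, report_threshold = 300,
                                policy = c("absorb", "drop")) {
  stopifnot(inherits(trace, "percept_trace"))
  policy <- match.arg(policy)
  if (report_threshold < 0) stop("report threshold must be >= 0")
  w <- trace$window
  lab <- trace$windows$label
  n_win <- length(lab)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reportable <- r$values %in% c("A", "B") & r$lengths * w >= report_threshold
  rep_idx <- which(reportable)

  window_state <- rep(NA_character_, n_win)
  window_epoch <- rep(NA_integer_, n_win)
  epochs <- data.frame(label = character(0), start = numeric(0),
                       end = numeric(0), duration = numeric(0),
                       censored = logical(0))
  t0 <- trace$windows$t_start[1]
  if (length(rep_idx) && policy == "drop") {
    st_v <- t0 + (starts[rep_idx] - 1L) * w
    en_v <- t0 + ends[rep_idx] * w
    epochs <- data.frame(label = r$values[rep_idx], start = st_v,
                         end = en_v, duration = en_v - st_v,
                         censored = st_v <= t0 | en_v >= trace$t_end)
    for (m in seq_along(rep_idx)) {
      ri <- rep_idx[m]
      window_state[starts[ri]:ends[ri]] <- r$values[ri]
      window_epoch[starts[ri]:ends[ri]] <- m
    }
  } else if (length(rep_idx)) {
    cur <- r$values[rep_idx[1]]
    ep_start <- t0 + (starts[rep_idx[1]] - 1L) * w
    ep_label <- cur
    ep_id <- 1L
    lab_v <- character(0); st_v <- numeric(0); en_v <- numeric(0)
    for (ri in rep_idx) {
      if (r$values[ri] != ep_label) {
        bnd <- t0 + (starts[ri] - 1L) * w
        lab_v <- c(lab_v, ep_label); st_v <- c(st_v, ep_start)
        en_v <- c(en_v, bnd)
        ep_start <- bnd; ep_label <- r$values[ri]; ep_id <- ep_id + 1L
      }
      window_state[starts[ri]:ends[ri]] <- r$values[ri]
      window_epoch[starts[ri]:ends[ri]] <- ep_id
    }
    lab_v <- c(lab_v, ep_label); st_v <- c(st_v, ep_start)
    en_v <- c(en_v, trace$t_end)
    epochs <- data.frame(label = lab_v, start = st_v, end = en_v,
                         duration = en_v - st_v,
                         censored = seq_along(lab_v) %in%
                           c(1L, length(lab_v)))
  }

  complete <- epochs$duration[!epochs$censored]
  stats <- if (length(complete) >= 2) {
    mo <- duration_moments(complete)
    gf <- gamma_fit(complete)
    pred <- c(A = sum(epochs$duration[epochs$label == "A"]),
              B = sum(epochs$duration[epochs$label == "B"]))
    pred <- pred / sum(epochs$duration)
    alt <- (nrow(epochs) - 1) / (sum(epochs$duration) / 1000)
    c(list(defined = TRUE, n = length(complete)), mo,
      list(gamma_shape = gf$shape, gamma_scale = gf$scale,
           predominance = pred, alternation_rate_hz = alt))
  } else {
    list(defined = FALSE, n = length(complete), mean = NA_real_,
         sd = NA_real_, cv = NA_real_, skewness = NA_real_,
         skew_cv = NA_real_, gamma_shape = NA_real_, gamma_scale = NA_real_,
         predominance = c(A = NA_real_, B = NA_real_),
         alternation_rate_hz = NA_real_)
  }

  structure(list(epochs = epochs, stats = stats,
                 window_state = window_state, window_epoch = window_epoch,
                 report_threshold = report_threshold, policy = policy,
                 window = w, t0 = t0, t_end = trace$t_end),
            class = "dominance_stats")
}

#' @export
print.dominance_stats <- function(x, ...) {
  s <- x$stats
  cat("dominance_stats:", nrow(x$epochs), "epochs (",
      s$n, "complete ), report threshold", x$report_threshold, "ms\n")
  if (isTRUE(s$defined))
    cat(sprintf("  mean = %.0f ms, CV_D = %.3f, skewness = %.2f, skew/CV = %.2f\n",
                s$mean, s$cv, s$skewness, s$skew_cv))
  invisible(x)
}

#' Sample moments of dominance durations
#'
#' Mean, standard deviation, coefficient of variation, skewness (adjusted
#' Fisher-Pearson estimator `G1 = g1 * sqrt(n(n-1))/(n-2)`) and the
#' skewness/CV ratio.
#'
#' @param durations numeric vector (>= 2 values).
#' @return A list with `mean`, `sd`, `cv`, `skewness`, `skew_cv`.
#' @export
duration_moments <- function(durations) {
  n <- length(durations)
  if (n < 2) stop("need at least 2 durations")
  m <- mean(durations)
  s <- sd(durations)
  cv <- s / m
  if (s == 0) {
    sk <- NA_real_
  } else {
    m2 <- mean((durations - m)^2)
    m3 <- mean((durations - m)^3)
    g1 <- m3 / m2^1.5
    sk <- if (n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else NA_real_
  }
  list(mean = m, sd = s, cv = cv, skewness = sk,
       skew_cv = if (!is.na(sk) && cv > 0) sk / cv else NA_real_)
}

# Maximum-likelihood gamma fit (shape/scale); NA on failure. Fitted on
# mean-rescaled data so the optimizer works at O(1) parameter scales.
gamma_fit <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0 || var(x) == 0)
    return(list(shape = NA_real_, scale = NA_real_))
  y <- x / m
  s0 <- max(1 / var(y), 1e-4)
  out <- tryCatch(suppressWarnings(
    MASS::fitdistr(y, "gamma", start = list(shape = s0, rate = s0),
                   lower = c(1e-6, 1e-6))),
    error = function(e) NULL)
  if (is.null(out)) return(list(shape = NA_real_, scale = NA_real_))
  list(shape = unname(out$estimate["shape"]),
       scale = m / unname(out$estimate["rate"]))
}

#' Regression of duration SD on mean across drive strengths
#'
#' Ordinary least squares through the origin, so the slope is directly
#' interpretable as an overall duration coefficient of variation. The
#' two-sided p-value is descriptive. A with-intercept fit is returned
#' alongside for comparison.
#'
#' @param mu per-drive mean dominance durations (>= 3 points).
#' @param sigma per-drive duration standard deviations.
#' @return A list with `slope`, `p_value`, and the with-intercept
#'   coefficients `intercept_fit`.
#' @export
sigma_mu_regression <- function(mu, sigma) {
  stopifnot(length(mu) == length(sigma))
  if (length(mu) < 3) stop("need at least 3 drive points")
  f0 <- lm(sigma ~ 0 + mu)
  f1 <- lm(sigma ~ mu)
  list(slope = unname(coef(f0)[1]),
       p_value = suppressWarnings(summary(f0)$coefficients[1, 4]),
       intercept_fit = unname(coef(f1)))
}

#' Report-threshold robustness of CV_D
#'
#' Recomputes the dominance-duration CV at several report thresholds and
#' summarizes its spread. Threshold-stable dynamics (genuine rivalry) give a
#' ratio near 1; drive-tracking dynamics inflate the CV at low thresholds.
#'
#' @param trace a `percept_trace`.
#' @param thresholds report thresholds (ms), default `c(150, 300, 450)`.
#' @return A list with the per-threshold table and the max/min CV ratio.
#' @export
threshold_robustness <- function(trace, thresholds = c(150, 300, 450)) {
  cv <- vapply(thresholds, function(th)
    dominance_durations(trace, th)$stats$cv, numeric(1))
  list(table = data.frame(threshold = thresholds, cv_d = cv),
       ratio = max(cv) / min(cv))
}

#' Per-window state mask
#'
#' Assigns each percept window to a dominant/suppressed state per pool.
#' Pool 1 is dominant in windows of reportable percept-A runs and suppressed
#' in windows of reportable percept-B runs (pool 2 mirrored); "neither"
#' windows and sub-threshold events belong to no mask.
#'
#' @param trace a `percept_trace`.
#' @param report_threshold report threshold (ms).
#' @return A data frame with `t_start`, `state` (`"A"`, `"B"` or `NA`) and
#'   `epoch` per window.
#' @export
state_mask <- function(trace, report_threshold = 300) {
  d <- dominance_durations(trace, report_threshold)
  data.frame(t_start = trace$windows$t_start, state = d$window_state,
             epoch = d$window_epoch)
}

# Contiguous masked-window blocks [start, end) for a pool/state combination.
mask_blocks <- function(dstats, pool, state) {
  target <- if (pool == 1L) c(dominant = "A", suppressed = "B")[[state]]
  else c(dominant = "B", suppressed = "A")[[state]]
  sel <- !is.na(dstats$window_state) & dstats$window_state == target
  if (!any(sel)) return(matrix(numeric(0), ncol = 2))
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  w <- dstats$window
  cbind(dstats$t0 + (starts[r$values] - 1L) * w,
        dstats$t0 + ends[r$values] * w)
}

pool_e_ids <- function(raster, pool) {
  lay <- raster$layout
  lay$id[lay$class == "E" & !is.na(lay$pool) & lay$pool == pool]
}

# spikes of the given neurons assigned to blocks; returns events with block id
events_in_blocks <- function(raster, ids, blocks) {
  ev <- raster$events[raster$events$neuron %in% ids, ]
  if (!nrow(blocks) || !nrow(ev))
    return(cbind(ev[0, ], block = integer(0)))
  breaks <- as.numeric(t(blocks))
  idx <- findInterval(ev$time, breaks)
  inside <- idx %% 2L == 1L
  ev <- ev[inside, ]
  cbind(ev, block = (idx[inside] + 1L) %/% 2L)
}

#' Interspike-interval CV per neuron, state-conditioned
#'
#' The CV of interspike intervals pooled across all same-state epochs of the
#' pool's excitatory neurons; intervals spanning a state change are
#' discarded. Neurons with fewer than `min_isis` qualifying intervals are
#' excluded.
#'
#' @param raster a `spike_raster`.
#' @param dstats a `dominance_stats` (provides the state mask).
#' @param pool pool id (1 or 2).
#' @param state `"dominant"` or `"suppressed"`.
#' @param min_isis minimum qualifying intervals per neuron (default 3).
#' @return A data frame with `neuron`, `n_isi`, `cv`.
#' @export
cv_isi <- function(raster, dstats, pool = 1L,
                   state = c("dominant", "suppressed"), min_isis = 3L) {
  state <- match.arg(state)
  blocks <- mask_blocks(dstats, pool, state)
  ev <- events_in_blocks(raster, pool_e_ids(raster, pool), blocks)
  if (!nrow(ev)) return(data.frame(neuron = integer(0), n_isi = integer(0),
                                   cv = numeric(0)))
  ord <- order(ev$neuron, ev$time)
  nrn <- ev$neuron[ord]; tms <- ev$time[ord]; blk <- ev$block[ord]
  ok <- diff(nrn) == 0L & diff(blk) == 0L
  isi <- diff(tms)[ok]
  who <- nrn[-1][ok]
  if (!length(isi)) return(data.frame(neuron = integer(0),
                                      n_isi = integer(0), cv = numeric(0)))
  n_isi <- tapply(isi, who, length)
  cv <- tapply(isi, who, function(x) sd(x) / mean(x))
  out <- data.frame(neuron = as.integer(names(n_isi)),
                    n_isi = as.integer(n_isi), cv = as.numeric(cv))
  out[out$n_isi >= min_isis & is.finite(out$cv), ]
}

# per-neuron x qualifying-window spike-count matrix for count-based measures;
# a count window qualifies when all percept windows it covers are in the
# masked state
count_matrix <- function(raster, dstats, pool, state, window = 100) {
  w <- dstats$window
  if (window %% w != 0)
    stop("count window must be a multiple of the percept window")
  ratio <- window %/% w
  target <- if (pool == 1L) c(dominant = "A", suppressed = "B")[[state]]
  else c(dominant = "B", suppressed = "A")[[state]]
  st <- dstats$window_state
  n_cw <- length(st) %/% ratio
  if (n_cw < 1) return(NULL)
  grp <- matrix(st[seq_len(n_cw * ratio)], nrow = ratio)
  qual <- which(colSums(!is.na(grp) & grp == target) == ratio)
  if (!length(qual)) return(NULL)
  ids <- pool_e_ids(raster, pool)
  ev <- raster$events[raster$events$neuron %in% ids, ]
  cw <- floor((ev$time - dstats$t0) / window) + 1L
  keep <- cw >= 1L & cw <= n_cw & cw %in% qual
  ev <- ev[keep, ]; cw <- cw[keep]
  col <- match(cw, qual)
  row <- match(ev$neuron, ids)
  counts <- matrix(0L, nrow = length(ids), ncol = length(qual))
  if (nrow(ev)) {
    tab <- table(factor(row, levels = seq_along(ids)),
                 factor(col, levels = seq_along(qual)))
    counts <- matrix(as.integer(tab), nrow = length(ids))
  }
  rownames(counts) <- ids
  counts
}

#' Spike-count Fano factor per neuron, state-conditioned
#'
#' Variance/mean of spike counts in `window`-ms windows that lie entirely
#' within the masked state. Neurons with zero mean count or fewer than
#' `min_windows` qualifying windows are excluded.
#'
#' @inheritParams cv_isi
#' @param window count window (ms, default 100).
#' @param min_windows minimum qualifying windows (default 20).
#' @return A data frame with `neuron`, `n_windows`, `mean_count`, `fano`.
#' @export
fano_factor <- function(raster, dstats, pool = 1L,
                        state = c("dominant", "suppressed"),
                        window = 100, min_windows = 20L) {
  state <- match.arg(state)
  counts <- count_matrix(raster, dstats, pool, state, window)
  empty <- data.frame(neuron = integer(0), n_windows = integer(0),
                      mean_count = numeric(0), fano = numeric(0))
  if (is.null(counts) || nrow(counts) == 0 ||
      ncol(counts) < min_windows) return(empty)
  mu <- rowMeans(counts)
  va <- apply(counts, 1, var)
  out <- data.frame(neuron = as.integer(rownames(counts)),
                    n_windows = ncol(counts), mean_count = mu,
                    fano = va / mu)
  out[out$mean_count > 0, ]
}

#' Pairwise spike-count correlations, state-conditioned
#'
#' Pearson correlation of `window`-ms spike counts for randomly sampled
#' within-pool excitatory pairs, restricted to windows entirely within the
#' masked state. Pairs with zero count variance are excluded.
#'
#' @inheritParams fano_factor
#' @param n_pairs number of sampled pairs (default 1000).
#' @param seed seed for pair sampling.
#' @param min_windows minimum qualifying windows (default 10).
#' @return A data frame with `i`, `j`, `r`.
#' @export
spike_count_correlations <- function(raster, dstats, pool = 1L,
                                     state = c("dominant", "suppressed"),
                                     window = 100, n_pairs = 1000,
                                     seed = 1, min_windows = 10L) {
  state <- match.arg(state)
  counts <- count_matrix(raster, dstats, pool, state, window)
  empty <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  if (is.null(counts) || ncol(counts) < min_windows) return(empty)
  n <- nrow(counts)
  pairs <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    unique(data.frame(i = pmin(i, j), j = pmax(i, j)))
  })
  x <- counts[pairs$i, , drop = FALSE]
  y <- counts[pairs$j, , drop = FALSE]
  sx <- apply(x, 1, sd); sy <- apply(y, 1, sd)
  ok <- sx > 0 & sy > 0
  m <- ncol(counts)
  r <- (rowMeans(x * y) - rowMeans(x) * rowMeans(y)) * m / (m - 1) /
    (sx * sy)
  ids <- as.integer(rownames(counts))
  data.frame(i = ids[pairs$i[ok]], j = ids[pairs$j[ok]], r = r[ok])
}

#' State-conditioned spiking summary for a rivalry run
#'
#' Pools the per-neuron statistics of both pools in their respective
#' dominant and suppressed states: CV of interspike intervals, Fano factor
#' (100 ms windows), sampled spike-count correlations and mean excitatory
#' firing rates.
#'
#' @param raster a `spike_raster`.
#' @param dstats a `dominance_stats`.
#' @param n_pairs sampled pairs per pool for the correlations.
#' @param seed seed for pair sampling.
#' @return A `spike_stats` list with elements `dominant` and `suppressed`,
#'   each holding `cv_isi` / `fano` / `r_sc` tables and their means, plus
#'   mean E rates (Hz) per state.
#' @export
spike_stats <- function(raster, dstats, n_pairs = 1000, seed = 1) {
  one_state <- function(state) {
    cvt <- rbind(cv_isi(raster, dstats, 1L, state),
                 cv_isi(raster, dstats, 2L, state))
    fat <- rbind(fano_factor(raster, dstats, 1L, state),
                 fano_factor(raster, dstats, 2L, state))
    rsc <- rbind(spike_count_correlations(raster, dstats, 1L, state,
                                          n_pairs = n_pairs, seed = seed),
                 spike_count_correlations(raster, dstats, 2L, state,
                                          n_pairs = n_pairs, seed = seed + 1))
    rate <- mean(c(state_rate(raster, dstats, 1L, state),
                   state_rate(raster, dstats, 2L, state)), na.rm = TRUE)
    list(cv_isi = cvt, fano = fat, r_sc = rsc,
         mean_cv_isi = mean(cvt$cv), mean_fano = mean(fat$fano),
         mean_r_sc = mean(rsc$r), mean_e_rate_hz = rate)
  }
  structure(list(dominant = one_state("dominant"),
                 suppressed = one_state("suppressed")),
            class = "spike_stats")
}

# mean E rate (Hz) of a pool within its masked state
state_rate <- function(raster, dstats, pool, state) {
  blocks <- mask_blocks(dstats, pool, state)
  if (!nrow(blocks)) return(NA_real_)
  ids <- pool_e_ids(raster, pool)
  ev <- events_in_blocks(raster, ids, blocks)
  total_s <- sum(blocks[, 2] - blocks[, 1]) / 1000
  nrow(ev) / (length(ids) * total_s)
}

#' @export
print.spike_stats <- function(x, ...) {
  for (st in c("dominant", "suppressed")) {
    s <- x[[st]]
    cat(sprintf("%-10s mean CV_ISI = %.3f (n=%d), mean Fano = %.3f, mean r_sc = %.4f, E rate = %.1f Hz\n",
                st, s$mean_cv_isi, nrow(s$cv_isi), s$mean_fano,
                s$mean_r_sc, s$mean_e_rate_hz))
  }
  invisible(x)
}

#' Levelt proposition checks on drive scans
#'
#' Evaluates the canonical psychophysical regularities on scan summaries.
#' The symmetric scan must provide columns `drive` and `mean_duration`; the
#' pool-A scan must provide `drive_a`, `pred_a`, `pred_b` and
#' `alternation_rate_hz`. Each scan needs at least 4 points.
#'
#' @param symmetric optional symmetric-scan summary (one row per drive).
#' @param pool_a optional pool-A-scan summary.
#' @return A list of check results (`pass`, effect size, detail):
#'   `levelt4` (mean duration decreases with drive), `levelt2_classic`
#'   (weakening pool-A drive below equi-dominance raises pool-B
#'   predominance), `levelt2_modified` (strengthening pool-A drive raises
#'   pool-A predominance) and `max_alternation` (alternation rate maximal at
#'   the equi-dominance point within one grid step).
#' @export
levelt_checks <- function(symmetric = NULL, pool_a = NULL) {
  out <- list()
  if (!is.null(symmetric)) {
    if (nrow(symmetric) < 4) stop("symmetric scan needs >= 4 points")
    ct <- suppressWarnings(cor.test(symmetric$drive, symmetric$mean_duration,
                                    method = "spearman"))
    out$levelt4 <- list(pass = unname(ct$estimate) < 0,
                        rho = unname(ct$estimate), p_value = ct$p.value)
  }
  if (!is.null(pool_a)) {
    if (nrow(pool_a) < 4) stop("pool-A scan needs >= 4 points")
    pool_a <- pool_a[order(pool_a$drive_a), ]
    equi <- which.min(abs(pool_a$pred_a - 0.5))
    lo <- pool_a[seq_len(equi), ]
    hi <- pool_a[equi:nrow(pool_a), ]
    rho_lo <- if (nrow(lo) >= 3)
      suppressWarnings(cor(lo$drive_a, lo$pred_b, method = "spearman"))
    else NA_real_
    rho_hi <- if (nrow(hi) >= 3)
      suppressWarnings(cor(hi$drive_a, hi$pred_a, method = "spearman"))
    else NA_real_
    out$levelt2_classic <- list(pass = isTRUE(rho_lo < 0), rho = rho_lo)
    out$levelt2_modified <- list(pass = isTRUE(rho_hi > 0), rho = rho_hi)
    peak <- which.max(pool_a$alternation_rate_hz)
    out$max_alternation <- list(pass = abs(peak - equi) <= 1L,
                                peak_drive = pool_a$drive_a[peak],
                                equi_drive = pool_a$drive_a[equi])
  }
  if (!length(out)) stop("provide at least one scan summary")
  out
}
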