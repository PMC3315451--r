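#' Flock separation dynamics
#'
#' Two per-frame cohesion measures: the **global separation** `d_global(t)`
#' is the mean distance of the agents from the population centroid; the
#' **local separation** `d_local(t)` is the mean distance of each agent
#' from the centroid of its own local neighbourhood (the agent itself plus
#' its `M` topological nearest neighbours at that frame). Including the
#' focal agent in the local centroid makes `M = N - 1` reduce exactly to
#' the global measure. A stable plateau in either signal indicates ordered,
#' synchronized movement; growth indicates dispersal.
#'
#' @param traj A [as_flock_traj()] trajectory.
#' @param M Neighbourhood size for the local measure, `1..N-1`.
#' @return A `separation_series` tibble with columns `t` (step index from
#'   0), `time` (seconds), `d_global`, `d_local` (metres); attributes `M`
#'   and `dt`.
#' @export
separation_series <- function(traj, M) {
  dm <- traj_dims(traj)
  if (dm$N < 2) abort("need at least 2 agents")
  if (M < 1 || M > dm$N - 1) stopf("M must be in 1..%d", dm$N - 1)
  arr <- traj_array(traj)
  dg <- d_global_frames(arr)
  dl <- vapply(seq_len(dm$T), function(t) {
    pos <- rbind(arr[t, , ])
    nb <- knn_all(pos, M, include_self = TRUE)
    mean(vapply(seq_len(dm$N), function(i) {
      cen <- colMeans(pos[nb[i, ], , drop = FALSE])
      sqrt(sum((pos[i, ] - cen)^2))
    }, numeric(1)))
  }, numeric(1))
  new_separation_series(
    tibble::tibble(t = seq_len(dm$T) - 1L,
                   time = sort(unique(traj$time)),
                   d_global = dg, d_local = dl),
    M = M, dt = traj_dt(traj))
}

# first n frames of a separation series, class preserved
flockfit_head_series <- function(series, n) {
  new_separation_series(tibble::as_tibble(series)[seq_len(min(n,
                                                    nrow(series))), ],
                        M = attr(series, "M"), dt = attr(series, "dt"))
}

new_separation_series <- function(data, M, dt) {
  tibble::new_tibble(data, M = as.integer(M), dt = dt,
                     class = "separation_series")
}

#' Pointwise ensemble mean of separation series
#'
#' @param series A list of [separation_series()] of equal length and `dt`.
#' @return One `separation_series` with the pointwise means.
#' @export
ensemble_mean <- function(series) {
  lens <- vapply(series, nrow, integer(1))
  if (length(unique(lens)) != 1) abort("series lengths differ")
  dts <- vapply(series, function(s) attr(s, "dt"), numeric(1))
  if (diff(range(dts)) > 1e-12) abort("series dt differ")
  out <- tibble::as_tibble(series[[1]])
  out$d_global <- rowMeans(vapply(series, `[[`, numeric(lens[1]),
                                  "d_global"))
  out$d_local <- rowMeans(vapply(series, `[[`, numeric(lens[1]),
                                 "d_local"))
  new_separation_series(out, M = attr(series[[1]], "M"), dt = dts[1])
}

#' Mean absolute separation error between two series
#'
#' The model-selection score: the mean over time of the absolute difference
#' in global separation between a candidate (model-generated) series and a
#' reference (data) series, in metres.
#'
#' @param candidate,reference [separation_series()] of equal length.
#' @return Mean absolute error, metres.
#' @export
selection_score <- function(candidate, reference) {
  if (nrow(candidate) != nrow(reference)) abort("series lengths differ")
  mean(abs(candidate$d_global - reference$d_global))
}

#' Select the best replicate model by collective behaviour
#'
#' Rolls out every candidate model on each set of initial conditions,
#' ensemble-averages the separation dynamics and scores each model either
#' by mean absolute error of `d_global` against a reference series
#' (`criterion = "mae"`) or by its own time-mean `d_global`
#' (`criterion = "cohesion"`, lower = more cohesive). Ties go to the
#' earlier model.
#'
#' Rollouts use each model's own neighbourhood size; `M` only sets the
#' local separation measure.
#'
#' @param models List of `flock_model`s (replicates).
#' @param ic_sets List of [initial_conditions()].
#' @param T Rollout length, frames.
#' @param M Neighbourhood size for the separation measures.
#' @param reference Reference [separation_series()] (required for `"mae"`).
#' @param criterion `"mae"` or `"cohesion"`.
#' @return A list with `model` (the winner), `index`, and a `scores`
#'   tibble.
#' @export
select_best_model <- function(models, ic_sets, T, M, reference = NULL,
                              criterion = c("mae", "cohesion")) {
  criterion <- match.arg(criterion)
  if (!length(models)) abort("need at least one model")
  if (!length(ic_sets)) abort("need at least one set of initial conditions")
  if (criterion == "mae" && is.null(reference)) {
    abort("criterion 'mae' needs a reference series")
  }
  scores <- purrr::map_dbl(models, function(mod) {
    ser <- purrr::map(ic_sets, function(ic) {
      separation_series(rollout(mod, ic, T = T, M = mod$M), M = M)
    })
    em <- ensemble_mean(ser)
    if (criterion == "mae") selection_score(em, reference)
    else mean(em$d_global)
  })
  idx <- which.min(scores)
  list(model = models[[idx]], index = idx,
       scores = tibble::tibble(model = seq_along(models), score = scores))
}

#' Mean separation error as a function of the interaction size M
#'
#' For each candidate neighbourhood size, fits `R` replicate A-type models
#' to the data, rolls each out from the data's own initial conditions for
#' the full recording, scores each rollout's global separation against the
#' data by [selection_score()], and averages over replicates. The
#' neighbourhood size whose models best follow the observed separation
#' dynamics on average is the data-supported interaction structure. The
#' comparison window can be truncated (`t_max`) to exclude, e.g., a flock
#' split at the end of a recording.
#'
#' @param data A [as_flock_traj()] trajectory.
#' @param m_values Candidate `M` values (0 = no collective component).
#' @param R Replicate fits per `M`.
#' @param cfg A [fit_config()]; replicate seeds derive from `cfg$seed`.
#' @param t_max Optional last step index (from 0) included in the score.
#' @return A tibble with columns `M`, `mean_mae` and a list column
#'   `scores` of the per-replicate errors.
#' @export
optimal_m_table <- function(data, m_values, R = 5L, cfg = fit_config(),
                            t_max = NULL) {
  dm <- traj_dims(data)
  if (any(m_values < 0 | m_values > dm$N - 1)) {
    abort("m_values must lie in 0..N-1")
  }
  ref <- separation_series(data, M = max(1L, min(m_values[m_values > 0],
                                                 dm$N - 1L)))
  keep <- if (is.null(t_max)) seq_len(nrow(ref)) else which(ref$t <= t_max)
  ic <- ic_from_data(data)
  rows <- purrr::map(m_values, function(m) {
    ds <- embed_a(data, M = m)
    mods <- fit_replicates(ds, cfg, R = R)
    sc <- purrr::map_dbl(mods, function(mod) {
      tr <- rollout(mod, ic, T = dm$T, M = m)
      ser <- separation_series(tr, M = max(1L, m))
      mean(abs(ser$d_global[keep] - ref$d_global[keep]))
    })
    tibble::tibble(M = m, mean_mae = mean(sc), scores = list(sc))
  })
  dplyr::bind_rows(rows)
}

# predictor D_i(t): mean distance of i to its M nearest neighbours, per
# frame; returns T x N matrix
nn_separation_frames <- function(arr, M) {
  Tn <- dim(arr)[1]; N <- dim(arr)[2]
  out <- matrix(NA_real_, Tn, N)
  for (t in seq_len(Tn)) {
    pos <- rbind(arr[t, , ])
    dmat <- as.matrix(stats::dist(pos))
    nb <- knn_all(pos, M, include_self = FALSE)
    out[t, ] <- vapply(seq_len(N), function(i) mean(dmat[i, nb[i, ]]),
                       numeric(1))
  }
  out
}

new_rule_curve <- function(data, kind, M, dt) {
  tibble::new_tibble(data, kind = kind, M = as.integer(M), dt = dt,
                     class = "rule_curve")
}

#' Attraction/repulsion and speed curves from trajectories
#'
#' Pools every (agent, step) sample from the supplied trajectories, takes
#' as predictor the mean distance `D_i(t)` of an agent to its `M` nearest
#' neighbours, and bins two responses at the next interval: the change in
#' neighbour separation `D_i(t+1) - D_i(t)` (metres per interval; positive
#' = repulsion, negative = attraction) and the speed `v_i(t+1)` (m/s). The
#' sign structure of the first curve — positive at short range, negative at
#' mid range, near zero beyond the interaction limit — summarizes the
#' effective interaction rule of whatever generated the trajectories.
#'
#' @param trajs A trajectory or list of trajectories (same `dt`).
#' @param M Neighbourhood size.
#' @param bin_width Bin width for the separation predictor, metres.
#' @param min_count Bins with fewer samples are flagged `empty`.
#' @param max_distance Analysis window, metres: samples whose neighbour
#'   separation exceeds this at `t` or `t + 1` are dropped. Model
#'   rollouts started far outside their training support can diverge to
#'   astronomical separations; a finite window keeps such runs from
#'   polluting the physically meaningful bins while their pre-divergence
#'   frames still contribute.
#' @return A list with `delta_separation` and `speed`, each a `rule_curve`
#'   tibble (`bin_lo`, `bin_hi`, `bin_mid`, `mean`, `se`, `count`,
#'   `empty`).
#' @export
attraction_speed_curves <- function(trajs, M, bin_width = 10,
                                    min_count = 20L, max_distance = Inf) {
  if (inherits(trajs, "flock_traj")) trajs <- list(trajs)
  if (M < 1) abort("M must be >= 1")
  if (bin_width <= 0) abort("bin_width must be positive")
  if (max_distance <= 0) abort("max_distance must be positive")
  samples <- purrr::map(trajs, function(tr) {
    arr <- traj_array(tr)
    dt <- traj_dt(tr)
    Tn <- dim(arr)[1]
    Dsep <- nn_separation_frames(arr, M)
    ts <- seq_len(Tn - 1)
    disp <- arr[ts + 1, , , drop = FALSE] - arr[ts, , , drop = FALSE]
    spd <- sqrt(apply(disp^2, c(1, 2), sum)) / dt
    tibble::tibble(D = as.vector(Dsep[ts, , drop = FALSE]),
                   Dnext = as.vector(Dsep[ts + 1, , drop = FALSE]),
                   v = as.vector(spd))
  })
  samples <- dplyr::bind_rows(samples)
  samples <- dplyr::filter(samples, pmax(.data$D, .data$Dnext) <=
                             max_distance)
  if (!nrow(samples)) abort("no samples inside max_distance")
  samples$dD <- samples$Dnext - samples$D
  edges <- seq(0, max(samples$D) + bin_width, by = bin_width)
  bin <- findInterval(samples$D, edges, rightmost.closed = TRUE)
  agg <- function(x) {
    g <- dplyr::group_by(tibble::tibble(bin = bin, x = x), .data$bin)
    s <- dplyr::summarise(g, mean = mean(.data$x),
                          se = sd(.data$x) / sqrt(dplyr::n()),
                          count = dplyr::n(), .groups = "drop")
    out <- tibble::tibble(bin = seq_len(length(edges) - 1))
    out <- dplyr::left_join(out, s, by = "bin")
    out$count[is.na(out$count)] <- 0L
    tibble::tibble(bin_lo = edges[out$bin], bin_hi = edges[out$bin + 1],
                   bin_mid = (edges[out$bin] + edges[out$bin + 1]) / 2,
                   mean = out$mean, se = out$se, count = out$count,
                   empty = out$count < min_count)
  }
  dt <- traj_dt(trajs[[1]])
  list(delta_separation = new_rule_curve(agg(samples$dD),
                                         "delta_separation", M, dt),
       speed = new_rule_curve(agg(samples$v), "speed", M, dt))
}

#' Alignment rule curve
#'
#' For every (agent, step) sample, the predictor is the circular mean of
#' the displacement headings over the agent and its `M` nearest
#' neighbours at `t` (mirroring a Vicsek-type alignment neighbourhood),
#' and the response is the agent's own displacement heading at `t + 1`.
#' Responses are binned by predictor over `(-pi, pi]` and summarized by
#' per-bin circular means. For a noiseless topological Vicsek flock the
#' curve is the identity; deviations measure how far an (inferred) rule is
#' from pure alignment. Samples with an undefined heading (zero
#' displacement) are skipped.
#'
#' @param trajs A 2D trajectory or list of them.
#' @param M Neighbourhood size.
#' @param n_bins Number of heading bins.
#' @return A `rule_curve` tibble with per-bin circular mean responses
#'   (radians).
#' @export
alignment_rule_curve <- function(trajs, M, n_bins = 36L) {
  if (inherits(trajs, "flock_traj")) trajs <- list(trajs)
  if (M < 1) abort("M must be >= 1")
  samples <- purrr::map(trajs, function(tr) {
    dm <- traj_dims(tr)
    if (dm$D != 2) abort("alignment curve requires 2D trajectories")
    arr <- traj_array(tr)
    frames <- purrr::map(2:(dm$T - 1), function(t) {
      pos <- rbind(arr[t, , ])
      disp_t <- pos - rbind(arr[t - 1, , ])
      disp_tp1 <- rbind(arr[t + 1, , ]) - pos
      nb <- knn_all(pos, M, include_self = TRUE)
      th <- atan2(disp_t[, 2], disp_t[, 1])
      nz <- rowSums(disp_t^2) > 0
      s <- ifelse(nz, sin(th), 0)
      co <- ifelse(nz, cos(th), 0)
      # neighbourhood circular mean, zero-displacement members excluded
      ssum <- rowSums(matrix(s[nb], dm$N))
      csum <- rowSums(matrix(co[nb], dm$N))
      nnz <- rowSums(matrix(nz[nb], dm$N))
      resp_ok <- rowSums(disp_tp1^2) > 0
      keep <- nnz > 0 & resp_ok
      tibble::tibble(pred = atan2(ssum[keep], csum[keep]),
                     resp = atan2(disp_tp1[keep, 2], disp_tp1[keep, 1]))
    })
    dplyr::bind_rows(frames)
  })
  samples <- dplyr::bind_rows(samples)
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(samples$pred, edges, rightmost.closed = TRUE)
  rows <- purrr::map(seq_len(n_bins), function(b) {
    r <- samples$resp[bin == b]
    cnt <- length(r)
    if (cnt) {
      mu <- circ_mean(r)
      Rbar <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
      csd <- sqrt(pmax(-2 * log(pmax(Rbar, 1e-12)), 0))
      se <- csd / sqrt(cnt)
    } else {
      mu <- NA_real_; se <- NA_real_
    }
    tibble::tibble(bin_lo = edges[b], bin_hi = edges[b + 1],
                   bin_mid = (edges[b] + edges[b + 1]) / 2,
                   mean = mu, se = se, count = cnt)
  })
  out <- dplyr::bind_rows(rows)
  out$empty <- out$count < 1L
  new_rule_curve(out, "alignment", M, traj_dt(trajs[[1]]))
}
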