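#' Initial conditions for model rollouts
#'
#' Two position frames: `x0` (step 0) and `x1` (step 1). Equal frames
#' encode "no initial velocity". Generators:
#'
#' * `ic_from_data()` takes the first two frames of a trajectory, so a
#'   rollout can be compared directly against its source recording.
#' * `ic_random_normal()` draws positions per coordinate from a normal
#'   distribution with the mean and `sd_scale` times the standard deviation
#'   of the trajectory's first frame, with no initial velocity. Scaling the
#'   spread up (e.g. `sd_scale = 2`) starts the flock more dispersed and
#'   probes the attraction dynamics.
#' * `ic_disc()` places `N` agents uniformly in a disc of radius
#'   `rho_c * sqrt(N)` metres (so `rho_c` fixes the initial density
#'   independently of `N`) and gives every agent the same initial speed
#'   `v_c * 15` m/s with independent uniform headings. `v_c` in `[0, 1]`
#'   spans rest to the 15 m/s cap, the typical cruising speed of homing
#'   pigeons.
#'
#' @param x0,x1 N x D position matrices, metres.
#' @return An `initial_conditions` list with fields `x0`, `x1`.
#' @export
initial_conditions <- function(x0, x1) {
  x0 <- rbind(x0); x1 <- rbind(x1)
  if (!all(dim(x0) == dim(x1))) abort("x0 and x1 shapes differ")
  structure(list(x0 = x0, x1 = x1), class = "initial_conditions")
}

#' @rdname initial_conditions
#' @param traj A [as_flock_traj()] trajectory.
#' @export
ic_from_data <- function(traj) {
  arr <- traj_array(traj)
  initial_conditions(arr[1, , , drop = TRUE], arr[2, , , drop = TRUE])
}

#' @rdname initial_conditions
#' @param sd_scale Multiplier on the per-coordinate standard deviation.
#' @param seed Integer seed.
#' @export
ic_random_normal <- function(traj, sd_scale = 1, seed) {
  if (sd_scale <= 0) abort("sd_scale must be positive")
  arr <- traj_array(traj)
  x0f <- rbind(arr[1, , , drop = TRUE])
  N <- nrow(x0f); D <- ncol(x0f)
  mu <- colMeans(x0f)
  sg <- apply(x0f, 2, sd) * sd_scale
  with_seed(seed, {
    x0 <- vapply(seq_len(D), function(d) rnorm(N, mu[d], sg[d]),
                 numeric(N))
    initial_conditions(x0, x0)
  })
}

#' @rdname initial_conditions
#' @param N Number of agents.
#' @param rho_c Density coefficient; disc radius is `rho_c * sqrt(N)` m.
#' @param v_c Speed coefficient in `[0, 1]`; initial speed is `v_c * 15`
#'   m/s.
#' @param dt Sampling interval of the model the rollout will use, seconds.
#' @param D Spatial dimension (altitude, if any, starts at 0 with no
#'   vertical velocity).
#' @export
ic_disc <- function(N, rho_c, v_c, dt, seed, D = 2) {
  if (N < 2) abort("N must be >= 2")
  if (rho_c <= 0) abort("rho_c must be positive")
  if (v_c < 0 || v_c > 1) abort("v_c must be in [0, 1]")
  r <- rho_c * sqrt(N)
  with_seed(seed, {
    rad <- r * sqrt(runif(N))
    ang <- runif(N, -pi, pi)
    x0 <- cbind(rad * cos(ang), rad * sin(ang))
    th <- runif(N, -pi, pi)
    s <- v_c * 15
    x1 <- x0 + s * dt * cbind(cos(th), sin(th))
    if (D == 3) {
      x0 <- cbind(x0, 0)
      x1 <- cbind(x1, 0)
    }
    initial_conditions(x0, x1)
  })
}

#' Free-run rollout of a fitted flock model
#'
#' Iterates a fitted model forward from initial conditions, rebuilding each
#' agent's embedding from the rolled-out trajectory at every step
#' (topological neighbourhoods recomputed from the current frame). R1/R2
#' models predict the next displacement, which is added to the current
#' position; A models predict the next absolute position directly. The
#' rollout is fully deterministic: the fitted model has no noise term.
#'
#' @param model A [fit_flock_model()] model.
#' @param ic An [initial_conditions()] object.
#' @param T Total number of frames to produce (including the two initial
#'   frames), >= 2.
#' @param M Neighbourhood size; defaults to the model's.
#' @return A `flock_traj` with `T` frames and `dt` taken from the model.
#' @export
rollout <- function(model, ic, T, M = model$M) {
  if (T < 2) abort("T must be >= 2")
  N <- nrow(ic$x0)
  D <- ncol(ic$x0)
  if (D != model$D) abort("initial conditions do not match model dimension")
  if (M > 0 && N < M + 1) abort("need at least M + 1 agents")
  scheme <- model$scheme
  arr <- array(NA_real_, dim = c(T, N, D))
  arr[1, , ] <- ic$x0
  if (T >= 2) arr[2, , ] <- ic$x1
  for (t in 2:max(2, T - 1)) {
    if (t + 1 > T) break
    pos_t <- rbind(arr[t, , ])
    pos_tm1 <- rbind(arr[t - 1, , ])
    disp_t <- pos_t - pos_tm1
    include_self <- scheme == "R1"
    nb <- if (M > 0) knn_all(pos_t, M, include_self = include_self) else NULL
    Z <- matrix(NA_real_, N, length(model$center))
    for (i in seq_len(N)) {
      Z[i, ] <- switch(scheme,
        R1 = colMeans(disp_t[nb[i, ], , drop = FALSE]),
        A = if (M > 0) {
          js <- nb[i, ]
          c(pos_t[i, ], pos_tm1[i, ],
            colMeans(pos_t[js, , drop = FALSE]),
            colMeans(pos_tm1[js, , drop = FALSE]))
        } else {
          c(pos_t[i, ], pos_tm1[i, ])
        },
        R2 = {
          js <- nb[i, ]
          c(disp_t[i, ],
            colMeans(disp_t[js, , drop = FALSE]),
            colMeans(pos_t[js, , drop = FALSE] -
                       matrix(pos_t[i, ], M, D, byrow = TRUE)))
        })
    }
    pred <- rbind(predict(model, Z))
    nxt <- if (scheme == "A") pred else pos_t + pred
    if (!all(is.finite(nxt))) {
      bad <- which(!stats::complete.cases(ifelse(is.finite(nxt), nxt, NA)))
      stopf("non-finite prediction at step %d for agent(s) %s",
            t + 1, paste(bad, collapse = ", "))
    }
    arr[t + 1, , ] <- nxt
  }
  traj_from_array(arr, dt = model$dt)
}

#' Grid sweep of rollout initial conditions
#'
#' Runs `K` repeat rollouts for every combination of density coefficient
#' `rho_c` and speed coefficient `v_c` (see [ic_disc()]), computing
#' separation dynamics for each run. Seeds are derived deterministically
#' from the master seed.
#'
#' @inheritParams rollout
#' @param N Agents per rollout.
#' @param rho_grid,v_grid Coefficient grids.
#' @param K Repeats per grid cell.
#' @param seed Master seed.
#' @return A tibble with one row per run: `rho_c`, `v_c`, `rep`, the
#'   [separation_series()] (list column `series`) and its time means
#'   `mean_d_global`, `mean_d_local`.
#' @export
sweep_r2 <- function(model, N, M, rho_grid, v_grid, K, T, seed) {
  if (!length(rho_grid) || !length(v_grid)) abort("grids must be non-empty")
  if (K < 1) abort("K must be >= 1")
  grid <- tidyr::expand_grid(rho_c = rho_grid, v_c = v_grid,
                             rep = seq_len(K))
  seeds <- derive_seeds(seed, nrow(grid), stride = 101L)
  runs <- purrr::pmap(list(grid$rho_c, grid$v_c, seq_len(nrow(grid))),
    function(rho, v, k) {
      ic <- ic_disc(N, rho, v, dt = model$dt, seed = seeds[k], D = model$D)
      tr <- rollout(model, ic, T = T, M = M)
      separation_series(tr, M = M)
    })
  grid$series <- runs
  grid$mean_d_global <- vapply(runs, function(s) mean(s$d_global),
                               numeric(1))
  grid$mean_d_local <- vapply(runs, function(s) mean(s$d_local), numeric(1))
  grid
}
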