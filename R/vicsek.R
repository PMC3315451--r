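#' Parameters of the topological Vicsek flock
#'
#' A constant-speed point-particle flock on an unbounded plane. Each agent
#' aligns its heading with the circular mean heading of itself and its `M`
#' topological (rank-based) nearest neighbours, perturbed by angular noise
#' drawn uniformly from `(-eta/2, eta/2)`. There are no periodic boundaries:
#' agents start in an `L` by `L` square and then move freely.
#'
#' @param N Number of agents (>= 2).
#' @param L Linear size of the initial square, metres. Together with `N` it
#'   sets the initial density `N / L^2`.
#' @param v Constant speed, metres per step.
#' @param eta Angular noise range, radians in `[0, 2*pi]`.
#' @param M Number of topological nearest neighbours, `0..N-1`.
#' @return A `vicsek_params` list.
#' @export
vicsek_params <- function(N, L, v, eta, M) {
  if (N < 2) abort("N must be >= 2")
  if (L <= 0) abort("L must be positive")
  if (v < 0) abort("v must be non-negative")
  if (eta < 0 || eta > 2 * pi) abort("eta must be in [0, 2*pi]")
  if (M < 0 || M > N - 1) abort("M must be in 0..N-1")
  structure(list(N = as.integer(N), L = L, v = v, eta = eta,
                 M = as.integer(M)),
            class = "vicsek_params")
}

#' Initialise a Vicsek state
#'
#' Positions i.i.d. uniform on `[0, L]^2`, headings i.i.d. uniform on
#' `(-pi, pi]`.
#'
#' @param params A [vicsek_params()].
#' @param seed Integer seed; the same seed always yields the same state.
#' @return A `vicsek_state` list with fields `positions` (N x 2 matrix,
#'   metres) and `headings` (N angles, radians).
#' @export
init_vicsek <- function(params, seed) {
  with_seed(seed, {
    pos <- cbind(runif(params$N, 0, params$L),
                 runif(params$N, 0, params$L))
    th <- wrap_angle(runif(params$N, -pi, pi))
    vicsek_state(pos, th)
  })
}

vicsek_state <- function(positions, headings) {
  structure(list(positions = positions, headings = wrap_angle(headings)),
            class = "vicsek_state")
}

#' Advance a Vicsek state by one step
#'
#' Synchronous update from the time-t snapshot: each agent's new heading is
#' the circular mean heading over itself and its `M` nearest neighbours
#' (Euclidean distance at time t, ties broken by lower agent index) plus a
#' uniform angular perturbation; the position then advances by `v` along the
#' new heading. Noise is drawn per agent in agent order from the current RNG
#' stream, so wrap calls in [with_seed()] (or `set.seed()`) for
#' reproducibility.
#'
#' @param state A `vicsek_state`.
#' @param params A [vicsek_params()].
#' @return The updated `vicsek_state`.
#' @export
step_vicsek <- function(state, params) {
  pos <- state$positions
  th <- state$headings
  N <- params$N
  nb <- knn_all(pos, params$M, include_self = TRUE)
  mean_th <- vapply(seq_len(N), function(i) circ_mean(th[nb[i, ]]),
                    numeric(1))
  noise <- if (params$eta > 0) {
    runif(N, -params$eta / 2, params$eta / 2)
  } else {
    numeric(N)
  }
  new_th <- wrap_angle(mean_th + noise)
  new_pos <- pos + params$v * cbind(cos(new_th), sin(new_th))
  vicsek_state(new_pos, new_th)
}

#' Simulate a topological Vicsek trajectory
#'
#' Initialises with [init_vicsek()] and applies `T - 1` synchronous steps.
#' The result is a [as_flock_traj()] trajectory with `dt = 1` (one model
#' step).
#'
#' @inheritParams init_vicsek
#' @param T Number of recorded frames, >= 3.
#' @return A 2D `flock_traj` with `T` frames.
#' @examples
#' p <- vicsek_params(N = 10, L = 5, v = 0.03, eta = 0.4, M = 3)
#' traj <- simulate_vicsek(p, T = 50, seed = 1)
#' @export
simulate_vicsek <- function(params, T, seed) {
  if (T < 3) abort("T must be >= 3")
  with_seed(seed, {
    st <- vicsek_state(
      cbind(runif(params$N, 0, params$L), runif(params$N, 0, params$L)),
      wrap_angle(runif(params$N, -pi, pi))
    )
    arr <- array(NA_real_, dim = c(T, params$N, 2))
    arr[1, , ] <- st$positions
    for (t in seq_len(T - 1)) {
      st <- step_vicsek(st, params)
      arr[t + 1, , ] <- st$positions
    }
    traj_from_array(arr, dt = 1)
  })
}
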