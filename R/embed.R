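#' Neighbour-aware embeddings of a trajectory
#'
#' These functions turn a trajectory into a tidy predictor/target sample
#' table for dynamical model fitting. Each row corresponds to one agent `i`
#' at one time step `t` (with both `t - 1` and `t + 1` in range), predictor
#' columns `z*` and target columns `y_*`. Three schemes are supported:
#'
#' * **R1** (`embed_r1()`): predictor = the mean displacement over agent `i`
#'   *and* its `M` nearest neighbours at `t`; target = the displacement of
#'   `i` over the next interval. This is the minimal embedding that captures
#'   a Vicsek-type alignment rule (2 predictors in 2D).
#' * **A** (`embed_a()`): predictors = the absolute position of `i` at `t`
#'   and `t - 1` and the mean position of its `M` nearest neighbours
#'   (excluding `i`) at the same two steps; target = the absolute position
#'   of `i` at `t + 1`. In 3D this is a 12-variable embedding; `M = 0`
#'   drops the neighbour blocks and gives the 6-variable "individual"
#'   embedding with no collective component. Neighbour sets are found once,
#'   at time `t`, and reused for the `t - 1` block.
#' * **R2** (`embed_r2()`): predictors = own displacement, mean neighbour
#'   displacement, and the mean positional offset from `i` to its
#'   neighbours (a hybrid of topological neighbour selection and metric
#'   separation); target = own next displacement. 9 variables in 3D, 6 in
#'   2D.
#'
#' The result is a `flock_embedding` tibble with index columns `flight`,
#' `agent`, `time` and attributes `scheme`, `M`, `D`, `dt`.
#'
#' @param traj A [as_flock_traj()] trajectory.
#' @param M Number of topological nearest neighbours.
#' @return A `flock_embedding` tibble with one row per (agent, time).
#' @examples
#' traj <- simulate_vicsek(vicsek_params(8, 5, 0.03, 0.3, 3), T = 20, seed = 1)
#' embed_r1(traj, M = 3)
#' @export
embed_r1 <- function(traj, M) {
  dm <- traj_dims(traj)
  if (dm$D != 2) abort("R1 embedding requires a 2D trajectory")
  check_embed_m(M, dm$N, min_m = 0L)
  build_embedding(traj, M, scheme = "R1")
}

#' @rdname embed_r1
#' @export
embed_a <- function(traj, M) {
  dm <- traj_dims(traj)
  check_embed_m(M, dm$N, min_m = 0L)
  build_embedding(traj, M, scheme = "A")
}

#' @rdname embed_r1
#' @export
embed_r2 <- function(traj, M) {
  dm <- traj_dims(traj)
  check_embed_m(M, dm$N, min_m = 1L)
  build_embedding(traj, M, scheme = "R2")
}

check_embed_m <- function(M, N, min_m) {
  if (M < min_m || M > N - 1) stopf("M must be in %d..%d", min_m, N - 1)
}

embedding_blocks <- function(scheme, M, D) {
  blocks <- switch(scheme,
    R1 = "nbhd_disp",
    A = if (M > 0) c("self_t", "self_tm1", "nbrs_t", "nbrs_tm1")
        else c("self_t", "self_tm1"),
    R2 = c("self_disp", "nbrs_disp", "nbrs_offset")
  )
  coords <- c("x", "y", "z")[seq_len(D)]
  list(blocks = blocks,
       z_names = as.vector(t(outer(blocks, coords, paste, sep = "_"))),
       y_names = paste0("y_", coords))
}

build_embedding <- function(traj, M, scheme) {
  dm <- traj_dims(traj)
  if (dm$T < 3) abort("need at least 3 time steps")
  arr <- traj_array(traj)
  D <- dm$D
  N <- dm$N
  nm <- embedding_blocks(scheme, M, D)
  p <- length(nm$z_names)
  steps <- 2:(dm$T - 1)                 # rows exist for t with t-1 and t+1
  n <- N * length(steps)
  Z <- matrix(NA_real_, n, p)
  Y <- matrix(NA_real_, n, D)
  row <- 0L
  for (t in steps) {
    pos_t <- arr[t, , , drop = TRUE]
    pos_tm1 <- arr[t - 1, , , drop = TRUE]
    disp_t <- pos_t - pos_tm1
    disp_tp1 <- arr[t + 1, , , drop = TRUE] - pos_t
    include_self <- scheme == "R1"
    nb <- if (M > 0) knn_all(pos_t, M, include_self = include_self) else NULL
    for (i in seq_len(N)) {
      row <- row + 1L
      z <- switch(scheme,
        R1 = colMeans(disp_t[nb[i, ], , drop = FALSE]),
        A = {
          if (M > 0) {
            js <- nb[i, ]
            c(pos_t[i, ], pos_tm1[i, ],
              colMeans(pos_t[js, , drop = FALSE]),
              colMeans(pos_tm1[js, , drop = FALSE]))
          } else {
            c(pos_t[i, ], pos_tm1[i, ])
          }
        },
        R2 = {
          js <- nb[i, ]
          c(disp_t[i, ],
            colMeans(disp_t[js, , drop = FALSE]),
            colMeans(pos_t[js, , drop = FALSE] -
                       matrix(pos_t[i, ], M, D, byrow = TRUE)))
        }
      )
      Z[row, ] <- z
      Y[row, ] <- if (scheme == "A") arr[t + 1, i, ] else disp_tp1[i, ]
    }
  }
  # time column: frame times of the central step t
  times <- min(traj$time) + (steps - 1) * traj_dt(traj)
  idx <- tibble::tibble(
    flight = "f1",
    agent = rep(traj_agents(traj), times = length(steps)),
    time = rep(times, each = N)
  )
  colnames(Z) <- nm$z_names
  colnames(Y) <- nm$y_names
  out <- dplyr::bind_cols(idx, tibble::as_tibble(Z), tibble::as_tibble(Y))
  out <- dplyr::arrange(out, .data$flight,
                        match(.data$agent, traj_agents(traj)), .data$time)
  new_flock_embedding(out, scheme = scheme, M = M, D = D,
                      dt = traj_dt(traj))
}

new_flock_embedding <- function(data, scheme, M, D, dt) {
  tibble::new_tibble(data, scheme = scheme, M = as.integer(M),
                     D = as.integer(D), dt = dt,
                     class = "flock_embedding")
}

#' @export
print.flock_embedding <- function(x, ...) {
  cat(sprintf("# flock_embedding: scheme %s, M = %d, D = %d, %d samples\n",
              attr(x, "scheme"), attr(x, "M"), attr(x, "D"), nrow(x)))
  NextMethod()
}

#' Predictor and target matrices of an embedding
#'
#' @param ds A `flock_embedding`.
#' @return A numeric matrix: n x p predictors (`embedding_Z`) or n x q
#'   targets (`embedding_Y`).
#' @export
embedding_Z <- function(ds) {
  nm <- embedding_blocks(attr(ds, "scheme"), attr(ds, "M"), attr(ds, "D"))
  as.matrix(ds[, nm$z_names])
}

#' @rdname embedding_Z
#' @export
embedding_Y <- function(ds) {
  nm <- embedding_blocks(attr(ds, "scheme"), attr(ds, "M"), attr(ds, "D"))
  as.matrix(ds[, nm$y_names])
}

#' Concatenate embeddings from several flights
#'
#' All inputs must share scheme, `M`, spatial dimension and sampling
#' interval (resample flights to a common `dt` first). Flight labels are
#' made unique.
#'
#' @param ... `flock_embedding` tables.
#' @return One combined `flock_embedding`.
#' @export
combine_embeddings <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && is.list(dss[[1]]) &&
      !inherits(dss[[1]], "flock_embedding")) {
    dss <- dss[[1]]
  }
  ref <- dss[[1]]
  for (ds in dss[-1]) {
    same <- identical(attr(ds, "scheme"), attr(ref, "scheme")) &&
      attr(ds, "M") == attr(ref, "M") && attr(ds, "D") == attr(ref, "D") &&
      isTRUE(all.equal(attr(ds, "dt"), attr(ref, "dt")))
    if (!same) abort("embeddings differ in scheme, M, D or dt")
  }
  tabs <- purrr::imap(dss, function(ds, k) {
    ds$flight <- sprintf("f%d", k)
    tibble::as_tibble(ds)
  })
  new_flock_embedding(dplyr::bind_rows(tabs), scheme = attr(ref, "scheme"),
                      M = attr(ref, "M"), D = attr(ref, "D"),
                      dt = attr(ref, "dt"))
}

#' Remove directional bias from an R2 embedding by planar rotation
#'
#' Trajectory data often share one dominant travel direction - because the
#' flight is goal-directed, or because a flock has ordered onto a common
#' heading - and a model fitted to them inherits that bias and
#' extrapolates poorly in rarely visited directions. The R2 scheme is
#' rotation-equivariant: rotating a sample's predictors
#' and target together yields an equally valid sample of the same
#' underlying rule. Each sample row is therefore rotated in the x-y plane
#' so that the headings of the target displacements are spread uniformly
#' (deterministically stratified) over the full circle. With rows taken in (flight, agent, time) order, row `k`
#' of `n` is rotated so its target heading becomes `-pi + 2*pi*k/n`. All
#' x-y pairs inside the predictors and the target of a row are rotated by
#' the same angle, so within-row geometry (norms, relative angles) is
#' preserved exactly; altitude components are left untouched. Rows with a
#' zero-length planar target are rotated by the destination heading itself.
#'
#' @param ds An R2 `flock_embedding`.
#' @return The debiased `flock_embedding`.
#' @export
rotate_debias <- function(ds) {
  scheme <- attr(ds, "scheme")
  if (!identical(scheme, "R2")) {
    abort("rotate_debias applies to the R2 embedding only")
  }
  D <- attr(ds, "D")
  nm <- embedding_blocks(scheme, attr(ds, "M"), D)
  ord <- order(ds$flight, ds$agent, ds$time)
  n <- nrow(ds)
  Z <- embedding_Z(ds)
  Y <- embedding_Y(ds)
  alpha <- atan2(Y[, 2], Y[, 1])
  zero <- sqrt(Y[, 1]^2 + Y[, 2]^2) == 0
  g <- numeric(n)
  g[ord] <- -pi + 2 * pi * seq_len(n) / n
  beta <- ifelse(zero, g, g - alpha)
  # x-y column pairs: each D-block contributes its first two coords
  for (b in seq_along(nm$blocks)) {
    xc <- (b - 1) * D + 1
    Z <- rotate_xy(Z, xc, xc + 1, beta)
  }
  Y <- rotate_xy(Y, 1, 2, beta)
  out <- tibble::as_tibble(ds)
  out[, nm$z_names] <- tibble::as_tibble(Z)
  out[, nm$y_names] <- tibble::as_tibble(Y)
  new_flock_embedding(out, scheme = scheme, M = attr(ds, "M"), D = D,
                      dt = attr(ds, "dt"))
}
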