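# Independent brute-force oracles and small fixture builders.

# plain double-loop topological Vicsek step, eta = 0 (deterministic part)
oracle_vicsek_step <- function(pos, th, M, v) {
  N <- nrow(pos)
  new_th <- numeric(N)
  for (i in seq_len(N)) {
    d <- rep(Inf, N)
    for (j in seq_len(N)) {
      if (j != i) d[j] <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    }
    nbrs <- integer(0)
    if (M > 0) {
      ord <- order(d, seq_len(N))
      nbrs <- ord[seq_len(M)]
    }
    set <- c(i, nbrs)
    new_th[i] <- atan2(mean(sin(th[set])), mean(cos(th[set])))
  }
  list(positions = pos + v * cbind(cos(new_th), sin(new_th)),
       headings = new_th)
}

# double-loop separation measures
oracle_separations <- function(pos, M) {
  N <- nrow(pos)
  cen <- colMeans(pos)
  dg <- mean(sqrt(rowSums((pos - matrix(cen, N, ncol(pos),
                                        byrow = TRUE))^2)))
  dl <- 0
  for (i in seq_len(N)) {
    d <- rep(Inf, N)
    for (j in seq_len(N)) {
      if (j != i) d[j] <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    }
    nbrs <- order(d, seq_len(N))[seq_len(M)]
    loc <- colMeans(pos[c(i, nbrs), , drop = FALSE])
    dl <- dl + sqrt(sum((pos[i, ] - loc)^2))
  }
  list(d_global = dg, d_local = dl / N)
}

# random smooth trajectory: straight lines plus jitter
random_traj <- function(N = 4, T = 8, D = 2, seed = 1, dt = 1) {
  set.seed(seed)
  arr <- array(NA_real_, c(T, N, D))
  x0 <- matrix(rnorm(N * D, sd = 5), N, D)
  v <- matrix(rnorm(N * D, sd = 0.5), N, D)
  for (t in seq_len(T)) {
    arr[t, , ] <- x0 + (t - 1) * v + matrix(rnorm(N * D, sd = 0.05), N, D)
  }
  flockfit:::traj_from_array(arr, dt = dt)
}

# trajectory from an explicit [T x N x D] array
traj_of <- function(arr, dt = 1) flockfit:::traj_from_array(arr, dt = dt)

# hand-built A-scheme model (M = 0): x(t+1) = scale * x(t), no RBF terms
hand_a_model <- function(D = 2, scale_fac = 1) {
  coords <- lapply(seq_len(D), function(j) {
    w <- numeric(2 * D)
    w[j] <- scale_fac
    structure(list(intercept = 0, linear_weights = w, terms = list(),
                   mdl = 0, sse = 0, n_train = 10L, trace = NULL),
              class = "rbf_coord_model")
  })
  names(coords) <- paste0("y_", c("x", "y", "z")[seq_len(D)])
  structure(list(scheme = "A", M = 0L, D = as.integer(D), dt = 1,
                 center = numeric(2 * D), scale = rep(1, 2 * D),
                 coords = coords, seed = NULL, config = NULL),
            class = "flock_model")
}

# hand-built R2-scheme model: f(z) = constant displacement c
hand_r2_const_model <- function(c_vec, M = 1L) {
  D <- length(c_vec)
  p <- 3 * D
  coords <- lapply(seq_len(D), function(j) {
    structure(list(intercept = c_vec[j], linear_weights = numeric(p),
                   terms = list(), mdl = 0, sse = 0, n_train = 10L,
                   trace = NULL),
              class = "rbf_coord_model")
  })
  names(coords) <- paste0("y_", c("x", "y", "z")[seq_len(D)])
  structure(list(scheme = "R2", M = as.integer(M), D = as.integer(D),
                 dt = 1, center = numeric(p), scale = rep(1, p),
                 coords = coords, seed = NULL, config = NULL),
            class = "flock_model")
}

# independent evaluation of an rbf_coord_model (no package internals)
predict_coord_oracle <- function(cm, Z) {
  out <- cm$intercept + drop(Z %*% cm$linear_weights)
  for (tm in cm$terms) {
    phi <- apply(Z, 1, function(z) {
      exp(-sum((z - tm$center)^2) / (2 * tm$radius^2))
    })
    out <- out + tm$weight * phi
  }
  out
}
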