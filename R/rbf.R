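#' Gaussian radial basis function
#'
#' `exp(-||z - center||^2 / (2 * radius^2))`, in `(0, 1]`. `z` may be a
#' single p-vector or an n x p matrix (one value per row).
#'
#' @param z Evaluation point(s).
#' @param center Centre, p-vector.
#' @param radius Positive length scale.
#' @return Numeric scalar or vector.
#' @export
gaussian_rbf <- function(z, center, radius) {
  if (radius <= 0) abort("radius must be positive")
  if (is.matrix(z)) {
    d2 <- rowSums(z^2) - 2 * drop(z %*% center) + sum(center^2)
    d2 <- pmax(d2, 0)
  } else {
    d2 <- sum((z - center)^2)
  }
  exp(-d2 / (2 * radius^2))
}

#' Description-length score for model selection
#'
#' A BIC-form description length, `(n/2)*log(sse/n) + (k/2)*log(n)`: the
#' first term is the data code length under Gaussian residuals, the second
#' the cost of transmitting `k` fitted parameters. Adding a basis function
#' is only worthwhile when its residual reduction outweighs its parameter
#' cost. `sse` is floored at `n * 1e-24` so perfect fits stay finite.
#'
#' @param n Number of training samples.
#' @param sse Residual sum of squares, >= 0.
#' @param k Effective number of parameters, `0 <= k < n`.
#' @return The score (lower is better).
#' @export
mdl_score <- function(n, sse, k) {
  if (sse < 0) abort("sse must be non-negative")
  if (n <= k) abort("over-parameterized: n must exceed k")
  sse <- max(sse, n * 1e-24)
  (n / 2) * log(sse / n) + (k / 2) * log(n)
}

#' Configuration of the greedy RBF fitter
#'
#' @param pool_size Number of random candidate basis functions drawn per
#'   iteration.
#' @param max_terms Hard cap on accepted basis functions.
#' @param patience Consecutive non-improving iterations before stopping.
#' @param radius_quantiles Candidate radii are random quantiles of the
#'   pairwise-distance distribution of the (standardized) training
#'   predictors, drawn uniformly between these two probabilities.
#' @param seed Integer seed making the fit deterministic; `NULL` uses the
#'   current RNG stream.
#' @return A `fit_config` list.
#' @export
fit_config <- function(pool_size = 50L, max_terms = 100L, patience = 3L,
                       radius_quantiles = c(0.05, 0.95), seed = NULL) {
  if (pool_size < 1) abort("pool_size must be >= 1")
  q <- radius_quantiles
  if (length(q) != 2 || q[1] <= 0 || q[2] <= q[1] || q[2] > 1) {
    abort("radius_quantiles must satisfy 0 < low < high <= 1")
  }
  structure(list(pool_size = as.integer(pool_size),
                 max_terms = as.integer(max_terms),
                 patience = as.integer(patience),
                 radius_quantiles = q,
                 seed = seed),
            class = "fit_config")
}

# least squares with ridge fallback on rank deficiency; returns unpivoted
# coefficients and SSE
ls_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    warn("rank-deficient design; falling back to ridge (1e-8)")
    XtX <- crossprod(X)
    diag(XtX) <- diag(XtX) + 1e-8
    coefs <- drop(solve(XtX, crossprod(X, y)))
  }
  res <- y - drop(X %*% coefs)
  list(coef = coefs, sse = sum(res^2))
}

#' Fit one output coordinate by greedy RBF selection
#'
#' Fits `y ~ intercept + linear(Z) + sum of Gaussian RBFs` by forward
#' selection. The affine part is fitted first by ordinary least squares.
#' Then, at each iteration, `pool_size` random candidates are drawn (centre
#' = a random training row, radius = a random quantile of the
#' pairwise-distance sample); every candidate is scored by the residual sum
#' of squares of the full least-squares refit with that candidate appended;
#' the single best candidate is accepted permanently only if it lowers the
#' description length ([mdl_score()] with `k = p + 1 + 3m`, counting
#' weight, centre scale and radius of each term as three effective
#' parameters). Fitting stops after `patience` consecutive rejections or at
#' `max_terms`.
#'
#' @param Z n x p predictor matrix (standardize columns for mixed units;
#'   [fit_flock_model()] does this automatically).
#' @param y Length-n target vector.
#' @param cfg A [fit_config()].
#' @return An `rbf_coord_model` with fields `intercept`, `linear_weights`,
#'   `terms` (list of `weight`/`center`/`radius`), `mdl`, `sse`, `n_train`
#'   and an iteration `trace` tibble.
#' @export
fit_coordinate <- function(Z, y, cfg = fit_config()) {
  if (!is.null(cfg$seed)) {
    with_seed(cfg$seed, fit_coordinate_impl(Z, y, cfg))
  } else {
    fit_coordinate_impl(Z, y, cfg)
  }
}

fit_coordinate_impl <- function(Z, y, cfg) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  p <- ncol(Z)
  if (n < p + 2) abort("need at least p + 2 samples")

  # pairwise-distance sample for the radius distribution
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  pd <- as.vector(stats::dist(Z[idx, , drop = FALSE]))
  pd <- pd[pd > 0]
  if (!length(pd)) pd <- 1

  X <- cbind(1, Z)
  base <- ls_fit(X, y)
  k <- p + 1L
  cur_sse <- base$sse
  cur_mdl <- mdl_score(n, cur_sse, k)
  terms <- list()
  trace <- list(tibble::tibble(iter = 0L, m = 0L, sse = cur_sse,
                               mdl = cur_mdl, accepted = TRUE))
  coefs <- base$coef

  Zsq <- rowSums(Z^2)
  qx <- qr(X)
  res <- qr.resid(qx, y)
  rejections <- 0L
  iter <- 0L
  while (length(terms) < cfg$max_terms && rejections < cfg$patience) {
    iter <- iter + 1L
    centers <- Z[sample.int(n, cfg$pool_size, replace = TRUE), ,
                 drop = FALSE]
    radii <- quantile(pd, runif(cfg$pool_size, cfg$radius_quantiles[1],
                                cfg$radius_quantiles[2]), names = FALSE)
    radii[radii <= 0] <- min(pd)
    best <- NULL
    # score each candidate by the SSE of the full refit with it appended;
    # computed via the orthogonal complement, which gives the identical SSE
    for (s in seq_len(cfg$pool_size)) {
      cen <- centers[s, ]
      d2 <- pmax(Zsq - 2 * drop(Z %*% cen) + sum(cen^2), 0)
      phi <- exp(-d2 / (2 * radii[s]^2))
      phi_perp <- qr.resid(qx, phi)
      denom <- sum(phi_perp^2)
      if (denom < 1e-12) next
      gain <- sum(res * phi_perp)^2 / denom
      if (is.null(best) || gain > best$gain) {
        best <- list(gain = gain, center = cen, radius = radii[s],
                     phi = phi)
      }
    }
    if (is.null(best)) {
      rejections <- rejections + 1L
      next
    }
    new_sse <- cur_sse - best$gain
    new_k <- p + 1L + 3L * (length(terms) + 1L)
    new_mdl <- if (new_k < n) mdl_score(n, new_sse, new_k) else Inf
    accepted <- new_mdl < cur_mdl
    if (accepted) {
      X <- cbind(X, best$phi)
      full <- ls_fit(X, y)
      coefs <- full$coef
      cur_sse <- full$sse
      cur_mdl <- mdl_score(n, cur_sse, new_k)
      terms <- c(terms, list(list(weight = NA_real_, center = best$center,
                                  radius = best$radius)))
      qx <- qr(X)
      res <- qr.resid(qx, y)
      rejections <- 0L
    } else {
      rejections <- rejections + 1L
    }
    trace <- c(trace, list(tibble::tibble(
      iter = iter, m = length(terms), sse = cur_sse,
      mdl = if (accepted) cur_mdl else new_mdl, accepted = accepted)))
  }

  m <- length(terms)
  w <- unname(coefs)
  for (j in seq_len(m)) terms[[j]]$weight <- w[p + 1L + j]
  structure(list(intercept = w[1],
                 linear_weights = w[2:(p + 1L)],
                 terms = terms,
                 mdl = cur_mdl,
                 sse = cur_sse,
                 n_train = n,
                 trace = dplyr::bind_rows(trace)),
            class = "rbf_coord_model")
}

# evaluate one coordinate model on an n x p matrix (same units as training)
predict_coord <- function(cm, Z) {
  out <- cm$intercept + drop(Z %*% cm$linear_weights)
  for (tm in cm$terms) {
    out <- out + tm$weight * gaussian_rbf(Z, tm$center, tm$radius)
  }
  out
}

#' Fit a multi-coordinate flock model to an embedding
#'
#' Fits one [fit_coordinate()] model per target coordinate on the shared
#' predictor matrix of the embedding. Predictor columns are standardized
#' (centre/scale recorded in the model and inverted at prediction time) so
#' that metres and metres-per-interval columns share one radius scale.
#' Coordinate fits use seeds derived from `cfg$seed`, making the whole
#' model reproducible.
#'
#' @param ds A `flock_embedding` (see [embed_r1()]).
#' @param cfg A [fit_config()].
#' @return A `flock_model` holding the per-coordinate models plus scheme,
#'   `M`, `D`, `dt` and standardization metadata.
#' @export
fit_flock_model <- function(ds, cfg = fit_config()) {
  Z <- embedding_Z(ds)
  Y <- embedding_Y(ds)
  center <- colMeans(Z)
  scale <- apply(Z, 2, sd)
  scale[scale < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, center), 2, scale, "/")
  q <- ncol(Y)
  seeds <- if (is.null(cfg$seed)) vector("list", q)
           else as.list(derive_seeds(cfg$seed, q, stride = 7919L))
  coords <- purrr::map(seq_len(q), function(j) {
    cj <- cfg
    cj$seed <- seeds[[j]]
    fit_coordinate(Zs, Y[, j], cj)
  })
  names(coords) <- colnames(Y)
  structure(list(scheme = attr(ds, "scheme"),
                 M = attr(ds, "M"),
                 D = attr(ds, "D"),
                 dt = attr(ds, "dt"),
                 center = center,
                 scale = scale,
                 coords = coords,
                 seed = cfg$seed,
                 config = cfg[c("pool_size", "max_terms", "patience",
                                "radius_quantiles")]),
            class = "flock_model")
}

#' @export
print.flock_model <- function(x, ...) {
  nt <- sum(vapply(x$coords, function(c) length(c$terms), integer(1)))
  cat(sprintf(
    "# flock_model: scheme %s, M = %d, D = %d, %d coordinate fits, %d RBF terms\n",
    x$scheme, x$M, x$D, length(x$coords), nt))
  invisible(x)
}

#' Predict next-step outputs of a flock model
#'
#' Evaluates the fitted per-coordinate functions on embedding vectors in
#' original units. For R1/R2 models the output is the predicted next
#' displacement; for A models the predicted next absolute position.
#'
#' @param object A `flock_model`.
#' @param z A p-vector or n x p matrix of embedding predictors.
#' @param ... Unused.
#' @return An n x q matrix (or q-vector for vector input).
#' @export
predict.flock_model <- function(object, z, ...) {
  vec <- !is.matrix(z)
  z <- rbind(z)
  if (ncol(z) != length(object$center)) {
    abort("embedding dimension does not match the model")
  }
  zs <- sweep(sweep(z, 2, object$center), 2, object$scale, "/")
  out <- vapply(object$coords, predict_coord, numeric(nrow(zs)), Z = zs)
  out <- rbind(out)
  if (vec) drop(out) else out
}

#' Fit replicate models with distinct seeds
#'
#' The candidate pools are random, so repeated fits yield different models;
#' replicate fitting plus downstream selection by behaviour is the standard
#' workflow. Replicate `r` uses seed `cfg$seed + r - 1`.
#'
#' @inheritParams fit_flock_model
#' @param R Number of replicates.
#' @return A list of `flock_model`s.
#' @export
fit_replicates <- function(ds, cfg = fit_config(), R = 5L) {
  if (R < 1) abort("R must be >= 1")
  base_seed <- cfg$seed %||% sample.int(1e6, 1)
  purrr::map(seq_len(R), function(r) {
    cr <- cfg
    cr$seed <- (base_seed + r - 1L) %% .Machine$integer.max
    fit_flock_model(ds, cr)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summaries of a fitted flock model
#'
#' `tidy()` returns one row per model term (affine terms and RBF terms) per
#' output coordinate; `glance()` returns one row of whole-model summaries.
#'
#' @param x A `flock_model`.
#' @param ... Unused.
#' @export
tidy.flock_model <- function(x, ...) {
  purrr::imap_dfr(x$coords, function(cm, nm) {
    aff <- tibble::tibble(
      coordinate = nm,
      term = c("(Intercept)", names(x$center)),
      type = c("intercept", rep("linear", length(cm$linear_weights))),
      weight = c(cm$intercept, cm$linear_weights),
      radius = NA_real_)
    if (length(cm$terms)) {
      rbf <- tibble::tibble(
        coordinate = nm,
        term = sprintf("rbf%d", seq_along(cm$terms)),
        type = "rbf",
        weight = vapply(cm$terms, `[[`, numeric(1), "weight"),
        radius = vapply(cm$terms, `[[`, numeric(1), "radius"))
      dplyr::bind_rows(aff, rbf)
    } else {
      aff
    }
  })
}

#' @rdname tidy.flock_model
#' @export
glance.flock_model <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    M = x$M,
    D = x$D,
    dt = x$dt,
    n_terms = sum(vapply(x$coords, function(c) length(c$terms), integer(1))),
    sse = sum(vapply(x$coords, `[[`, numeric(1), "sse")),
    mdl = sum(vapply(x$coords, `[[`, numeric(1), "mdl")),
    n_train = x$coords[[1]]$n_train)
}

#' Serialize a flock model to JSON
#'
#' The JSON document holds scheme, `M`, `D`, `dt`, the standardization
#' vectors and every coordinate model (intercept, linear weights, RBF
#' terms, score, residuals, sample count) at full double precision, so a
#' round trip reproduces predictions exactly.
#'
#' @param model A `flock_model`.
#' @param path Output file path.
#' @return `write_flock_model()` invisibly returns `path`;
#'   `read_flock_model()` returns the `flock_model`.
#' @export
write_flock_model <- function(model, path) {
  doc <- list(
    scheme = model$scheme, M = model$M, D = model$D, dt = model$dt,
    center = model$center, scale = model$scale, seed = model$seed,
    config = model$config,
    coords = purrr::map(model$coords, function(cm) {
      list(intercept = cm$intercept,
           linear_weights = cm$linear_weights,
           terms = purrr::map(cm$terms, function(tm) {
             list(weight = tm$weight, center = tm$center,
                  radius = tm$radius)
           }),
           mdl = cm$mdl, sse = cm$sse, n_train = cm$n_train)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_flock_model
#' @export
read_flock_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  coords <- purrr::map(doc$coords, function(cm) {
    structure(list(intercept = cm$intercept,
                   linear_weights = as.numeric(cm$linear_weights),
                   terms = purrr::map(cm$terms, function(tm) {
                     list(weight = tm$weight,
                          center = as.numeric(tm$center),
                          radius = tm$radius)
                   }),
                   mdl = cm$mdl, sse = cm$sse,
                   n_train = as.integer(cm$n_train),
                   trace = NULL),
              class = "rbf_coord_model")
  })
  structure(list(scheme = doc$scheme, M = as.integer(doc$M),
                 D = as.integer(doc$D), dt = doc$dt,
                 center = setNames(as.numeric(doc$center),
                                   names(doc$center)),
                 scale = setNames(as.numeric(doc$scale), names(doc$scale)),
                 coords = coords,
                 seed = doc$seed,
                 config = doc$config),
            class = "flock_model")
}
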