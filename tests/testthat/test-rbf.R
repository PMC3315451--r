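test_that("gaussian_rbf matches its closed form and is bounded", {
  expect_equal(gaussian_rbf(c(0, 0), c(0, 0), 1), 1)
  expect_equal(gaussian_rbf(c(1, 0), c(0, 0), 1), exp(-0.5),
               tolerance = 1e-15)
  expect_equal(gaussian_rbf(c(3, 4), c(0, 0), 2), exp(-25 / 8),
               tolerance = 1e-12)
  set.seed(1)
  Z <- matrix(rnorm(40), 10, 4)
  cen <- rnorm(4)
  got <- gaussian_rbf(Z, cen, 1.7)
  want <- apply(Z, 1, function(z) exp(-sum((z - cen)^2) / (2 * 1.7^2)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got > 0 & got <= 1))
  expect_error(gaussian_rbf(c(0, 0), c(0, 0), 0), "positive")
})

test_that("mdl_score matches its formula and penalizes parameters", {
  expect_equal(mdl_score(100, 50, 5),
               50 * log(0.5) + 2.5 * log(100), tolerance = 1e-12)
  expect_lt(mdl_score(100, 50, 5), mdl_score(100, 50, 8))
  expect_lt(mdl_score(100, 10, 5), mdl_score(100, 50, 5))
  expect_true(is.finite(mdl_score(100, 0, 5)))  # floored, not -Inf
  expect_error(mdl_score(10, 5, 10), "over-parameterized")
  expect_error(mdl_score(10, -1, 2), "non-negative")
})

test_that("affine base fit matches the normal-equations oracle", {
  set.seed(3)
  Z <- matrix(rnorm(200), 50, 4)
  y <- 2 + Z %*% c(1, -2, 0.5, 3) + rnorm(50, sd = 0.3)
  cm <- fit_coordinate(Z, drop(y),
                       fit_config(pool_size = 5, max_terms = 0, seed = 1))
  X <- cbind(1, Z)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(c(cm$intercept, cm$linear_weights), drop(beta),
               tolerance = 1e-8)
  expect_equal(cm$sse, sum((y - X %*% beta)^2), tolerance = 1e-8)
  expect_length(cm$terms, 0)
})

test_that("a planted linear law is recovered with zero RBF terms", {
  set.seed(4)
  Z <- matrix(rnorm(600), 200, 3)
  y <- drop(0.7 + Z %*% c(2, -1, 0.25))          # exactly linear, no noise
  cm <- fit_coordinate(Z, y, fit_config(pool_size = 20, seed = 11))
  expect_length(cm$terms, 0)
  expect_lt(max(abs(c(cm$intercept, cm$linear_weights) -
                      c(0.7, 2, -1, 0.25))), 1e-6)
  expect_equal(predict_coord_oracle(cm, Z), y, tolerance = 1e-6)

  # constant target: intercept only
  cc <- fit_coordinate(Z, rep(3.25, 200),
                       fit_config(pool_size = 10, seed = 5))
  expect_length(cc$terms, 0)
  expect_equal(cc$intercept, 3.25, tolerance = 1e-8)
  expect_lt(max(abs(cc$linear_weights)), 1e-8)
})

test_that("a planted linear-plus-Gaussian-bump law is fitted well", {
  set.seed(6)
  Z <- matrix(runif(1200, -2, 2), 600, 2)
  truth <- function(Z) {
    drop(Z %*% c(1, -0.5)) +
      3 * gaussian_rbf(Z, c(0.5, -0.5), 0.6) -
      2 * gaussian_rbf(Z, c(-1, 1), 0.8)
  }
  y <- truth(Z) + rnorm(600, sd = 0.05)
  cm <- fit_coordinate(Z, y, fit_config(pool_size = 60, seed = 21))
  expect_gt(length(cm$terms), 0)
  rmse <- sqrt(mean((predict_coord_oracle(cm, Z) - truth(Z))^2))
  expect_lt(rmse, 0.1)
  # the accepted trace is monotone decreasing in MDL
  tr <- dplyr::filter(cm$trace, accepted)
  expect_true(all(diff(tr$mdl) < 0))
})

test_that("fits are deterministic given a seed and vary across seeds", {
  set.seed(8)
  Z <- matrix(runif(300, -1, 1), 150, 2)
  y <- sin(2 * Z[, 1]) + rnorm(150, sd = 0.1)
  a <- fit_coordinate(Z, y, fit_config(pool_size = 15, seed = 7))
  b <- fit_coordinate(Z, y, fit_config(pool_size = 15, seed = 7))
  expect_identical(a[names(a) != "trace"], b[names(b) != "trace"])
  expect_identical(a$trace, b$trace)
  # seeded fitting does not disturb the global RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(fit_coordinate(Z, y, fit_config(seed = 7)))
  expect_identical(runif(3), before)
})

test_that("fit_flock_model standardizes, predicts and round-trips JSON", {
  tr <- simulate_vicsek(vicsek_params(10, 5, 0.03, 0.4, 3), T = 40,
                        seed = 2)
  ds <- embed_r1(tr, M = 3)
  m <- fit_flock_model(ds, fit_config(pool_size = 10, max_terms = 5,
                                      seed = 31))
  expect_s3_class(m, "flock_model")
  expect_identical(m$scheme, "R1")
  expect_identical(names(m$coords), c("y_x", "y_y"))

  Z <- embedding_Z(ds)
  pred <- predict(m, Z)
  expect_equal(dim(pred), c(nrow(Z), 2))
  # single-row vector input agrees with matrix input
  expect_equal(predict(m, Z[5, ]), pred[5, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # standardization is invertible: manual evaluation matches predict()
  zs <- sweep(sweep(Z, 2, m$center), 2, m$scale, "/")
  manual <- vapply(m$coords, predict_coord_oracle, numeric(nrow(zs)),
                   Z = zs)
  expect_equal(unname(pred), unname(manual), tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_flock_model(m, path)
  m2 <- read_flock_model(path)
  expect_equal(predict(m2, Z), pred, tolerance = 0)  # lossless round trip
  expect_identical(m2$scheme, m$scheme)
  expect_identical(m2$M, m$M)

  expect_error(predict(m, Z[, 1, drop = FALSE]), "dimension")
})

test_that("replicates differ by seed and tidy/glance summarize the model", {
  tr <- simulate_vicsek(vicsek_params(8, 5, 0.03, 0.5, 2), T = 30, seed = 3)
  ds <- embed_r1(tr, M = 2)
  reps <- fit_replicates(ds, fit_config(pool_size = 8, max_terms = 4,
                                        seed = 100), R = 3)
  expect_length(reps, 3)
  expect_identical(vapply(reps, `[[`, numeric(1), "seed"),
                   c(100, 101, 102))

  td <- tidy(reps[[1]])
  expect_true(all(c("coordinate", "term", "type", "weight") %in%
                    names(td)))
  expect_equal(sum(td$type == "intercept"), 2)
  gl <- glance(reps[[1]])
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_train, nrow(ds))
  expect_equal(gl$n_terms,
               sum(td$type == "rbf"))
})
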