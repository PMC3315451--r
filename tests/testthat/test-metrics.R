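test_that("separation measures match hand values and the brute oracle", {
  # 3 collinear agents: centroid at x = 5/3
  arr <- array(0, c(1, 3, 2))
  arr[1, , 1] <- c(0, 1, 4)
  tr <- traj_of(arr)
  s <- separation_series(tr, M = 1)
  expect_equal(s$d_global, mean(abs(c(0, 1, 4) - 5 / 3)),
               tolerance = 1e-12)
  # local, M = 1: neighbourhood centroids at 0.5, 0.5, 2.5
  expect_equal(s$d_local, mean(c(0.5, 0.5, 1.5)), tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:5) {
    N <- sample(4:12, 1)
    pos <- matrix(rnorm(2 * N, sd = 20), N, 2)
    a <- array(0, c(1, N, 2)); a[1, , ] <- pos
    M <- sample(1:(N - 1), 1)
    got <- separation_series(traj_of(a), M = M)
    want <- oracle_separations(pos, M)
    expect_equal(got$d_global, want$d_global, tolerance = 1e-12)
    expect_equal(got$d_local, want$d_local, tolerance = 1e-12)
    # self-inclusive local centroid: M = N - 1 collapses to global
    full <- separation_series(traj_of(a), M = N - 1)
    expect_equal(full$d_local, full$d_global, tolerance = 1e-12)
  }
})

test_that("ensemble_mean averages pointwise and validates inputs", {
  tr1 <- random_traj(N = 4, T = 6, seed = 1)
  tr2 <- random_traj(N = 4, T = 6, seed = 2)
  s1 <- separation_series(tr1, M = 2)
  s2 <- separation_series(tr2, M = 2)
  em <- ensemble_mean(list(s1, s2))
  expect_equal(em$d_global, (s1$d_global + s2$d_global) / 2,
               tolerance = 1e-12)
  expect_equal(em$d_local, (s1$d_local + s2$d_local) / 2,
               tolerance = 1e-12)
  s3 <- separation_series(random_traj(N = 4, T = 5, seed = 3), M = 2)
  expect_error(ensemble_mean(list(s1, s3)), "lengths differ")
})

test_that("selection_score is the mean absolute d_global gap", {
  mk <- function(dg) flockfit:::new_separation_series(
    tibble::tibble(t = seq_along(dg) - 1L, time = seq_along(dg) - 1,
                   d_global = dg, d_local = dg), M = 1L, dt = 1)
  expect_equal(selection_score(mk(c(1, 2, 3)), mk(c(2, 2, 5))),
               mean(c(1, 0, 2)), tolerance = 1e-12)
  expect_equal(selection_score(mk(c(1, 2)), mk(c(1, 2))), 0)
  expect_error(selection_score(mk(1:3), mk(1:4)), "lengths differ")
})

test_that("select_best_model ranks hand models by behaviour", {
  frozen <- hand_a_model(D = 2, scale_fac = 1)     # x(t+1) = x(t)
  expanding <- hand_a_model(D = 2, scale_fac = 1.5)
  x0 <- rbind(c(0, 0), c(10, 0), c(0, 10))
  ic <- initial_conditions(x0, x0)
  ref <- separation_series(rollout(frozen, ic, T = 8), M = 1)

  out <- select_best_model(list(frozen, expanding), list(ic), T = 8,
                           M = 1, reference = ref, criterion = "mae")
  expect_equal(out$index, 1)
  expect_equal(out$scores$score[1], 0, tolerance = 1e-12)
  out2 <- select_best_model(list(expanding, frozen), list(ic), T = 8,
                            M = 1, reference = ref, criterion = "mae")
  expect_equal(out2$index, 2)

  # cohesion: the frozen flock has the smaller time-mean d_global
  out3 <- select_best_model(list(expanding, frozen), list(ic), T = 8,
                            M = 1, criterion = "cohesion")
  expect_equal(out3$index, 2)
  expect_error(select_best_model(list(frozen), list(ic), T = 8, M = 1,
                                 criterion = "mae"),
               "reference")
})

test_that("optimal_m_table returns one scored row per candidate M", {
  tr <- simulate_vicsek(vicsek_params(8, 5, 0.03, 0.4, 3), T = 25, seed = 6)
  tab <- optimal_m_table(tr, m_values = c(0, 2), R = 2,
                         cfg = fit_config(pool_size = 5, max_terms = 2,
                                          seed = 50))
  expect_identical(names(tab), c("M", "mean_mae", "scores"))
  expect_equal(tab$M, c(0, 2))
  expect_true(all(is.finite(tab$mean_mae)))
  expect_true(all(lengths(tab$scores) == 2))
  expect_equal(tab$mean_mae, vapply(tab$scores, mean, numeric(1)),
               tolerance = 1e-12)
  expect_error(optimal_m_table(tr, m_values = 9), "0..N-1")
})

test_that("attraction and speed curves match a hand-built separating pair", {
  # two agents receding symmetrically: separation 30, 32, 34, ... metres
  T <- 30
  arr <- array(0, c(T, 2, 2))
  arr[, 1, 1] <- -(15 + seq_len(T) - 1)
  arr[, 2, 1] <- +(15 + seq_len(T) - 1)
  tr <- traj_of(arr)
  cur <- attraction_speed_curves(tr, M = 1, bin_width = 10, min_count = 2)
  ds <- cur$delta_separation
  expect_s3_class(ds, "rule_curve")
  expect_equal(sum(ds$count), 2 * (T - 1))     # every sample lands in a bin
  nonempty <- dplyr::filter(ds, count > 0)
  # separation always grows by exactly 2 m per interval
  expect_equal(nonempty$mean, rep(2, nrow(nonempty)), tolerance = 1e-12)
  expect_true(all(nonempty$se == 0 | is.na(nonempty$se) |
                    nonempty$se < 1e-12))
  # bin edges are multiples of the width and samples sit where expected
  expect_true(all(ds$bin_lo %% 10 == 0))
  first <- dplyr::filter(ds, count > 0)$bin_lo[1]
  expect_equal(first, 30)                      # first predictor D = 30 m
  sp <- cur$speed
  ne_sp <- dplyr::filter(sp, count > 0)
  expect_equal(ne_sp$mean, rep(1, nrow(ne_sp)), tolerance = 1e-12)
  # empty flag honours min_count
  expect_true(all(ds$empty[ds$count < 2]))
})

test_that("alignment curve is the identity for a noiseless Vicsek flock", {
  tr <- simulate_vicsek(vicsek_params(20, 3, 0.05, 0, 3), T = 60, seed = 14)
  cur <- alignment_rule_curve(tr, M = 3, n_bins = 36)
  expect_equal(nrow(cur), 36)
  used <- dplyr::filter(cur, count > 0)
  expect_gt(nrow(used), 0)
  dev <- abs(flockfit:::circ_diff(used$mean, used$bin_mid))
  expect_lt(max(dev), pi / 36 + 1e-6)          # within half a bin width

  # heading pi is handled without wrap-around averaging artefacts
  Tn <- 10
  arr <- array(0, c(Tn, 3, 2))
  for (i in 1:3) arr[, i, 1] <- -(seq_len(Tn)) ; arr[, , 2] <- 0
  arr[, 2, 2] <- 1; arr[, 3, 2] <- 2
  cpi <- alignment_rule_curve(traj_of(arr), M = 1, n_bins = 36)
  hot <- dplyr::filter(cpi, count > 0)
  expect_equal(nrow(hot), 1)
  expect_lt(abs(flockfit:::circ_diff(hot$mean, pi)), 1e-9)

  # a stationary flock yields no usable samples at all
  still <- traj_of(array(1, c(8, 6, 2)) *
                     rep(1:6, each = 8))       # distinct fixed positions
  cst <- alignment_rule_curve(still, M = 2)
  expect_true(all(cst$count == 0))
})
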