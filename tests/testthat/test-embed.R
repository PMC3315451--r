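test_that("topological kNN sorts by distance with index tie-breaking", {
  p <- rbind(c(0, 0), c(1, 0), c(3, 0), c(-1, 0))
  expect_identical(knn_topological(p, i = 1, M = 2), c(2L, 4L))
  expect_identical(knn_topological(p, i = 1, M = 3), c(2L, 4L, 3L))
  expect_identical(knn_topological(p, i = 1, M = 1, include_self = TRUE), 1L)
  expect_identical(knn_topological(p, i = 1, M = 0), integer(0))
  # exact tie: agents 2 and 4 both at distance 1 from agent 1
  expect_identical(knn_topological(p, i = 1, M = 1), 2L)
  expect_error(knn_topological(p, i = 1, M = 4), "M must be")
})

# shared hand fixture: N = 3 agents, T = 3 frames, 2D
hand_arr <- function() {
  arr <- array(NA_real_, c(3, 3, 2))
  arr[1, , ] <- rbind(c(0, 0), c(1, 0), c(4, 0))
  arr[2, , ] <- rbind(c(0, 1), c(1, 1), c(4, 2))
  arr[3, , ] <- rbind(c(1, 1), c(2, 1), c(4, 3))
  arr
}

test_that("R1 embedding matches the hand example", {
  ds <- embed_r1(traj_of(hand_arr()), M = 1)
  expect_s3_class(ds, "flock_embedding")
  expect_equal(nrow(ds), 3)                       # N * (T - 2)
  expect_identical(colnames(embedding_Z(ds)),
                   c("nbhd_disp_x", "nbhd_disp_y"))
  # disp(t=2): a=(0,1) b=(0,1) c=(0,2); 1-NN of a,b is each other, of c is b
  expect_equal(unname(embedding_Z(ds)),
               rbind(c(0, 1), c(0, 1), c(0, 1.5)), tolerance = 1e-12)
  expect_equal(unname(embedding_Y(ds)),
               rbind(c(1, 0), c(1, 0), c(0, 1)), tolerance = 1e-12)
  expect_equal(ds$time, rep(1, 3))
  expect_equal(attr(ds, "M"), 1L)
})

test_that("A embedding matches the hand example and M = 0 drops neighbours", {
  ds <- embed_a(traj_of(hand_arr()), M = 1)
  expect_equal(ncol(embedding_Z(ds)), 8)          # 4 * D in 2D
  # row for agent a: pos_t, pos_tm1, nbr(b) pos_t, nbr(b) pos_tm1
  expect_equal(unname(embedding_Z(ds)[1, ]),
               c(0, 1, 0, 0, 1, 1, 1, 0), tolerance = 1e-12)
  # target is the absolute next position, not a displacement
  expect_equal(unname(embedding_Y(ds)[1, ]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(embedding_Y(ds)[3, ]), c(4, 3), tolerance = 1e-12)

  ds0 <- embed_a(traj_of(hand_arr()), M = 0)
  expect_equal(ncol(embedding_Z(ds0)), 4)         # 2 * D
  expect_identical(colnames(embedding_Z(ds0)),
                   c("self_t_x", "self_t_y", "self_tm1_x", "self_tm1_y"))

  tr3 <- random_traj(N = 5, T = 6, D = 3, seed = 2)
  expect_equal(ncol(embedding_Z(embed_a(tr3, M = 2))), 12)
})

test_that("R2 embedding matches the hand example and has 3D blocks", {
  ds <- embed_r2(traj_of(hand_arr()), M = 1)
  expect_equal(ncol(embedding_Z(ds)), 6)          # 3 * D in 2D
  # agent c: own disp (0,2); nbr b disp (0,1); offset b - c = (-3,-1)
  expect_equal(unname(embedding_Z(ds)[3, ]),
               c(0, 2, 0, 1, -3, -1), tolerance = 1e-12)
  expect_equal(unname(embedding_Y(ds)[3, ]), c(0, 1), tolerance = 1e-12)

  tr3 <- random_traj(N = 6, T = 7, D = 3, seed = 4)
  ds3 <- embed_r2(tr3, M = 2)
  expect_equal(ncol(embedding_Z(ds3)), 9)
  expect_equal(nrow(ds3), 6 * 5)
  expect_error(embed_r2(tr3, M = 0), "M must be")
})

test_that("R1 and R2 predictors are translation invariant, A is equivariant", {
  tr <- random_traj(N = 5, T = 8, seed = 6)
  arr <- flockfit:::traj_array(tr)
  shift <- c(250, -90)
  arr_s <- arr
  arr_s[, , 1] <- arr[, , 1] + shift[1]
  arr_s[, , 2] <- arr[, , 2] + shift[2]
  tr_s <- traj_of(arr_s)

  for (f in list(function(x) embed_r1(x, 2), function(x) embed_r2(x, 2))) {
    expect_equal(embedding_Z(f(tr_s)), embedding_Z(f(tr)), tolerance = 1e-9)
    expect_equal(embedding_Y(f(tr_s)), embedding_Y(f(tr)), tolerance = 1e-9)
  }

  za <- embedding_Z(embed_a(tr, 2))
  za_s <- embedding_Z(embed_a(tr_s, 2))
  expect_equal(za_s, za + matrix(rep(shift, 4), nrow(za), 8, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("R1 embedding is rotation equivariant", {
  tr <- random_traj(N = 5, T = 8, seed = 13)
  arr <- flockfit:::traj_array(tr)
  a <- 0.61
  Rm <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  arr_r <- arr
  for (t in seq_len(dim(arr)[1])) arr_r[t, , ] <- arr[t, , ] %*% t(Rm)
  z <- embedding_Z(embed_r1(tr, 2))
  z_r <- embedding_Z(embed_r1(traj_of(arr_r), 2))
  expect_equal(z_r, z %*% t(Rm), tolerance = 1e-9,
               ignore_attr = "dimnames")
  y <- embedding_Y(embed_r1(tr, 2))
  y_r <- embedding_Y(embed_r1(traj_of(arr_r), 2))
  expect_equal(y_r, y %*% t(Rm), tolerance = 1e-9,
               ignore_attr = "dimnames")
})

test_that("combine_embeddings stacks flights and rejects mismatches", {
  a <- embed_r2(random_traj(N = 4, T = 6, seed = 1), M = 2)
  b <- embed_r2(random_traj(N = 3, T = 5, seed = 2), M = 2)
  both <- combine_embeddings(a, b)
  expect_equal(nrow(both), nrow(a) + nrow(b))
  expect_identical(sort(unique(both$flight)), c("f1", "f2"))
  expect_identical(attr(both, "scheme"), "R2")
  expect_error(
    combine_embeddings(a, embed_r2(random_traj(N = 4, T = 6, seed = 3),
                                   M = 3)),
    "differ")
})

test_that("rotate_debias stratifies target headings and preserves geometry", {
  ds <- embed_r2(random_traj(N = 6, T = 20, seed = 21), M = 3)
  out <- rotate_debias(ds)
  n <- nrow(out)
  Y0 <- embedding_Y(ds); Y1 <- embedding_Y(out)
  Z0 <- embedding_Z(ds); Z1 <- embedding_Z(out)

  # headings hit the deterministic grid -pi + 2*pi*k/n exactly
  got <- sort(atan2(Y1[, 2], Y1[, 1]))
  want <- sort(flockfit:::wrap_angle(-pi + 2 * pi * seq_len(n) / n))
  expect_equal(got, want, tolerance = 1e-9)

  # norms of every x-y pair are preserved
  expect_equal(sqrt(Y1[, 1]^2 + Y1[, 2]^2), sqrt(Y0[, 1]^2 + Y0[, 2]^2),
               tolerance = 1e-12)
  for (b in 0:2) {
    expect_equal(sqrt(Z1[, 2 * b + 1]^2 + Z1[, 2 * b + 2]^2),
                 sqrt(Z0[, 2 * b + 1]^2 + Z0[, 2 * b + 2]^2),
                 tolerance = 1e-12)
  }
  # relative angle between own displacement and target is preserved
  rel0 <- flockfit:::wrap_angle(atan2(Y0[, 2], Y0[, 1]) -
                                  atan2(Z0[, 2], Z0[, 1]))
  rel1 <- flockfit:::wrap_angle(atan2(Y1[, 2], Y1[, 1]) -
                                  atan2(Z1[, 2], Z1[, 1]))
  expect_equal(rel1, rel0, tolerance = 1e-9)

  # 3D: altitude columns untouched
  ds3 <- embed_r2(random_traj(N = 4, T = 10, D = 3, seed = 22), M = 2)
  out3 <- rotate_debias(ds3)
  expect_identical(out3$self_disp_z, ds3$self_disp_z)
  expect_identical(out3$nbrs_offset_z, ds3$nbrs_offset_z)
  expect_identical(out3$y_z, ds3$y_z)

  expect_error(rotate_debias(embed_a(random_traj(seed = 1), 2)),
               "R2")
  expect_error(rotate_debias(embed_r1(random_traj(seed = 1), 2)),
               "R2")
})
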