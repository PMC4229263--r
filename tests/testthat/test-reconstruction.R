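test_that("two orthogonal noiseless cameras triangulate exactly", {
  cam1 <- camera_model(c(0, 0, 1600))              # looks down -Z
  cam2 <- camera_model(c(1600, 0, 0))              # looks down -X
  X <- c(10, 20, 800)
  # X is at depth 800 from cam1 and 1590 from cam2; both in front
  uv <- rbind(unlist(project(cam1, X)[1, c("u", "v")]),
              unlist(project(cam2, X)[1, c("u", "v")]))
  tri <- triangulate(list(camera_matrix(cam1), camera_matrix(cam2)), uv)
  expect_equal(tri$point, X, tolerance = 1e-9)
  expect_lt(tri$residual_px, 1e-9)
  expect_error(triangulate(list(camera_matrix(cam1)), uv[1, , drop = FALSE]),
               "fewer than 2")
})

test_that("six-view DLT triangulation equals the reprojection-minimizing oracle", {
  P <- facemotion3d:::rig_matrices(fx_rig)
  set.seed(21)
  for (i in 1:10) {
    X <- runif(3, -150, 150)
    uv <- t(vapply(fx_rig$cameras, function(cam)
      unlist(project(cam, X)[1, c("u", "v")]), numeric(2)))
    tri <- triangulate(P, uv)
    oracle <- triangulate_gn(P, uv, init = X + rnorm(3))
    expect_equal(tri$point, oracle, tolerance = 1e-9)
  }
})

test_that("the noiseless linear rod reconstructs to 176.84 mm every frame", {
  sess <- simulate_rod_session(fx_rig, rod_linear(), "static", 2,
                               sigma_px = 0, seed = 31)
  traj <- reconstruct(sess, fx_cal0)
  per <- measure_rod_session(traj, rod_linear())
  expect_equal(nrow(per), 200L)
  expect_lt(max(abs(per$value - 176.84)), 1e-6)
})

test_that("labelling tracks a static scene into complete trajectories", {
  # synthetic clouds from a noiseless static rod: strip labels
  sess <- simulate_rod_session(fx_rig, rod_linear(), "static", 5,
                               sigma_px = 0, seed = 32)
  traj <- reconstruct(sess, fx_cal0)
  clouds <- lapply(sort(unique(traj$frame)), function(f) {
    d <- traj[traj$frame == f & !traj$gap, ]
    list(frame = f, points = as.matrix(d[, c("x", "y", "z")]),
         n_cameras = d$n_cameras)
  })
  template <- as.matrix(traj[traj$frame == 1, c("x", "y", "z")])
  rownames(template) <- c("R1", "R2")
  out <- label_and_track(clouds, template)
  expect_equal(sum(out$gap), 0L)
  expect_equal(nrow(out), 1000L)
  d1 <- out[out$label == "R1", ]
  expect_equal(unname(as.matrix(d1[, c("x", "y", "z")])[1, ]),
               unname(template["R1", ]))
})

test_that("a dropped frame becomes a gap and the marker is re-acquired", {
  frames <- 1:20
  pts <- cbind(frames * 2, 0, 0)  # 200 mm/s along x, within the gate
  clouds <- lapply(frames, function(f) {
    if (f == 10) list(frame = f, points = matrix(numeric(0), 0, 3))
    else list(frame = f, points = pts[f, , drop = FALSE])
  })
  template <- matrix(pts[1, ], 1, 3, dimnames = list("M", NULL))
  out <- label_and_track(clouds, template)
  expect_true(out$gap[out$frame == 10])
  expect_false(any(out$gap[out$frame != 10]))
  expect_equal(out$x[out$frame == 20], 40)
})

test_that("labelling is permutation-safe and matches optimal assignment", {
  rest <- face_points(fx_face)[1:6, ]
  clouds <- list(list(frame = 1, points = rest))
  drift <- rest + matrix(rnorm(18, sd = 0.5), 6, 3)
  clouds[[2]] <- list(frame = 2, points = drift[c(3, 1, 6, 2, 4, 5), ])
  out1 <- label_and_track(clouds, rest)
  # shuffling cloud point order must not change the result
  clouds2 <- clouds
  clouds2[[2]]$points <- drift[c(6, 5, 4, 3, 2, 1), ]
  out2 <- label_and_track(clouds2, rest)
  expect_equal(out1[order(out1$frame, out1$label), c("label", "x", "y", "z")],
               out2[order(out2$frame, out2$label), c("label", "x", "y", "z")],
               ignore_attr = TRUE)
  # frame-2 assignment equals the brute-force minimum-total-distance match
  D <- outer(1:6, 1:6, Vectorize(function(i, j)
    dist3(rest[i, ], clouds[[2]]$points[j, ])))
  best <- brute_assignment(D)
  got <- out1[out1$frame == 2, ]
  for (i in 1:6)
    expect_equal(unname(unlist(got[got$label == rownames(rest)[i],
                                   c("x", "y", "z")])),
                 unname(clouds[[2]]$points[best[i], ]))
})

test_that("ambiguous initial labelling is an error listing offenders", {
  tmpl <- rbind(A = c(0, 0, 0), B = c(1, 0, 0))
  clouds <- list(list(frame = 1, points = rbind(c(0.4, 0, 0), c(50, 0, 0))))
  expect_error(label_and_track(clouds, tmpl), "ambiguous")
})

test_that("gap filling interpolates short interior gaps only", {
  n <- 30
  traj <- data.frame(frame = 1:n, time_s = (1:n - 1) / 100, label = "M",
                     x = (1:n) * 1.5, y = 3, z = -2, n_cameras = 6L,
                     gap = FALSE, residual_px = 0)
  expect_equal(fill_gaps(traj)[, names(traj)], traj)  # no gaps: identity
  g <- traj
  g[14:16, c("x", "y", "z")] <- NA
  g$gap[14:16] <- TRUE
  filled <- fill_gaps(g)
  expect_false(any(filled$gap))
  expect_equal(filled$x[14:16], c(21, 22.5, 24), tolerance = 1e-9)
  # long gaps stay; edge gaps are refused (no extrapolation)
  g2 <- traj
  g2$gap[5:20] <- TRUE
  g2[5:20, c("x", "y", "z")] <- NA
  expect_equal(sum(fill_gaps(g2, max_gap_frames = 10)$gap), 16L)
  g3 <- traj
  g3$gap[1:2] <- TRUE
  g3[1:2, c("x", "y", "z")] <- NA
  expect_equal(sum(fill_gaps(g3)$gap), 2L)
})

test_that("rigid-pair distance spread shrinks as noise goes to zero", {
  spread <- vapply(c(1, 0.25, 0), function(sg) {
    sess <- simulate_rod_session(fx_rig, rod_linear(), "static", 1,
                                 sigma_px = sg, seed = 55)
    traj <- reconstruct(sess, fx_cal0)
    sd(measure_rod_session(traj, rod_linear())$value)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[3], 1e-9)
})

test_that("default-noise face reconstruction recovers truth under 0.5 mm RMS", {
  sess <- simulate_expression_session(fx_face, fx_rig,
                                      default_schedule(1, rest_s = 0.3),
                                      sigma_px = 0.5, seed = 60)
  traj <- reconstruct(sess, fx_cal05)
  expect_equal(sum(traj$gap), 0L)
  err <- cbind(traj$x - sess$truth$x, traj$y - sess$truth$y,
               traj$z - sess$truth$z)
  expect_lt(sqrt(mean(rowSums(err^2))), 0.5)
})
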