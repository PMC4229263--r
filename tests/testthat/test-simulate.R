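test_that("pinhole projection matches the homogeneous-matrix oracle", {
  cam <- fx_rig$cameras[[2]]
  # optical-axis point lands on the principal point
  axis_pt <- cam$center + 500 * cam$R[3, ]
  pr <- project(cam, axis_pt)
  expect_equal(c(pr$u, pr$v), cam$principal, tolerance = 1e-9)
  # doubling depth halves the offset from the principal point
  off <- 30 * cam$R[1, ] + 20 * cam$R[2, ]
  p1 <- project(cam, cam$center + 400 * cam$R[3, ] + off)
  p2 <- project(cam, cam$center + 800 * cam$R[3, ] + off)
  expect_equal((c(p1$u, p1$v) - cam$principal) / 2,
               c(p2$u, p2$v) - cam$principal, tolerance = 1e-9)
  # random points agree with the explicit 3x4 matrix product
  P <- camera_matrix(cam)
  set.seed(3)
  for (i in 1:20) {
    X <- c(runif(2, -150, 150), runif(1, -150, 150))
    ph <- as.numeric(P %*% c(X, 1))
    pr <- project(cam, X)
    expect_equal(c(pr$u, pr$v), ph[1:2] / ph[3], tolerance = 1e-9)
  }
  expect_error(project(cam, cam$center - 100 * cam$R[3, ]), "behind")
})

test_that("rig cameras have proper rotations and positive focal lengths", {
  for (cam in fx_rig$cameras) {
    expect_equal(crossprod(cam$R), diag(3), tolerance = 1e-12)
    expect_equal(det(cam$R), 1, tolerance = 1e-12)
    expect_gt(cam$focal_px, 0)
  }
})

test_that("wand sweeps are collinear, complete, deterministic and exact at zero noise", {
  s <- simulate_wand_sweep(fx_rig, n_frames = 50, sigma_px = 0, seed = 5)
  expect_equal(length(unique(s$truth$frame)), 50L)
  # three wand markers are collinear with the configured spacings
  for (f in c(1, 25, 50)) {
    m <- as.matrix(s$truth[s$truth$frame == f, c("x", "y", "z")])
    expect_equal(dist3(m[1, ], m[2, ]), 100, tolerance = 1e-9)
    expect_equal(dist3(m[2, ], m[3, ]), 150, tolerance = 1e-9)
    expect_equal(dist3(m[1, ], m[3, ]), 250, tolerance = 1e-9)
  }
  # noiseless observations equal the reprojection of truth
  tk <- paste(s$truth$frame, s$truth$marker, sep = "/")
  for (ci in 1:6) {
    oc <- s$observations[s$observations$camera == ci, ]
    X <- as.matrix(s$truth[match(paste(oc$frame, oc$marker, sep = "/"), tk),
                           c("x", "y", "z")])
    pr <- project(fx_rig$cameras[[ci]], X)
    expect_equal(oc$u, pr$u, tolerance = 1e-9)
    expect_equal(oc$v, pr$v, tolerance = 1e-9)
  }
  # seed determinism, and different seeds differ
  s2 <- simulate_wand_sweep(fx_rig, n_frames = 50, sigma_px = 0, seed = 5)
  expect_identical(s, s2)
  s3 <- simulate_wand_sweep(fx_rig, n_frames = 50, sigma_px = 0, seed = 6)
  expect_false(identical(s$truth, s3$truth))
})

test_that("rod sessions honour duration, frequency and rigidity", {
  s <- simulate_rod_session(fx_rig, rod_linear(), "static", 5, 0, seed = 2)
  expect_equal(length(unique(s$truth$frame)), 500L)
  sd6 <- simulate_rod_session(fx_rig, rod_linear(), "dynamic", 6, 0, seed = 2)
  expect_equal(length(unique(sd6$truth$frame)), 600L)
  # the rigid phantom keeps its end-to-end truth distance in every frame
  for (s_ in list(s, sd6)) {
    d <- vapply(unique(s_$truth$frame), function(f) {
      m <- as.matrix(s_$truth[s_$truth$frame == f, c("x", "y", "z")])
      dist3(m[1, ], m[2, ])
    }, numeric(1))
    expect_equal(d, rep(176.84, length(d)), tolerance = 1e-9)
  }
})

test_that("expression sessions compose head motion and expression displacement", {
  sched <- default_schedule(1, rest_s = 0.5, gap_s = 0.2)
  # null session: no expressions, no head motion -> constant trajectories
  null_s <- simulate_expression_session(fx_face, fx_rig,
                                        default_schedule(integer(0),
                                                         rest_s = 0.6),
                                        head_motion = NULL, sigma_px = 0,
                                        seed = 1)
  for (mk in c("B", "h", "HM1")) {
    m <- as.matrix(null_s$truth[null_s$truth$marker == mk, c("x", "y", "z")])
    expect_lt(max(apply(m, 2, function(v) diff(range(v)))), 1e-12)
  }
  # head motion only: world positions move, head-frame truth is constant
  hm <- simulate_expression_session(fx_face, fx_rig,
                                    default_schedule(integer(0), rest_s = 1),
                                    sigma_px = 0, seed = 3)
  mB <- as.matrix(hm$truth[hm$truth$marker == "B", c("x", "y", "z")])
  expect_gt(max(apply(mB, 2, function(v) diff(range(v)))), 1)
  hB <- as.matrix(hm$truth_head[hm$truth_head$marker == "B",
                                c("x", "y", "z")])
  expect_lt(max(apply(hB, 2, function(v) diff(range(v)))), 1e-12)
  # brow lift: peak head-frame deviation of B equals the configured 8 mm
  bl <- simulate_expression_session(fx_face, fx_rig, sched,
                                    head_motion = NULL, sigma_px = 0,
                                    seed = 4)
  rest <- face_points(fx_face)["B", ]
  hB <- as.matrix(bl$truth_head[bl$truth_head$marker == "B",
                                c("x", "y", "z")])
  dev <- sqrt(rowSums(sweep(hB, 2, rest)^2))
  expect_equal(max(dev), 8, tolerance = 1e-9)
  # helmet markers carry no expression motion
  hH <- as.matrix(bl$truth_head[bl$truth_head$marker == "HM1",
                                c("x", "y", "z")])
  expect_lt(max(apply(hH, 2, function(v) diff(range(v)))), 1e-12)
  expect_error(simulate_expression_session(fx_face, fx_rig,
                                           default_schedule(99)),
               "unregistered")
})

test_that("the visibility report flags markers seen by fewer than 3 cameras", {
  s <- simulate_wand_sweep(fx_rig, n_frames = 30, sigma_px = 0, seed = 8)
  vis <- visibility_report(s)
  expect_equal(nrow(vis), nrow(s$truth))
  expect_true(all(vis$n_cameras <= 6))
  # drop all but two cameras for one frame-marker and expect a flag
  s$observations <- s$observations[
    !(s$observations$frame == 1 & s$observations$marker == "W1" &
        s$observations$camera > 2), ]
  vis2 <- visibility_report(s)
  expect_true(vis2$flagged[vis2$frame == 1 & vis2$marker == "W1"])
  expect_false(attr(vis2, "ok"))
})

test_that("identical seeds give identical expression datasets", {
  a <- simulate_expression_session(fx_face, fx_rig,
                                   default_schedule(5, rest_s = 0.3),
                                   sigma_px = 0.5, seed = 77)
  b <- simulate_expression_session(fx_face, fx_rig,
                                   default_schedule(5, rest_s = 0.3),
                                   sigma_px = 0.5, seed = 77)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
})
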