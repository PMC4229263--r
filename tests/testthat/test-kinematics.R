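test_that("differentiation is exact for constant and linear motion", {
  n <- 100
  const <- matrix(rep(c(3, -1, 2), each = n), n, 3)
  ka <- velocity_acceleration(const)
  expect_lt(max(abs(ka$velocity)), 1e-9)
  expect_lt(max(abs(ka$acceleration)), 1e-9)
  # 10 mm/s along x at 100 Hz
  lin <- cbind((0:(n - 1)) * 0.1, 0, 0)
  ka <- velocity_acceleration(lin)
  expect_equal(ka$velocity[, 1], rep(10, n), tolerance = 1e-9)
  expect_lt(max(abs(ka$acceleration[6:(n - 5), ])), 1e-6)
  expect_error(velocity_acceleration(lin[1:4, ]), "too short")
})

test_that("differentiation matches the analytic derivative of a sinusoid", {
  t <- (0:299) / 100
  pos <- cbind(5 * sin(2 * pi * 2 * t), 0, 0)   # 2 Hz, 5 mm amplitude
  ka <- velocity_acceleration(pos)
  mid <- 50:250
  v_true <- 5 * 2 * pi * 2 * cos(2 * pi * 2 * t)
  a_true <- -5 * (2 * pi * 2)^2 * sin(2 * pi * 2 * t)
  expect_lt(max(abs(ka$velocity[mid, 1] - v_true[mid])) / max(abs(v_true)),
            0.01)
  expect_lt(max(abs(ka$acceleration[mid, 1] - a_true[mid])) / max(abs(a_true)),
            0.01)
})

test_that("expression summaries recover the simulated brow lift", {
  sched <- default_schedule(1, rest_s = 0.5)
  sess <- simulate_expression_session(fx_face, fx_rig, sched,
                                      head_motion = NULL, sigma_px = 0,
                                      seed = 23)
  anat <- truth_trajectories(sess, head = TRUE)  # head frame = anatomical
  s <- expression_summary(anat, expression_frames = 51:300,
                          rest_frames = 1:50, landmarks = c("B", "a"))
  B <- s[s$landmark == "B", ]
  expect_equal(B$max_deviation_mm, 8, tolerance = 0.01)
  expect_equal(c(B$dir_x, B$dir_y, B$dir_z), c(0, 1, 0), tolerance = 1e-6)
  # a (right tragus) is inactive in a brow lift
  expect_lt(s$max_deviation_mm[s$landmark == "a"], 1e-9)
  # null session: all maxima zero
  null_s <- simulate_expression_session(fx_face, fx_rig,
                                        default_schedule(integer(0),
                                                         rest_s = 1),
                                        head_motion = NULL, sigma_px = 0,
                                        seed = 23)
  s0 <- expression_summary(truth_trajectories(null_s, head = TRUE),
                           expression_frames = 51:100, rest_frames = 1:50)
  expect_lt(max(s0$max_deviation_mm), 1e-9)
  expect_lt(max(s0$max_speed_mm_s), 1e-6)
})

test_that("doubling the amplitude doubles deviation and speed maxima", {
  disp <- expression_displacements()
  disp2 <- disp
  disp2[, c("dx", "dy", "dz")] <- 2 * disp2[, c("dx", "dy", "dz")]
  sched <- default_schedule(1, rest_s = 0.5)
  mk_summary <- function(d) {
    sess <- simulate_expression_session(fx_face, fx_rig, sched,
                                        head_motion = NULL, sigma_px = 0,
                                        seed = 24, displacements = d)
    expression_summary(truth_trajectories(sess, head = TRUE),
                       expression_frames = 51:300, rest_frames = 1:50,
                       landmarks = "B", smooth = FALSE)
  }
  s1 <- mk_summary(disp); s2 <- mk_summary(disp2)
  expect_equal(s2$max_deviation_mm, 2 * s1$max_deviation_mm,
               tolerance = 1e-9)
  expect_equal(s2$max_speed_mm_s, 2 * s1$max_speed_mm_s, tolerance = 1e-9)
})

test_that("max speed bounds the largest single-frame displacement", {
  sess <- simulate_expression_session(fx_face, fx_rig,
                                      default_schedule(8, rest_s = 0.5),
                                      head_motion = NULL, sigma_px = 0,
                                      seed = 25)
  anat <- truth_trajectories(sess, head = TRUE)
  for (lab in c("III", "H")) {
    pos <- as.matrix(anat[anat$label == lab, c("x", "y", "z")])
    ka <- velocity_acceleration(pos)
    step <- sqrt(rowSums(diff(ka$position)^2))
    expect_gte(max(sqrt(rowSums(ka$velocity^2))) / 100, max(step) - 1e-9)
  }
})

test_that("the static measure set has the 20 reporting rows", {
  rest <- face_points(fx_face)[fx_face$type == "face", ]
  sm <- static_measures(rest)
  expect_equal(nrow(sm), 20L)
  expect_equal(as.vector(table(sm$class)[c("distance", "angle", "direction")]),
               c(8L, 4L, 8L))
  expect_true(all(is.finite(sm$value)))
  # mirrored pairs are equal on the symmetric template
  val <- function(p) sm$value[sm$parameter == p]
  expect_equal(val("G-H (distance)"), val("g-h (distance)"))
  expect_equal(val("I-G (distance)"), val("I-g (distance)"))
  expect_equal(val("∠CED"), val("∠ced"))
  expect_equal(val("∠EHh"), val("∠ehH"))
  # direction X components mirror in sign
  expect_equal(val("G-H (direction) X"), -val("g-h (direction) X"))
  # hand-checked vertex angle: collinear C, E, D spans 180 degrees
  rest2 <- rest
  rest2["C", ] <- c(10, 0, 0); rest2["E", ] <- c(0, 0, 0)
  rest2["D", ] <- c(-5, 0, 0)
  sm2 <- static_measures(rest2)
  expect_equal(sm2$value[sm2$parameter == "∠CED"], 180)
  expect_error(static_measures(rest[1:5, ]), "missing landmark")
})

test_that("static measures are invariant to rigid motion of the head", {
  rest <- face_points(fx_face)[fx_face$type == "face", ]
  fr <- anatomical_frame(rest)
  anat0 <- facemotion3d:::to_frame_coords(fr, rest)
  rownames(anat0) <- rownames(rest)
  base <- static_measures(anat0)
  set.seed(26)
  for (i in 1:5) {
    rt <- random_rigid()
    moved <- apply_rigid(rt, rest)
    rownames(moved) <- rownames(rest)
    fr2 <- anatomical_frame(moved)
    anat2 <- facemotion3d:::to_frame_coords(fr2, moved)
    rownames(anat2) <- rownames(rest)
    expect_equal(static_measures(anat2)$value, base$value, tolerance = 1e-9)
  }
})

test_that("the full analysis chain runs on a reconstructed session", {
  sched <- default_schedule(1, rest_s = 0.5)
  sess <- simulate_expression_session(fx_face, fx_rig, sched,
                                      sigma_px = 0.5, seed = 27)
  traj <- reconstruct(sess, fx_cal05)
  res <- analyze_session(traj, sched)
  expect_equal(nrow(res$static), 20L)
  expect_equal(unique(res$dynamic$expression), 1)
  B <- res$dynamic[res$dynamic$landmark == "B", ]
  expect_equal(B$max_deviation_mm, 8, tolerance = 0.5)
  expect_gt(B$dir_y, 0.9)
})
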