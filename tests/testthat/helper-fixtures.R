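# Shared fixtures (built once per test run) and independent oracles.

fx_rig <- default_rig()

# noiseless wand sweep + calibration: exact-model reference
fx_wand0 <- simulate_wand_sweep(fx_rig, n_frames = 400, sigma_px = 0,
                                seed = 11)
fx_cal0 <- calibrate_dlt(fx_wand0, seed = 11)

# default-noise wand sweep + calibration (0.5 px)
fx_wand05 <- simulate_wand_sweep(fx_rig, n_frames = 600, sigma_px = 0.5,
                                 seed = 12)
fx_cal05 <- calibrate_dlt(fx_wand05, seed = 12)

fx_face <- face_template()

random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
             c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
             c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  list(R = R, t = rnorm(3, sd = 50))
}

apply_rigid <- function(rt, pts) {
  if (is.null(dim(pts))) return(as.numeric(rt$R %*% pts + rt$t))
  t(rt$R %*% t(pts) + rt$t)
}

# Gauss-Newton reprojection-error-minimizing triangulation oracle,
# independent of the package's linear DLT path.
triangulate_gn <- function(P, uv, init) {
  X <- init
  for (iter in 1:100) {
    r <- numeric(0); J <- NULL
    for (i in seq_along(P)) {
      p <- as.numeric(P[[i]] %*% c(X, 1))
      r <- c(r, p[1] / p[3] - uv[i, 1], p[2] / p[3] - uv[i, 2])
      Ju <- (P[[i]][1, 1:3] * p[3] - P[[i]][3, 1:3] * p[1]) / p[3]^2
      Jv <- (P[[i]][2, 1:3] * p[3] - P[[i]][3, 1:3] * p[2]) / p[3]^2
      J <- rbind(J, Ju, Jv)
    }
    dx <- as.numeric(solve(crossprod(J), crossprod(J, -r)))
    X <- X + dx
    if (sqrt(sum(dx^2)) < 1e-12) break
  }
  X
}

# Brute-force ICC(1,1) by explicit sum-of-squares loops.
icc_brute <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    rm_ <- sum(x[i, ]) / k
    ssb <- ssb + k * (rm_ - gm)^2
    for (j in seq_len(k)) ssw <- ssw + (x[i, j] - rm_)^2
  }
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# all permutations of 1..n (small n only)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[p], nrow(p)))
  }))
}

# minimum-total-distance one-to-one assignment by exhaustion
brute_assignment <- function(D) {
  pp <- perms(nrow(D))
  costs <- apply(pp, 1, function(p) sum(D[cbind(seq_len(nrow(D)), p)]))
  pp[which.min(costs), ]
}

# head-frame truth trajectories of a session as a trajectory data.frame
truth_trajectories <- function(session, head = FALSE) {
  tr <- if (head) session$truth_head else session$truth
  out <- data.frame(frame = tr$frame,
                    time_s = (tr$frame - 1) / session$clock$frequency_hz,
                    label = tr$marker, x = tr$x, y = tr$y, z = tr$z,
                    n_cameras = 6L, gap = FALSE, residual_px = 0)
  attr(out, "frequency_hz") <- session$clock$frequency_hz
  out
}
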