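test_that("bold_fraction splits fluctuation variance at the reference echo", {
  ## degenerate mixtures
  f0 <- simulate_fluctuations(sim_config(bold_fraction = 0, n_rois = 5L, n_t = 20L))
  expect_true(all(f0$delta_r2s == 0))
  expect_false(all(f0$delta_rho == 0))
  f1 <- simulate_fluctuations(sim_config(bold_fraction = 1, n_rois = 5L, n_t = 20L))
  expect_true(all(f1$delta_rho == 0))

  ## empirical variance ratio at TE_ref for a long run
  cfg <- sim_config(bold_fraction = 0.5, n_rois = 10L, n_t = 20000L, seed = 5L)
  fl <- simulate_fluctuations(cfg)
  te2 <- cfg$echo_times[2]
  v_bold <- apply(fl$delta_r2s * te2, 1, var)
  v_rho <- apply(fl$delta_rho, 1, var)
  ratio <- v_bold / (v_bold + v_rho)
  expect_true(all(abs(ratio - 0.5) < 0.02))
})

test_that("simulation is reproducible and rejects bad covariances", {
  cfg <- sim_config(n_rois = 8L, n_t = 30L, seed = 99L)
  a <- simulate_fluctuations(cfg)
  b <- simulate_fluctuations(cfg)
  expect_identical(a$delta_rho, b$delta_rho)
  expect_identical(a$delta_r2s, b$delta_r2s)

  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 2   # indefinite
  expect_error(sim_config(n_rois = 4L, network_covariance = bad),
               "positive semidefinite")
  expect_error(sim_config(n_rois = 4L,
                          network_covariance = matrix(runif(16), 4)),
               "symmetric")
})

test_that("empirical covariance of delta_rho recovers the target network", {
  cfg <- sim_config(bold_fraction = 0, n_rois = 20L, n_t = 20000L, seed = 17L)
  fl <- simulate_fluctuations(cfg)
  emp <- cov(t(fl$delta_rho))
  target <- (cfg$spc_sigma / 100)^2 * cfg$network_covariance
  rel <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel, 0.05)
})

test_that("synthesize_roi_spc applies the linearized model", {
  ## zero-mean two-point fluctuations so centering changes nothing
  rho <- matrix(c(0.01, -0.01), 1)
  dr2 <- matrix(c(0.001, -0.001), 1)
  fl <- manual_fluct(rho, dr2)
  ts <- synthesize_roi_spc(fl, echo_times = c(30, 60))
  ## 100 * (0.01 - 0.001*30) = -2 percent
  expect_equal(unname(ts$values[[1]][1, 1]), -2)
  expect_equal(unname(ts$values[[2]][1, 1]), -5)
  expect_identical(ts$units, "spc")

  ## pure S_o: identical series at every echo
  fl_so <- manual_fluct(matrix(rnorm(40), 4), matrix(0, 4, 10))
  ts_so <- synthesize_roi_spc(fl_so, echo_times = c(10, 20, 40))
  expect_equal(ts_so$values[[1]], ts_so$values[[2]])
  expect_equal(ts_so$values[[1]], ts_so$values[[3]])

  ## pure BOLD: series scale as TE_j / TE_i
  fl_b <- manual_fluct(matrix(0, 4, 10), matrix(rnorm(40, sd = 1e-4), 4))
  ts_b <- synthesize_roi_spc(fl_b, echo_times = c(10, 20, 40))
  expect_equal(ts_b$values[[2]], 2 * ts_b$values[[1]])
  expect_equal(ts_b$values[[3]], 4 * ts_b$values[[1]])
})

test_that("voxel synthesis evaluates the mono-exponential model", {
  gdim <- c(2L, 1L, 1L)
  s0 <- array(1000, gdim)
  r2s <- array(0.03, gdim)
  roi_map <- array(0L, gdim)           # no fluctuation anywhere
  fl <- manual_fluct(matrix(0, 1, 2), matrix(0, 1, 2))
  scan <- synthesize_voxel_scan(list(s0_bar = s0, r2s_bar = r2s), fl, roi_map,
                                echo_times = c(30, 60), thermal_sigma = 0)
  expect_equal(scan$data[[1]][1, 1, 1, 1], 1000 * exp(-0.9))
  expect_equal(round(scan$data[[1]][1, 1, 1, 1], 2), 406.57)
  ## TE -> 0 limit: signal approaches S0_bar
  scan0 <- synthesize_voxel_scan(list(s0_bar = s0, r2s_bar = r2s), fl, roi_map,
                                 echo_times = c(1e-9, 30))
  expect_equal(scan0$data[[1]][1, 1, 1, 1], 1000, tolerance = 1e-9)

  ## driving R2* negative is a hard error
  fl_big <- manual_fluct(matrix(0, 1, 2), matrix(c(-0.05, 0.05), 1))
  roi_map2 <- array(1L, gdim)
  expect_error(
    synthesize_voxel_scan(list(s0_bar = s0, r2s_bar = r2s), fl_big, roi_map2,
                          echo_times = c(30, 60)),
    "non-positive")
})

test_that("small-fluctuation voxel SPC matches the linearization within 1%", {
  cfg <- sim_config(n_rois = 8L, n_t = 200L, bold_fraction = 0.5,
                    spc_sigma = 0.2, seed = 21L)
  fl <- simulate_fluctuations(cfg)
  ## amplitude precondition of the linearization
  expect_lt(max(abs(fl$delta_rho)), 0.01)
  expect_lt(max(abs(fl$delta_r2s)) * max(cfg$echo_times), 0.01)
  gdim <- c(2L, 2L, 2L)
  roi_map <- array(seq_len(8L), gdim)
  baseline <- list(s0_bar = array(500, gdim), r2s_bar = array(1 / 40, gdim))
  scan <- synthesize_voxel_scan(baseline, fl, roi_map, cfg$echo_times,
                                thermal_sigma = 0)
  for (e in seq_along(cfg$echo_times)) {
    m <- matrix(scan$data[[e]], 8, cfg$n_t)
    spc_hat <- 100 * sweep(m, 1, rowMeans(m), "-") / rowMeans(m)
    pred <- 100 * (fl$delta_rho - fl$delta_r2s * cfg$echo_times[e])
    pred <- pred - rowMeans(pred)
    pred_vox <- pred[as.vector(roi_map), ]
    expect_lt(norm(spc_hat - pred_vox, "F") / norm(pred_vox, "F"), 0.01)
  }
})

test_that("TR jitter adds a TE-independent saturation term", {
  fl <- simulate_fluctuations(sim_config(n_rois = 4L, n_t = 6L, seed = 2L))
  same <- apply_tr_jitter(fl, rep(0, 6))
  expect_identical(same$delta_rho, fl$delta_rho)

  ## fully relaxed limit: added term is 1/(1 - exp(-TR/T1)) - 1 > 0
  relaxed <- apply_tr_jitter(fl, rep(Inf, 6), t1 = 1.4, nominal_tr = 2.5)
  added <- relaxed$delta_rho - fl$delta_rho
  expect_equal(unique(round(as.vector(added), 12)),
               round(1 / (1 - exp(-2.5 / 1.4)) - 1, 12))
  expect_gt(added[1, 1], 0)

  expect_error(apply_tr_jitter(fl, rep(0, 6), t1 = -1), "T1")
  expect_error(apply_tr_jitter(fl, rep(-3, 6)), "positive")
  expect_error(apply_tr_jitter(fl, rep(0, 5)), "per timepoint")
})

test_that("cardiac-gated TR jitter drags p_BOLD down versus a constant-TR twin", {
  cfg <- sim_config(n_rois = 30L, n_t = 300L, bold_fraction = 0.8, seed = 31L)
  fl <- simulate_fluctuations(cfg)
  p_const <- scan_pbold(synthesize_roi_spc(fl))$p_bold
  set.seed(32L)
  offsets <- abs(rnorm(cfg$n_t, sd = 0.7))   # wait-for-beat delays
  fl_j <- apply_tr_jitter(fl, offsets, t1 = 1.4, nominal_tr = 2.5)
  p_jit <- scan_pbold(synthesize_roi_spc(fl_j))$p_bold
  expect_lt(p_jit, p_const)
})

test_that("background fixture has the stated noise and zero structure", {
  z <- generate_background_fixture(c(4L, 4L, 4L), n_t = 10L, sigma = 0)
  expect_true(all(vapply(z$data, function(v) all(v == 0), logical(1))))

  bg <- generate_background_fixture(c(6L, 6L, 6L), n_t = 200L, sigma = 1,
                                    zero_fraction = 0.2, seed = 4L,
                                    folded = TRUE)
  zero_counts <- rowSums(matrix(bg$data[[1]], 216, 200) == 0)
  expect_equal(mean(zero_counts), 40, tolerance = 0.05)
  expect_true(all(bg$data[[1]] >= 0))

  unf <- generate_background_fixture(c(6L, 6L, 6L), n_t = 200L, sigma = 2,
                                     seed = 5L, folded = FALSE)
  expect_equal(sd(unf$data[[2]]), 2, tolerance = 0.02)
})
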