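test_that("quadruple enumeration counts and slopes are right", {
  q3 <- enumerate_quadruples(c(13.9, 31.7, 49.5))
  expect_identical(nrow(q3), 15L)                 # 3 echoes -> 6 pairs -> 15
  q2 <- enumerate_quadruples(c(10, 20))
  expect_identical(nrow(q2), 3L)                  # 2 echoes -> 3 pairs -> 3
  expect_error(enumerate_quadruples(13.9), ">= 2 echoes")

  ## slope of [(TE1,TE1),(TE3,TE3)] with TEs 13.9/49.5
  row <- q3[q3$te_i == 13.9 & q3$te_j == 13.9 & q3$te_k == 49.5 & q3$te_l == 49.5, ]
  expect_equal(row$m, 49.5^2 / 13.9^2, tolerance = 1e-12)
  expect_equal(row$m, 12.683, tolerance = 1e-3)
  ## canonical ordering: every slope >= 1, theta in [0, pi/2), chord in [0, 1)
  expect_true(all(q3$m >= 1))
  expect_true(all(q3$theta >= 0 & q3$theta < pi / 2))
  expect_true(all(q3$chord >= 0 & q3$chord < 1))
  expect_equal(q3$chord, chord_distance(q3$theta, 0.5))
})

test_that("chord_distance is the closed-form chord length", {
  expect_equal(chord_distance(0), 0)
  expect_equal(chord_distance(pi, 0.5), 1)
  expect_equal(chord_distance(pi / 4, 0.5), 2 * 0.5 * sin(pi / 8))
  expect_equal(round(chord_distance(pi / 4, 0.5), 5), 0.38268)
  expect_error(chord_distance(-0.1), "theta")
  expect_error(chord_distance(3.5), "theta")
})

test_that("edge geometry reproduces hand-computed distances and labels", {
  mk <- function(v12) matrix(c(0, v12, v12, 0), 2, 2)
  quad <- list(m = 2)
  ## point on the identity line
  e <- edge_geometry(mk(0.2), mk(0.2), quad)
  expect_equal(e$d_so, 0)
  expect_identical(e$pref, 0)
  ## point on the BOLD line
  e <- edge_geometry(mk(0.1), mk(0.2), quad)
  expect_equal(e$d_bold, 0)
  expect_identical(e$pref, 1)
  ## point (1, 0) with m = 2
  e <- edge_geometry(mk(1), mk(0), quad)
  expect_equal(e$d_so, 1 / sqrt(2))
  expect_equal(round(e$d_so, 5), 0.70711)
  expect_equal(e$d_bold, 2 / sqrt(5))
  expect_equal(round(e$d_bold, 5), 0.89443)
  expect_identical(e$pref, 0)
  expect_equal(e$weight, 1)
  ## 3-4-5 triangle weight
  e <- edge_geometry(mk(0.3), mk(0.4), quad)
  expect_equal(e$weight, 0.5)
  ## tie band
  e <- edge_geometry(mk(1e-5), mk(1e-5 * 2), list(m = 2), delta = 1e-3)
  expect_identical(e$pref, 0.5)
})

test_that("vectorized geometry equals the scalar brute-force oracle exactly", {
  set.seed(123)
  for (i in 1:100) {
    n <- 10
    fx <- matrix(rnorm(n * n, sd = 0.3), n)
    fy <- matrix(rnorm(n * n, sd = 0.3), n)
    m <- exp(runif(1, 0, 3))
    got <- edge_geometry(fx, fy, list(m = m))
    want <- oracle_edge_geometry(fx, fy, m)
    expect_identical(got$d_so, want$d_so)
    expect_identical(got$d_bold, want$d_bold)
    expect_identical(got$pref, want$pref)
    expect_identical(got$weight, want$weight)
    expect_identical(got$roi_a, want$roi_a)
    expect_identical(got$roi_b, want$roi_b)
  }
})

test_that("the literal printed labelling is available and inverted", {
  mk <- function(v12) matrix(c(0, v12, v12, 0), 2, 2)
  ## far from BOLD line, near identity: literal rule calls it BOLD-preferring
  e <- edge_geometry(mk(1), mk(0), list(m = 2), literal_eq14 = TRUE)
  expect_identical(e$pref, 1)
  e <- edge_geometry(mk(0.1), mk(0.2), list(m = 2), literal_eq14 = TRUE)
  expect_identical(e$pref, 0)
})

test_that("quadruple_pbold is the origin-weighted preference mean", {
  mk_edges <- function(pref, w)
    data.frame(roi_a = 1, roi_b = 2, fc_x = 0, fc_y = 0, d_so = 0, d_bold = 0,
               pref = pref, weight = w)
  expect_equal(quadruple_pbold(mk_edges(c(1, 1, 1), c(1, 2, 3))), 1)
  expect_equal(quadruple_pbold(mk_edges(c(1, 0), c(1, 1))), 0.5)
  expect_equal(quadruple_pbold(mk_edges(c(1, 0), c(3, 1))), 0.75)
  expect_warning(p <- quadruple_pbold(mk_edges(c(1, 0), c(0, 0))), "undefined")
  expect_true(is.na(p))
})

test_that("scan_pbold handles pure regimes and a literal S_o-only signal", {
  cfg0 <- sim_config(bold_fraction = 0, seed = 11L)     # 50 ROIs, Nt = 500
  p0 <- scan_pbold(synthesize_roi_spc(simulate_fluctuations(cfg0)))
  expect_lte(p0$p_bold, 0.05)
  cfg1 <- sim_config(bold_fraction = 1, seed = 11L)
  p1 <- scan_pbold(synthesize_roi_spc(simulate_fluctuations(cfg1)))
  expect_gte(p1$p_bold, 0.95)

  ## identical series at every echo: every edge sits on the identity line
  set.seed(3)
  m <- matrix(rnorm(80), 8); m <- m - rowMeans(m)
  ts <- roi_ts_set(list(m, m, m), c(10, 20, 40), units = "spc")
  res <- scan_pbold(ts)
  expect_equal(res$p_bold, 0)

  ## consistency of the stored chord-weighted average
  pq <- res$per_quadruple
  ok <- !is.na(pq$p_bold)
  expect_equal(res$p_bold,
               sum(pq$chord[ok] * pq$p_bold[ok]) / sum(pq$chord[ok]),
               tolerance = 1e-12)
})

test_that("axis swap within a quadruple changes nothing", {
  cfg <- sim_config(n_rois = 15L, n_t = 120L, bold_fraction = 0.6, seed = 9L)
  ts <- synthesize_roi_spc(simulate_fluctuations(cfg))
  quads <- enumerate_quadruples(ts$echo_times)
  for (q in seq_len(nrow(quads))) {
    fx <- covariance_fc(ts, quads$ix_i[q], quads$ix_j[q])
    fy <- covariance_fc(ts, quads$ix_k[q], quads$ix_l[q])
    e1 <- edge_geometry(fx, fy, list(m = quads$m[q]))
    e2 <- edge_geometry(fy, fx, list(m = 1 / quads$m[q]))
    expect_equal(e1$d_so, e2$d_so, tolerance = 1e-12)
    expect_equal(e1$d_bold, e2$d_bold, tolerance = 1e-12)
    expect_identical(e1$pref, e2$pref)
    expect_equal(quadruple_pbold(e1), quadruple_pbold(e2), tolerance = 1e-12)
  }
})

test_that("p_BOLD is monotone in the BOLD fraction and stays in range", {
  fractions <- c(0, 0.25, 0.5, 0.75, 1)
  p <- vapply(fractions, function(f) {
    cfg <- sim_config(bold_fraction = f, seed = 42L)   # 50 ROIs, Nt = 500
    scan_pbold(synthesize_roi_spc(simulate_fluctuations(cfg)))$p_bold
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate and invalid inputs are handled safely", {
  ## TE1*TE4 = TE2*TE3 gives an m = 1 quadruple: chord 0, no division blowup
  quads4 <- enumerate_quadruples(c(10, 20, 40, 80))
  expect_true(any(quads4$m == 1 & quads4$chord == 0))
  set.seed(5)
  mats <- lapply(1:4, function(e) { m <- matrix(rnorm(40), 4); m - rowMeans(m) })
  ts4 <- roi_ts_set(mats, c(10, 20, 40, 80), units = "spc")
  res4 <- scan_pbold(ts4)
  expect_true(res4$p_bold >= 0 && res4$p_bold <= 1)

  set.seed(5)
  m1 <- matrix(rnorm(40), 4); m1 <- m1 - rowMeans(m1)
  m2 <- matrix(rnorm(40), 4); m2 <- m2 - rowMeans(m2)
  ts <- roi_ts_set(list(m1, m2), c(10, 20), units = "spc")
  res <- scan_pbold(ts)
  expect_true(res$p_bold >= 0 && res$p_bold <= 1)
  expect_true(all(res$per_quadruple$chord >= 0))

  expect_error(scan_pbold(ts, delta = 1e-3, chord_radius = 0.5,
                          symmetrize = FALSE)$p_bold, NA)
  ## all-zero input: weights all zero everywhere -> undefined
  z <- matrix(0, 3, 5)
  tz <- roi_ts_set(list(z, z), c(10, 20), units = "spc")
  expect_error(suppressWarnings(scan_pbold(tz)), "undefined")
  ## raw units rejected
  raw <- manual_raw_ts(list(abs(m1) + 10, abs(m2) + 10), c(10, 20))
  expect_error(scan_pbold(raw), "spc")
})

test_that("symmetrized cross-echo covariance is a small perturbation", {
  cfg <- sim_config(n_rois = 20L, n_t = 200L, bold_fraction = 0.9, seed = 13L)
  ts <- synthesize_roi_spc(simulate_fluctuations(cfg))
  p_raw <- scan_pbold(ts)$p_bold
  p_sym <- scan_pbold(ts, symmetrize = TRUE)$p_bold
  expect_gte(p_sym, 0.8)
  expect_lt(abs(p_raw - p_sym), 0.1)
})
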