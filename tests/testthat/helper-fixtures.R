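## Fixtures are built in code at test time; nothing binary ships in the repo.

## A bare fluctuation container (bypasses the generator) for direct
## evaluations of the signal model.
manual_fluct <- function(delta_rho, delta_r2s, echo_times = c(13.9, 31.7, 49.5)) {
  structure(list(delta_r2s = delta_r2s, delta_rho = delta_rho,
                 config = list(echo_times = echo_times)),
            class = "fluctuation_series")
}

## Small raw-unit ROI series set: baseline + optional per-echo matrices.
manual_raw_ts <- function(values, echo_times) {
  roi_ts_set(values, echo_times, units = "raw")
}

## Scalar per-edge brute-force oracle for the plane geometry: one edge at a
## time, textbook point-to-line formulas, no vectorization. Kept independent
## of edge_geometry().
oracle_edge_geometry <- function(fc_x, fc_y, m, delta = 1e-3) {
  n <- nrow(fc_x)
  rows <- list()
  for (x in 1:(n - 1)) for (y in (x + 1):n) {
    a <- fc_x[x, y]
    b <- fc_y[x, y]
    ## distance from (a, b) to y = x, i.e. line x - y = 0
    d_so <- abs(a - b) / sqrt(1^2 + (-1)^2)
    ## distance from (a, b) to y = m x, i.e. line m*x - y = 0
    d_bold <- abs(m * a - b) / sqrt(m^2 + (-1)^2)
    pref <- if (d_so - d_bold > delta) 1 else if (d_bold - d_so > delta) 0 else 0.5
    rows[[length(rows) + 1L]] <- data.frame(
      roi_a = x, roi_b = y, fc_x = a, fc_y = b, d_so = d_so, d_bold = d_bold,
      pref = pref, weight = sqrt(a^2 + b^2))
  }
  out <- do.call(rbind, rows)
  out[order(out$roi_b, out$roi_a), ]   # column-major upper-triangle order
}

## Brute-force across-echo covariance: explicit per-pair loop over Eq-style
## sums, independent of the matrix implementation.
oracle_covariance <- function(mat_a, mat_b) {
  n <- nrow(mat_a)
  nt <- ncol(mat_a)
  out <- matrix(0, n, n)
  for (x in 1:n) for (y in 1:n) {
    sx <- mat_a[x, ] - mean(mat_a[x, ])
    sy <- mat_b[y, ] - mean(mat_b[y, ])
    out[x, y] <- sum(sx * sy) / (nt - 1)
  }
  out
}

## 4D array with a given voxel-value generator, for io tests.
make_4d <- function(dims, nt, fill) {
  array(fill(prod(dims) * nt), dim = c(dims, nt))
}

## plain numeric matrix from an fc_matrix (drops class/attributes)
strip_fc <- function(x) matrix(as.numeric(unclass(x)), nrow(x))
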