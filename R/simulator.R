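## Multi-echo signal simulator.
##
## Generates ROI-level and voxel-level multi-echo data from the
## mono-exponential decay model
##   S(x,t,TE_i) = S_o(x,t) * exp(-R2*(x,t) * TE_i) + n(x,t)
## with two independent fluctuation sources: net-magnetization changes
## (delta_rho = dS_o/S_o_bar, TE-independent) and transverse-relaxation
## changes (delta_r2s, whose signal footprint scales with TE — the BOLD
## mechanism). The mixture parameter bold_fraction sets, at the reference
## echo (the second TE), the share of fluctuation variance carried by the
## R2* route, so bold_fraction = 0 is a pure-S_o (artifact-dominated) world
## and bold_fraction = 1 a pure-BOLD world.

#' Simulation configuration
#'
#' @param n_rois number of ROIs (default 50).
#' @param n_t number of timepoints (default 500).
#' @param echo_times echo times in ms; default 13.9/31.7/49.5 (a typical
#'   3-echo 3T protocol).
#' @param bold_fraction in [0,1]: at the reference echo (second TE), the
#'   fraction of fluctuation variance contributed by the R2* (BOLD) source.
#' @param network_covariance N_rois x N_rois symmetric PSD target covariance
#'   (correlation-scale, unit diagonal recommended). Default: 5 equal blocks
#'   with within-block covariance 0.8 and none between, mimicking a
#'   stereotypical resting-state network structure.
#' @param spc_sigma total fluctuation standard deviation at the reference
#'   echo, in percent-signal-change units. Default 1 (i.e. 1% of the mean
#'   signal, typical of resting-state ROI series).
#' @param thermal_sigma standard deviation of additive thermal noise in
#'   scanner units (voxel-level synthesis only).
#' @param seed RNG seed; the same seed yields the same standardized draws for
#'   every bold_fraction, so mixtures are comparable.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_rois = 50L, n_t = 500L,
                       echo_times = c(13.9, 31.7, 49.5),
                       bold_fraction = 0.5,
                       network_covariance = NULL,
                       spc_sigma = 1,
                       thermal_sigma = 0,
                       seed = 1L) {
  if (!is_count(n_rois) || n_rois < 2) pq_stop("sim", "n_rois must be an integer >= 2")
  if (!is_count(n_t) || n_t < 2) pq_stop("sim", "n_t must be an integer >= 2")
  echo_times <- check_echo_times(echo_times, "sim")
  if (!is.numeric(bold_fraction) || bold_fraction < 0 || bold_fraction > 1)
    pq_stop("sim", "bold_fraction must lie in [0, 1]")
  if (is.null(network_covariance))
    network_covariance <- default_network_covariance(n_rois)
  if (!isSymmetric(structure(network_covariance, dimnames = NULL), tol = 1e-10))
    pq_stop("sim", "network_covariance must be symmetric")
  ev <- eigen(network_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    pq_stop("sim", "network_covariance must be positive semidefinite")
  if (thermal_sigma < 0) pq_stop("sim", "thermal_sigma must be >= 0")
  if (spc_sigma <= 0) pq_stop("sim", "spc_sigma must be > 0")
  structure(list(n_rois = as.integer(n_rois), n_t = as.integer(n_t),
                 echo_times = echo_times, bold_fraction = bold_fraction,
                 network_covariance = network_covariance,
                 spc_sigma = spc_sigma, thermal_sigma = thermal_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default block-structured network covariance
#'
#' Five (or \code{n_blocks}) equal-size diagonal blocks with within-block
#' covariance \code{within} and zero between blocks; unit diagonal.
#'
#' @param n_rois number of ROIs.
#' @param n_blocks number of networks (default 5).
#' @param within within-block off-diagonal covariance (default 0.8).
#' @return An \code{n_rois} x \code{n_rois} PSD matrix.
#' @export
default_network_covariance <- function(n_rois, n_blocks = 5L, within = 0.8) {
  block <- rep(seq_len(n_blocks), length.out = n_rois)
  block <- sort(block)
  sigma <- outer(block, block, function(a, b) ifelse(a == b, within, 0))
  diag(sigma) <- 1
  sigma
}

## PSD square root via eigendecomposition (tolerates semidefinite inputs,
## unlike chol); deterministic.
psd_factor <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

## Reference echo: the second TE (BOLD weighting is TE-dependent and scan
## quality is conventionally reported at the middle echo).
te_ref <- function(echo_times) echo_times[2L]

#' Simulate ROI-level fluctuation sources
#'
#' Draws delta_rho (dimensionless, fractional) and delta_r2s (1/ms) as
#' mutually independent zero-mean Gaussian processes, each with inter-ROI
#' covariance proportional to the configured network covariance. Variances
#' are scaled so that at the reference echo,
#' var(delta_r2s * TE_ref) / [var(delta_r2s * TE_ref) + var(delta_rho)]
#' equals \code{bold_fraction} for every ROI. The standardized draws depend
#' only on the seed and dimensions, so runs differing only in
#' \code{bold_fraction} share the same underlying noise.
#'
#' @param config a \code{sim_config}.
#' @return An object of class \code{fluctuation_series}: list with matrices
#'   \code{delta_r2s} and \code{delta_rho} (N_rois x N_t) plus the config.
#' @export
simulate_fluctuations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- psd_factor(config$network_covariance)
  z_rho <- matrix(stats::rnorm(config$n_rois * config$n_t), config$n_rois)
  z_r2s <- matrix(stats::rnorm(config$n_rois * config$n_t), config$n_rois)
  f <- config$bold_fraction
  s_frac <- config$spc_sigma / 100                 # percent -> fractional
  delta_rho <- sqrt(1 - f) * s_frac * (L %*% z_rho)
  delta_r2s <- sqrt(f) * (s_frac / te_ref(config$echo_times)) * (L %*% z_r2s)
  structure(list(delta_r2s = delta_r2s, delta_rho = delta_rho, config = config),
            class = "fluctuation_series")
}

#' Synthesize ROI-level percent-signal-change series (linearized model)
#'
#' Applies the linearized multi-echo signal model: at echo i,
#' S_x,i(t) = delta_rho_x(t) - delta_r2s_x(t) * TE_i, expressed in percent
#' units (x100). No noise term.
#'
#' @param fluct a \code{fluctuation_series}.
#' @param echo_times echo times in ms (defaults to the generating config's).
#' @return An \code{roi_ts_set} with \code{units = "spc"}.
#' @export
synthesize_roi_spc <- function(fluct, echo_times = NULL) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  echo_times <- check_echo_times(echo_times %||% fluct$config$echo_times, "sim")
  values <- lapply(echo_times, function(te) {
    m <- 100 * (fluct$delta_rho - fluct$delta_r2s * te)
    m - rowMeans(m)                                # exact zero-mean spc rows
  })
  roi_ts_set(values, echo_times, units = "spc")
}

#' Synthesize a full voxel-level multi-echo scan (nonlinear model)
#'
#' Evaluates S = S0_bar * (1 + delta_rho) * exp(-(R2s_bar + delta_r2s) * TE_i)
#' + n per voxel and timepoint, with i.i.d. Gaussian thermal noise of sd
#' \code{thermal_sigma} added everywhere (including outside the object, where
#' S0_bar = 0). Voxels are tied to ROI fluctuation rows through
#' \code{roi_map}; voxels labeled 0 carry no fluctuation.
#'
#' @param baseline list with 3D arrays \code{s0_bar} (>= 0, arbitrary units)
#'   and \code{r2s_bar} (1/ms, > 0 inside the object).
#' @param fluct a \code{fluctuation_series}.
#' @param roi_map 3D integer array on the baseline grid; value r > 0 assigns
#'   the voxel to fluctuation row r, 0 means background.
#' @param echo_times echo times in ms.
#' @param thermal_sigma Gaussian noise sd (scanner units).
#' @param seed RNG seed for the noise.
#' @param affine voxel-to-world matrix for the resulting scan.
#' @return An \code{me_scan} (mask = object support, i.e. s0_bar > 0).
#' @export
synthesize_voxel_scan <- function(baseline, fluct, roi_map, echo_times,
                                  thermal_sigma = 0, seed = 1L,
                                  affine = diag(4)) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  echo_times <- check_echo_times(echo_times, "sim")
  s0 <- baseline$s0_bar
  r2s <- baseline$r2s_bar
  gdim <- dim(s0)
  if (!identical(dim(r2s), gdim) || !identical(dim(roi_map), gdim))
    pq_stop("sim", "baseline grids and roi_map must share dimensions")
  if (any(s0 < 0)) pq_stop("sim", "s0_bar must be non-negative")
  n_t <- ncol(fluct$delta_rho)
  labs <- as.integer(roi_map)
  if (max(labs) > nrow(fluct$delta_rho))
    pq_stop("sim", "roi_map labels exceed number of fluctuation rows")
  n_vox <- prod(gdim)
  ## per-voxel fluctuation series (background rows are zero)
  rho_v <- matrix(0, n_vox, n_t)
  dr2_v <- matrix(0, n_vox, n_t)
  inroi <- labs > 0L
  rho_v[inroi, ] <- fluct$delta_rho[labs[inroi], , drop = FALSE]
  dr2_v[inroi, ] <- fluct$delta_r2s[labs[inroi], , drop = FALSE]
  r2s_t <- as.vector(r2s) + dr2_v
  bad <- which(inroi & as.vector(r2s) > 0 & apply(r2s_t, 1, min) <= 0)
  if (length(bad))
    pq_stop("sim", "fluctuations drive R2* non-positive at voxel(s) ",
            paste(utils::head(bad, 3), collapse = ", "),
            " — reduce fluctuation amplitude")
  set.seed(seed)
  vols <- lapply(echo_times, function(te) {
    s <- as.vector(s0) * (1 + rho_v) * exp(-r2s_t * te)
    if (thermal_sigma > 0)
      s <- s + matrix(stats::rnorm(n_vox * n_t, sd = thermal_sigma), n_vox, n_t)
    array(s, dim = c(gdim, n_t))
  })
  me_scan(vols, echo_times, mask = array(s0 > 0, gdim), affine = affine)
}

#' Emulate irregular-TR (cardiac-gated) saturation fluctuations
#'
#' Cardiac gating makes the repetition time irregular, which modulates the
#' steady-state longitudinal magnetization and injects TE-independent S_o
#' fluctuations. This adds to delta_rho the relative steady-state change
#' (1 - exp(-TR_t/T1)) / (1 - exp(-TR_nom/T1)) - 1 for each timepoint, where
#' TR_t = nominal_tr + tr_offsets[t]; identical across echoes by
#' construction. A single-compartment saturation emulation, not a full Bloch
#' simulation.
#'
#' @param fluct a \code{fluctuation_series}.
#' @param tr_offsets per-timepoint TR deviation from nominal, in seconds
#'   (may include +Inf = fully relaxed).
#' @param t1 longitudinal relaxation time in seconds (default 1.4, gray
#'   matter at 3T).
#' @param nominal_tr nominal repetition time in seconds (default 2.5).
#' @return The modified \code{fluctuation_series}.
#' @export
apply_tr_jitter <- function(fluct, tr_offsets, t1 = 1.4, nominal_tr = 2.5) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  if (t1 <= 0) pq_stop("sim", "T1 must be positive")
  if (nominal_tr <= 0) pq_stop("sim", "nominal TR must be positive")
  n_t <- ncol(fluct$delta_rho)
  if (length(tr_offsets) != n_t)
    pq_stop("sim", "tr_offsets must have one entry per timepoint (", n_t, ")")
  tr_t <- nominal_tr + tr_offsets
  if (any(tr_t <= 0)) pq_stop("sim", "effective TR must stay positive")
  denom <- 1 - exp(-nominal_tr / t1)
  sat <- (1 - exp(-tr_t / t1)) / denom - 1
  fluct$delta_rho <- fluct$delta_rho +
    matrix(sat, nrow(fluct$delta_rho), n_t, byrow = TRUE)
  fluct
}

#' Generate an object-free background scan
#'
#' Produces a multi-echo scan containing only noise, for exercising the
#' thermal-noise estimator and its voxel-exclusion rules. Values are
#' Gaussian(0, sigma) per voxel/timepoint/echo, folded to |.| when
#' \code{folded = TRUE} (magnitude-image background), with a controllable
#' fraction of exact-zero timepoints per voxel.
#'
#' @param grid_dim 3 integers.
#' @param n_t number of timepoints.
#' @param sigma Gaussian sd (scanner units), >= 0.
#' @param zero_fraction probability that any voxel/timepoint is set to
#'   exactly 0 (independently, per echo).
#' @param seed RNG seed.
#' @param echo_times echo times in ms.
#' @param folded take absolute values (default TRUE).
#' @return An \code{me_scan} with no mask.
#' @export
generate_background_fixture <- function(grid_dim = c(12L, 12L, 12L), n_t = 100L,
                                        sigma = 1, zero_fraction = 0,
                                        seed = 1L,
                                        echo_times = c(13.9, 31.7, 49.5),
                                        folded = TRUE) {
  if (sigma < 0) pq_stop("sim", "sigma must be >= 0")
  if (zero_fraction < 0 || zero_fraction > 1)
    pq_stop("sim", "zero_fraction must lie in [0, 1]")
  set.seed(seed)
  n <- prod(grid_dim) * n_t
  vols <- lapply(seq_along(echo_times), function(e) {
    x <- stats::rnorm(n, sd = sigma)
    if (folded) x <- abs(x)
    if (zero_fraction > 0)
      x[stats::runif(n) < zero_fraction] <- 0
    array(x, dim = c(grid_dim, n_t))
  })
  me_scan(vols, echo_times)
}

#' Simulate a complete voxel-level dataset on disk
#'
#' Builds a cubic-ROI phantom (each ROI a cube of side \code{roi_side} on a
#' lattice with a background border), synthesizes the nonlinear voxel-level
#' scan, and writes one 4D NIfTI per echo, a labeled atlas, a mask and a
#' ground-truth JSON to \code{out_dir}. Baseline: S0_bar = 1000 inside the
#' object, R2*_bar = 1/40 per ms (T2* = 40 ms, cortical gray matter at 3T).
#'
#' @param config a \code{sim_config}.
#' @param out_dir output directory.
#' @param roi_side cube edge length in voxels (default 2).
#' @param tr_offsets optional per-timepoint TR offsets (s) passed to
#'   \code{\link{apply_tr_jitter}}.
#' @return Invisibly, a list with the written paths and the ground truth.
#' @export
simulate_voxel_dataset <- function(config, out_dir, roi_side = 2L,
                                   tr_offsets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_rois <- config$n_rois
  per_axis <- ceiling(n_rois^(1 / 3))
  gdim <- rep(per_axis * (roi_side + 1L) + 1L, 3L)
  roi_map <- array(0L, gdim)
  k <- 0L
  for (iz in seq_len(per_axis)) for (iy in seq_len(per_axis)) for (ix in seq_len(per_axis)) {
    if (k >= n_rois) break
    k <- k + 1L
    ox <- 1L + (ix - 1L) * (roi_side + 1L)
    oy <- 1L + (iy - 1L) * (roi_side + 1L)
    oz <- 1L + (iz - 1L) * (roi_side + 1L)
    roi_map[ox + seq_len(roi_side), oy + seq_len(roi_side), oz + seq_len(roi_side)] <- k
  }
  s0 <- array(0, gdim); s0[roi_map > 0L] <- 1000
  r2s <- array(1 / 40, gdim)
  baseline <- list(s0_bar = s0, r2s_bar = r2s)
  fluct <- simulate_fluctuations(config)
  if (!is.null(tr_offsets)) fluct <- apply_tr_jitter(fluct, tr_offsets)
  scan <- synthesize_voxel_scan(baseline, fluct, roi_map, config$echo_times,
                                thermal_sigma = config$thermal_sigma,
                                seed = config$seed + 1L)
  affine <- diag(c(3, 3, 3, 1))                    # 3 mm isotropic
  echo_paths <- file.path(out_dir, sprintf("echo-%02d.nii.gz", seq_along(config$echo_times)))
  for (i in seq_along(echo_paths))
    write_nifti(scan$data[[i]], echo_paths[i], affine = affine)
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_nifti(array(as.numeric(roi_map), gdim), atlas_path, affine = affine)
  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_nifti(array(as.numeric(s0 > 0), gdim), mask_path, affine = affine)
  truth <- list(tool = "pboldqa",
                version = as.character(utils::packageVersion("pboldqa")),
                seed = config$seed,
                bold_fraction = config$bold_fraction,
                n_rois = n_rois, n_t = config$n_t,
                echo_times_ms = config$echo_times,
                spc_sigma = config$spc_sigma,
                thermal_sigma = config$thermal_sigma,
                grid_dim = gdim, roi_side = roi_side,
                tr_jitter = !is.null(tr_offsets))
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(echo_paths = echo_paths, atlas_path = atlas_path,
                 mask_path = mask_path, truth_path = truth_path, truth = truth,
                 roi_map = roi_map))
}
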