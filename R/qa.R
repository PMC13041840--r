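## Companion QA metrics: TSNR and background thermal-noise estimation.

#' Temporal signal-to-noise ratio for one echo
#'
#' Voxel-wise TSNR = temporal mean / temporal standard deviation (sample sd,
#' Nt - 1 denominator). When the input is a residual volume from which the
#' mean was regressed out, supply \code{mean_to_reintroduce}: that 3D mean is
#' added back to every timepoint first, so TSNR is always computed on
#' detrended-but-mean-bearing data. The scan summary is the median over
#' in-mask voxels with finite TSNR; zero-variance voxels are undefined and
#' excluded from the median, with their count reported.
#'
#' @param data 4D numeric array (one echo).
#' @param mask 3D binary array, or NULL for all voxels.
#' @param mean_to_reintroduce optional 3D array added to every timepoint.
#' @return An object of class \code{tsnr_summary}: \code{map} (3D TSNR, NA
#'   where undefined), \code{median} over the mask, \code{n_undefined},
#'   \code{mask_provenance}.
#' @export
tsnr <- function(data, mask = NULL, mean_to_reintroduce = NULL) {
  d <- dim(data)
  if (length(d) != 4L) pq_stop("qa", "tsnr expects a 4D array")
  if (d[4L] < 2L) pq_stop("qa", "need Nt >= 2 for TSNR")
  n_vox <- prod(d[1:3])
  m <- matrix(data, n_vox, d[4L])
  if (!is.null(mean_to_reintroduce)) {
    if (!identical(dim(mean_to_reintroduce), d[1:3]))
      pq_stop("qa", "mean_to_reintroduce grid does not match data grid")
    m <- m + as.vector(mean_to_reintroduce)
  }
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (d[4L] - 1L))
  map <- mu / sdv
  map[sdv == 0] <- NA_real_
  if (is.null(mask)) {
    sel <- rep(TRUE, n_vox)
    prov <- "all voxels"
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
      pq_stop("qa", "mask grid does not match data grid")
    sel <- as.logical(mask != 0)
    prov <- "user mask"
  }
  vals <- map[sel]
  n_undef <- sum(!is.finite(vals))
  if (n_undef > 0)
    pq_log("qa", n_undef, " in-mask voxel(s) with zero temporal variance excluded from TSNR median",
           level = "WARN")
  structure(list(map = array(map, d[1:3]),
                 median = stats::median(vals[is.finite(vals)]),
                 n_undefined = n_undef, mask_provenance = prov),
            class = "tsnr_summary")
}

#' @export
print.tsnr_summary <- function(x, ...) {
  cat(sprintf("tsnr_summary: median = %.2f over %s (%d undefined voxel(s))\n",
              x$median, x$mask_provenance, x$n_undefined))
  invisible(x)
}

#' Estimate thermal noise from background voxels
#'
#' Approximates the thermal-noise level of an unprocessed scan as the
#' spatial standard deviation over object- and ghosting-free voxels.
#' Background voxels are those with temporal mean at most
#' \code{bg_mean_max} in every echo, excluding voxels whose count of
#' exactly-zero timepoints exceeds \code{max_zero_count} in any echo. Per
#' echo, sigma is the spatial sd across background voxels computed per
#' volume (timepoint) and then averaged over time — robust to slow drifts.
#'
#' @param scan an \code{me_scan} of raw (unprocessed) data.
#' @param bg_mean_max background mean-signal ceiling in scanner units
#'   (default 2; scanner-unit dependent).
#' @param max_zero_count maximum tolerated number of exactly-zero timepoints
#'   per voxel (default 20; an absolute count, so revisit for very long or
#'   short runs).
#' @return An object of class \code{thermal_noise_estimate}: per-echo
#'   \code{sigma}, \code{n_background} voxels used, and exclusion counts.
#' @export
estimate_thermal_noise <- function(scan, bg_mean_max = 2, max_zero_count = 20) {
  stopifnot(inherits(scan, "me_scan"))
  d <- scan$dim
  n_vox <- prod(d[1:3])
  mats <- lapply(scan$data, function(v) matrix(v, n_vox, d[4L]))
  means <- vapply(mats, rowMeans, numeric(n_vox))            # n_vox x n_echo
  zeros <- vapply(mats, function(m) rowSums(m == 0), numeric(n_vox))
  low_mean <- rowSums(means <= bg_mean_max) == length(mats)  # all echoes
  few_zeros <- rowSums(zeros > max_zero_count) == 0          # no echo over
  bg <- low_mean & few_zeros
  n_excl_mean <- sum(!low_mean)
  n_excl_zero <- sum(low_mean & !few_zeros)
  if (!any(bg))
    pq_stop("qa", "no object-free voxels; is this a skull-stripped or masked image?")
  sigma <- vapply(mats, function(m) {
    mean(apply(m[bg, , drop = FALSE], 2, stats::sd))
  }, numeric(1))
  structure(list(sigma = sigma, echo_times = scan$echo_times,
                 n_background = sum(bg),
                 n_excluded_mean_rule = n_excl_mean,
                 n_excluded_zero_rule = n_excl_zero,
                 bg_mean_max = bg_mean_max, max_zero_count = max_zero_count,
                 background = bg),
            class = "thermal_noise_estimate")
}

#' @export
print.thermal_noise_estimate <- function(x, ...) {
  cat(sprintf("thermal_noise_estimate: sigma = %s (TE = %s ms), %d background voxels\n",
              paste(sprintf("%.3f", x$sigma), collapse = "/"),
              paste(x$echo_times, collapse = "/"), x$n_background))
  cat(sprintf("excluded: %d by mean-signal rule (> %g), %d by zero-count rule (> %d zeros)\n",
              x$n_excluded_mean_rule, x$bg_mean_max,
              x$n_excluded_zero_rule, x$max_zero_count))
  invisible(x)
}
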