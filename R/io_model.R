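## Multi-echo scan container, parcellation handling, ROI extraction, reports.

#' Construct a multi-echo scan object
#'
#' Bundles one 4D intensity array per echo with the echo times (ms), an
#' optional repetition time (s), an optional binary brain mask and the
#' voxel-to-world affine. All echoes must share the same spatial grid and
#' number of timepoints.
#'
#' @param data list of 4D numeric arrays (x, y, z, t), one per echo.
#' @param echo_times numeric vector of echo times in ms, strictly increasing.
#' @param tr nominal repetition time in seconds, or NULL.
#' @param mask 3D logical/numeric array marking in-brain voxels, or NULL.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return An object of class \code{me_scan}.
#' @export
me_scan <- function(data, echo_times, tr = NULL, mask = NULL, affine = diag(4)) {
  if (!is.list(data) || length(data) < 2L)
    pq_stop("io", "p_BOLD requires >= 2 echoes")
  echo_times <- check_echo_times(echo_times)
  if (length(data) != length(echo_times))
    pq_stop("io", "number of echo volumes (", length(data),
            ") does not match number of echo times (", length(echo_times), ")")
  dims <- lapply(data, dim)
  for (i in seq_along(data)) {
    if (length(dims[[i]]) != 4L)
      pq_stop("io", "echo ", i, " is not a 4D array")
    if (!identical(dims[[i]], dims[[1L]]))
      pq_stop("io", "shape mismatch: echo ", i, " has dim ",
              paste(dims[[i]], collapse = "x"), " but echo 1 has ",
              paste(dims[[1L]], collapse = "x"))
  }
  if (dims[[1L]][4L] < 2L) pq_stop("io", "need at least 2 timepoints (Nt >= 2)")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims[[1L]][1:3]))
      pq_stop("io", "mask grid does not match scan grid")
    mask <- array(as.logical(mask != 0), dim = dims[[1L]][1:3])
  }
  structure(list(data = data, echo_times = echo_times, tr = tr, mask = mask,
                 affine = affine, dim = dims[[1L]]),
            class = "me_scan")
}

#' @export
print.me_scan <- function(x, ...) {
  cat(sprintf("me_scan: %d echoes (TE = %s ms), grid %s, Nt = %d, mask: %s\n",
              length(x$data), paste(x$echo_times, collapse = "/"),
              paste(x$dim[1:3], collapse = "x"), x$dim[4L],
              if (is.null(x$mask)) "none" else sprintf("%d voxels", sum(x$mask))))
  invisible(x)
}

#' Load a multi-echo scan from per-echo NIfTI files
#'
#' Reads one 4D NIfTI per echo and validates grid consistency. Echo times
#' supplied out of order are sorted ascending (together with their files),
#' with a warning.
#'
#' @param paths character vector of NIfTI paths, one per echo (>= 2).
#' @param echo_times echo times in ms, same length as \code{paths}.
#' @param mask_path optional path to a 3D binary mask NIfTI.
#' @param tr nominal repetition time in seconds (optional).
#' @return An \code{me_scan}.
#' @export
load_me_scan <- function(paths, echo_times, mask_path = NULL, tr = NULL) {
  if (length(paths) < 2L) pq_stop("io", "p_BOLD requires >= 2 echoes")
  if (length(paths) != length(echo_times))
    pq_stop("io", "one echo time per file required")
  if (is.unsorted(echo_times, strictly = TRUE)) {
    pq_log("io", "echo times supplied out of order; sorting ascending", level = "WARN")
    pq_warn("io", "echo times supplied out of order; echoes re-sorted to ascending TE")
    ord <- order(echo_times)
    paths <- paths[ord]
    echo_times <- echo_times[ord]
  }
  vols <- vector("list", length(paths))
  affine <- NULL
  for (i in seq_along(paths)) {
    nii <- read_nifti(paths[i])
    if (length(nii$dim) != 4L)
      pq_stop("io", "not a 4D NIfTI: ", paths[i])
    if (i > 1L && !identical(nii$dim, dim(vols[[1L]])))
      pq_stop("io", "shape mismatch across echoes at file: ", paths[i])
    vols[[i]] <- nii$data
    if (is.null(affine)) affine <- nii$affine
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mnii <- read_nifti(mask_path)
    if (!identical(as.integer(mnii$dim[1:3]), as.integer(dim(vols[[1L]])[1:3])))
      pq_stop("io", "mask grid does not match scan grid: ", mask_path)
    mask <- mnii$data != 0
    dim(mask) <- dim(vols[[1L]])[1:3]
  }
  me_scan(vols, echo_times, tr = tr, mask = mask, affine = affine)
}

#' Load a brain parcellation
#'
#' Accepts either an integer-labeled atlas NIfTI on the scan grid, or a table
#' of spheres (columns \code{label}, \code{x_mm}, \code{y_mm}, \code{z_mm},
#' \code{radius_mm}) rasterized through the scan affine: a voxel belongs to a
#' sphere when its center lies within the radius. Spheres landing entirely
#' outside the grid produce ROIs with empty voxel sets (and a warning); such
#' ROIs are removed later by the coverage filter.
#'
#' @param source path to an atlas NIfTI, or a data.frame/TSV path with the
#'   sphere columns above.
#' @param grid an \code{me_scan}, or a list with elements \code{dim} (3 ints)
#'   and \code{affine} (4x4).
#' @return An object of class \code{parcellation} with fields \code{roi_ids},
#'   \code{voxels} (list of linear voxel indices per ROI) and \code{coverage}
#'   (filled by \code{\link{filter_rois_by_coverage}}).
#' @export
load_parcellation <- function(source, grid) {
  if (inherits(grid, "me_scan")) grid <- list(dim = grid$dim[1:3], affine = grid$affine)
  gdim <- as.integer(grid$dim[1:3])
  if (is.character(source) && length(source) == 1L && grepl("\\.nii(\\.gz)?$", source)) {
    nii <- read_nifti(source)
    if (!identical(as.integer(nii$dim[1:3]), gdim))
      pq_stop("io", "atlas grid ", paste(nii$dim[1:3], collapse = "x"),
              " does not match scan grid ", paste(gdim, collapse = "x"))
    labs <- round(nii$data)
    ids <- sort(unique(labs[labs != 0]))
    voxels <- lapply(ids, function(id) which(labs == id))
    names(voxels) <- as.character(ids)
    return(new_parcellation(as.integer(ids), voxels, gdim))
  }
  tab <- if (is.data.frame(source)) source else
    utils::read.table(source, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm", "radius_mm")
  if (!all(need %in% names(tab)))
    pq_stop("io", "sphere table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$label)) pq_stop("io", "duplicate ROI labels in sphere table")
  ## world coordinates of every voxel center (0-based indices through affine)
  ijk <- as.matrix(expand.grid(i = 0:(gdim[1] - 1L), j = 0:(gdim[2] - 1L),
                               k = 0:(gdim[3] - 1L)))
  world <- ijk %*% t(grid$affine[1:3, 1:3]) +
    matrix(grid$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
  voxels <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    d2 <- (world[, 1] - tab$x_mm[r])^2 + (world[, 2] - tab$y_mm[r])^2 +
      (world[, 3] - tab$z_mm[r])^2
    voxels[[r]] <- which(d2 <= tab$radius_mm[r]^2 + 1e-9)
    if (length(voxels[[r]]) == 0L)
      pq_warn("io", "ROI ", tab$label[r], ": sphere rasterized to an empty voxel set")
  }
  names(voxels) <- as.character(tab$label)
  new_parcellation(as.integer(tab$label), voxels, gdim)
}

new_parcellation <- function(roi_ids, voxels, gdim, coverage = NULL) {
  n_vox <- prod(gdim)
  for (v in voxels)
    if (length(v) && (min(v) < 1L || max(v) > n_vox))
      pq_stop("io", "voxel index outside the grid")
  structure(list(roi_ids = roi_ids, voxels = voxels, dim = gdim,
                 coverage = coverage), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d ROIs on grid %s%s\n", length(x$roi_ids),
              paste(x$dim, collapse = "x"),
              if (is.null(x$coverage)) "" else " (coverage-filtered)"))
  invisible(x)
}

#' Filter ROIs by field-of-view coverage
#'
#' Retains ROIs with at least \code{threshold} of their voxels inside the
#' mask (boundary inclusive: coverage equal to the threshold is kept).
#' Dropped labels are reported; if nothing survives, an error is raised.
#'
#' @param parcellation a \code{parcellation}.
#' @param mask 3D binary array on the same grid.
#' @param threshold minimum in-mask fraction, default 0.95.
#' @return The filtered \code{parcellation}, with \code{coverage} populated.
#' @export
filter_rois_by_coverage <- function(parcellation, mask, threshold = 0.95) {
  if (!inherits(parcellation, "parcellation")) pq_stop("io", "not a parcellation")
  if (!identical(as.integer(dim(mask)), as.integer(parcellation$dim)))
    pq_stop("io", "mask grid does not match parcellation grid")
  mvec <- as.logical(mask != 0)
  cov <- vapply(parcellation$voxels, function(v) {
    if (length(v) == 0L) return(0)
    mean(mvec[v])
  }, numeric(1))
  keep <- cov >= threshold
  if (!any(keep)) pq_stop("io", "no ROI survives coverage filter")
  if (any(!keep))
    pq_log("io", "coverage filter dropped ", sum(!keep), " ROI(s): ",
           paste(parcellation$roi_ids[!keep], collapse = ", "), level = "WARN")
  new_parcellation(parcellation$roi_ids[keep], parcellation$voxels[keep],
                   parcellation$dim, coverage = cov[keep])
}

#' Extract ROI-mean timeseries per echo
#'
#' For each echo and each ROI, the representative timeseries is the unweighted
#' spatial mean over the ROI's voxels at each timepoint.
#'
#' @param scan an \code{me_scan}.
#' @param parcellation a coverage-filtered \code{parcellation}; every ROI must
#'   have a non-empty voxel set.
#' @return An object of class \code{roi_ts_set} with \code{units = "raw"}:
#'   a list of per-echo N_r x Nt matrices plus echo times and ROI ids.
#' @export
extract_roi_timeseries <- function(scan, parcellation) {
  if (!inherits(scan, "me_scan")) pq_stop("io", "not an me_scan")
  if (!inherits(parcellation, "parcellation")) pq_stop("io", "not a parcellation")
  if (!identical(as.integer(parcellation$dim), as.integer(scan$dim[1:3])))
    pq_stop("io", "parcellation grid does not match scan grid")
  empty <- lengths(parcellation$voxels) == 0L
  if (any(empty))
    pq_stop("io", "empty ROI(s): ", paste(parcellation$roi_ids[empty], collapse = ", "),
            " (run filter_rois_by_coverage first)")
  n_vox <- prod(scan$dim[1:3])
  nt <- scan$dim[4L]
  values <- lapply(scan$data, function(vol) {
    m <- matrix(vol, nrow = n_vox, ncol = nt)
    out <- t(vapply(parcellation$voxels, function(v) {
      if (length(v) == 1L) m[v, ] else colMeans(m[v, , drop = FALSE])
    }, numeric(nt)))
    rownames(out) <- as.character(parcellation$roi_ids)
    out
  })
  roi_ts_set(values, scan$echo_times, parcellation$roi_ids, units = "raw")
}

#' Construct an ROI timeseries set
#'
#' @param values list of per-echo N_r x Nt matrices.
#' @param echo_times echo times in ms.
#' @param roi_ids integer ROI labels.
#' @param units "raw" (scanner units) or "spc" (percent signal change; rows
#'   have temporal mean ~0).
#' @return An object of class \code{roi_ts_set}.
#' @export
roi_ts_set <- function(values, echo_times, roi_ids = NULL, units = c("raw", "spc")) {
  units <- match.arg(units)
  echo_times <- check_echo_times(echo_times, "fc")
  if (!is.list(values) || length(values) != length(echo_times))
    pq_stop("fc", "one matrix per echo required")
  d1 <- dim(values[[1L]])
  for (v in values)
    if (!is.matrix(v) || !identical(dim(v), d1))
      pq_stop("fc", "all echo matrices must share N_r x Nt shape")
  roi_ids <- roi_ids %||% seq_len(d1[1L])
  if (units == "spc") {
    for (v in values) {
      mu <- rowMeans(v)
      scale <- pmax(apply(v, 1, stats::sd), .Machine$double.eps)
      if (any(abs(mu) > 1e-10 * pmax(scale, 1)))
        pq_stop("fc", "spc rows must have temporal mean ~0")
    }
  }
  structure(list(values = values, echo_times = echo_times,
                 roi_ids = roi_ids, units = units, n_rois = d1[1L], n_t = d1[2L]),
            class = "roi_ts_set")
}

#' @export
print.roi_ts_set <- function(x, ...) {
  cat(sprintf("roi_ts_set: %d ROIs x %d timepoints, %d echoes (TE = %s ms), units = %s\n",
              x$n_rois, x$n_t, length(x$echo_times),
              paste(x$echo_times, collapse = "/"), x$units))
  invisible(x)
}

#' Write the QA report
#'
#' Writes a machine-readable scan summary (JSON, full precision) with a TSV
#' mirror of the per-quadruple breakdown, and optionally a per-quadruple edge
#' table (requires \code{scan_pbold(..., keep_edges = TRUE)}).
#'
#' @param result a \code{pbold_result}.
#' @param aux optional named list merged into the summary (e.g. TSNR medians,
#'   thermal-noise estimates, seed, config).
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the named vector of files written.
#' @export
write_report <- function(result, aux = NULL, out_dir) {
  if (!inherits(result, "pbold_result")) pq_stop("io", "not a pbold_result")
  if (!is.character(out_dir) || length(out_dir) != 1L || !nzchar(out_dir))
    pq_stop("io", "out_dir must be a non-empty directory path")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) pq_stop("io", "cannot create output directory: ", out_dir)
  }
  summary <- c(list(
    tool = "pboldqa",
    version = as.character(utils::packageVersion("pboldqa")),
    p_bold = result$p_bold,
    n_rois = result$n_rois,
    echo_times_ms = result$te_list,
    delta = result$delta,
    chord_radius = result$chord_radius,
    n_quadruples = nrow(result$per_quadruple),
    n_undefined_quadruples = sum(is.na(result$per_quadruple$p_bold)),
    per_quadruple = result$per_quadruple
  ), aux)
  json_path <- file.path(out_dir, "pbold_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  tsv_path <- file.path(out_dir, "pbold_quadruples.tsv")
  utils::write.table(result$per_quadruple, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(summary = json_path, quadruples = tsv_path)
  if (!is.null(result$edges)) {
    edge_path <- file.path(out_dir, "pbold_edges.tsv")
    utils::write.table(result$edges, edge_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, edges = edge_path)
  }
  invisible(files)
}
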