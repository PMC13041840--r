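## The p_BOLD metric.
##
## For a quadruple of echo-time pairs ((TE_i,TE_j),(TE_k,TE_l)), each edge
## (x, y) of the parcellation is plotted as the point
## (C[x,y; TE_i,TE_j], C[x,y; TE_k,TE_l]) of across-echo covariances.
## S_o-dominated edges fall on the identity line; BOLD-dominated edges fall
## on the zero-intercept line of slope m = TE_k*TE_l / (TE_i*TE_j). Each
## edge is labelled by which line it sits closer to (with a tie tolerance
## delta), weighted by its distance to the origin, averaged within the
## quadruple, and the quadruples are averaged with chord-distance weights
## 2*R*sin(theta/2) reflecting how separable the two lines are.

#' Enumerate echo-time quadruples
#'
#' Pairs are all unordered echo pairs with repetition (P = Ne(Ne+1)/2);
#' quadruples are all unordered combinations of two distinct pairs
#' (P(P-1)/2), so 3 echoes give 15 quadruples. Within each quadruple the
#' pair with the smaller TE product is placed on the x-axis, making the BOLD
#' slope m >= 1; the per-edge geometry is invariant to this choice.
#'
#' @param echo_times echo times in ms (>= 2).
#' @param chord_radius radius R of the chord-distance circle (default 0.5).
#' @return A data.frame with one row per quadruple: echo indices
#'   \code{ix_i, ix_j, ix_k, ix_l}, TEs \code{te_i, te_j, te_k, te_l},
#'   slope \code{m}, angle \code{theta} (radians), and \code{chord}.
#' @export
enumerate_quadruples <- function(echo_times, chord_radius = 0.5) {
  echo_times <- check_echo_times(echo_times, "pbold")
  ne <- length(echo_times)
  pairs <- do.call(rbind, lapply(seq_len(ne), function(a)
    cbind(a = a, b = a:ne)))
  np <- nrow(pairs)
  combos <- utils::combn(np, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(q) {
    p1 <- pairs[combos[1L, q], ]
    p2 <- pairs[combos[2L, q], ]
    prod1 <- echo_times[p1[["a"]]] * echo_times[p1[["b"]]]
    prod2 <- echo_times[p2[["a"]]] * echo_times[p2[["b"]]]
    if (prod2 < prod1) { tmp <- p1; p1 <- p2; p2 <- tmp }
    m <- (echo_times[p2[["a"]]] * echo_times[p2[["b"]]]) /
      (echo_times[p1[["a"]]] * echo_times[p1[["b"]]])
    theta <- abs(atan(m) - pi / 4)
    data.frame(ix_i = p1[["a"]], ix_j = p1[["b"]],
               ix_k = p2[["a"]], ix_l = p2[["b"]],
               te_i = echo_times[p1[["a"]]], te_j = echo_times[p1[["b"]]],
               te_k = echo_times[p2[["a"]]], te_l = echo_times[p2[["b"]]],
               m = m, theta = theta,
               chord = chord_distance(theta, chord_radius))
  })
  quads <- do.call(rbind, rows)
  quads$quadruple_id <- seq_len(nrow(quads))
  quads[, c("quadruple_id", setdiff(names(quads), "quadruple_id"))]
}

#' Chord distance between the BOLD and identity lines
#'
#' The length of the chord subtended by the angle theta between the two
#' lines on a circle of the given radius centered at the origin:
#' 2 * radius * sin(theta / 2).
#'
#' @param theta angle in radians, in [0, pi].
#' @param radius circle radius (default 0.5).
#' @return The chord length.
#' @export
chord_distance <- function(theta, radius = 0.5) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi))
    pq_stop("pbold", "theta must lie in [0, pi]")
  2 * radius * sin(theta / 2)
}

#' Per-edge geometry for one quadruple
#'
#' Takes the strictly upper triangles (roi_a < roi_b, diagonal excluded) of
#' the two covariance matrices as edge coordinates (a, b) and computes:
#' d_so = |a - b| / sqrt(2) (distance to the identity line),
#' d_bold = |m*a - b| / sqrt(m^2 + 1) (distance to the zero-intercept line of
#' slope m), the preference label, and the origin-distance weight
#' w = sqrt(a^2 + b^2).
#'
#' By default an edge prefers whichever line it is closer to: pref = 1 when
#' d_so - d_bold > delta, 0 when d_bold - d_so > delta, 0.5 when the two
#' distances agree within delta. \code{literal_eq14 = TRUE} applies the
#' orientation exactly as printed in the source formula (which labels edges
#' farther from the BOLD line as BOLD-preferring); it is provided for
#' comparison only and inverts the metric's meaning.
#'
#' @param fcm_x,fcm_y covariance \code{fc_matrix} objects for the x- and
#'   y-axis echo pairs (same N_r).
#' @param quad one row of \code{\link{enumerate_quadruples}} (or any list
#'   with element \code{m}).
#' @param delta tie tolerance in covariance (percent-spc squared) units,
#'   default 1e-3.
#' @param literal_eq14 use the literal printed labelling (default FALSE).
#' @return A data.frame with columns \code{roi_a, roi_b, fc_x, fc_y, d_so,
#'   d_bold, pref, weight}.
#' @export
edge_geometry <- function(fcm_x, fcm_y, quad, delta = 1e-3,
                          literal_eq14 = FALSE) {
  if (!identical(dim(fcm_x), dim(fcm_y)))
    pq_stop("pbold", "FC matrices differ in size")
  if (!is.null(attr(fcm_x, "estimator")) &&
      (attr(fcm_x, "estimator") != "covariance" ||
       attr(fcm_y, "estimator") != "covariance"))
    pq_stop("pbold", "edge geometry requires covariance FC matrices")
  n <- nrow(fcm_x)
  if (n < 2L) pq_stop("pbold", "need at least 2 ROIs")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # roi_a < roi_b
  a <- unclass(fcm_x)[ut]
  b <- unclass(fcm_y)[ut]
  m <- quad$m
  if (!is.finite(m) || m <= 0) pq_stop("pbold", "slope m must be positive")
  d_so <- abs(a - b) / sqrt(2)
  d_bold <- abs(m * a - b) / sqrt(m^2 + 1)
  if (literal_eq14) {
    pref <- ifelse(d_bold > d_so + delta, 1,
                   ifelse(d_bold < d_so + delta, 0, 0.5))
  } else {
    gap <- d_so - d_bold
    pref <- ifelse(gap > delta, 1, ifelse(gap < -delta, 0, 0.5))
  }
  data.frame(roi_a = ut[, 1L], roi_b = ut[, 2L], fc_x = a, fc_y = b,
             d_so = d_so, d_bold = d_bold, pref = pref,
             weight = sqrt(a^2 + b^2))
}

#' Quadruple-level p_BOLD
#'
#' Weighted mean of the edge preference labels, weighted by distance to the
#' origin. If every weight is zero the quadruple is undefined (NA, with a
#' warning); undefined quadruples are dropped from the scan-level average.
#'
#' @param edges data.frame from \code{\link{edge_geometry}}.
#' @return A value in [0, 1], or NA.
#' @export
quadruple_pbold <- function(edges) {
  if (nrow(edges) == 0L) pq_stop("pbold", "no edges")
  wsum <- sum(edges$weight)
  if (wsum == 0) {
    pq_warn("pbold", "all edge weights zero; quadruple p_BOLD undefined")
    return(NA_real_)
  }
  sum(edges$weight * edges$pref) / wsum
}

#' Scan-level p_BOLD
#'
#' Runs the full procedure on percent-signal-change ROI series: covariance
#' FC for every echo pair, per-edge geometry and preference for every
#' echo-time quadruple, origin-distance-weighted averaging within quadruples,
#' and chord-distance weighting across quadruples.
#'
#' @param ts an \code{roi_ts_set} with \code{units = "spc"} (>= 2 echoes,
#'   >= 2 ROIs, Nt >= 2).
#' @param delta tie tolerance (default 1e-3, covariance units on the percent
#'   scale; scale-dependent, see the vignette).
#' @param chord_radius chord circle radius R (default 0.5).
#' @param symmetrize average each cross-echo covariance with its transpose
#'   before taking the upper triangle (default FALSE: the raw asymmetric
#'   upper triangle is used).
#' @param literal_eq14 see \code{\link{edge_geometry}}.
#' @param keep_edges retain the per-quadruple edge tables in the result
#'   (default FALSE; can be large).
#' @return An object of class \code{pbold_result}: \code{p_bold} in [0, 1],
#'   the per-quadruple breakdown, and (optionally) the edge table.
#' @export
scan_pbold <- function(ts, delta = 1e-3, chord_radius = 0.5,
                       symmetrize = FALSE, literal_eq14 = FALSE,
                       keep_edges = FALSE) {
  stopifnot(inherits(ts, "roi_ts_set"))
  if (ts$units != "spc") pq_stop("pbold", "scan_pbold expects units = 'spc' (run to_spc)")
  if (ts$n_rois < 2L) pq_stop("pbold", "need at least 2 ROIs")
  quads <- enumerate_quadruples(ts$echo_times, chord_radius)
  ne <- length(ts$echo_times)
  ## cache covariance matrices for all unordered echo pairs
  cache <- list()
  get_cov <- function(a, b) {
    key <- paste(a, b)
    if (is.null(cache[[key]])) {
      m <- covariance_fc(ts, a, b)
      if (symmetrize) {
        sym <- (unclass(m) + t(unclass(m))) / 2
        m <- fc_matrix(sym, "covariance", attr(m, "te_pair"), attr(m, "n_t"))
      }
      cache[[key]] <<- m
    }
    cache[[key]]
  }
  p_q <- numeric(nrow(quads))
  n_edges <- integer(nrow(quads))
  edge_tables <- if (keep_edges) vector("list", nrow(quads)) else NULL
  for (q in seq_len(nrow(quads))) {
    fx <- get_cov(quads$ix_i[q], quads$ix_j[q])
    fy <- get_cov(quads$ix_k[q], quads$ix_l[q])
    edges <- edge_geometry(fx, fy, quads[q, ], delta = delta,
                           literal_eq14 = literal_eq14)
    p_q[q] <- quadruple_pbold(edges)
    n_edges[q] <- nrow(edges)
    if (keep_edges) {
      edges <- cbind(quadruple_id = quads$quadruple_id[q],
                     te_pair_x = sprintf("(%g,%g)", quads$te_i[q], quads$te_j[q]),
                     te_pair_y = sprintf("(%g,%g)", quads$te_k[q], quads$te_l[q]),
                     edges)
      edge_tables[[q]] <- edges
    }
  }
  per_quadruple <- cbind(quads, p_bold = p_q, n_edges = n_edges)
  ok <- !is.na(p_q)
  wsum <- sum(per_quadruple$chord[ok])
  if (!any(ok) || wsum == 0)
    pq_stop("pbold", "all quadruples undefined or zero chord weight; p_BOLD undefined")
  p_bold <- sum(per_quadruple$chord[ok] * p_q[ok]) / wsum
  structure(list(p_bold = p_bold, per_quadruple = per_quadruple,
                 n_rois = ts$n_rois, te_list = ts$echo_times,
                 delta = delta, chord_radius = chord_radius,
                 symmetrize = symmetrize, literal_eq14 = literal_eq14,
                 edges = if (keep_edges) do.call(rbind, edge_tables) else NULL),
            class = "pbold_result")
}

#' @export
print.pbold_result <- function(x, ...) {
  cat(sprintf("p_BOLD = %.4f  (%d ROIs, %d echoes, %d quadruples%s)\n",
              x$p_bold, x$n_rois, length(x$te_list), nrow(x$per_quadruple),
              if (any(is.na(x$per_quadruple$p_bold)))
                sprintf(", %d undefined", sum(is.na(x$per_quadruple$p_bold)))
              else ""))
  cat(sprintf("delta = %g, chord radius = %g\n", x$delta, x$chord_radius))
  invisible(x)
}
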