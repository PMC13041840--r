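## Across-echo functional connectivity.
##
## Pearson correlation between signals at two (possibly different) echoes is
## echo-time independent in both the S_o-dominated and the BOLD-dominated
## regime, so it cannot separate them. Covariance is echo-time independent
## only under S_o dominance; under BOLD dominance it scales with the product
## TE_i * TE_j of the contributing echo times. That asymmetry is what the
## p_BOLD geometry exploits.

#' Convert raw ROI series to percent signal change
#'
#' Each row becomes 100 * (S - S_bar) / S_bar, where S_bar is the row's
#' temporal mean; rows then have temporal mean exactly 0. The percent (x100)
#' scale is used throughout the package because the p_BOLD defaults
#' (tie tolerance delta = 1e-3, chord radius R = 0.5) are defined on it.
#'
#' @param ts an \code{roi_ts_set} with \code{units = "raw"}; every row must
#'   have a strictly positive temporal mean.
#' @return An \code{roi_ts_set} with \code{units = "spc"}.
#' @export
to_spc <- function(ts) {
  stopifnot(inherits(ts, "roi_ts_set"))
  if (ts$units != "raw") pq_stop("fc", "to_spc expects units = 'raw'")
  values <- vector("list", length(ts$values))
  for (e in seq_along(ts$values)) {
    mu <- rowMeans(ts$values[[e]])
    bad <- which(mu <= 0)
    if (length(bad))
      pq_stop("fc", "non-positive temporal mean for ROI(s) ",
              paste(ts$roi_ids[bad], collapse = ", "), " at echo ", e,
              "; cannot form signal percent change")
    values[[e]] <- 100 * sweep(ts$values[[e]], 1, mu, "-") / mu
  }
  roi_ts_set(values, ts$echo_times, ts$roi_ids, units = "spc")
}

centered <- function(m) m - rowMeans(m)

#' Across-echo covariance connectivity matrix
#'
#' Entry (x, y) is the sample covariance (Nt - 1 denominator) between ROI
#' x's series at echo \code{echo_a} and ROI y's series at echo \code{echo_b}.
#' Temporal means are re-removed before the product even though spc rows are
#' already ~zero-mean, to bound floating-point drift. The matrix is generally
#' asymmetric when \code{echo_a != echo_b}.
#'
#' @param ts an \code{roi_ts_set} with \code{units = "spc"}.
#' @param echo_a,echo_b echo indices (1-based).
#' @return An \code{fc_matrix} (N_r x N_r) with attributes \code{estimator},
#'   \code{te_pair}, \code{n_t}.
#' @export
covariance_fc <- function(ts, echo_a, echo_b) {
  stopifnot(inherits(ts, "roi_ts_set"))
  if (ts$units != "spc") pq_stop("fc", "FC estimators expect units = 'spc' (run to_spc)")
  if (ts$n_t < 2L) pq_stop("fc", "need Nt >= 2 for covariance")
  a <- centered(ts$values[[echo_a]])
  b <- centered(ts$values[[echo_b]])
  m <- tcrossprod(a, b) / (ts$n_t - 1)
  fc_matrix(m, "covariance", ts$echo_times[c(echo_a, echo_b)], ts$n_t, ts$roi_ids)
}

#' Across-echo Pearson connectivity matrix
#'
#' Entry (x, y) is the Pearson correlation between ROI x at echo
#' \code{echo_a} and ROI y at echo \code{echo_b}. Zero-variance rows yield
#' NA entries with a warning (never a silent 0).
#'
#' @inheritParams covariance_fc
#' @return An \code{fc_matrix} with entries in [-1, 1] (or NA).
#' @export
pearson_fc <- function(ts, echo_a, echo_b) {
  stopifnot(inherits(ts, "roi_ts_set"))
  if (ts$units != "spc") pq_stop("fc", "FC estimators expect units = 'spc' (run to_spc)")
  if (ts$n_t < 2L) pq_stop("fc", "need Nt >= 2 for correlation")
  a <- centered(ts$values[[echo_a]])
  b <- centered(ts$values[[echo_b]])
  sa <- sqrt(rowSums(a^2))
  sb <- sqrt(rowSums(b^2))
  za <- sa == 0
  zb <- sb == 0
  if (any(za) || any(zb))
    pq_warn("fc", "zero-variance ROI series; correlations set to NA for ROI(s) ",
            paste(unique(ts$roi_ids[za | zb]), collapse = ", "))
  sa[za] <- NA_real_
  sb[zb] <- NA_real_
  m <- tcrossprod(a, b) / outer(sa, sb)
  m <- pmin(pmax(m, -1), 1)                     # clamp fp rounding only
  fc_matrix(m, "pearson", ts$echo_times[c(echo_a, echo_b)], ts$n_t, ts$roi_ids)
}

fc_matrix <- function(m, estimator, te_pair, n_t, roi_ids = NULL) {
  if (!is.null(roi_ids)) dimnames(m) <- list(roi_ids, roi_ids)
  structure(m, class = c("fc_matrix", "matrix"),
            estimator = estimator, te_pair = as.numeric(te_pair), n_t = n_t)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("fc_matrix: %dx%d, estimator = %s, TE pair = (%g, %g) ms, Nt = %d\n",
              nrow(x), ncol(x), attr(x, "estimator"),
              attr(x, "te_pair")[1], attr(x, "te_pair")[2], attr(x, "n_t")))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Write an FC matrix to TSV
#'
#' Dense TSV with a two-comment-line header recording the estimator and the
#' echo-time pair.
#'
#' @param fcm an \code{fc_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fc_matrix <- function(fcm, path) {
  stopifnot(inherits(fcm, "fc_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# estimator: %s", attr(fcm, "estimator")),
               sprintf("# te_pair_ms: %.6g %.6g", attr(fcm, "te_pair")[1],
                       attr(fcm, "te_pair")[2])), con)
  utils::write.table(unclass(fcm), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
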