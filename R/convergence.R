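#' Discard the burn-in head of a per-frame series
#'
#' Drops the first `floor(fraction * length)` frames. The burn-in is given
#' as a frame fraction (not time) so synthetic and imported trajectories
#' share one code path; the default pipeline fraction 6/11 mirrors
#' discarding the first 600 ns of a 1.1 us trajectory.
#'
#' @param series numeric vector (or `cdr_rmsd_series`), non-empty.
#' @param fraction fraction of frames to drop, in [0, 1).
#' @return the tail of the series (same class as the input values).
#' @export
discard_burn_in <- function(series, fraction) {
  vals <- if (inherits(series, "cdr_rmsd_series")) series$values else series
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("burn-in fraction must lie in [0, 1)")
  if (!length(vals)) stop("empty series")
  drop <- floor(fraction * length(vals))
  if (drop >= length(vals)) stop("burn-in would discard every frame")
  out <- vals[(drop + 1L):length(vals)]
  if (inherits(series, "cdr_rmsd_series")) {
    series$values <- out
    series
  } else out
}

#' Post-burn-in stability check
#'
#' Population standard deviation of a (post-burn-in) RMSD series; the run
#' passes when the deviation is below the threshold (default 1.0 Angstrom,
#' the conventional convergence yardstick for a folded domain).
#'
#' @param series numeric vector, length >= 2.
#' @param threshold Angstrom.
#' @return list with `std` and logical `passed`.
#' @export
stability_check <- function(series, threshold = 1.0) {
  series <- if (inherits(series, "cdr_rmsd_series")) series$values else series
  if (length(series) < 2L) stop("need at least 2 values")
  s <- sqrt(mean((series - mean(series))^2))
  list(std = s, passed = s < threshold)
}

# Freedman-Diaconis breaks on a pooled sample; 20 equal bins if IQR = 0
.fd_breaks <- function(pooled) {
  rng <- range(pooled)
  if (diff(rng) == 0) return(NULL)  # constant: caller treats as identical
  iqr <- stats::IQR(pooled)
  h <- 2 * iqr / length(pooled)^(1 / 3)
  nbin <- if (iqr == 0 || h <= 0) 20L else max(1L, ceiling(diff(rng) / h))
  seq(rng[1], rng[2], length.out = nbin + 1L)
}

#' Histogram overlap between the two halves of a series
#'
#' Splits the (post-burn-in) series at its midpoint, histograms both halves
#' on shared Freedman-Diaconis bins computed from the pooled series, and
#' returns the overlap coefficient sum(min(p1, p2)) in [0, 1]: 1 when the
#' halves sample the same distribution, 0 when their supports are disjoint.
#' A reproducible surrogate for the visual first-half/last-half comparison
#' used to judge trajectory convergence.
#'
#' @param series numeric vector, length >= 4.
#' @return overlap coefficient in [0, 1].
#' @export
half_split_overlap <- function(series) {
  series <- if (inherits(series, "cdr_rmsd_series")) series$values else series
  n <- length(series)
  if (n < 4L) stop("need at least 4 values to split")
  mid <- floor(n / 2)
  a <- series[seq_len(mid)]
  b <- series[(mid + 1L):n]
  breaks <- .fd_breaks(series)
  if (is.null(breaks)) return(1)  # constant series: identical halves
  ca <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1L)
  cb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1L)
  sum(pmin(ca / length(a), cb / length(b)))
}

#' Flag outlier runs by the MAD rule
#'
#' A run is flagged when its series mean deviates from the median of the
#' run means by more than `k` times the (raw) median absolute deviation of
#' the run means, and by more than `min_abs` in absolute terms. The
#' absolute floor keeps the relative rule from firing on the milliangstrom
#' spread of a set of well-behaved replicates, where the MAD itself is
#' nearly zero. Deterministic stand-in for by-eye exclusion of a deviant
#' replicate; with MAD = 0 (all runs alike) nothing is flagged. The rule is
#' advisory: the pipeline reports flags and excludes only when configured to.
#'
#' @param series_list named list (run id -> numeric series or
#'   `cdr_rmsd_series`), length >= 3.
#' @param k spread multiplier, default 3.
#' @param min_abs minimum absolute deviation of a flagged run's mean from
#'   the median run mean, in the series' units; default 0.5 (Angstrom for
#'   RMSD series).
#' @return character vector of flagged run ids (possibly empty).
#' @export
flag_outlier_runs <- function(series_list, k = 3, min_abs = 0.5) {
  if (length(series_list) < 3L) stop("need at least 3 runs")
  vals <- lapply(series_list, function(s)
    if (inherits(s, "cdr_rmsd_series")) s$values else s)
  ids <- names(series_list)
  if (is.null(ids)) ids <- paste0("RUN-", seq_along(series_list))
  m <- vapply(vals, mean, numeric(1))
  med <- stats::median(m)
  mad0 <- stats::mad(m, constant = 1)
  if (mad0 == 0) return(character(0))
  ids[abs(m - med) > k * mad0 & abs(m - med) > min_abs]
}

#' Convergence report for one run
#'
#' Applies the burn-in, then the stability check and the half-split overlap
#' on the retained tail (set `split_after_burn_in = FALSE` to split the full
#' series instead).
#'
#' @param series global C-alpha RMSD series of the run (numeric or
#'   `cdr_rmsd_series`).
#' @param run_id run identifier.
#' @param burn_in_fraction frame fraction to discard first.
#' @param std_threshold Angstrom; default 1.0.
#' @param overlap_threshold minimum acceptable overlap; default 0.5.
#' @param split_after_burn_in logical; split the post-burn-in tail (default)
#'   or the full series.
#' @return an object of class `convergence_report`.
#' @export
convergence_report <- function(series, run_id = "RUN-1",
                               burn_in_fraction = 6 / 11,
                               std_threshold = 1.0,
                               overlap_threshold = 0.5,
                               split_after_burn_in = TRUE) {
  vals <- if (inherits(series, "cdr_rmsd_series")) series$values else series
  tail_vals <- discard_burn_in(vals, burn_in_fraction)
  st <- stability_check(tail_vals, std_threshold)
  ov <- half_split_overlap(if (split_after_burn_in) tail_vals else vals)
  structure(list(run_id = run_id,
                 post_burnin_std = st$std,
                 std_threshold = std_threshold,
                 passed_std = st$passed,
                 half_split_overlap = ov,
                 overlap_threshold = overlap_threshold,
                 passed_overlap = ov >= overlap_threshold,
                 is_outlier = FALSE),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence> %s: std %.3f A (%s), overlap %.2f (%s)%s\n",
              x$run_id, x$post_burnin_std,
              if (x$passed_std) "pass" else "FAIL",
              x$half_split_overlap,
              if (x$passed_overlap) "pass" else "FAIL",
              if (x$is_outlier) " [outlier]" else ""))
  invisible(x)
}
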