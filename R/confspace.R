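#' Pool per-run samples, with optional run exclusion
#'
#' Concatenates (already burn-in-trimmed) per-run samples into one pooled
#' set, keeping per-sample provenance. Runs listed in `exclude` are left
#' out, mirroring the exclusion of a non-converged replicate.
#'
#' @param series_list named list (run id -> numeric vector or
#'   `cdr_rmsd_series`).
#' @param exclude character vector of run ids to drop.
#' @return data.frame of class `pooled_samples` with columns `run_id`,
#'   `frame`, `value`.
#' @export
pool_runs <- function(series_list, exclude = character(0)) {
  ids <- names(series_list)
  if (is.null(ids)) ids <- paste0("RUN-", seq_along(series_list))
  keep <- !(ids %in% exclude)
  if (!any(keep)) stop("all runs excluded; nothing to pool")
  out <- do.call(rbind, lapply(which(keep), function(k) {
    v <- series_list[[k]]
    if (inherits(v, "cdr_rmsd_series")) v <- v$values
    data.frame(run_id = ids[k], frame = seq_along(v), value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("pooled_samples", "data.frame")
  attr(out, "n_runs_pooled") <- sum(keep)
  out
}

#' Peak-normalized kernel density profile of a pooled sample
#'
#' Gaussian-kernel density (Silverman's rule-of-thumb bandwidth unless
#' overridden) on an even grid spanning [min - 3h, max + 3h], then divided
#' by its maximum so the peak is exactly 1 — the display convention for
#' conformational-space profiles. The reported mean and standard deviation
#' are plain sample moments, not moments of the smoothed density. A sample
#' with zero spread yields a degenerate single-point profile (flagged, not
#' an error) so a frozen region does not abort a whole pipeline.
#'
#' @param samples numeric vector or a [pool_runs()] result; >= 5 values.
#' @param grid_points grid resolution; default 512.
#' @param bandwidth optional numeric bandwidth (Angstrom or Q units);
#'   default Silverman.
#' @return an object of class `density_profile`: `grid`, `density` (max 1),
#'   `raw_bandwidth`, `sample_mean`, `sample_std`, `n_samples`,
#'   `n_runs_pooled`, `degenerate`.
#' @export
kde_profile <- function(samples, grid_points = 512, bandwidth = NULL) {
  n_runs <- 1L
  if (inherits(samples, "pooled_samples")) {
    n_runs <- attr(samples, "n_runs_pooled")
    samples <- samples$value
  }
  samples <- as.numeric(samples)
  if (length(samples) < 5L) stop("need at least 5 samples for a density")
  m <- mean(samples); s <- stats::sd(samples)
  if (diff(range(samples)) == 0) {
    return(structure(list(grid = samples[1L], density = 1,
                          raw_bandwidth = 0, sample_mean = m,
                          sample_std = s, n_samples = length(samples),
                          n_runs_pooled = n_runs, degenerate = TRUE),
                     class = "density_profile"))
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(samples) else bandwidth
  d <- stats::density(samples, bw = bw, kernel = "gaussian",
                      n = grid_points, cut = 3)
  structure(list(grid = d$x, density = d$y / max(d$y), raw_bandwidth = bw,
                 sample_mean = m, sample_std = s,
                 n_samples = length(samples), n_runs_pooled = n_runs,
                 degenerate = FALSE),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> n = %d (%d run%s), mean %.4g, sd %.4g%s\n",
              x$n_samples, x$n_runs_pooled,
              if (x$n_runs_pooled == 1) "" else "s",
              x$sample_mean, x$sample_std,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Plot a density profile
#' @param x a `density_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", ylim = c(0, 1),
                 xlab = "value", ylab = "normalized density", ...)
  invisible(x)
}

#' Correlation between Q and a region RMSD across frames
#'
#' Pearson and Spearman coefficients over frame-aligned (Q, RMSD) pairs.
#' When run ids are supplied, per-run coefficients are reported too: pooling
#' runs can inflate a correlation through between-run mean shifts, so the
#' pooled value is the headline and the per-run table the diagnostic.
#' Constant input yields NA coefficients with `constant_input = TRUE`.
#'
#' @param q numeric Q values (pooled, frame-aligned with `rmsd`).
#' @param rmsd numeric region RMSD values, same length, >= 10 points.
#' @param run_id optional character vector of run ids per point.
#' @return an object of class `correlation_result`: `pearson_r`,
#'   `spearman_rho`, `n_points`, `per_run` (data.frame or NULL),
#'   `constant_input`.
#' @export
q_rmsd_correlation <- function(q, rmsd, run_id = NULL) {
  q <- as.numeric(q); rmsd <- as.numeric(rmsd)
  if (length(q) != length(rmsd)) stop("q and rmsd differ in length")
  if (length(q) < 10L) stop("need at least 10 points")
  const <- stats::sd(q) == 0 || stats::sd(rmsd) == 0
  pe <- if (const) NA_real_ else stats::cor(q, rmsd, method = "pearson")
  sp <- if (const) NA_real_ else stats::cor(q, rmsd, method = "spearman")
  per_run <- NULL
  if (!is.null(run_id)) {
    stopifnot(length(run_id) == length(q))
    per_run <- do.call(rbind, lapply(split(seq_along(q), run_id), function(ix) {
      ok <- stats::sd(q[ix]) > 0 && stats::sd(rmsd[ix]) > 0
      data.frame(run_id = run_id[ix[1L]],
                 pearson_r = if (ok) stats::cor(q[ix], rmsd[ix]) else NA_real_,
                 spearman_rho = if (ok)
                   stats::cor(q[ix], rmsd[ix], method = "spearman")
                 else NA_real_,
                 n_points = length(ix), stringsAsFactors = FALSE)
    }))
    rownames(per_run) <- NULL
  }
  structure(list(pearson_r = pe, spearman_rho = sp, n_points = length(q),
                 per_run = per_run, constant_input = const),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> pearson %.3f, spearman %.3f (n = %d)%s\n",
              x$pearson_r, x$spearman_rho, x$n_points,
              if (x$constant_input) " [constant input]" else ""))
  invisible(x)
}

#' Compare the breadth of two conformational-space profiles
#'
#' Pure comparison of sample standard deviations (breadth) and means (shift)
#' of two density profiles; no test statistic.
#'
#' @param profile_a,profile_b `density_profile` objects.
#' @param label_a,label_b names used in the report.
#' @return list with `broader` ("A", "B" or "equal"), `std_a`, `std_b`,
#'   `std_ratio`, `mean_shift` (mean A - mean B).
#' @export
breadth_compare <- function(profile_a, profile_b,
                            label_a = "A", label_b = "B") {
  stopifnot(inherits(profile_a, "density_profile"),
            inherits(profile_b, "density_profile"))
  sa <- profile_a$sample_std; sb <- profile_b$sample_std
  list(broader = if (sa > sb) label_a else if (sb > sa) label_b else "equal",
       std_a = sa, std_b = sb,
       std_ratio = if (sb > 0) sa / sb else NA_real_,
       mean_shift = profile_a$sample_mean - profile_b$sample_mean)
}
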