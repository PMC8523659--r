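#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares fit of `mobile` onto `reference`: finds the proper rotation
#' R and translation t minimizing the RMSD between `mobile %*% t(R) + t` and
#' `reference`. The reflection branch of the SVD solution is corrected by
#' flipping the sign of the smallest singular direction, so the returned
#' rotation always has determinant +1.
#'
#' @param mobile,reference N x 3 coordinate matrices (Angstrom), N >= 3,
#'   not collinear.
#' @return an object of class `rigid_transform`: list with `rotation` (3 x 3)
#'   and `translation` (length-3), to be applied as
#'   `coords %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required for a rigid fit")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)                       # 3x3 covariance
  sv <- svd(H)
  # degenerate (collinear/coincident) point sets have rank < 2
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-10)
    stop("degenerate point configuration (rank < 2): cannot fit")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  structure(list(rotation = R, translation = as.vector(cr - R %*% cm)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform` from [kabsch_fit()].
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        -transform$translation)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' No superposition is performed here; this is the plain
#' sqrt(mean squared pairwise distance).
#'
#' @param a,b N x 3 coordinate matrices (Angstrom), equal size, N >= 1.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("coordinate sets differ in shape")
  if (nrow(a) < 1L) stop("empty coordinate sets")
  sqrt(mean(rowSums((a - b)^2)))
}

#' @keywords internal
new_rmsd_series <- function(values, region, run_id, reference_tag) {
  stopifnot(all(values >= 0))
  structure(list(values = as.numeric(values), region = region,
                 run_id = run_id, reference_tag = reference_tag),
            class = "cdr_rmsd_series")
}

#' @export
print.cdr_rmsd_series <- function(x, ...) {
  cat("<rmsd series> ", x$region, ", ", length(x$values), " frames, mean ",
      format(mean(x$values), digits = 4), " A (", x$run_id, ")\n", sep = "")
  invisible(x)
}

# per-frame: fit on fit_idx CA, apply to whole frame, RMSD over rmsd_idx
.fit_rmsd_series <- function(ensemble, reference, fit_idx, rmsd_idx,
                             region, reference_tag) {
  if (nrow(ensemble$topology$xyz) != nrow(reference$xyz))
    stop("ensemble and reference topologies differ in atom count")
  ref_fit <- reference$xyz[fit_idx, , drop = FALSE]
  ref_tgt <- reference$xyz[rmsd_idx, , drop = FALSE]
  vals <- vapply(ensemble$frames, function(f) {
    tr <- kabsch_fit(f[fit_idx, , drop = FALSE], ref_fit)
    moved <- apply_transform(tr, f[rmsd_idx, , drop = FALSE])
    rmsd(moved, ref_tgt)
  }, numeric(1))
  new_rmsd_series(vals, region, ensemble$run_id, reference_tag)
}

#' Per-frame region C-alpha RMSD after framework superposition
#'
#' For every frame, the framework C-alpha atoms are superposed onto the
#' reference (Kabsch), the fitted transform is applied to the whole frame,
#' and the RMSD of the selected region's C-alpha atoms against the reference
#' is recorded. This is the mobility metric for CDR loops: framework motion
#' is removed, loop motion relative to the scaffold remains.
#'
#' @param ensemble a `cdr_ensemble`.
#' @param reference a `cdr_structure` sharing the ensemble's topology.
#' @param annotation a `region_annotation` for the reference.
#' @param region region label whose C-alpha RMSD is reported (e.g. "CDR1").
#' @param reference_tag label recorded on the series (default "native").
#' @return a `cdr_rmsd_series`.
#' @export
cdr_rmsd_series <- function(ensemble, reference, annotation, region,
                            reference_tag = "native") {
  stopifnot(inherits(ensemble, "cdr_ensemble"),
            inherits(reference, "cdr_structure"))
  fit_idx <- region_atom_indices(reference, annotation, "framework", "calpha")
  rmsd_idx <- region_atom_indices(reference, annotation, region, "calpha")
  if (length(fit_idx) < 3L)
    stop("framework has fewer than 3 CA atoms; cannot superpose")
  if (!length(rmsd_idx))
    stop("region '", region, "' selects no CA atoms")
  .fit_rmsd_series(ensemble, reference, fit_idx, rmsd_idx, region,
                   reference_tag)
}

#' Per-frame global C-alpha RMSD
#'
#' Fits on all C-alpha atoms and reports RMSD over all C-alpha atoms; the
#' convergence diagnostics run on this series.
#'
#' @inheritParams cdr_rmsd_series
#' @return a `cdr_rmsd_series` with region `"global"`.
#' @export
global_rmsd_series <- function(ensemble, reference,
                               reference_tag = "native") {
  stopifnot(inherits(ensemble, "cdr_ensemble"),
            inherits(reference, "cdr_structure"))
  idx <- ca_indices(reference)
  if (length(idx) < 3L) stop("fewer than 3 CA atoms in reference")
  .fit_rmsd_series(ensemble, reference, idx, idx, "global", reference_tag)
}

#' Collect RMSD series into a long data frame
#' @param series_list list of `cdr_rmsd_series`.
#' @return data.frame with columns run_id, frame, region, rmsd_angstrom.
#' @export
rmsd_series_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(run_id = s$run_id, frame = seq_along(s$values),
               region = s$region, rmsd_angstrom = s$values,
               stringsAsFactors = FALSE)))
}
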