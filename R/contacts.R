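#' Parameters of the fraction-of-native-contacts statistic
#'
#' Q soft-counts, per frame, how many native atom pairs are still in
#' contact: Q(X) = (1/N) * sum over native pairs (i,j) of
#' 1 / (1 + exp(beta * (r_ij(X) - lambda * r0_ij))),
#' where r0_ij is the pair distance in the native structure. `beta` controls
#' the steepness of the logistic switch and `lambda` tolerates thermal
#' fluctuation of a formed contact. The native pair list uses heavy atoms
#' within `contact_cutoff` whose residues are more than `min_seq_separation`
#' apart in sequence.
#'
#' @param beta smoothing, 1/Angstrom (> 0); default 5.
#' @param lambda formed-contact fluctuation factor (>= 1); default 1.8, the
#'   all-atom convention.
#' @param contact_cutoff native-distance cutoff, Angstrom; default 4.5.
#' @param min_seq_separation residues; pairs separated by more than this
#'   qualify; default 3.
#' @return an object of class `q_params`.
#' @export
q_params <- function(beta = 5, lambda = 1.8, contact_cutoff = 4.5,
                     min_seq_separation = 3) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(lambda) || lambda < 1) stop("lambda must be >= 1")
  if (!is.numeric(contact_cutoff) || contact_cutoff <= 0)
    stop("contact_cutoff must be > 0")
  if (min_seq_separation < 0) stop("min_seq_separation must be >= 0")
  structure(list(beta = beta, lambda = lambda,
                 contact_cutoff = contact_cutoff,
                 min_seq_separation = as.integer(min_seq_separation)),
            class = "q_params")
}

#' Build the native contact set from a reference structure
#'
#' All heavy-atom pairs (i < j) whose residues are more than
#' `min_seq_separation` apart and whose native distance is at most
#' `contact_cutoff` Angstrom, in lexicographic (i, j) order. Hydrogens are
#' excluded even if present. Contacts are computed once from the native
#' structure and frozen for every frame and run of a system.
#'
#' @param reference a `cdr_structure` with heavy atoms in >= 2 residues.
#' @param params a [q_params()].
#' @return an object of class `contact_set`: data frame `pairs`
#'   (i, j, res_i, res_j, r0) and count `N`.
#' @export
find_native_contacts <- function(reference, params = q_params()) {
  stopifnot(inherits(reference, "cdr_structure"),
            inherits(params, "q_params"))
  heavy <- which(reference$atoms$is_heavy)
  res <- reference$atoms$residue_seq[heavy]  # author numbering: gaps count
  if (length(unique(res)) < 2L)
    stop("reference must contain heavy atoms in at least 2 residues")
  xyz <- reference$xyz[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  sep_ok <- abs(outer(res, res, "-")) > params$min_seq_separation
  hit <- which(upper.tri(d) & d <= params$contact_cutoff & sep_ok,
               arr.ind = TRUE)
  if (!nrow(hit))
    stop("no native contacts found: reference looks unfolded or degenerate")
  # map back to full-structure atom indices, lexicographic (i, j)
  ord <- order(hit[, 1L], hit[, 2L])
  hit <- hit[ord, , drop = FALSE]
  pairs <- data.frame(i = heavy[hit[, 1L]], j = heavy[hit[, 2L]],
                      res_i = res[hit[, 1L]], res_j = res[hit[, 2L]],
                      r0 = d[hit])
  structure(list(pairs = pairs, N = nrow(pairs), params = params),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> ", x$N, " native heavy-atom pairs, r0 in [",
      format(min(x$pairs$r0), digits = 3), ", ",
      format(max(x$pairs$r0), digits = 3), "] A\n", sep = "")
  invisible(x)
}

#' Fraction of native contacts of one frame
#'
#' Evaluates Q(X) = (1/N) * sum_(i,j) 1/(1 + exp(beta * (r_ij(X) -
#' lambda * r0_ij))) over the frozen native pair list. Distance-based only:
#' no superposition is needed and the value is rigid-motion invariant.
#'
#' @param coords N_atoms x 3 frame coordinates indexed like the reference
#'   structure the contacts were built from.
#' @param contacts a [find_native_contacts()] result.
#' @param params a [q_params()]; defaults to the parameters stored with the
#'   contact set.
#' @return Q in (0, 1).
#' @export
q_value <- function(coords, contacts, params = contacts$params) {
  stopifnot(inherits(contacts, "contact_set"))
  coords <- as.matrix(coords)
  p <- contacts$pairs
  if (max(p$i, p$j) > nrow(coords))
    stop("frame has fewer atoms than the contact set indexes (topology error)")
  dv <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  r <- sqrt(rowSums(dv * dv))
  mean(1 / (1 + exp(params$beta * (r - params$lambda * p$r0))))
}

#' Per-frame Q series of an ensemble
#'
#' @param ensemble a `cdr_ensemble` whose topology covers the contact
#'   indices.
#' @inheritParams q_value
#' @return numeric vector, one Q per frame, in frame order.
#' @export
q_series <- function(ensemble, contacts, params = contacts$params) {
  stopifnot(inherits(ensemble, "cdr_ensemble"))
  vapply(ensemble$frames, q_value, numeric(1),
         contacts = contacts, params = params)
}

#' Write a contact set to CSV
#' @param contacts a `contact_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  .write_csv(contacts$pairs, path)
}
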