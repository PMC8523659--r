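# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk that a test did not itself write.

# CA-only structure from an n x 3 coordinate matrix
make_ca_structure <- function(coords, resno = seq_len(nrow(coords)),
                              chain = "A") {
  coords <- as.matrix(coords)
  new_structure(
    data.frame(atom_name = "CA", element = "C", residue_seq = resno,
               chain_id = chain, resid = "ALA", stringsAsFactors = FALSE),
    coords)
}

# straight CA chain with fixed spacing along x
make_chain <- function(n, spacing = 3.8) {
  make_ca_structure(cbind((seq_len(n) - 1) * spacing, 0, 0))
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(coords, R, t) sweep(coords %*% t(R), 2, -t)

# independent scalar evaluation of the smoothed native-contact formula:
# a plain double loop, no vectorization shared with the implementation
scalar_q_oracle <- function(coords, pairs, r0, beta, lambda) {
  total <- 0
  for (k in seq_along(r0)) {
    d <- coords[pairs[k, 1], ] - coords[pairs[k, 2], ]
    r <- sqrt(sum(d * d))
    total <- total + 1 / (1 + exp(beta * (r - lambda * r0[k])))
  }
  total / length(r0)
}

# brute-force native-contact enumeration: O(n^2) double loop over atoms
brute_force_contacts <- function(structure, cutoff = 4.5, min_sep = 3) {
  at <- structure$atoms
  heavy <- which(at$is_heavy)
  out <- NULL
  for (a in heavy) for (b in heavy) {
    if (a >= b) next
    if (abs(at$residue_seq[a] - at$residue_seq[b]) <= min_sep) next
    r <- sqrt(sum((structure$xyz[a, ] - structure$xyz[b, ])^2))
    if (r <= cutoff) out <- rbind(out, c(a, b, r))
  }
  out
}

# small folded-ish random fixture: n atoms packed in a ball, one per residue
random_packed_structure <- function(n = 30, radius = 8, seed = 1) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 3), n, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * stats::runif(n)^(1 / 3)
  make_ca_structure(pts)
}

default_scaffold <- function(seed = 1)
  build_scaffold(scaffold_spec(n_residues = 128, seed = seed))

scaffold_annotation <- function(scaffold)
  assign_regions(identity_numbering(scaffold), imgt_scheme())

# minimal ensemble spec wrapper used by several files
quick_spec <- function(scaffold, ann, amps, n_frames = 50, n_runs = 1,
                       seed = 1, rigid = list(rotation_deg = 0,
                                              translation_A = 0),
                       altstate = NULL) {
  ensemble_spec(scaffold, ann, region_amplitudes = amps,
                altstate = altstate, rigid_noise = rigid,
                n_frames = n_frames, n_runs = n_runs, base_seed = seed)
}
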