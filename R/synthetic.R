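#' Specification of a synthetic CA scaffold
#'
#' The scaffold is a compact self-avoiding C-alpha trace standing in for a
#' folded single-domain scaffold: consecutive CA atoms 3.8 +/- 0.1 Angstrom
#' apart (the trans-peptide CA-CA distance), no two non-consecutive atoms
#' closer than 3.5 Angstrom, and packing dense enough that the default
#' native-contact rule finds a substantial contact set.
#'
#' @param n_residues number of residues (>= 10); default 128, an
#'   IMGT-numbered VHH span.
#' @param atoms_per_residue 1 (CA-only, default) or more; extra atoms are
#'   pseudo-side-chain sites 1.5 Angstrom from the CA.
#' @param compactness optional target radius of gyration, Angstrom; by
#'   default the trace fills a near-cubic lattice block (maximally compact).
#'   Larger targets elongate the block; bond lengths are never rescaled.
#' @param seed integer RNG seed; output is deterministic per seed.
#' @return an object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(n_residues = 128, atoms_per_residue = 1,
                          compactness = NULL, seed = 1) {
  if (n_residues < 10) stop("n_residues must be >= 10")
  if (atoms_per_residue < 1) stop("atoms_per_residue must be >= 1")
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 compactness = compactness, seed = as.integer(seed)),
            class = "scaffold_spec")
}

# serpentine path through an nx x ny x nz lattice block, spacing `a`
.serpentine <- function(n, a, aspect = c(1, 1, 1)) {
  side <- ceiling((n * prod(1 / aspect))^(1 / 3))
  dims <- pmax(1L, ceiling(side * aspect))
  while (prod(dims) < n) dims[which.min(dims)] <- dims[which.min(dims)] + 1L
  pts <- matrix(0, n, 3)
  k <- 0L
  row_ct <- 0L  # flips x direction every traversed row to keep steps adjacent
  for (iz in seq_len(dims[3]) - 1L) {
    ys <- seq_len(dims[2]) - 1L
    if (iz %% 2L == 1L) ys <- rev(ys)
    for (iy in ys) {
      xs <- seq_len(dims[1]) - 1L
      if (row_ct %% 2L == 1L) xs <- rev(xs)
      row_ct <- row_ct + 1L
      for (ix in xs) {
        k <- k + 1L
        if (k > n) return(pts * a)
        pts[k, ] <- c(ix, iy, iz)
      }
    }
  }
  pts * a
}

#' Build a synthetic scaffold structure
#'
#' Lays the trace along a serpentine path through a compact lattice block
#' with 3.8-Angstrom spacing (so the chain is self-avoiding by construction
#' and every lattice neighbor pair is a native contact), then applies a
#' small seeded jitter. Residues are numbered 1..n on chain A.
#'
#' @param spec a [scaffold_spec()].
#' @return a `cdr_structure`.
#' @export
build_scaffold <- function(spec = scaffold_spec()) {
  stopifnot(inherits(spec, "scaffold_spec"))
  n <- spec$n_residues
  a <- 3.8
  aspect <- c(1, 1, 1)
  if (!is.null(spec$compactness)) {
    # search elongations for the closest achievable radius of gyration
    cands <- lapply(seq(1, 6, by = 0.25), function(e) c(1, 1, e))
    rg <- vapply(cands, function(asp) {
      p <- .serpentine(n, a, asp)
      sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
    }, numeric(1))
    aspect <- cands[[which.min(abs(rg - spec$compactness))]]
  }
  ca <- .serpentine(n, a, aspect)
  set.seed(spec$seed)
  ca <- ca + matrix(stats::rnorm(n * 3, sd = 0.015), n, 3)
  if (spec$atoms_per_residue > 1L) {
    extra <- spec$atoms_per_residue - 1L
    dirs <- matrix(stats::rnorm(n * extra * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    side <- ca[rep(seq_len(n), each = extra), ] + 1.5 * dirs
    xyz <- matrix(0, n * spec$atoms_per_residue, 3)
    names_all <- character(nrow(xyz))
    sc_names <- paste0("CB", seq_len(extra))
    if (extra >= 1) sc_names[1] <- "CB"
    for (r in seq_len(n)) {
      rows <- (r - 1L) * spec$atoms_per_residue + seq_len(spec$atoms_per_residue)
      xyz[rows[1L], ] <- ca[r, ]
      xyz[rows[-1L], ] <- side[(r - 1L) * extra + seq_len(extra), ]
      names_all[rows] <- c("CA", sc_names)
    }
  } else {
    xyz <- ca
    names_all <- rep("CA", n)
  }
  res <- rep(seq_len(n), each = spec$atoms_per_residue)
  new_structure(data.frame(atom_name = names_all,
                           element = "C",
                           residue_seq = res,
                           chain_id = "A",
                           resid = "ALA",
                           stringsAsFactors = FALSE), xyz)
}

#' Specification of a synthetic conformational ensemble
#'
#' Frames are the reference plus (i) independent per-frame Gaussian
#' displacements whose standard deviation per coordinate is set per region,
#' (ii) optionally a discrete alternative loop conformation (a frozen
#' displacement of one region, drawn with a mixture weight) and (iii) a
#' random rigid motion of the whole frame. Ground truth (which region moves
#' how much) is therefore known exactly. Displacements are i.i.d. across
#' frames: the generator emulates the marginal distributions of an
#' equilibrated trajectory, not its time correlation.
#'
#' @param reference a `cdr_structure` (e.g. [build_scaffold()]).
#' @param annotation a `region_annotation` for the reference.
#' @param region_amplitudes named numeric vector/list, region label ->
#'   Gaussian sigma per coordinate, Angstrom. Unnamed regions default to 0.
#' @param altstate optional list(region, magnitude, weight): with
#'   probability `weight` a frame's `region` is displaced by a frozen
#'   random direction per residue scaled to `magnitude` Angstrom, giving a
#'   genuinely bimodal RMSD distribution.
#' @param rigid_noise list(rotation_deg, translation_A): per-frame random
#'   rigid motion (sigma of rotation angle in degrees, of each translation
#'   component in Angstrom).
#' @param n_frames frames per run (< 2048 to keep RNG substreams disjoint).
#' @param n_runs number of independent runs.
#' @param base_seed integer; run r uses seed `xor(base_seed, r)`, and every
#'   (run, frame, stage) triple gets its own RNG substream, so ensembles
#'   are bit-reproducible and per-region draws are exactly independent.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(reference, annotation, region_amplitudes,
                          altstate = NULL,
                          rigid_noise = list(rotation_deg = 0,
                                             translation_A = 0),
                          n_frames = 200, n_runs = 1, base_seed = 1) {
  stopifnot(inherits(reference, "cdr_structure"),
            inherits(annotation, "region_annotation"))
  amp <- unlist(region_amplitudes)
  if (is.null(names(amp)) || !all(names(amp) %in% REGION_LABELS))
    stop("unknown region label in region_amplitudes: ",
         paste(setdiff(names(amp), REGION_LABELS), collapse = ", "))
  if (any(amp < 0)) stop("amplitudes must be >= 0")
  full <- stats::setNames(rep(0, length(REGION_LABELS)), REGION_LABELS)
  full[names(amp)] <- amp
  if (!is.null(altstate)) {
    stopifnot(is.list(altstate),
              all(c("region", "magnitude", "weight") %in% names(altstate)))
    if (!altstate$region %in% REGION_LABELS)
      stop("unknown region label in altstate: ", altstate$region)
    if (altstate$weight < 0 || altstate$weight > 1)
      stop("altstate weight must lie in [0, 1]")
    # frozen per-residue displacement, drawn once at spec creation
    res_sel <- which(annotation$labels == altstate$region)
    set.seed(.substream_seed(bitwXor(as.integer(base_seed), 104729L), 0L, 4L))
    d <- matrix(stats::rnorm(length(res_sel) * 3), ncol = 3)
    d <- d / sqrt(rowSums(d^2)) * altstate$magnitude
    altstate$residues <- res_sel
    altstate$displacement <- d
  }
  structure(list(reference = reference, annotation = annotation,
                 region_amplitudes = full, altstate = altstate,
                 rigid_noise = rigid_noise,
                 n_frames = as.integer(n_frames),
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "ensemble_spec")
}

# disjoint 31-bit substream seeds for (run_seed, frame, stage), frame < 2048
.substream_seed <- function(run_seed, frame, stage) {
  (run_seed %% 2039L) * 1048576L + frame * 512L + stage
}

.rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

#' Generate synthetic ensembles, one per run
#'
#' See [ensemble_spec()] for the frame model and the RNG substream
#' discipline. Identical specs give bit-identical frames; changing one
#' region's amplitude rescales only that region's displacement draws,
#' leaving every other region's draws (and the rigid-motion draws)
#' untouched.
#'
#' @param spec an [ensemble_spec()].
#' @return list of `cdr_ensemble`, run ids "RUN-1".."RUN-k".
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ref <- spec$reference
  xyz0 <- ref$xyz
  n_atoms <- nrow(xyz0)
  sigma_atom <- spec$region_amplitudes[
    spec$annotation$labels[ref$atoms$res_ord]]
  rot_sd <- spec$rigid_noise$rotation_deg * pi / 180
  tr_sd <- spec$rigid_noise$translation_A
  lapply(seq_len(spec$n_runs), function(r) {
    run_seed <- bitwXor(spec$base_seed, r)
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      set.seed(.substream_seed(run_seed, f, 1L))
      fr <- xyz0 + matrix(stats::rnorm(n_atoms * 3), n_atoms, 3) * sigma_atom
      if (!is.null(spec$altstate)) {
        set.seed(.substream_seed(run_seed, f, 2L))
        if (stats::runif(1) < spec$altstate$weight) {
          rows <- ref$atoms$res_ord %in% spec$altstate$residues
          fr[rows, ] <- fr[rows, ] + spec$altstate$displacement[
            match(ref$atoms$res_ord[rows], spec$altstate$residues), ]
        }
      }
      if (rot_sd > 0 || tr_sd > 0) {
        set.seed(.substream_seed(run_seed, f, 3L))
        R <- .rotation_matrix(stats::rnorm(3), stats::rnorm(1, sd = rot_sd))
        tr <- stats::rnorm(3, sd = tr_sd)
        ctr <- colMeans(fr)
        fr <- sweep(sweep(fr, 2, ctr) %*% t(R), 2, -(ctr + tr))
      }
      fr
    })
    new_ensemble(ref, frames, run_id = paste0("RUN-", r))
  })
}

#' Named generator presets
#'
#' `"vhh_contrast"` returns a pair of ensemble specs sharing one scaffold,
#' a desk-scale stand-in for a flexible wild type against a conformationally
#' restrained variant. The "broad" system has a flexible CDR1 (sigma 1.5
#' Angstrom) that additionally hops into a discrete alternative loop
#' conformation (2.5 Angstrom displacement, 25% occupancy) — the two-state
#' picture behind broad, Q-coupled CDR1 distributions. The "narrow" system
#' keeps CDR1 in a single basin (sigma 0.5 Angstrom, no alternative state).
#' Both share the canonical VHH mobility ordering CDR3 (1.8) > CDR1 > CDR2
#' (0.3), a rigid framework (0.15), per-frame rigid noise (5 degrees / 1
#' Angstrom) and 5 runs of 200 frames.
#'
#' @param name preset name; currently `"vhh_contrast"`.
#' @param base_seed integer seed controlling scaffold and ensembles.
#' @return named list of [ensemble_spec()] objects (`broad`, `narrow`)
#'   plus `scaffold` and `annotation`.
#' @export
preset <- function(name = "vhh_contrast", base_seed = 1) {
  if (!identical(name, "vhh_contrast"))
    stop("unknown preset: '", name, "'")
  base_seed <- as.integer(base_seed)
  scaffold <- build_scaffold(scaffold_spec(n_residues = 128,
                                           seed = base_seed))
  ann <- assign_regions(identity_numbering(scaffold), imgt_scheme())
  common <- list(CDR3 = 1.8, CDR2 = 0.3, FR1 = 0.15, FR2 = 0.15,
                 FR3 = 0.15, FR4 = 0.15)
  rigid <- list(rotation_deg = 5, translation_A = 1)
  mk <- function(cdr1_sigma, seed, alt)
    ensemble_spec(scaffold, ann,
                  region_amplitudes = c(common, list(CDR1 = cdr1_sigma)),
                  altstate = alt, rigid_noise = rigid,
                  n_frames = 200, n_runs = 5, base_seed = seed)
  list(broad = mk(1.5, base_seed,
                  list(region = "CDR1", magnitude = 2.5, weight = 0.25)),
       narrow = mk(0.5, bitwXor(base_seed, 23456L), NULL),
       scaffold = scaffold, annotation = ann)
}
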