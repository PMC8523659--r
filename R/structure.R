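#' @keywords internal
"_PACKAGE"

#' Construct a structure object
#'
#' A `cdr_structure` holds one conformation: an atom table and an n x 3
#' coordinate matrix in Angstrom. Residue ordinals (1-based, contiguous in
#' chain order) are derived from the author residue numbering, which is kept
#' for reporting.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `residue_seq`
#'   (author numbering, integer), `chain_id`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `cdr_structure` with elements `atoms` (the atom
#'   table, plus `is_heavy` and `res_ord` columns), `xyz`, `n_residues`.
#' @export
new_structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n x 3 matrix matching the atom table")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  need <- c("atom_name", "element", "residue_seq", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms$atom_name   <- as.character(atoms$atom_name)
  atoms$element     <- toupper(as.character(atoms$element))
  atoms$residue_seq <- as.integer(atoms$residue_seq)
  atoms$chain_id    <- as.character(atoms$chain_id)
  atoms$is_heavy    <- atoms$element != "H"
  # residue ordinal: order of first appearance (chain/file order)
  key <- paste(atoms$chain_id, atoms$residue_seq)
  atoms$res_ord <- match(key, unique(key))
  # at most one CA per residue
  ca <- atoms$atom_name == "CA"
  if (anyDuplicated(atoms$res_ord[ca]))
    stop("duplicate CA atom within a residue (residue_seq ",
         paste(unique(atoms$residue_seq[ca][duplicated(atoms$res_ord[ca])]),
               collapse = ", "), ")")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz,
                 n_residues = max(atoms$res_ord)),
            class = "cdr_structure")
}

#' @export
print.cdr_structure <- function(x, ...) {
  cat("<cdr_structure> ", nrow(x$atoms), " atoms, ", x$n_residues,
      " residues, ", sum(x$atoms$atom_name == "CA"), " CA\n", sep = "")
  invisible(x)
}

#' Indices of C-alpha atoms
#' @param structure a `cdr_structure`.
#' @return integer vector of atom indices whose name is "CA", in residue order.
#' @export
ca_indices <- function(structure) {
  which(structure$atoms$atom_name == "CA")
}

# derive an element symbol from a PDB atom name (protein atoms; no metals)
.element_from_name <- function(name) {
  el <- sub("^[0-9']*", "", trimws(name))
  substr(el, 1L, 1L)
}

# scan raw PDB lines; returns list(atom_lines_idx) or stops with line numbers
.scan_pdb_lines <- function(lines, path) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  if (!length(idx))
    stop("no ATOM records found in '", path, "'")
  for (i in idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record (too short) at line ", i, " of '", path, "'")
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed ATOM record (non-numeric coordinates) at line ", i,
           " of '", path, "'")
  }
  idx
}

# bio3d atom table -> keep mask: blank/"A" altloc, optionally one chain
.atom_keep <- function(atom, chain = NULL) {
  alt <- atom$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  ch <- atom$chain
  ch[is.na(ch)] <- ""
  if (is.null(chain)) chain <- ch[keep][1L]
  keep & ch == chain
}

.atoms_from_bio3d <- function(atom) {
  el <- atom$elesy
  bad <- is.na(el) | trimws(el) == ""
  el[bad] <- .element_from_name(atom$elety[bad])
  data.frame(atom_name   = trimws(atom$elety),
             element     = toupper(trimws(el)),
             residue_seq = atom$resno,
             chain_id    = ifelse(is.na(atom$chain), "", atom$chain),
             resid       = atom$resid,
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM records (first MODEL if several are present). Alternate
#' locations other than blank or "A" are dropped; hydrogens are retained but
#' flagged via `is_heavy`. By default only the first chain is kept (a VHH is
#' a single domain); pass `chain` to select another.
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier to select.
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  .scan_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atom)) stop("no ATOM records found in '", path, "'")
  keep <- .atom_keep(atom, chain)
  atom <- atom[keep, , drop = FALSE]
  if (!nrow(atom)) stop("no atoms left after chain/altloc selection in '",
                        path, "'")
  new_structure(.atoms_from_bio3d(atom),
                cbind(atom$x, atom$y, atom$z))
}

#' Construct an ensemble object
#'
#' A `cdr_ensemble` is an ordered set of frames sharing one topology. Every
#' frame must have the same atom count and order as the topology; this is
#' enforced here, at construction.
#'
#' @param topology a `cdr_structure` (the first frame's topology).
#' @param frames list of n x 3 coordinate matrices, one per frame.
#' @param run_id identifier for the run this trajectory belongs to.
#' @param frame_spacing time per frame, arbitrary units (metadata only).
#' @return an object of class `cdr_ensemble`.
#' @export
new_ensemble <- function(topology, frames, run_id = "RUN-1",
                         frame_spacing = 1) {
  stopifnot(inherits(topology, "cdr_structure"))
  if (!is.list(frames) || !length(frames))
    stop("frames must be a non-empty list of coordinate matrices")
  n <- nrow(topology$xyz)
  frames <- lapply(seq_along(frames), function(k) {
    f <- as.matrix(frames[[k]])
    storage.mode(f) <- "double"
    if (!identical(dim(f), c(n, 3L)) && !(nrow(f) == n && ncol(f) == 3L))
      stop("frame ", k, " has ", nrow(f), " atoms; topology has ", n,
           " (topology mismatch)")
    if (!all(is.finite(f))) stop("frame ", k, " has non-finite coordinates")
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  structure(list(topology = topology, frames = frames,
                 run_id = as.character(run_id),
                 frame_spacing = frame_spacing),
            class = "cdr_ensemble")
}

#' @export
print.cdr_ensemble <- function(x, ...) {
  cat("<cdr_ensemble> ", length(x$frames), " frames x ",
      nrow(x$topology$xyz), " atoms (", x$run_id, ")\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `cdr_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL/ENDMDL block becomes one frame; a file with plain ATOM records
#' and no MODEL cards is treated as a single-frame trajectory. All models
#' must agree in atom count and atom ordering (name and residue number);
#' disagreement raises a topology-mismatch error.
#'
#' @inheritParams read_pdb
#' @param run_id run identifier to attach to the ensemble.
#' @param frame_spacing time per frame (metadata only).
#' @return a [new_ensemble()] object.
#' @export
read_multimodel_pdb <- function(path, chain = NULL, run_id = "RUN-1",
                                frame_spacing = 1) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  .scan_pdb_lines(lines, path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) <= 1L) {
    s <- read_pdb(path, chain = chain)
    return(new_ensemble(s, list(s$xyz), run_id = run_id,
                        frame_spacing = frame_spacing))
  }
  # per-model atom signature check before handing to bio3d
  model_of <- findInterval(seq_along(lines), model_starts)
  is_atom <- startsWith(lines, "ATOM")
  sig <- split(paste(substr(lines[is_atom], 13, 16),
                     substr(lines[is_atom], 23, 26)),
               model_of[is_atom])
  counts <- lengths(sig)
  if (length(unique(counts)) != 1L)
    stop("topology mismatch: models differ in atom count (",
         paste(counts, collapse = ", "), ")")
  for (k in seq_along(sig))
    if (!identical(sig[[k]], sig[[1L]]))
      stop("topology mismatch: atom ordering of model ", k,
           " differs from model 1")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          verbose = FALSE))
  atom <- pdb$atom
  keep <- atom$type == "ATOM" & .atom_keep(atom, chain)
  atom <- atom[keep, , drop = FALSE]
  if (!nrow(atom)) stop("no atoms left after chain/altloc selection")
  xyz_cols <- bio3d::atom2xyz(which(keep))
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
  topo <- new_structure(.atoms_from_bio3d(atom),
                        matrix(xyz[1L, ], ncol = 3L, byrow = TRUE))
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE))
  new_ensemble(topo, frames, run_id = run_id, frame_spacing = frame_spacing)
}

.write_pdb_models <- function(structure, frames, path) {
  at <- structure$atoms
  resid <- if ("resid" %in% names(at)) at$resid else rep("ALA", nrow(at))
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  if (length(frames) == 1L) xyz <- xyz[1L, ]  # no MODEL card for one frame
  chain <- substr(paste0(at$chain_id, "A"), 1L, 1L)
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$residue_seq,
                   resid = resid, elety = at$atom_name, chain = chain,
                   elesy = at$element, verbose = FALSE)
  invisible(path)
}

#' Write a structure to a PDB file
#'
#' Fixed-column ATOM records, coordinates at 3 decimals (PDB precision).
#'
#' @param structure a `cdr_structure`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "cdr_structure"))
  .write_pdb_models(structure, list(structure$xyz), path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, numbered from 1.
#'
#' @param ensemble a `cdr_ensemble`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cdr_ensemble"))
  .write_pdb_models(ensemble$topology, ensemble$frames, path)
}
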