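REGION_LABELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Region boundary scheme on an antibody numbering scale
#'
#' Inclusive position intervals, one per region, covering the variable
#' domain. The default follows the IMGT delimitation of a heavy-chain
#' variable domain: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
#' CDR3 105-117, FR4 118-128. Boundaries are overridable because deposited
#' annotations sometimes renumber CDR3 insertions sequentially, pushing FR4
#' (and mutations reported "in CDR3") past position 128.
#'
#' @param boundaries named list of `c(start, end)` integer pairs; names must
#'   be exactly FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @return an object of class `region_scheme`.
#' @export
region_scheme <- function(boundaries = list(
    FR1 = c(1, 26),  CDR1 = c(27, 38), FR2 = c(39, 55), CDR2 = c(56, 65),
    FR3 = c(66, 104), CDR3 = c(105, 117), FR4 = c(118, 128))) {
  if (!setequal(names(boundaries), REGION_LABELS))
    stop("boundaries must carry exactly the labels ",
         paste(REGION_LABELS, collapse = ", "))
  boundaries <- boundaries[REGION_LABELS]
  b <- t(vapply(boundaries, function(x) as.numeric(x[1:2]), numeric(2)))
  if (any(b[, 1] > b[, 2])) stop("each interval must have start <= end")
  if (any(diff(as.vector(t(b))) < 0))
    stop("intervals must be disjoint and ordered FR1 < CDR1 < ... < FR4")
  structure(list(boundaries = boundaries), class = "region_scheme")
}

#' IMGT default region scheme
#' @return a [region_scheme()] with IMGT heavy-domain boundaries.
#' @export
imgt_scheme <- function() region_scheme()

#' Numbering map: residue ordinal to numbering-scheme position
#'
#' @param positions integer positions on the numbering scale, one per
#'   residue ordinal (1-based, in chain order). Must be non-decreasing.
#' @param suffix optional character insertion suffixes ("" for none).
#' @return an object of class `numbering_map`.
#' @export
numbering_map <- function(positions, suffix = NULL) {
  positions <- as.integer(positions)
  if (anyNA(positions)) stop("positions must be integers")
  if (is.unsorted(positions)) stop("positions must be non-decreasing")
  if (is.null(suffix)) suffix <- rep("", length(positions))
  stopifnot(length(suffix) == length(positions))
  structure(list(positions = positions, suffix = as.character(suffix)),
            class = "numbering_map")
}

#' Identity numbering from a structure's author numbering
#'
#' For synthetic scaffolds (and pre-renumbered files) the author residue
#' number is already the scheme position.
#'
#' @param structure a `cdr_structure`.
#' @return a [numbering_map()] mapping ordinal k to residue k's author number.
#' @export
identity_numbering <- function(structure) {
  stopifnot(inherits(structure, "cdr_structure"))
  at <- structure$atoms
  numbering_map(at$residue_seq[match(seq_len(structure$n_residues),
                                     at$res_ord)])
}

#' Read a numbering map from a two-column TSV file
#'
#' Columns: residue ordinal (1-based) and scheme position; a position may
#' carry a trailing insertion letter (e.g. "112A"), which is stored as a
#' suffix and inherits the integer part's region.
#'
#' @param path TSV file path (header optional; lines starting with '#' are
#'   skipped).
#' @return a [numbering_map()].
#' @export
read_numbering_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("ordinal", "position"),
                          colClasses = "character")
  if (tolower(df$ordinal[1]) %in% c("ordinal", "ord")) df <- df[-1, ]
  ord <- as.integer(df$ordinal)
  if (anyNA(ord) || !identical(sort(ord), seq_along(ord)))
    stop("ordinals must be 1..R, each exactly once")
  pos_txt <- df$position[order(ord)]
  pos <- as.integer(sub("[A-Za-z]+$", "", pos_txt))
  if (anyNA(pos)) stop("unparseable positions: ",
                       paste(pos_txt[is.na(pos)], collapse = ", "))
  numbering_map(pos, suffix = sub("^[0-9]+", "", pos_txt))
}

#' Assign each residue to a framework or CDR region
#'
#' Every residue position must fall in exactly one scheme interval
#' (insertion-suffixed positions inherit the integer part's region);
#' positions outside all intervals raise an error naming them.
#'
#' @param numbering a [numbering_map()].
#' @param scheme a [region_scheme()]; IMGT by default.
#' @return an object of class `region_annotation`: `labels` is a character
#'   vector, one label per residue ordinal.
#' @export
assign_regions <- function(numbering, scheme = imgt_scheme()) {
  stopifnot(inherits(numbering, "numbering_map"),
            inherits(scheme, "region_scheme"))
  pos <- numbering$positions
  labels <- rep(NA_character_, length(pos))
  for (lab in REGION_LABELS) {
    b <- scheme$boundaries[[lab]]
    labels[pos >= b[1] & pos <= b[2]] <- lab
  }
  if (anyNA(labels))
    stop("positions outside all region intervals: residue ordinal(s) ",
         paste(which(is.na(labels)), collapse = ", "), " (position ",
         paste(pos[is.na(labels)], collapse = ", "), ")")
  structure(list(labels = labels, scheme = scheme, numbering = numbering),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation> ", length(x$labels), " residues: ",
      paste(sprintf("%s=%d", REGION_LABELS,
                    tabulate(factor(x$labels, REGION_LABELS), 7L)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Atom indices belonging to a region
#'
#' @param structure a `cdr_structure`.
#' @param annotation a `region_annotation` for the same structure (one label
#'   per residue ordinal).
#' @param region one of FR1..FR4, CDR1..CDR3, or `"framework"` (union of the
#'   four FR segments) or `"all"`.
#' @param atoms which atoms to select: `"calpha"`, `"heavy"` or `"all"`.
#' @return integer atom indices into the structure's atom table.
#' @export
region_atom_indices <- function(structure, annotation, region,
                                atoms = c("calpha", "heavy", "all")) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(structure, "cdr_structure"),
            inherits(annotation, "region_annotation"))
  if (length(annotation$labels) != structure$n_residues)
    stop("annotation covers ", length(annotation$labels),
         " residues but structure has ", structure$n_residues)
  labs <- switch(region,
                 framework = c("FR1", "FR2", "FR3", "FR4"),
                 all = REGION_LABELS,
                 region)
  if (!all(labs %in% REGION_LABELS)) stop("unknown region: ", region)
  res_sel <- which(annotation$labels %in% labs)
  at <- structure$atoms
  idx <- which(at$res_ord %in% res_sel)
  if (atoms == "calpha") idx <- idx[at$atom_name[idx] == "CA"]
  if (atoms == "heavy")  idx <- idx[at$is_heavy[idx]]
  idx
}
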