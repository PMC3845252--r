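# Structure input/output and residue bookkeeping.
#
# A `mol_structure` is a light container over an atom table (one row per
# ATOM/HETATM record of model 1) plus a residue index built in file order.
# Residue identity is (chain, resno, insertion code); insertion codes
# participate in identity and ordering is file order, never a numeric sort,
# so chain topology is preserved for link vectors.

# Standard atomic masses (u) for the elements seen in protein/DNA structures.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  "NA" = 22.990, K = 39.098, CL = 35.45, CA = 40.078, BR = 79.904, I = 126.904
)
.default_mass <- 12.011

mass_from_element <- function(element) {
  el <- toupper(trimws(element))
  m <- unname(.element_masses[el])
  unknown <- is.na(m) | el == ""
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s; using default mass %.3f u",
                    paste(unique(el[unknown]), collapse = ", "), .default_mass),
            call. = FALSE)
    m[unknown] <- .default_mass
  }
  m
}

# Guess an element symbol from a PDB atom name when the element column is
# blank (common in synthetic/minimal files).
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE"), two, one)
}

new_mol_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  needed <- c("serial", "name", "element", "chain", "resno", "icode", "alt",
              "resid", "x", "y", "z", "mass")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (!all(atoms$mass > 0)) stop("non-positive atom mass")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  first <- !duplicated(key)
  residues <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                         icode = atoms$icode[first], key = key[first],
                         stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 residues = residues,
                 atom_res = match(key, residues$key),
                 chain_order = unique(atoms$chain)),
            class = "mol_structure")
}

#' Read a structure from a PDB file
#'
#' Reads all ATOM/HETATM records of the first model of a PDB file into a
#' `mol_structure`.  When an atom is present in several alternate locations,
#' the first-listed location is kept.  Atomic masses are assigned from the
#' element column (falling back to a guess from the atom name); unknown
#' elements trigger a warning and receive the default carbon mass.
#'
#' @param path Path to a PDB file.
#' @param keep_hydrogens Keep hydrogen atoms if present (default `TRUE`; the
#'   all-atom elastic network uses every atom in the file).
#' @return A `mol_structure`: list with the atom table (`atoms`), the residue
#'   index in file order (`residues`), the atom-to-residue map (`atom_res`)
#'   and `chain_order`.
#' @seealso [write_pdb()], [make_pairs()]
#' @export
read_pdb <- function(path, keep_hydrogens = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable or unparsable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no parsable ATOM/HETATM records in ", path)
  icode <- ifelse(is.na(a$insert), "", a$insert)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  # altloc policy: one atom per (chain, residue, atom name); keep the
  # first-listed location.
  keep <- !duplicated(paste(a$chain, a$resno, icode, a$elety, sep = "|"))
  a <- a[keep, , drop = FALSE]
  icode <- icode[keep]; alt <- alt[keep]
  element <- ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                    element_from_name(a$elety), toupper(trimws(a$elesy)))
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = element,
                      chain = ifelse(is.na(a$chain), " ", a$chain),
                      resno = a$resno, icode = icode, alt = alt,
                      resid = a$resid, x = a$x, y = a$y, z = a$z,
                      mass = mass_from_element(element),
                      stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms left after filtering in ", path)
  rownames(atoms) <- NULL
  new_mol_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records (plus a terminating END line) that
#' round-trip through [read_pdb()].  Coordinates that do not fit the
#' fixed-column field (outside \[-999.999, 9999.999\] Angstrom) raise an error
#' rather than being truncated.
#'
#' @param structure A `mol_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "mol_structure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  bad <- a$x < -999.999 | a$x > 9999.999 | a$y < -999.999 | a$y > 9999.999 |
    a$z < -999.999 | a$z > 9999.999
  if (any(bad))
    stop(sprintf("%d atom(s) have coordinates outside the fixed-column PDB range",
                 sum(bad)))
  n <- nrow(a)
  ok <- tryCatch({
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", n), resno = a$resno, resid = a$resid,
                     eleno = a$serial, elety = a$name, chain = a$chain,
                     insert = ifelse(a$icode == "", NA, a$icode),
                     alt = ifelse(a$alt == "", NA, a$alt),
                     o = rep(1, n), b = rep(0, n), elesy = a$element,
                     end = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) TRUE)
  if (!isTRUE(ok) || !file.exists(path))
    stop("could not write PDB file to ", path)
  invisible(path)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), nrow(x$residues),
              paste(x$chain_order, collapse = ", ")))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)
n_residues <- function(structure) nrow(structure$residues)

#' Select a named residue subset of one chain
#'
#' @param structure A `mol_structure`.
#' @param chain Chain identifier.
#' @param range Optional inclusive `c(lo, hi)` interval of residue sequence
#'   numbers; `NULL` selects the whole chain.
#' @param label Human-readable subset label (defaults to the chain id).
#' @return A `residue_set`: the selected rows of the residue index, in file
#'   order, with the structure's residue row numbers in `$rows`.
#' @export
residue_set <- function(structure, chain, range = NULL, label = chain) {
  stopifnot(inherits(structure, "mol_structure"))
  if (!chain %in% structure$chain_order)
    stop("chain '", chain, "' not present in structure")
  res <- structure$residues
  sel <- res$chain == chain
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    sel <- sel & res$resno >= range[1] & res$resno <= range[2]
  }
  if (!any(sel))
    stop("residue range [", paste(range, collapse = ", "), "] is empty in chain ",
         chain)
  structure(list(label = label, chain = chain,
                 rows = which(sel), keys = res$key[sel]),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("residue_set '%s': chain %s, %d residues\n",
              x$label, x$chain, length(x$rows)))
  invisible(x)
}

# list of atom-index vectors, one per residue of the set (set order)
set_atom_indices <- function(structure, set) {
  stopifnot(inherits(set, "residue_set"))
  lapply(set$rows, function(r) which(structure$atom_res == r))
}

#' Declare the POUS/POUHD split of a POU chain
#'
#' The POU transcription factor consists of two DNA-binding subunits (POUS
#' and POUHD) joined by a flexible linker; the split is user configuration
#' because structures differ in their residue numbering.
#'
#' @param chain_id Chain carrying the POU protein.
#' @param pou_s_range,pou_hd_range Inclusive `c(lo, hi)` residue-number
#'   intervals of the two subunits.  They must not overlap.
#' @return A `subunit_split` object.
#' @export
subunit_split <- function(chain_id, pou_s_range, pou_hd_range) {
  stopifnot(length(pou_s_range) == 2L, length(pou_hd_range) == 2L,
            pou_s_range[1] <= pou_s_range[2],
            pou_hd_range[1] <= pou_hd_range[2])
  if (max(pou_s_range[1], pou_hd_range[1]) <= min(pou_s_range[2], pou_hd_range[2]))
    stop("POUS and POUHD residue ranges overlap")
  structure(list(chain_id = chain_id,
                 pou_s_range = as.numeric(pou_s_range),
                 pou_hd_range = as.numeric(pou_hd_range)),
            class = "subunit_split")
}

#' Assemble the two observed protein pairs
#'
#' Pair 1 is (POUHD, Sox) and pair 2 is (POUS, Sox): the POU protein is split
#' into its two subunits, each of which is paired against the whole HMG (Sox)
#' chain.  DNA chains never enter a pair.
#'
#' @param structure A `mol_structure`.
#' @param sox_chain Chain id of the HMG (Sox) protein.
#' @param split A [subunit_split()] for the POU chain.
#' @return List with elements `pair1` and `pair2`; each is a `pair_spec`
#'   with `protein_a` (the POU subunit) and `protein_b` (the Sox chain),
#'   both `residue_set`s.
#' @export
make_pairs <- function(structure, sox_chain, split) {
  stopifnot(inherits(structure, "mol_structure"), inherits(split, "subunit_split"))
  if (identical(sox_chain, split$chain_id))
    stop("Sox chain id equals the POU chain id")
  if (!sox_chain %in% structure$chain_order)
    stop("Sox chain '", sox_chain, "' not present in structure")
  if (!split$chain_id %in% structure$chain_order)
    stop("POU chain '", split$chain_id, "' not present in structure")
  pou_s <- residue_set(structure, split$chain_id, split$pou_s_range, "POUS")
  pou_hd <- residue_set(structure, split$chain_id, split$pou_hd_range, "POUHD")
  sox <- residue_set(structure, sox_chain, label = "Sox")
  for (s in list(pou_s, pou_hd, sox))
    if (length(s$rows) < 2L)
      stop("protein subset '", s$label, "' has fewer than 2 residues")
  pair_spec <- function(id, a, b)
    structure(list(pair_id = id, protein_a = a, protein_b = b), class = "pair_spec")
  list(pair1 = pair_spec(1L, pou_hd, sox),
       pair2 = pair_spec(2L, pou_s, sox))
}

#' @export
print.pair_spec <- function(x, ...) {
  cat(sprintf("pair %d: %s (%d res) vs %s (%d res)\n", x$pair_id,
              x$protein_a$label, length(x$protein_a$rows),
              x$protein_b$label, length(x$protein_b$rows)))
  invisible(x)
}
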