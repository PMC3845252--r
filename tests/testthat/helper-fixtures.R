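pdb_tempfile <- function() tempfile(fileext = ".pdb")

# minimal structure from bare coordinates (one CA bead per residue, chain A)
bead_structure <- function(pos, chain = "A") {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  coopnma:::new_mol_structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", chain = chain,
    resno = seq_len(n), icode = "", alt = "", resid = "ALA",
    x = pos[, 1], y = pos[, 2], z = pos[, 3], mass = 12.011,
    stringsAsFactors = FALSE))
}
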