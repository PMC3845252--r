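# coopnma

Protein–protein cooperativity in collective motions, from elastic-network
normal modes.

## What it is for

When a POU-family transcription factor (such as Oct-1, with its two
DNA-binding subunits POUS and POUHD joined by a flexible linker) and an
HMG-box factor (such as Sox-2) bind the same enhancer, the ternary complex
moves as a coupled mechanical system.  `coopnma` asks whether each POU
subunit moves *with* the Sox protein in the soft collective motions of the
complex, and how often one subunit, the other, or both are involved.  It is
aimed at structural bioinformaticians studying protein–protein or
protein–DNA complexes who want a dynamics-based cooperativity summary from
a single PDB structure.

## The method

1. **Normal modes.** The complex becomes an anisotropic elastic network
   (all atoms as nodes, springs within a 10 Å cutoff, uniform stiffness
   γ): $V = \tfrac{\gamma}{2}\sum_{(i,j)} (d_{ij} - d^0_{ij})^2$.  The
   exact Hessian of this potential is diagonalised; after the six rigid
   zero-modes, the essential modes 7–16 describe the softest internal
   motions.
2. **Curves.** Per mode and per protein: a motion-magnitude curve (mean
   atom displacement norm per residue,
   $M_{R_i} = \frac{1}{N_i}\sum_j \lVert d_{ij}\rVert$) or a
   rotation-angle curve (angle of each inter-residue link between the
   equilibrium and mode-deformed structures).
3. **Segment correlation.** The POU chain is split into its subunits and
   paired against Sox: pair 1 = (POUHD, Sox), pair 2 = (POUS, Sox).
   Because the proteins differ in length, for each window length
   $\lambda = \mathrm{round}(p\,x)$ (with $x$ the shorter residue count
   and $p = 1.0,\dots,0.5$) an exhaustive search finds the two
   $\lambda$-segments, one per protein, with the largest $|r|$ (Pearson).
   That yields a signed 6×10 table $c_{mn}$ per pair.
4. **Cooperativity counts.** Per table row, a filter (row median by
   default; tertile, quartile, mean also available) marks entries with
   $|c_{mn}|$ strictly above the row threshold as significant.  Over all
   360 triples (pair-1 row, pair-2 row, mode), the indexes **s1** (only
   pair 1 significant), **s2** (only pair 2) and **d** (both) are counted,
   each split into positive/negative subtypes by the signs of the
   underlying correlations.

Synthetic generators (`gen_complex()`, `gen_curve_pair()`,
`gen_corr_table()`) provide every input the pipeline needs, so the whole
method is testable without downloads.

## Worked example

```r
library(coopnma)

st  <- gen_complex(atoms_per_res = 3, seed = 1)   # synthetic POU/Sox/DNA complex
st
#> mol_structure: 390 atoms, 130 residues, chains A, B, C

cfg <- pipeline_config(structure = st, sox_chain = "B",
                       split = attr(st, "split"), seed = 1)
report <- run_pipeline(cfg)

report$medians
#>    p     pair1     pair2
#>  1.0 0.4296218 0.4699881
#>  0.9 0.5914197 0.5496257
#>  0.8 0.6440616 0.5691665
#>  0.7 0.6964122 0.6649071
#>  0.6 0.7503707 0.7566800
#>  0.5 0.7824964 0.8105180

report$filters$median$counts
#> median filter: s1 = 88 (+84/-4), s2 = 88 (+77/-11), d = 92 (+89/-3) of 360
```

Reading the output: the per-p medians rise as the windows shorten (shorter
segments correlate more easily), and the two pairs track each other
closely on this symmetric synthetic complex.  Of the 360 (row, row, mode)
triples, 92 have *both* protein pairs significantly correlated (mode D,
overwhelmingly with matching signs, 89 of 92), while 88 each involve only
one pair.  With the median filter and tie-free tables, s1 + d = s2 + d =
180 exactly, so s1 = s2 — a useful internal check.  On a real complex the
asymmetry between pair 1 and pair 2 (POUHD vs POUS) is the quantity of
interest.

For a real structure, replace the generator with a file and name the
subunit ranges:

```r
cfg <- pipeline_config(pdb = "complex.pdb", sox_chain = "C",
                       split = subunit_split("A", c(1, 75), c(83, 143)))
```

A YAML-driven command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

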