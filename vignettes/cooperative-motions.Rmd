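---
title: "Detecting protein-protein cooperativity in collective motions"
author: "coopnma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein-protein cooperativity in collective motions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnma)
```

## The question and the model

When two transcription factors bind the same regulatory DNA element -- here
a POU-family protein (e.g. Oct-1) and an HMG-box protein (e.g. Sox-2) on an
enhancer -- their function depends not only on static contacts but on
whether they *move together* in the soft collective motions of the ternary
complex.  `coopnma` quantifies that: it extracts the low-frequency normal
modes of the complex, turns each mode into per-residue motion profiles for
each protein, finds the most correlated equal-length segment pair between
the two proteins, and summarises, over many segment lengths and modes, how
often one or both protein pairs move in a significantly correlated way.

### Harmonic approximation and elastic networks

Near a stable conformation $q^0$ the potential energy is approximated by
its second-order expansion $V(q) \approx \tfrac12\,\Delta q^\top H\,\Delta
q$ with $H$ the $3N\times 3N$ Hessian.  Rather than differentiating a
force field, the Hessian is built geometrically with an elastic network
model: every pair of sites closer than a cutoff $\gamma_c$ is joined by a
harmonic spring of uniform stiffness $\gamma$.  The anisotropic network
model (ANM) potential used here is

$$V_{\mathrm{ANM}} \;=\; \frac{\gamma}{2}\sum_{(i,j)\,:\,d^0_{ij}\le\gamma_c}
\bigl(\lVert R_i - R_j\rVert - \lVert R^0_i - R^0_j\rVert\bigr)^2 ,$$

whose Hessian has the off-diagonal $3\times3$ super-block
$-\gamma\,\hat r\hat r^\top$ per spring ($\hat r$ the unit bond vector)
and diagonal blocks equal to minus the sum of the row's off-diagonal
blocks.  The pair sum is over unordered connected pairs; with this
convention a single bond along $x$ contributes the classic
$\gamma\left(\begin{smallmatrix}1&-1\\-1&1\end{smallmatrix}\right)$ coupling with
non-zero eigenvalue $2\gamma$.  The Gaussian (isotropic) variant is the
$N\times N$ Kirchhoff matrix (`build_gnm_kirchhoff()`), kept for
comparison; the pipeline itself runs on the ANM.

Because the equilibrium geometry *is* the spring rest state, rigid
translations and rotations cost no energy: a connected, non-collinear ANM
has exactly six zero eigenvalues.  Modes are numbered over the full
ascending spectrum, so the first interesting ("essential") modes are 7
onwards; the pipeline analyses modes 7--16.

Defaults: cutoff 10 Å, $\gamma = 1$, all-atom granularity, no mass
weighting.  All four are configurable.  Mass weighting
($M^{-1/2}HM^{-1/2}$) is available but off by default: the downstream
correlation statistics are invariant to uniform rescaling of a mode and
only weakly sensitive to mass weighting, and uniform masses keep the
geometry interpretable.  The zero-mode tolerance is relative --
an eigenvalue below $10^{-8}\lambda_{\max}$ counts as trivial -- which is
dimensionless and robust across network sizes.  More than six near-zero
eigenvalues on an ANM is diagnosed as a disconnected network and reported
with component sizes rather than silently analysed.

Eigendecomposition uses the dense symmetric solver (LAPACK via `eigen()`),
a deliberate choice: at the desk scale this package targets (up to a few
thousand atoms) a full dense decomposition is fast and exact, and avoids
the convergence tuning an iterative sparse solver needs.

## From modes to curves

**Motion-magnitude curves** (`magnitude_curve()`).  For mode $k$ with unit
eigenvector scattered to atoms, the magnitude of residue $i$ is the mean
displacement norm over that residue's own $N_i$ atoms:
$M_{R_i} = \frac{1}{N_i}\sum_{j=1}^{N_i} \lVert d_{ij}\rVert$.  The
divisor is the residue's own atom count (an "average over component
atoms"), not the protein-wide count; the two conventions differ only by a
per-curve constant for uniform atom counts, but the per-residue divisor is
the one that makes curves comparable across residues of different size.
Pearson correlation is scale-invariant, so the eigenvector amplitude is
irrelevant for magnitude analysis (a property the test suite asserts).

**Rotation-angle curves** (`rotation_angle_curve()`).  Each residue is
reduced to a representative point -- the all-atom centroid by default
(consistent with the all-atom magnitudes; the CA atom is selectable) --
and consecutive representatives are joined into link vectors.  The curve
holds, per link, the angle between the equilibrium link and the link in
the mode-deformed structure.  Angles *do* depend on the deformation
amplitude (the map is nonlinear), so the pipeline fixes a physical scale:
the eigenvector is scaled so the maximum per-atom displacement is 1 Å
(configurable), and the amplitude is recorded on the curve.  Numerically
the angle is evaluated as $\mathrm{atan2}(\lVert u\times v\rVert,\,u\cdot
v)$ -- identical to the clamped-arccos form but well-conditioned near 0
and $\pi$, so a rigid translation yields angles at round-off level rather
than at the $\sqrt{\epsilon}$ level the arccos form produces.  Zero-length
links (coincident representatives) get angle 0 with a warning.

## The segment search

The two proteins of a pair have different lengths, so correlations are
computed between equal-length *segments*.  For a window length $\lambda$,
`best_segment_pair()` scores **every** placement of a $\lambda$-window in
curve 1 against every placement in curve 2 by $|r|$ (Pearson) and returns
the maximising pair with its signed correlation.  The exhaustive
all-placements search is the default; a restricted common-shift variant is
available (`search = "shift"`) for comparison, since the verbal
description "shift one curve along the other" admits both readings and
the two-subscript form of the optimisation supports the exhaustive one.

Numerical choices worth stating:

* *Window lengths.* $\lambda = \mathrm{round}(p\,x)$ with $x$ the shorter
  residue count, rounding half away from zero, floored at 2.  The default
  grid is $p = 1.0, 0.9, \dots, 0.5$; shorter windows are excluded because
  very short segments correlate highly by chance.
* *Zero-variance windows.* A constant window has undefined $r$; it is
  defined as 0 and flagged degenerate, so it can never be counted as
  significant and biases nothing upward.
* *Ties.* Window pairs whose $|r|$ agree within $10^{-9}$ are treated as
  exact ties (every 2-point window has $|r| = 1$, and equal windows can
  differ at round-off), and ties resolve to the smallest start in curve 1,
  then in curve 2.  This makes the search deterministic and
  floating-point-stable.

Running the search over the $6\times10$ grid of $p$ values and essential
modes gives the signed correlation table $c_{mn}$ of a pair
(`correlation_table()`), the central intermediate of the method.

## Significance filters and cooperative modes

Per table row $m$ (one $p$), a filter defines a threshold on $|c_{mn}|$:
the row median (default), the row mean, or the lower empirical tertile or
quartile, $\inf\{v : F(v)\ge p\}$ -- the smallest order statistic whose
rank fraction reaches $p$.  Significance is *strictly greater than* the
threshold.  For rows of 10 distinct absolute values this fixes the
significant count per row exactly: 5 (median), 6 (tertile), 7 (quartile)
-- the arithmetic that also pins the total-count identities below.  The
strict inequality and the lower-quantile convention are forced by that
arithmetic; other quantile definitions break it.

Two logic matrices per pair: $L$ (significant?) and $Z$ (sign,
with $c \ge 0$ counted positive).  Counting runs over all triples of a
$p^1$ row, a $p^2$ row and a mode -- $6\times6\times10 = 360$ triples --
so the two pairs are compared at *all* combinations of segment lengths:

* $s_1$: only pair 1 significant; $s_2$: only pair 2; $d$: both.
* Subtypes: $s_{i,\mathrm{pos}}$ by the sign of the significant
  correlation; $d_\mathrm{pos}$ when both signs agree.

The implementation is a direct triple loop; an equivalent row-replication
(expand row $m$ of $L^1$ to a full matrix, combine elementwise with
$L^2$) is kept internally and the suite asserts both agree, along with an
independent recount.  Useful identities the tests exploit: with
distinct-valued rows, $s_1 + d = s_2 + d$ is exactly $6\cdot6\cdot5 = 180$
(median), 216 (tertile), 252 (quartile) -- so $s_1 = s_2$ under these
filters, and any departure from the identity in real data is a tie
diagnostic, which is why `logic_pair()` reports per-row significant
counts.

For the rotation-angle family two condensations are provided: the first
principal component of a protein's 10 angle curves (positions as
observations, modes as variables, column-centred; the condensed curve is
the PC-1 score series, sign-aligned with the per-position mean curve),
which yields a single correlation column per pair; and the unnormalised
Fourier magnitude spectrum (DC included) of each curve, which keeps the
full $6\times10$ machinery.  Note that a PC-condensed table has one
column, so per-row strict filters are vacuous there -- the condensed
analysis is read from the correlation column itself, as in the original
presentation.  Magnitude spectra are non-negative, which tends to push
correlations positive; that is a property of the transform, not of the
proteins, and is one reason the Fourier variant is regarded as the least
trustworthy of the three families.

## The synthetic study system

`gen_complex()` emulates the shape of the real inputs without any
download: three bead chains -- a 60-residue POU-like chain with an
annotated two-subunit split joined by a stretched low-density linker, a
40-residue Sox-like chain, and a 30-residue DNA-like chain -- each built
as a 3.8 Å-step random walk confined to a ball of protein-like density
($R \approx 2.1\,n^{1/3}$ Å), packed so the 10 Å cutoff yields one
connected network.  Chain sizes follow the scale of the real POU/HMG/DNA
complexes (a ~75-residue POU region, ~70-residue HMG box, tens of base
pairs); bead spacing is the canonical CA--CA distance.  Everything is a
pure function of its seed.

What it does *not* emulate: real secondary structure, side-chain packing,
sequence, or the specific interface geometry of POU/HMG complexes.
Passing tests therefore demonstrate that the *method* is implemented
correctly and behaves as the theory predicts on connected protein-density
networks -- not that any particular biological conclusion transfers.
Published correlation values for the real complexes additionally depend on
the original server's unstated elastic-network parameters, so they anchor
table layout and sign conventions here, not numerical targets.

`gen_curve_pair()` plants a shared smooth latent signal in one window of
each of two positive curves.  Both windows carry the latent plus
independent noise whose variance is calibrated from the target correlation
$\rho$ (noise variance $= \sigma^2_{\mathrm{latent}}(1-\rho)/\rho$, so the
expected window correlation is $\rho$); a multiplier scales that
calibrated noise, with 0 giving perfectly correlated windows.  Curves are
kept non-negative because they model displacement norms.
`gen_corr_table()` draws signed tables with controlled sign patterns and
per-row distinct absolute values for exercising the filter arithmetic.

## Problem sizes and defaults used in validation

The shipped validation runs use: 100 random connected networks of 10--60
nodes for the spectral suite; 20 ten-node networks for the
finite-difference Hessian check (step $10^{-4}$, tolerance $10^{-5}$); 200
random curve pairs of length ≤ 40 for the brute-force segment-search
comparison; 50 seeds at target correlation 0.95, window 20 in curves of
45/60 points, for planted-window recovery (≥ 80 % overlap in ≥ 90 % of
seeds); and the full pipeline on the default 130-residue, 3-atom-per-
residue complex (390 atoms, a 1170-dimensional Hessian), which completes
in seconds.

## Known limitations

* The POUS/POUHD residue ranges are configuration, never inferred: real
  structures number their subunits differently and no range is hard-coded.
* Only model 1 of multi-model PDB files is used, the first-listed
  alternate location is kept per atom, and no structure repair is
  attempted (missing atoms, chain breaks are the user's responsibility;
  links are formed between residues consecutive in file order).
* The counting attaches no inferential statistics -- the S/D indexes are
  descriptive summaries, and differences between them carry no p-values.
* Dense eigendecomposition bounds practical input size to a few thousand
  atoms; coarse-grain with `granularity = "c-alpha"` for larger systems.

## A minimal session

```{r example, eval = FALSE}
st <- gen_complex(atoms_per_res = 3, seed = 1)
cfg <- pipeline_config(structure = st, sox_chain = "B",
                       split = attr(st, "split"), seed = 1)
report <- run_pipeline(cfg)
report$medians                      # per-p median |c| of the two pairs
report$filters$median$counts        # s1 / s2 / d and signed subtypes
```
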