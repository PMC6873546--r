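---
title: "Principal interactions of knowledge-based pair potentials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pripot)
```

## The model

A distance-dependent knowledge-based potential (KBP) assigns an atom
pair of types $i, j$ at distance $d$ the energy

$$\Delta E^{ij}(d) = -RT \,\ln\frac{f^{ij}_{\mathrm{obs}}(d)}{f^{ij}_{r}(d)},$$

with $f_{\mathrm{obs}}$ the relative frequency of such pairs in a set
of native structures and $f_r$ a reference (background) distribution.
`pripot` types atom pairs by their *residues'* identities only. This is
deliberately coarser than atom-name typing (DOPE/DFIRE style): it makes
the atomic double sum and the residue-pair decomposition of the total
energy exactly consistent, so the total energy of a structure is both
the sum over its contacts and the sum of a 210-component pair-type
vector. Every unordered atom pair is counted once, which realises the
$\tfrac12$ of the usual double-sum notation.

The pair-type energy vectors of $n$ natives form the $n \times 210$
total-energy (TE) matrix. Principal interactions are extracted from the
column-centered matrix (CTE) by eigendecomposition of
$\Sigma = U^\top U/(n-1)$: keep the smallest $m$ leading components
reaching 80 % of total variance, compute per-variable squared-loading
contributions in percent, weight them by eigenvalues, and select the
variables whose total contribution strictly exceeds the uniform cutoff
$\tau = \sum_{j \le m} (100/p)\,\lambda_j$. Two properties are asserted
at run time on every call: $\tau$ equals the mean total contribution
(an algebraic identity), and $m$ is minimal for the variance rule.

One published description of the centering step refers to centering
the *samples*; the covariance definition requires centering the
*variables*. Column centering is the default here because the
covariance of column-centered data is what the eigendecomposition
operates on; a row-centering mode exists for completeness but feeds no
downstream machinery.

With exactly exchangeable columns the contributions are uniform and
equal $\tau$, so the strict inequality selects nothing in exact
arithmetic; in floating point, ties at $\tau$ resolve by rounding
noise. This degenerate case does not arise for data with any real
variance structure.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| contact cutoff | 15 (dfire-like) / 6 (dbni-like) | Å | the two conventional contact definitions; strict `d < cutoff` |
| min. sequence separation | 0 / 5 | residues | exclusive threshold; the non-local-only convention uses "> 5" |
| bin width | 0.5 | Å | conventional for distance-dependent KBPs |
| pseudocount | 0.01 | counts/cell | keeps log-ratios finite; scale-invariant downstream |
| reference | averaged | — | marginal product of pair and distance totals |
| power-law exponent | 1.61 | — | finite-ideal-gas convention; `alpha = 2` is the uniform-density gas |
| RT | 1 | energy | rankings, Z-scores and the selection are invariant to a global positive scale |
| variance threshold | 80 | % | the selection's component rule |

Half-open conventions are used throughout: a distance bin is
$[\ell, h)$, and "less than cutoff" is strict. Sequence-separation
filters run on gap-free 0-based internal indices assigned after
parsing, not on author-assigned PDB residue numbers.

The Delaunay-tessellation contact filter (a Bowyer–Watson
tetrahedralisation of the interaction centers; only atom pairs sharing
a tessellation edge are eligible) is a generic neighbour filter. It can
only remove contacts relative to the same scheme without it.
Near-degenerate circumsphere tests are resolved conservatively (points
within tolerance count as inside), which is the standard robustness
compromise for point sets close to coplanar.

C-alpha RMSD superposes conformations by optimal least-squares rigid
fit (SVD with reflection guard) before averaging, because decoys are
not guaranteed pre-aligned to their native; a no-superposition mode is
available. Externally provided per-decoy RMSD tables (`rmsd.tsv` in a
decoy directory) take precedence over internal superposition so
published decoy-set tables can be honoured exactly.

## Evaluation criteria and tie rules

Top1 requires the native energy to be *strictly* lowest; a tie with the
best decoy counts against recognition (conservative) with a warning.
Both Z-scores use the sample standard deviation (divisor $n-1$),
consistent with the covariance convention. The best decoy for
Z-score$_b$ is identified by lowest RMSD, never by score, and both the
native and the best decoy are excluded from the reference mean and
standard deviation. Fraction enrichment uses top-set sizes
$\max(1, \lfloor 0.2N \rfloor)$ and is undefined below $N = 5$ (its
upper bound 5 would otherwise be violated by the floor rule). Ties at
the minimum energy resolve toward the lower-RMSD structure, with a
warning. The PI statistic counts *atomic contacts* whose residue-pair
type is selected, over all contacts passing the full scheme — a count
ratio, not an energy ratio, reported as mean ± sd over a decoy set.

## What the synthetic generators emulate

`generate_chain()` grows a confined self-avoiding walk of single-center
residues: fixed 3.8 Å virtual bonds, 3.5 Å excluded volume, and
confinement to a sphere of radius $0.8 \times 3.8\,L^{1/3}$ Å, which
reproduces the packing density of globular proteins (about 110 Å$^3$
per residue). Sequences are uniform over the 20 standard residues.
`generate_decoy_ladder()` perturbs every coordinate with isotropic
Gaussian noise of per-decoy magnitude, yielding RMSD ladders that rise
stochastically with the noise (Spearman correlation > 0.9 at 50
decoys), emulating decoy sets whose RMSDs spread evenly from
near-native to very different. `generate_planted_matrix()` draws
independent Gaussian columns with a designated high-variance subset —
the covariance structure the selection procedure assumes.

What the generators do **not** emulate: real side-chain packing,
secondary structure, sequence–structure correlation (sequences are
random, so no pair type is physically privileged), or
fragment-assembly decoys with native-like topology. Consequently,
passing tests demonstrate the correctness and internal consistency of
the machinery and that the potential rewards native-like compactness
and packing against coordinate noise — not that any particular pair
type matters in real proteins. On real natives the same machinery
concentrates on hydrophobic-core pair types; here the selected set
reflects sampling variance of the energy matrix, which is exactly what
a selection run on exchangeable columns should do.

## Study conditions of the built-in benchmark

`synthetic_benchmark()` trains on 20 chains of 30 residues and
evaluates on 10 independent targets with 20 perturbation decoys each —
sizes at which the full pipeline (training, energy matrix, selection,
two evaluations) completes in seconds on one CPU while still giving
stable aggregates. Its defaults differ from the real-data presets
because one-atom-per-residue chains at this corpus size have far
sparser contact statistics than 6 000 all-heavy-atom natives:

* **Reference: power-law, $\alpha = 2$** (uniform-density ideal gas).
  The averaged reference divides out the pooled distance distribution —
  on random-sequence chains that pooled profile (excluded volume,
  bonded geometry, compact packing) is virtually the *only* real
  signal, so the averaged reference leaves pure sampling noise. The
  ideal-gas reference keeps it.
* **Cutoff 15 Å with sequence separation > 2.** The cutoff deliberately
  exceeds the ~9 Å radius of the generated chains: the reference then
  expects substantial pair density at distances the compact native
  cannot realise, making mid-range native contacts attractive and the
  expansion caused by coordinate noise costly. This is the same
  mechanism that makes long-cutoff KBPs sensitive to compactness in
  real proteins.
* **3 Å bins, pseudocount 0.1.** About 2 000 training contacts spread
  over 210 pair types support only a few counts per cell; 0.5 Å bins
  at this scale leave most cells empty, and the log of near-empty
  cells injects a positive bias into every score. Five bins and a
  firmer pseudocount keep the per-contact noise below the physical
  signal.

Under these conditions the native is ranked strictly lowest in the
large majority of targets once decoy noise reaches 2 Å, with mean
energy–RMSD correlation around +0.5 (seeds 1–5: Top1 7–10 of 10).

## Numerical choices

* Eigendecomposition uses the symmetric LAPACK path on
  $(\Sigma + \Sigma^\top)/2$; eigenvalues below zero by rounding are
  clipped, and substantial negativity warns.
* Centering checks, symmetry checks and the $\tau$-equals-mean
  assertion run at relative tolerance $10^{-8}$.
* Component order among numerically tied eigenvalues follows LAPACK's
  output; $m$ depends only on cumulative sums, which are
  tie-order-invariant.
* Serialised potentials print 17 significant digits so a round-trip
  reproduces energies bit-exactly.
* Seeded generators save and restore the caller's RNG state, so they
  are pure functions of their specs.

## Known limitations

* Residue-level pair typing cannot reproduce published DOPE/DFIRE/DBNI
  parameter tables; the potential is a generic trainable KBP with
  configurable contact schemes approximating those definitions.
* Single chains only; no mmCIF; hydrogens always excluded; MSE is the
  only nonstandard residue mapped (to MET), others are skipped with a
  warning.
* The tessellation filter is a plain Delaunay edge filter, not a
  reproduction of any published tessellation potential, and is
  quadratic-ish in practice — adequate for chains and single domains,
  not for very large complexes.
* Reduced scoring masks non-principal pair types to zero; re-weighting
  them is out of scope.
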