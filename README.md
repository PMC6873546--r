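# pripot

Principal interactions of knowledge-based pair potentials.

## What it is for

Distance-dependent knowledge-based potentials (KBPs) score a protein
conformation as a sum of pairwise atomic energies

    dE^ij(d) = -RT ln( f_obs^ij(d) / f_ref^ij(d) ),

where `f_obs` is the frequency of atom pairs *i, j* at distance *d* in a
database of native structures and `f_ref` is a reference (background)
distribution. Typing atom pairs by the identities of their residues, the
total energy of a structure *S* decomposes over the 210 unordered
amino-acid pair types:

    dE(S) = 1/2 * sum_{A,B} dE(A,B),    dE(A,B) = sum_{i in A, j in B} dE^ij(d).

Stacking the 210-component vectors of many native structures gives an
*n* × 210 total-energy matrix (TE). `pripot` extracts the **principal
interactions** — the pair types that carry most of the variance of
native energies — by:

1. column-centering TE and forming the covariance `Sigma = U'U/(n-1)`;
2. eigendecomposition `Sigma = V L V'`, eigenvalues non-increasing;
3. keeping the smallest *m* components whose variance proportions
   `t_j = 100 * lambda_j / sum(lambda)` reach 80 %;
4. per-variable contributions `C_kj = 100 * V_j(k)^2 / sum_k V_j(k)^2`
   and totals `sum_{j<=m} C_kj * lambda_j`;
5. selecting variables whose total contribution strictly exceeds the
   uniform cutoff `tau = sum_{j<=m} (100/p) * lambda_j` (at p = 210,
   the per-component factor is 1/2.1). `tau` is algebraically the mean
   total contribution.

Scoring with only the selected pair types (the *principal interaction
model*) is compared with the full model on decoy sets via six
criteria: Top1 (native strictly lowest), the native Z-score, the RMSD
of the energy minimum, the Pearson correlation between energy and
C-alpha RMSD, the 20 % fraction enrichment (range 0–5), and the
best-decoy Z-score, plus the PI statistic (fraction of atomic contacts
covered by the selected types). The audience is structural
bioinformaticians studying scoring functions and protein fold
recognition.

The package also ships seeded synthetic generators — compact
self-avoiding chains, coordinate-perturbation decoy ladders, planted
high-variance energy matrices — so the whole pipeline is testable
without any external structure database.

## Worked example

```r
library(pripot)

b <- synthetic_benchmark(seed = 1, noise_sds = seq(2, 6, length.out = 20))
print(b$selection)
print(b$eval_full)
print(b$eval_reduced)
```

```
Principal-interaction selection: 75 of 210 variables above tau = 89.63
  m = 12 components capture 80.9% of variance (threshold 80%)
  top of ranking: GLU-MET, GLN-GLU, ARG-THR, HIS-LYS, GLU-LYS, LYS-MET, GLY-MET, ARG-ILE
Decoy evaluation (full model), 10 targets:
  Top1 9/10  Z-score 2.84  RMSD 0.38  PC 0.45  F.E. 2.75  Z-score_b 1.14
Decoy evaluation (reduced model), 10 targets:
  Top1 8/10  Z-score 2.39  RMSD 0.95  PC 0.33  F.E. 2.62  Z-score_b 0.97
  PI 0.36 +/- 0.03
```

Reading the numbers: a potential trained on 20 generated natives ranks
the true native strictly lowest in 9 of 10 decoy sets (Top1), with the
native on average 2.84 decoy standard deviations below the decoy mean
(Z-score) and energies positively correlated with RMSD (PC 0.45).
Restricting scoring to the 75 selected pair types barely degrades
discrimination (Top1 8/10) while using about a third of the atomic
contacts (PI). On generated chains with uniformly random sequences no
pair type is physically special, so the selected set reflects sampling
variance of the energy matrix; on real native structures the same
machinery concentrates on hydrophobic-core pair types.

Real data go through the same functions: `read_pdb()` /
`read_decoy_set()` for PDB files and decoy directories, `kbp()` to
train (presets `contact_scheme_preset("dbni-like" | "dfire-like")`),
`build_te_matrix()`, `select_principal()`, `evaluate_collection()` and
`success_curve()`.

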