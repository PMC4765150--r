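---
title: "Structure-based MRF coevolution analysis: model, scores and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based MRF coevolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrf)
```

## The model

A multiple sequence alignment (MSA) of a protein family is modeled as a
Markov random field (Potts model) over its L columns. Each column i carries
a node weight vector $v_i \in \mathbb{R}^{21}$ over the 20 amino acids plus
the gap, treated as an additional state; each edge $(i,j)$ carries a
coupling matrix $w_{ij} \in \mathbb{R}^{21 \times 21}$. The probability of
an aligned sequence $x$ is

$$P(x) \propto \prod_i e^{v_i(x_i)} \prod_{(i,j) \in E} e^{w_{ij}(x_i, x_j)}.$$

The defining choice of this package is the edge set $E$: instead of the
complete graph used by pseudo-likelihood contact-prediction methods, $E$ is
the *intramolecular contact map* of the protein's 3D structure — residue
pairs whose C$\beta$–C$\beta$ distance (C$\alpha$ for glycine) is strictly
below 8 Å, the CASP contact definition. Because all edges then share the
structural constraint, the coevolution signal they carry is differentiated
by other constraints, notably functional ones, and the parameter space
shrinks from $O(L^2)$ to $O(|E|)$ coupling matrices, with fitting cost
linear in $|E|$.

### Fitting

The joint likelihood is intractable (global partition function), so the
package maximizes the standard pseudo-likelihood

$$\mathrm{pll}(v, w) = \sum_m \sum_i \log P(x_i[m] \mid x_{-i}[m]),$$

where each conditional is a softmax over the 21 states with logits
$v_i(k) + \sum_{j \in N(i)} w_{ij}(k, x_j)$ and a *local* partition
function $Z_i$. Every edge contributes to the conditionals of both
endpoints (the usual double counting). Overfitting is controlled by L2
penalties $R(v,w) = \lambda_v \sum_i \lVert v_i \rVert_2^2 + \lambda_w
\sum_{(i,j)} \lVert w_{ij} \rVert_2^2$ with $\lambda_v = 0.01$ and
$\lambda_w = 0.2$, flat constants applied per node and per edge (no scaling
by $L$ or by degree). $R - \mathrm{pll}$ is convex and is minimized by
L-BFGS-B (`stats::optim`) from zero initialization, so fitting is
deterministic; convergence is a projected-gradient max-norm of $10^{-5}$ or
500 iterations, whichever comes first (non-convergence returns the best
model found, with a warning). One coupling matrix is stored per undirected
edge, rows indexed by the lower-numbered endpoint; the other endpoint sees
the transpose. The gap state participates fully in fitting and is
regularized like any amino acid; it is excluded only at scoring time.

## Scores

*Pairwise.* The coevolution score of edge $(i,j)$ is the squared Frobenius
norm of the 20×20 amino-acid block of $\hat w_{ij}$ (gap row/column
excluded); a square-root variant is available behind a flag. Scores are
corrected by the average-product correction (APC),
$s(i,j) - \bar s_i \bar s_j / \bar s$, with node and overall means taken
over *existing* edges only — the sparse graph defines no score off-graph.

*Positional.* Three coevolution measures and two conservation measures are
computed per residue, each also Z-normalized over the protein (population
SD; constant vectors map to zero and are flagged):

- **NW** — KL divergence $\sum_{k=1}^{20} f_i(k)\log[f_i(k)/p_i(k)]$
  between the observed column frequencies $f_i$ (gap-excluded
  normalization) and $p_i$, the softmax of the fitted node weight over the
  20 amino acids. Couplings absorb the part of a column's preferences
  explained by its 3D neighbors, so a large NW marks a residue whose
  distribution is strongly shaped by coevolution.
- **EW** — mean APC-corrected score of the residue's incident contacts.
- **FC** — fraction of incident contacts whose pair Z-score exceeds 3.
- **KLD / JSD** — divergence of $f_i$ from the alignment-wide background
  $q$ (asymmetric, and symmetrized with mixture weight $\lambda = 0.5$,
  bounded by $\log 2$). Natural logarithms throughout.

Isolated nodes (no contacts, e.g. unresolved residues after
structure-to-MSA mapping) get EW = FC = 0 and a flag rather than being
dropped, so all vectors stay length L. The background $q$ receives a
$10^{-6}$ pseudocount on unseen amino acids so KLD stays finite.

## Evaluation utilities

Contacts are labeled positive when at least one endpoint is an annotated
functional site, negative when neither is; non-contact pairs are ignored.
ROC curves sweep all thresholds with ties grouped, so the trapezoid AUC
equals the normalized Mann–Whitney U statistic (verified against an
all-pairs oracle in the tests). Partial AUCs are unnormalized areas over
FPR ∈ [0, b], b ∈ {0.1, 0.2, 0.5}. Curves from several proteins are
vertically averaged on a common FPR grid. Normalized-rank fractions take
the top round(ρL) items (rounding half away from zero — the convention is
not dictated by the score definitions; a cutoff of zero items is reported
missing). The random baseline averages 100 score permutations. Scores can
be combined by maximum-likelihood logistic regression (ridge fallback under
separation) with repeated k-fold cross-validated AUC (20-fold, 30 repeats
by default; single-class training folds are skipped with a warning).

## The synthetic world

The generator exists so that every claim the package makes can be verified
without external downloads. It emulates:

- **Structure:** a self-avoiding 3D random walk with 3.8 Å steps (the
  C$\alpha$ virtual bond) and a 4 Å excluded volume, giving a sparse,
  connected 8 Å contact graph (mean degree ≈ 7 at L = 50, comparable to
  globular proteins).
- **Model:** node fields drawn i.i.d. $N(0, \sigma_v^2)$ and a handful of
  "strong" edges carrying a symmetric favorable two-letter block
  ($w(a,b) = w(b,a) = c$ for one random pair $a \neq b$), with the favored
  letters given neutral (zero) fields at the two coupled positions; all
  other couplings are exactly zero, so the planted signal is analytically
  transparent and independent of the field draw.
- **Alignment:** single-site Gibbs sampling from the exact model
  conditionals (burn-in 100 sweeps, thinning 5 — strong couplings make
  single-site chains sticky, and 5 full sweeps between draws keeps rows
  close to independent), verified for L ≤ 3 against brute-force
  enumeration of the joint distribution.
- **Sites:** the nodes incident to strong edges, optionally diluted with
  random decoys.

### Choice of generator defaults

The defaults are $\sigma_v = 1.5$ and $c = 9$, fixed after a design-phase
power analysis and not revisited. Three considerations drove them:

1. *Column conservation.* $\sigma_v = 0.1$ (near-uniform columns) is not a
   realistic protein family: real columns are conserved. It is also the
   worst case for pseudo-likelihood estimation noise — with M = 2000
   sequences every amino-acid pair combination has ~4.5 expected
   co-occurrences, and the flat $\lambda_w = 0.2$ penalty (negligible
   against a data term summed over 2000 rows) leaves per-entry noise of
   ~0.5, i.e. background edge norms of ~130 that swamp any single planted
   entry. $\sigma_v = 1.5$ gives a median top-residue frequency around
   0.3, typical of family alignments, and concentrates counts so that
   background norms stop drowning the signal.
2. *Neutral favored-letter fields.* With random fields of sd 1.5, the
   favored pair can land on letters whose fields are strongly negative, in
   which case even a large coupling never produces co-occurrences — the
   "strong" edge is strong on paper only, and recovery results fluctuate
   wildly with the letter draw. Zeroing the fields of the two favored
   letters at the two coupled positions makes the planted contrast a
   property of the coupling alone.
3. *Coupling strength.* With neutral favored fields, $c = 9$ puts the
   favored pair's lock-in probability near 0.5: strong enough that the
   coupling is cleanly recovered from a few hundred sequences (compensating
   charge pairs and disulfides behave this way), yet variable enough that
   the coupling remains identifiable separately from the node weight. This
   balance matters for the NW score specifically: if a pair locks in
   almost deterministically, the coupled columns become near-constant,
   node weight and coupling are only jointly identified, and the L2 ratio
   ($\lambda_w / \lambda_v = 20$) pushes the whole explanation into the
   cheap node weight — the NW signal then vanishes even though the edge
   signal is huge. Weak couplings (c = 3) err the other way: recoverable
   in rank terms only at much larger M.

A caveat found during the same analysis and kept as a documented
limitation: on sparse graphs the APC node means are contaminated by the
node's own few edges. In an unrealistically uniform background
($\sigma_v = 0.1$) with very strong couplings, concentration-induced
estimator noise at the coupled columns inflates their node means enough
that APC *inverts* the ranking (raw AUC 0.97, APC AUC 0.26 in one such
configuration). In the realistic regime the correction behaves as
intended. Users applying the package to alignments with extreme
composition should inspect raw scores alongside APC scores.

### What a green test establishes — and what it does not

The synthetic MSAs are i.i.d. samples from the true model: they contain no
phylogenetic correlation, no indels beyond the gap state, no alignment
error, and no sequence redundancy (consequently no sequence reweighting is
applied — the reference procedure states none either, and the optional
80%-identity reweighting flag stays off by default). Recovery results on
this world verify the estimator and the score algebra; they do not certify
performance on real families, where effective sequence numbers and
phylogenetic bias matter.

## Numerical choices

- Strict `<` at the 8.0 Å cutoff; ties at exactly 8.0 are excluded.
- `min_separation = 1`: no sequence-separation filter by default (the
  contact definition states none), but the knob exists.
- Softmax computations are max-shifted; conditionals sum to 1 to machine
  precision.
- Z-scores use the population SD; the difference from the sample SD
  vanishes for large L.
- Top-k rounding is half away from zero; ROC ties are grouped at one
  threshold.
- Ambiguity codes (X, B, Z, J, U, O) encode as gap: the 21-state model has
  no ambiguity semantics.
- Unresolved structure residues become isolated columns rather than being
  guessed into the graph.
- The L=2 Gibbs-oracle comparison allows ~2% of the 441 cells outside the
  3-standard-error band: 441 simultaneous 3σ checks are expected to leave
  ~0.3% outside by chance alone, and residual autocorrelation of the
  thinned chain widens a few cells further.

## Worked example

```{r example, eval = FALSE}
# simulate a 50-residue protein with 5 strongly coevolving contacts
bench <- simulate_benchmark(L = 50, n_strong = 5, M = 2000, seed = 7)
model <- fit_mrf(bench$msa, bench$graph)
pairs <- score_pairs(model)       # raw, APC, Z per contact
res   <- score_residues(model, bench$msa)  # NW/EW/FC/KLD/JSD (+ _z)

# do APC-corrected scores recover the planted contacts?
truth <- as.integer(seq_len(nrow(bench$graph$edges)) %in%
                    bench$planted$strong_edges)
roc_and_auc(pairs$apc, truth)$auc

# are planted functional sites enriched in NW?
lab <- as.integer(res$position %in% bench$sites)
roc_and_auc(res$nw_z, lab)$auc
```

Fitting the L = 50, M = 2000 instance takes a few minutes on one CPU; the
cost of one objective evaluation is linear in the number of contacts
(asserted in the tests by counting edge visits, 2·M·|E| per evaluation).

## Known limitations

- Sparse-graph APC (see above): node means over few edges are noisy and
  self-contaminated; the classical correction assumes a complete score
  matrix.
- FC's denominator is the number of incident contacts (the sparse model
  defines no other pairs), so FC values of low-degree residues are coarse.
- No sequence reweighting by default; families with heavy redundancy will
  overweight clades.
- The optimizer warning at 500 iterations is common for M ≥ 1000 with the
  very tight default gradient tolerance; the returned model is fully
  usable (objective changes beyond that point are in the noise floor of
  the scores).
- Whether the original procedure regularized gap parameters differently,
  or used sequence weighting, is unstated; this package regularizes
  uniformly and applies no weighting.
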