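---
title: "Methods: signal peptide gain and loss across ortholog families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal peptide gain and loss across ortholog families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpevo)
```

## The question and the model

Orthologous bacterial proteins are not guaranteed to share their cellular
destination: a cleavable Sec signal peptide — the ~20–30-residue N-terminal
targeting segment with a positively charged n-region, a hydrophobic h-region
and a polar c-region ending in a signal peptidase I A-x-A-type motif — can be
gained or lost along a lineage. `sigpevo` reconstructs these transitions on
the trees of ortholog clusters and asks how they relate to annotation error,
to molecular mechanism, and to bacterial lifestyle (free-living, commensal,
endosymbiotic).

The analysis treats the presence of a signal peptide as a binary character
observed at the leaves of each cluster tree. Fitch parsimony assigns
ancestral state sets that minimise the number of state changes: the
bottom-up pass takes the intersection of the children's sets when it is
nonempty and otherwise their union (each union is one change); the top-down
pass intersects each node's set with its parent's final set, falling back to
the node's own set. A branch is a **gain** when the final sets go {0}→{1}, a
**loss** for {1}→{0}, and **uncertain** whenever either endpoint remains
ambiguous ({0,1}). This uncertainty rule — ambiguity at either endpoint, per
branch — is one of several defensible operationalisations (one could instead
count changes over all minimal labelings); it was chosen because it is
deterministic and directly checkable against brute-force enumeration, which
the test suite does exhaustively for small trees. The same machinery runs on
the three-state lifestyle character (0 free-living, 1 endosymbiont, 2
commensal), and each branch's lifestyle transition class is read off the
child's final set.

Because parsimony needs rooted trees and tree inference yields unrooted
ones, trees are rooted at the midpoint of the longest leaf-to-leaf path. Tied
diameter pairs are broken by the lexicographically smallest pair of leaf
labels so rooting is deterministic; if the midpoint falls exactly on a node
the root attaches there. When no external tree is supplied a neighbor-joining
tree on `1 − identity` distances stands in; it is intentionally uncorrected,
because the stand-in only needs topological plausibility on synthetic data —
real analyses are expected to supply externally inferred trees.

## Consensus secretion states and cluster classes

Per-protein secretion states are a consensus over three predictor outputs
with strict priority: a twin-arginine (Tat) call rejects the whole cluster
(Tat substrates use a different pathway and would confound Sec-signal
analysis); agreement of the two Sec predictors yields POSITIVE or NEGATIVE;
disagreement discards the protein. Clusters keep a class label — positive,
negative or mixed — and only mixed clusters (the ones that must contain at
least one transition, or an annotation error) enter the parsimony analysis.
Clusters with fewer than three retained members are dropped, since no
meaningful tree exists below that size.

The package does not reimplement any published predictor. Its scorer is a
transparent rule-based stand-in for the tripartite architecture: an
admissible cleavage point needs a net-positive n-region prefix (2–5
residues), a hydrophobic stretch of ≥ 7 residues with mean Kyte–Doolittle
hydropathy ≥ 1.6, and small residues ({A, G, C}) at the −3/−1 motif
positions, with the cleavage point inside residues 15–40. The score exceeds
0.5 exactly when such a cleavage point exists. The 0.5 threshold, the
hydropathy cutoff and the motif set are exposed as arguments; S was left out
of the motif set to keep spurious cleavage points rare in random sequence.
The Tat detector looks for the (S/T)-R-R-x-F-L-K consensus with invariant
arginines and configurable degenerate flanks.

## Gene start correction between the two parsimony rounds

A mis-annotated gene start that truncates the signal peptide produces a
spurious loss. For every consensus-negative member of a mixed cluster the
package derives a search window from the alignment: the first-residue offsets
(in ungapped residues) to every signal-peptide-bearing member, maximised in
each direction, plus 30 residues on both sides. Every in-frame ATG/GTG/TTG
whose shift lies inside the window yields a candidate protein (upstream
candidates are discarded if an in-frame stop intervenes), each candidate
N-terminus is re-predicted, and a decision is taken with fixed priority: a
Tat-positive candidate rejects the cluster; any reliable positive candidate
is accepted (highest SignalP-like score, ties by smallest absolute shift,
then codon); otherwise a reliable negative keeps the annotation; if no start
gives a reliable prediction the protein is deleted as discordant. When only
the unchanged start is reliably negative and some shifted candidate is
discordant, the protein is kept as negative — deletion is reserved for
proteins that are unreliable at every start, the conservative reading of the
priority list. Offsets are measured in residue space and converted to
nucleotides (×3) because windows defined directly on alignment columns are
ill-defined across gaps.

After the corrections the clusters are re-filtered and re-classified, the
alignments updated, and the parsimony analysis re-run; the report compares
both rounds (kept-event and kept-mixed-cluster fractions).

## Event mechanisms

For each gain or loss, the molecular route is inferred from the alignment of
the extant descendants of the branch's parent node — the last common ancestor
before the event. (Only the latest event on any root-to-leaf path is
analysed; an event with another event below it is superseded, and opposite-
type ancestor/descendant pairs are reported as reversals.) For each pair of a
signal-peptide-bearing descendant s and a signal-peptide-free descendant t,
the length ratio `lr` is the number of residues of t inside the alignment
columns of s's signal peptide, divided by the signal peptide length. `lr ≈ 0`
means the segment was inserted or deleted wholesale; `lr ≈ 1` means the
segment is still there and the event proceeded by point substitutions. An
event's `lr` is the mean over pairs (a representative-pair or pooled variant
would also be defensible; the mean is symmetric and stable). Events are
classified indel at `lr ≤ 0.1`, substitution at `0.9 ≤ lr ≤ 1.1`, and
intermediate otherwise; both thresholds are arguments. For substitution-like
pairs the package also splits N-terminal identity into the three cleavage-
site columns (−3..−1) versus the remaining signal peptide columns, using the
shorter-sequence normalization throughout (identical residues divided by the
shorter ungapped length — so a fragment aligned perfectly to a longer
sequence scores 1).

## Lifestyle association statistics

The per-cluster discrimination score
`d = (a⁺ − a⁻)/(a⁺ + a⁻) − (b⁺ − b⁻)/(b⁺ + b⁻)` contrasts the signal peptide
balance of two lifestyles inside one cluster; it is antisymmetric and bounded
in [−2, 2], with the extremes reached when one lifestyle is all-secreted and
the other all-cytoplasmic. Each score is accompanied by a two-tailed Fisher
exact p-value on the underlying 2×2 table; GO enrichment uses the one-sided
(upper-tail) Fisher test per term per group against the pooled background,
after each protein's annotation set is closed over `is_a` ancestors. No
multiple-testing correction is applied by default, matching the raw-Fisher
reporting convention of this analysis type; `stats::p.adjust` can be applied
to the returned tables by the user. Distribution comparisons use the
two-sample Kolmogorov–Smirnov test (asymptotic p) and, for the joint
distribution of genome size and secreted fraction, a permutation test on the
energy-distance statistic: the named multivariate two-sample test family has
no canonical multivariate construction, so the energy statistic — which has
the same null logic under label permutation — stands in, with the p-value
`(1 + #exceedances)/(B + 1)` and a fixed seed.

## The synthetic-data generator

No public dataset with known ancestral secretion states exists, so the
package ships a generator whose ground truth is exact by construction. Its
defaults describe the study conditions the package is validated under:

* 153 species in one order, nested genera/families consistent with a rooted
  binary species tree; lifestyles drawn independently per species with
  fractions 120:21:12 (free-living:endosymbiont:commensal); nominal genome
  sizes per lifestyle with means 3596/1066/3730 genes (endosymbiont genomes
  markedly reduced).
* 500 ortholog families; sizes `3 + NegBin(size 1.2, mu 16)` truncated to the
  species count, giving a mean near 20 with a long tail and a mode at the
  minimum size of 3, the shape typical of ortholog databases. Membership is
  weighted by genome size, and secreted-ancestor families down-weight
  endosymbionts (factor 0.4) so that secretome size co-varies with lifestyle.
* Per branch: loss probability 0.02 on signal-peptide-bearing lineages and
  gain probability 0.005 (the 4:1 asymmetry this analysis type reports);
  mechanism mix 0.8 indel : 0.2 substitution; background substitutions at
  0.02 per site per branch on the mature sequence (active signal peptides
  change only through events, keeping the truth exact).
* Signal peptides are built from the tripartite model (n-region 2–5 with a
  basic residue, h-region 8–14 hydrophobics, polar c-region ending A-x-A,
  cleavage inside 15–40); indel gains prepend a fresh segment (new alignment
  columns), substitution events mutate the existing N-terminal residues in
  place. 2% of secreted-ancestor families carry a Tat-type R-R signal instead
  and are expected to be rejected whole.
* Coding sequences are back-translated with uniform synonymous codon choice
  (codon bias is irrelevant here) into 300 nt of random context per side;
  10% of signal-peptide-bearing members get their annotated start moved
  downstream past the signal peptide to the next in-frame start, the planted
  annotation error the correction round must undo.
* Predictor noise is a per-tool flip probability; the default is zero so
  that the generator's calls equal the ground truth, and tests switch noise
  on explicitly where it is the subject.

Two consistency passes keep the ground truth unambiguous. A repair pass
edits leaves whose heuristic call or Tat call drifted from the planted state
(random mature sequence occasionally forms a plausible N-terminus); a
sanitization pass removes alternative in-frame starts that would spuriously
predict as signal-peptide-positive, by rewriting the offending context codon
or making a synonymous codon swap (for ATG, by breaking the spurious
architecture with point edits mirrored in the alignment). Without this the
start-correction scan would "discover" signal peptides the truth does not
contain, and no-error runs would not be no-ops.

What the generator does **not** emulate: realistic substitution matrices or
rate heterogeneity, codon-level selection, horizontal transfer, alignment
error (the emitted alignment is the true one), clustering error in ortholog
assignment, and any evolutionary dynamics of lifestyle (lifestyles are
independent draws at the tips, so there is no ground truth for lifestyle
transitions — the three-state parsimony code is validated on constructed
cases instead). Passing recovery tests therefore demonstrates correctness of
the inference machinery under the model's assumptions, not robustness of the
biology to alignment or prediction error on real data.

## Estimating the loss:gain rate asymmetry

The raw called loss:gain count ratio is not an estimate of the underlying
rate ratio, for two reasons: losses can only occur on branches whose parent
carries a signal peptide (and gains on the complement), so unbalanced state
occupancy distorts the counts; and analysing only mixed clusters conditions
on at least one event, inflating the apparent rates. `estimate_event_rates()`
therefore divides each event count by its opportunity count (branches with
the corresponding unambiguous parent state) and adds the branches of pure
positive/negative clusters as event-free opportunities. On simulations with
a 4:1 loss:gain rate ratio this estimator recovers the ratio within the
Poisson-propagated sampling error of the event counts, which is what the
recovery test asserts (agreement with 4 within 3 standard errors of the log
ratio).

## Numerical choices and edge cases

* Midpoint rooting treats distances within `1e-9` as ties; total branch
  length is conserved to the same tolerance.
* NJ branch lengths below zero are clamped to 0; a pair with no shared
  aligned columns has identity 0 by definition.
* Polytomies are resolved deterministically (lexicographic order, zero-length
  branches) before Fitch so per-branch event accounting is well defined; the
  root branch generates no event.
* Fisher tests, KS and the Spearman t-approximation are delegated to
  `stats::fisher.test`/`phyper`, `stats::ks.test` and a rank-based
  computation with average ranks; the test suite checks them against
  exhaustive enumeration and direct ECDF/rank oracles.
* The permutation p-value is never below `1/(B + 1)`; B defaults to 999
  (499 inside the pipeline report for speed).

## Problem sizes used in validation

The validation suite runs the full pipeline at 150 species × 500 families
once (the package's reference reproduction scale, a few minutes on one CPU),
and uses 40–200-family simulations for the targeted recovery checks:
event recovery and mechanism recovery on a 60-species × 200-family run with
elevated rates (loss 0.04, gain 0.01, mechanism mix 0.5) for statistical
power at fixed seeds, and start-error recovery on a 60-species × 150-family
run at the default 10% corruption rate. Fitch-versus-brute-force equivalence
is exhaustive over all labeled rooted binary shapes with up to 5 leaves
crossed with all leaf assignments, and randomly sampled (with a library
cross-check) at 6–7 leaves, where full enumeration is no longer practical.

## Known limitations

* The heuristic scorer is far weaker than real predictors; its purpose is a
  consistent, testable stand-in, and absolute secretome fractions from it
  should not be interpreted biologically.
* Uncertain-event semantics follow the per-branch ambiguity rule above;
  analyses that count ambiguous regions once rather than per branch will
  report different uncertain totals.
* The energy-distance permutation test is a stand-in for an unspecified
  multivariate two-sample test; only its null logic, not its exact statistic,
  matches other implementations.
* `read_sp_dataset()` recovers the species of a protein from the
  `<cluster>|<species>` id convention of the generator; datasets from other
  sources need a `proteins` table supplied in code.
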