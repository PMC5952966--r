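# sigpevo

Orthologous bacterial proteins can differ in whether they are secreted: the
cleavable Sec **signal peptide** — a ~20–30-residue N-terminal segment with a
positively charged n-region, a hydrophobic h-region and a polar c-region
ending in an A-x-A-type cleavage motif — is gained and lost in the course of
evolution. `sigpevo` is an R package for reconstructing and characterising
these events across ortholog clusters, for researchers in comparative
genomics and molecular evolution. It implements:

* **Consensus secretion states** from per-protein predictor calls (SignalP-,
  Phobius- and TatP-like outputs): a twin-arginine (Tat) call rejects the
  whole cluster, agreement of the Sec predictors gives a reliable
  positive/negative, disagreement discards the protein; clusters are
  classified positive / negative / mixed.
* **Fitch parsimony** on rooted cluster trees for the binary signal peptide
  state and the 3-state lifestyle character (free-living / endosymbiont /
  commensal), with branch-level event calling: gain ({0}→{1}), loss
  ({1}→{0}), uncertain (ambiguous endpoint), and the keep/stay non-events;
  midpoint rooting and a neighbor-joining stand-in for externally built
  trees.
* **Gene start correction**: mis-annotated starts masquerade as signal
  peptide losses, so every reliable-negative member of a mixed cluster is
  re-scanned over alternative in-frame ATG/GTG/TTG starts inside an
  MSA-derived window (maximal first-residue offsets to signal-peptide-bearing
  members, plus 30 residues each way), candidates are re-predicted, and a
  fixed priority rule accepts/rejects them; then a second round of parsimony
  measures how many round-1 events survive.
* **Mechanism classification** via the length ratio
  `lr = L(aligned non-SP N-terminus) / L(signal peptide)`: whole-segment
  indels give `lr ≈ 0`, substitution-driven events `lr ≈ 1`; latest-event
  filtering, reversal detection and cleavage-site vs. remainder identity
  profiles.
* **Lifestyle association**: the per-cluster discrimination score
  `d(a,b,g) = (a⁺−a⁻)/(a⁺+a⁻) − (b⁺−b⁻)/(b⁺+b⁻)` (bounded in [−2, 2]) with
  two-tailed Fisher tests, GO term enrichment (ancestor-closed annotations,
  one-sided Fisher against the pooled background), Kolmogorov–Smirnov and
  energy-distance permutation tests, Spearman correlations.
* A **synthetic-data generator** producing fully ground-truth-labelled
  datasets — species tree and taxonomy, lifestyles, ortholog families with
  planted gain/loss events of both mechanisms, coding sequences with genomic
  context, planted gene start errors, noisy predictor calls, GO annotations —
  so the entire pipeline is testable end to end without any downloads.

## Worked example

```r
library(sigpevo)

cfg <- sim_config(seed = 42, n_species = 40, n_families = 60)
dataset <- simulate_dataset(cfg)
report <- run_all(dataset)
report
#> <sp_run_report>
#>   clusters round 1: 44 negative, 1 positive, 15 mixed
#>   clusters round 2: 44 negative, 4 positive, 12 mixed
#>   events round 1: 6 gain / 32 loss / 2 uncertain
#>   events round 2: 4 gain / 16 loss / 2 uncertain
#>   kept: 55.0% of events, 80.0% of mixed clusters
```

Reading the output: of 60 simulated families, 15 are *mixed* (members both
with and without a signal peptide) and enter the parsimony analysis. Round 1
calls 32 losses, but 10% of secreted members carry a planted gene start
error, so many of those losses are annotation artifacts; the correction step
rescues them (3 clusters even become all-positive) and round 2 keeps 16
losses — the kept-event fraction of 55% is the signature of spurious losses
being removed. The loss:gain *rate* asymmetry is estimated per opportunity,
not from raw counts:

```r
estimate_event_rates(report$round2$events, report$classes_round2)
#> # A tibble: 1 × 7
#>   n_loss n_gain loss_opportunities gain_opportunities loss_rate gain_rate ratio
#> 1     16      4                466               1626    0.0343   0.00246  14.0
```

(with only 4 gains the ratio is noisy; the validation suite estimates it on
a 200-family run, where it recovers the simulated 4:1 within sampling
error). Mechanisms split as expected for a generator with an 80:20
indel:substitution mix:

```r
report$mechanism$summary
#> # A tibble: 4 × 3
#>   type  category         n
#> 1 gain  indel            3
#> 2 gain  substitution     1
#> 3 loss  indel           12
#> 4 loss  substitution     4
```

`tidy(report)` returns the branch-level event table (with taxonomic ranks),
`glance(report)` a one-row summary, and `autoplot(report, type = "secretome")`
/ `"identity"` / `"lr"` the standard figures. `write_sp_dataset()` /
`read_sp_dataset()` persist a dataset as plain FASTA/TSV/Newick/OBO files.

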