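---
title: "Interspecies miRNA target prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspecies miRNA target prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarp)
```

## The problem

Host cells and the viruses that infect them regulate each other's genes
through microRNAs: a host miRNA can silence a viral transcript, and a
virus-encoded miRNA can silence a host mRNA. Most established target
predictors assume intra-species interactions and lean on evolutionary
conservation of the target site, which is meaningless across a host--virus
boundary. `mirtarp` predicts target sites from sequence and thermodynamics
alone, so the same machinery screens host miRNAs against viral genomes and
viral miRNAs against host transcripts (for the human side, 3'UTR FASTA is
the recommended input, since animal miRNA sites concentrate there).

The pipeline has two decision stages and one annotation stage:

1. **Seed scan.** Find every maximal run of at least `b` consecutive
   Watson--Crick pairs (default `b = 7`) between the miRNA and the target
   read antiparallel. This is implemented as an exact k-mer index lookup:
   every length-`b` window of the target is indexed, and every length-`b`
   window of the miRNA's reverse complement is looked up and extended to
   maximality. Unlike a heuristic similarity search, the scan is provably
   complete: a run of length at least `b` always contains a length-`b`
   window and is therefore always found.
2. **Duplex assessment.** Around each seed (extended by `site_flank`,
   default 15 nt per side; overlapping windows of the same miRNA/target/
   strand are merged first), compute the minimum free energy of the
   intermolecular miRNA--site duplex under a nearest-neighbor model, and
   keep the site iff `mfe <= e` (default `e = -25` kcal/mol, inclusive, so
   a duplex exactly at the cutoff passes).
3. **Accessibility annotation.** Fold the target region around each
   surviving site (`fold_flank`, default 70 nt per side) and report the
   local folding MFE and the unpaired fraction of the site. This is
   reported, never filtered on: a site in a tightly structured region is
   still listed, with the evidence alongside.

## The energy model

Both thermodynamic engines share one nearest-neighbor parameter set
(`inst/extdata/rna_nn_dg37_v1.tsv`), Turner-style Gibbs free-energy
increments at 37&nbsp;°C in kcal/mol: a 6×6 stacking table over the pair
alphabet {AU, UA, GC, CG, GU, UG}; bulge, internal-loop and hairpin
initiation penalties by loop size (logarithmic extrapolation beyond the
tabulated sizes, coefficient `lxc`); an internal-loop asymmetry term
(0.6 kcal/mol per unpaired-length difference, capped at 3.0); an
intermolecular duplex initiation of +4.10; a +0.50 penalty per helix end
closed by AU/UA/GU/UG; and a linear multibranch-loop model
(offset +9.30, −0.90 per branch, 0.00 per unpaired base). The file is
versioned, plain text, and documented in its header; `--energy-params` /
`load_energy_model(path)` swap in an alternative set.

Deliberate simplifications, chosen so that the model is unambiguous and a
brute-force enumeration oracle can verify both engines exactly: no dangling
ends, no coaxial stacking, no terminal-mismatch tables, no special 1×1 /
2×1 / 2×2 internal-loop tables, no tetraloop bonuses, and no
stack-across-the-bulge rule for length-1 bulges. The terminal AU/GU penalty
is applied uniformly at every helix end -- duplex ends, pairs flanking a
bulge or internal loop, hairpin closing pairs, multiloop closing pairs and
branches, and exterior-loop branches. An isolated pair is both ends of its
helix, so it collects the penalty twice. Predicted energies therefore
differ by roughly 1--3 kcal/mol from tools that include mismatch and dangle
terms; rankings of strong sites are hardly affected, and the default cutoff
was calibrated to this family of models.

**Duplex engine** (`hybridize()`). The hybrid structure is restricted to
the standard hybridization model: antiparallel, non-crossing pairs
(Watson--Crick and G:U wobble), no intramolecular pairs within either
strand, and loops limited to stacks, bulges and internal loops with total
unpaired size at most `max_loop = 30`. With branching excluded, dynamic
programming over (miRNA position, window position) is exact:
`V(i,j)`, the best sub-duplex whose outermost pair is `(i,j)`, is the
minimum over terminating the helix or bridging to an inner pair `(k,l)`
with a stack or loop term. The returned energy always equals
`score_duplex()` of the returned pair list -- the independent re-scoring
function doubles as the oracle's scorer. A pairless duplex is defined as
+Inf (not 0), so empty structures can never pass any cutoff. Windows are
capped at 200 nt (seeds already localize sites); the rare merged window
longer than that is tiled with overlapping 200-nt sub-windows and the
lowest-MFE duplex is kept, preserving one reported site per merged window.

**Folding engine** (`fold_local()`). Zuker-style MFE folding of the local
window under the same parameters, with hairpins (≥ 3 unpaired bases),
stacks, bulges, internal loops (≤ `max_loop`) and multibranch loops under
the linear model. The empty structure scores 0, so the folding MFE is
never positive. Windows are capped at 300 nt; the default `fold_flank` of
70 nt per side follows common accessibility-window practice (an
artifact-level choice -- not a value inherited from any reference tool) and
keeps the default window at ~190 nt for a 22-nt site.

**Tie-breaking.** Co-optimal structures are resolved by a fixed,
documented traceback order so unpaired fractions and alignment strings are
reproducible: in the fold, stack, then interior/bulge (inner 5' position
ascending, 3' descending), then hairpin, then multibranch (split point
ascending); in the duplex, helix termination first, then transitions with
inner 5' position ascending and 3' descending; duplex start pairs are
scanned miRNA-position ascending, window-position descending. Seed matches
tie-broken by (target start, miRNA start, target end).

## Seed-stage pairing rules

The seed requires Watson--Crick pairs only -- no G:U wobble -- because the
scan tests identity against the reverse complement, which cannot represent
wobble; wobble pairs are admitted in the thermodynamic stages. `N` never
pairs anywhere: windows containing `N` are not indexed, extension stops at
`N`, and the energy engines assign no pair type to it, so unknown bases can
never fabricate stability. The seed's position on the miRNA is
unconstrained; no canonical 5'-end seed (positions 2--8) is imposed, since
the match length requirement, not position, is the filter here. By default
only the forward strand of each target record is scanned; `--both-strands`
additionally scans the reverse complement (ambisense and negative-sense
viral genomes) and reports those sites with strand `-` in forward-strand
coordinates.

## What the synthetic fixtures emulate

`generate_fixture()` produces miRNAs (random 20--24 nt at a requested GC
fraction), i.i.d. random targets, and planted sites with a machine-readable
truth table: `perfect` plants are exact reverse complements, `mismatched`
plants carry 1--3 substitutions, `bulged` plants a 1--2 nt target-side
insertion. Planted intervals are separated by at least `min_gap`
(default 40 nt) so that, at the default `site_flank`, each plant's
assessment window stays distinct and recovery is countable per plant.
`shuffle_preserving_dinucleotides()` (a random Eulerian path on the
dinucleotide transition graph) turns any target into a composition-matched
negative control.

The i.i.d. background is the simplest defensible null: it does not emulate
codon structure, repeat content, or the skewed composition of real viral
genomes. Passing the planted-recovery and shuffled-control tests therefore
shows the machinery is sound -- complete seed scan, correct energies,
monotone thresholds -- not that the default cutoffs are optimally tuned for
any particular virus family. On real data the practical knobs are `b`
(sensitivity of the scan) and `e` (stringency of the thermodynamic
filter); both reports are monotone in these, so relaxing them only ever
adds sites.

## Numerical and testing choices

Energies are plain doubles; the DP fill and its traceback evaluate
identical expressions, so tracebacks match cell values to within 1e-9
kcal/mol and re-scoring (`score_duplex()`, `score_structure()`) agrees with
engine output to better than 1e-6. Both engines are verified against
exhaustive enumeration of all admissible structures on windows where that
is tractable (≤ 18 nt combined); at those sizes multibranch loops are never
energetically admissible, so the multiloop path is verified by hand-summed
explicit structures and by re-scoring DP tracebacks of larger (40--190 nt)
windows, where multibranch optima do occur. The seed scanner is verified
against a naive per-diagonal scan on hundreds of random instances. The test
suite's problem sizes (100 enumeration instances per engine, 200 seed
instances, 50 recovery fixtures of 600 nt, and a 100-miRNA × 200-kb
throughput screen) were chosen to exercise every code path at desk scale;
the throughput case extrapolates linearly, as indexing is linear in target
length and each merged window costs a fixed-size DP.

## Known limitations

- Energies are MFE point estimates; no partition function, ensemble
  probabilities, or suboptimal structures (enumeration exists only as a
  test oracle).
- Accessibility is a folding MFE over a fixed window, not an opening
  energy; it is deliberately reported rather than thresholded, and is not
  combined with the duplex energy into a net score.
- The duplex cutoff applies to the duplex MFE alone.
- No temperature rescaling: the shipped parameters are 37 °C increments.
- Multi-segment viral genomes are keyed per FASTA record; aggregation to
  species level is left to the caller.
- Mature-miRNA length limits (reject < 10 nt, warn outside 15--30 nt) are
  bookkeeping guards, not biological claims.
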