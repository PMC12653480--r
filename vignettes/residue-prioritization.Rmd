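---
title: "Prioritizing functional residues of a seven-transmembrane odorant receptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing functional residues of a seven-transmembrane odorant receptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsite)
```

## The problem

Insect odorant receptors (ORs) are seven-transmembrane (7-TM) subunits
that, together with the conserved co-receptor Orco, form odorant-gated
ion channels. Unlike GPCRs they adopt an inverted topology: the
N-terminus is cytoplasmic, and ligand recognition is thought to involve
the extracellular loops (ELs) and the extracellular ends of the later TM
helices. Given an ortholog family of an OR of interest, a predicted TM
topology, and a predicted 3-D structure, which individual residues are
the best candidates for mutagenesis?

orsite answers this with a three-way join, each ingredient deliberately
simple and auditable:

1. **Conservation.** For every alignment column,
   \(C_i = \max_r \mathrm{count}(r) / n_i\): the frequency of the modal
   residue among the \(n_i\) valid residues of column \(i\). Scores live
   in \([0, 1]\).
2. **Topology.** TM segment ranges plus the membrane side of the
   N-terminus (produced externally, e.g. by a consensus predictor such
   as TOPCONS) determine every loop and tail by alternation, and define
   a *candidate-region mask* of positions plausibly involved in ligand
   contact.
3. **Exposure.** From the C\(\alpha\) trace of a predicted structure,
   each residue gets the simplified accessibility score
   \(\mathrm{ASA}_i = \max(0, 20 - N_i) + 2 D_i\), where \(N_i\) counts
   C\(\alpha\) neighbors within 8 Å and \(D_i\) is the nearest-C\(\alpha\)
   distance in Å; raw scores are mapped linearly onto \([0, 100]\).

Residues with \(C_i \ge 0.9\) inside the mask are *preliminary
candidates*; candidates ranked by normalized exposure give the *key
residues* (default: top 5). A JTT/Neighbor-Joining phylogeny with
bootstrap support contextualizes the family but never gates selection —
the tree is a report product, not a filter.

## What the scores assume

The conservation score is a pure column statistic. Gaps (`-`) and the
ambiguity codes `X`, `B`, `Z` are excluded from both the numerator and
\(n_i\); this is the stricter of the two readings of "valid residues"
and is fixed here for determinism. A column with no valid residue at
all is flagged and scored 0, so thresholds can never select it. Two
threshold conventions coexist on purpose: summary *reporting* calls a
column highly conserved when \(C_i > 0.9\) (the ">90% identity"
convention), while candidate *selection* uses \(C_i \ge 0.9\). Both are
separate configuration values; with 11 sequences the difference is
real, since \(10/11 \approx 0.909\) passes one test and not the other.

The exposure score is a screening proxy, not a solvent-accessible
surface area. It uses only C\(\alpha\) geometry: low local packing
(few neighbors within 8 Å) and a long nearest-neighbor distance both
indicate exposure. The neighbor test is inclusive (`<= 8` Å); the
nearest-neighbor distance considers *all* residues of the chain, which
the formula requires so that \(D_i\) exists even when \(N_i = 0\). When
every raw score is identical the linear normalization is degenerate;
all values are set to 0 (never 100, so no residue is spuriously
reported as most exposed) and a warning is raised. True probe-based
algorithms (Shrake–Rupley, Lee–Richards) are out of scope by design.

## Phylogenetics

Pairwise distances are maximum-likelihood estimates under the JTT
empirical model: the exchangeabilities and equilibrium frequencies are
the published reference values, assembled into a reversible rate matrix
normalized to one expected substitution per site per unit time. The
transition matrix \(P(t) = e^{Qt}\) is computed via eigendecomposition
of the \(\pi\)-symmetrized form, so the pairwise log-likelihood can be
maximized cheaply by bracketed scalar search on \([0, 10]\) to a
tolerance of \(10^{-6}\). Distances that press against the cap of 10
substitutions/site are flagged saturated rather than dropped. Identical
sequences return exactly 0.

Trees come from a hand-written Saitou–Nei Neighbor-Joining
agglomeration. Two details matter for reproducibility and are why the
implementation is not delegated: ties in the Q-criterion are broken by
the lexicographically smallest pair of cluster labels, and negative
branch-length estimates are clamped to zero with a warning. On additive
matrices NJ is exact, and the test suite verifies both exactness and
agreement with an independent implementation on random additive inputs.

Bootstrap support resamples alignment columns with replacement
(\(L\) columns per replicate, default 100 replicates), recomputes
distances and the NJ tree, and reports for each internal bipartition of
the *original* tree the percentage of replicates containing it — support
annotates the original topology, not a consensus. Per-replicate random
streams are derived from the master seed by replicate index, so any
single replicate can be reproduced in isolation. Replicates where some
pair shares no valid column are skipped (and excluded from the
denominator); more than 50% skips aborts the run.

## Topology annotation and the candidate mask

Loop derivation is a pure alternation walk: starting from the
N-terminal side, every TM crossing flips the membrane side, inter-TM
gaps become ELs or ILs accordingly, and the chain ends become tails.
Zero-length loops and tails are representable and flagged rather than
rejected — a receptor whose last TM helix ends at the final residue has
an extracellular C-tail of length zero, which is a legitimate
annotation, not an error.

The notion of "regions likely to form ligand-binding pockets" admits
two readings, and the package implements both:

* `loops_plus_full_tms` (default, `tm_min_index = 3`): all EL residues
  plus every residue of TM3–TM7. This matches how candidate regions are
  marked in practice for insect ORs — and matters because functionally
  validated positions in this family include residues in the
  *cytoplasmic* half of TM3, which the literal reading would exclude.
* `loops_plus_tm_termini` (`w = 4`): all EL residues plus the `w`
  residues at the extracellular-facing end of each TM helix — the
  literal "termini of transmembrane segments" reading.

The discrepancy between the two readings is documented, not resolved;
the figure-consistent rule is the default, the literal rule one switch
away.

## Joining coordinates

Alignment reference positions, topology positions, and PDB residue
numbers must refer to the same 1-based numbering of the focal protein.
An integer `pdb_offset` remaps structures numbered differently. Length
disagreements between the three inputs are hard consistency errors
naming all three lengths — never silent drops. Ranking ties are broken
by smaller \(N_i\), then larger \(D_i\), then smaller position, making
reports fully deterministic; all floating-point report fields are
rounded to 4 decimals at serialization while internal computation stays
at full precision.

One genuinely open choice is the normalization scope: whether exposure
scores are rescaled over all residues of the protein or only over the
selected candidates. Published candidate score ranges are compatible
with either. The default is candidates-only (`norm_scope =
"candidates"`), since reported ranges in this setting are ranges over
the candidate set; the alternative is one switch away and does not
change the ranking order, only the displayed values.

## The synthetic generators

Because real ortholog sets and predicted structures live behind
external services, the package ships generators that emulate their
statistical and geometric structure:

* `simulate_family()` draws an ancestral sequence from the JTT
  equilibrium frequencies and evolves it down a random tree under three
  column rate classes — invariant (rate 0), moderate (1) and fast (4) —
  with default fractions 0.20 / 0.26 / 0.54 chosen to mirror the
  conservation-class proportions observed in real Dipteran OR45a
  ortholog sets. The default tree depth (`mean_pairwise = 0.7` before
  class multipliers) is calibrated so a default family's realized mean
  pairwise JTT distance lands near the ~1.1 substitutions/site seen in
  such sets. Ragged ends are terminal deletions only (emulating the
  315–415 aa length spread of real orthologs) so column indexing stays
  trivial. Planted positions are forced invariant and reported as
  ground truth.
* `simulate_bundle()` builds an idealized 7-helix C\(\alpha\) bundle:
  ideal helices (1.5 Å rise, 100° twist per residue, 2.3 Å helical
  radius — standard α-helix geometry, stated here as modeling choices),
  axes on a circle of radius 8.5 Å, alternating up/down, connected by
  equal-arc-length loop arcs that bulge away from the membrane slab so
  loop residues step ~3.8 Å like the helices do. Gaussian jitter
  (σ = 0.2 Å) roughens the trace. The matching topology (TM ranges =
  helical segments, cytoplasmic N-terminus) and exposure truth labels
  (loop/tail and outward-facing residues vs. inward-facing ones) are
  emitted alongside.

What the generators do **not** emulate: insertion-rich alignments
(only terminal raggedness), rate variation within a class, realistic
side-chain packing, loop ensembles, or any AlphaFold-like energetics.
Passing tests on synthetic data therefore demonstrate that the
*pipeline machinery* is correct and that planted signal is recovered —
not that the biological conclusions for any particular receptor are
right.

For parameter-recovery experiments the background is made deliberately
hostile to false positives while staying realistic in divergence:
`fraction_invariant = 0`, all background columns fast, and
`mean_pairwise = 1.1`. Under those conditions background conservation
hovers around 0.3–0.5, the planted keys are the only near-invariant
sites, and across independent seeds all planted keys must occupy the
top ranks, with conserved-but-buried decoys selected yet ranked below
them. With the default (paper-calibrated) fractions instead, columns
conserved by chance also enter the candidate set — exactly as real
near-invariant columns would — so the demo fixture reports more
candidates than planted keys.

## Numerical and size choices

* Distance optimization: golden-section/parabolic bracketed search
  (`stats::optimize`) with tolerance \(10^{-6}\); saturation flagged at
  \(\mathrm{cap} - 10^{-4}\).
* Neighbor statistics use the exact all-pairs distance matrix; at
  chain lengths of a few hundred residues no spatial index is
  warranted, and the brute-force oracle doubles as the reference in
  tests.
* Test problem sizes — alignments of 120–1000 columns, 2–12 taxa,
  bundles of 400 residues, 100 NJ exactness trees, 20 recovery seeds,
  100 bootstrap replicates — were chosen so each property is exercised
  at a scale where failures are attributable, and the whole suite runs
  comfortably on a laptop.
* The bootstrap restores the caller's RNG state afterwards, so runs
  compose without surprising downstream code.

## Worked example

```{r example, eval = FALSE}
fx <- write_fixture("demo_fixture", seed = 42)
cfg <- pipeline_config(alignment = fx$paths$alignment,
                       pdb       = fx$paths$pdb,
                       topology  = fx$paths$topology,
                       replicates = 100, seed = 1)
report <- run_pipeline(cfg, "demo_out")
report$candidates
```

The report bundle contains the per-column conservation TSV, the ranked
candidate TSV, the distance matrix (TSV and PHYLIP), the
support-annotated Newick tree, and a JSON manifest with the
configuration, seed, package version and input checksums. Reruns with
the same config and inputs are byte-identical.

## Known limitations

* The conservation score ignores residue similarity (a column of I/L/V
  scores as variable as one of D/K/W); substitution-aware scores are a
  possible extension but are not what this pipeline defines.
* The exposure proxy is blind to side chains and to the membrane: a
  lipid-facing TM residue can score as "exposed". The candidate mask is
  what keeps the ranking focused on plausibly ligand-facing regions.
* Bootstrap support on very short or low-diversity alignments is
  dominated by NJ tie-breaking; ties are resolved deterministically,
  but support values on such inputs should be read with care.
* NJ with ML pairwise distances is a context tree, not a substitute
  for full ML or Bayesian inference when the phylogeny itself is the
  question.
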