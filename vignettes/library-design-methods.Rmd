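---
title: "Designing disulphide-rich peptide expression libraries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing disulphide-rich peptide expression libraries: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomlib)
```

`venomlib` covers the in-silico half of a high-throughput pipeline that
turns thousands of venom-peptide sequences into an *E. coli*-expressed,
oxidation-verified, concentration-normalized screening bank. This vignette
explains the models behind each stage, the parameters that matter, and the
design decisions taken where more than one reasonable convention exists.

## Peptide records and cysteine frameworks

A peptide record carries the sequence plus derived cysteine statistics. The
framework string projects the sequence onto its cysteines: cysteines at
consecutive positions concatenate (`CC`), all others are dash-separated.
`C-C-CC-C-C` is the inhibitor cystine knot; `C-C-C-C-C-CC-C` the
three-finger fold. Runs of three or more consecutive cysteines — not seen
in the common natural scaffolds but possible in principle — are rendered as
that many concatenated `C`s, a deliberate generalization of the pairwise
notation. The maximum bridge count is `floor(n_cys / 2)`; an odd cysteine
count leaves one unpaired thiol and is flagged (`odd_cysteines`), since
such peptides behave differently in oxidative folding.

### The synthetic generator

`generate_synthetic_library()` emulates the composition of a large natural
venom-peptide collection: lengths uniform on 35–120 residues (below 35,
chemical synthesis is the method of choice, so recombinant libraries start
there), bridge counts uniform on 1–9, a taxon mix of 43 % spider, 31 %
scorpion, 10 % snake, 7 % centipede, 6 % cone snail and 3 % other, and
about 2 % of records with an odd cysteine count. Cysteines are placed by
sampling either a named natural framework compatible with the drawn
cysteine count (60 % of the time, when one exists) or a random framework
whose blocks are mostly isolated cysteines with occasional adjacent pairs;
remaining residues are uniform over the 19 non-Cys letters by default.

What it does **not** emulate: real venom peptides have strongly biased
residue composition (cationic, aromatic-rich), length–taxon correlations
(snake three-finger toxins are long), and framework frequencies far from
uniform. Tests passing on generated libraries therefore demonstrate
correctness of the algorithms, not performance claims about any specific
natural library. Generation is bit-for-bit reproducible under its seed.

## Codon design

Every synthesized gene is `GAGAACCTGTACTTCCAA` (TEV site, ENLYFQ) + peptide
codons + `TAATAA` (duplicated stop). Prefix and suffix are immutable; only
peptide codons are optimized.

**CAI.** Relative adaptiveness is `w = f / max f` within each synonymous
family; CAI is the geometric mean of `w` over scored codons. Met, Trp
(single-codon families, always `w = 1`) and stops are excluded from scoring
— the Sharp–Li convention; `exclude = character(0)` switches to scoring
them. The packaged default table is a standard *E. coli* K-12 usage table
(per-thousand frequencies); any three-column table can be supplied, and
only within-family ratios matter.

**Constraint set** (defaults, all configurable via
`design_constraints()`): GC 40–60 % measured globally over the whole gene
(prefix and stops included) rather than in windows — the genes are only
130–390 nt long, so a windowed rule would add parameters without power;
homopolymers ≤ 5 nt; G/C-only runs ≤ 6 nt; zero forbidden-motif hits on
either strand (default list: σ70 −10 box `TATAAT`, strong Shine–Dalgarno
`AGGAGG` — deliberately minimal, as motif screening is configuration, not
science); codons with `w` below 0.1 are "rare" and excluded; `|#TGC −
#TGT| ≤ 1` per gene, because balancing the two cysteine codons measurably
helps expression of cysteine-dense peptides.

**Optimizer.** The start point gives every residue its `w = 1` codon, with
cysteines alternating TGC/TGT. Violations are then repaired by single-codon
synonymous substitutions: a repair is admissible if it does not increase
the number of violated constraints and strictly reduces a continuous
severity (GC distance from the band, excess run lengths, motif/rare-codon
counts, cysteine imbalance). Among admissible candidates the highest-`w`
codon wins, tie-broken by raw frequency, then alphabetical codon order; the
seeded RNG decides only among exact ties and the visit order of violations.
The budget is `10 ×` peptide length steps; on exhaustion (or when no
admissible repair exists) the design is returned with explicit failed
flags — never an exception — because at plate scale a flagged design is
actionable and a crash is not. Single-codon moves only: pairwise swaps
would enlarge the neighbourhood for marginal gain at these gene lengths.

A genuine corner exists: for short, extremely AT-coded peptides (mostly
K/N/I/F/Y plus many cysteines) the cysteine-balance rule pins roughly half
the cysteine codons at TGT, and reaching 40 % GC then costs enough
low-`w` substitutions (AAG for lysine runs is the canonical offender) that
CAI ≥ 0.8 becomes unattainable — a dynamic-programming bound over all
codon choices confirms the conflict is real, not an optimizer artefact.
Such designs are returned with `cai = FALSE` flags; in a 200-peptide
generated library this affects on the order of one design.

## Assembly oligonucleotides

Tiling is deterministic and anchored at position 0 of the top strand. With
period `P = max_len + gap = 80`, top oligos span `[80i, 80i + 60)`
(truncated at the gene end), internal bottom oligos `[80j + 40, 80j +
100)` (clamped at the gene end), and a terminal bottom oligo covers the
tail when the gene extends past the last internal bottom start. This
geometry makes every opposite-strand junction overlap exactly 20 nt and
every same-strand gap exactly 20 nt, and yields 6 oligos for a 220-nt gene
and 4 for a 137-nt gene. Terminal pieces shorter than 15 nt are extended
leftward into the duplex to 15 nt — a primer below ~15 nt would not prime
reliably; the count is unchanged. The two outermost oligos double as the
amplification primers. `oligo_count()` is the closed form of the same
scheme and agrees with the full tiling across the whole length range.

`simulate_assembly()` is the package's own inverse check: it verifies
strand alternation, overlap widths, exact reverse-complement agreement on
every junction, stitches the top-strand consensus and compares it
base-by-base with the gene, and warns when a junction overlap k-mer occurs
more than once in the gene (a mispriming risk during assembly PCR). No
melting-temperature balancing is attempted — the geometry, not
thermodynamics, is the specification here.

## Fusion constructs

The construct is carrier–His6–TEV–peptide; cleavage after ENLYFQ releases
the native peptide with no added residue. The production carrier sequence
is vector-specific configuration, so the module supports two levels: a
sequence-bearing carrier (masses from residue masses of the joined chain;
the carrier sequence is expected to contain its internal His6 tag) and a
mass-only carrier with default 27,787 Da. The mass-only convention is
`fusion = carrier_mass + peptide_mass` — the constant is defined to absorb
the junction chemistry, which keeps the two paths within a residue-mass
rounding of each other once the constant is calibrated from a sequence.
`synthetic_carrier()` ships a clearly-labelled synthetic stand-in for
examples and tests. GenBank output annotates carrier, His6, TEV site,
peptide and stop and round-trips through standard parsers.

## Mass QC

Masses come from elemental composition: residue formulas summed plus one
water, dotted with monoisotopic or abundance-weighted average atomic
masses (NIST values), so average masses are self-consistent with the
isotope engine. Each disulphide bridge removes two hydrogens: 2 × 1.007825
Da (mono) or 2 × 1.00794 Da (average), giving a strictly decreasing
species ladder from the reduced form to the fully oxidized isoform.

Oxidation-state calls pick the ladder species nearest the observed
deconvoluted mass; the default tolerance is 1.0 Da in average mode, suited
to single-quadrupole deconvolution (monoisotopic mode is available for
higher-resolution instruments). Ties — including float-level ties within
1e-9 Da — resolve toward the more oxidized species, reflecting
that reduced forms are essentially never observed for peptides oxidized in
the periplasm; misfolded material precipitates earlier in the process
instead of appearing as a reduced mass.

The isotope engine convolves per-element isotopologue distributions
(binomial/multinomial over natural abundances, indexed by nucleon offset)
using binary exponentiation, with internal pruning at 1e-12 of the running
maximum; output patterns are max-normalized and truncated below 1e-4. An
atom-by-atom polynomial expansion — same mathematics, different algorithm
— serves as the oracle in tests, with agreement required to 1e-6.

Quantification uses the Gill–von Hippel composition rule (5500·W + 1490·Y
+ 125·cystine); a zero coefficient is flagged low-confidence because A280
cannot see such peptides, and conversion functions then require
peak-area-derived concentrations instead. All concentration/yield
arithmetic is exact; no rounding is applied before reporting.

## Bank triage

Bins are half-open so the prose ranges partition `[0, ∞)`: `> 20 µM`
normalize to 10 µM in 250 µL (C1V1 = C2V2, moles conserved exactly);
`[5, 20]` as-is into the 10 µM bank; `[1, 5)` into the 1 µM bank; `< 1`
discarded and counted as a non-producing clone. Exactly 20 and exactly 5
fall in the as-is bin and exactly 1 in the 1 µM bank — the convention is
configurable in principle but fixed here for reproducibility. Plates hold
80 peptides; columns 1 and 12 (2 × 8 wells) are reserved for assay
controls — the reference process says only "2 × 8 empty wells", so the
column choice is this package's convention. Five 50-µL copies per plate
are asserted feasible against the 250-µL stock. Report percentages use
round-half-away-from-zero to integers; note that 562/2736 renders as 21 %
under this rule even where "~20 %" appears in prose summaries.

## Synthesis and screening simulation

Errors are single-base events — the dominant failure mode of oligo-derived
synthesis, where truncated oligos cause deletions. Per clone the error
count is Poisson(`rate_per_kb · L / 1000`), positions uniform, types from
the spectrum (default 76 % deletion / 7 % insertion / 17 % substitution).
Multi-base deletions are not modelled. The analytic oracle is
`P(correct) = exp(−rate · L / 1000)`; sequential screening of up to
`max_colonies` (default 3) clones has closed-form rank fractions
`p, pq, pq²` and mean colonies among recovered `(p + 2pq + 3pq²)/(1 − q³)`.

The published error-rate estimator for such pipelines is ambiguous about
multi-error clones, so two estimators are reported: a naive one (incorrect
clones ÷ kb sequenced, each incorrect clone counted as one error — an
undercount whenever a clone carries several errors) and a Poisson
maximum-likelihood one (`−ln p̂₁ / mean kb`). Their spread brackets the
underlying rate.

## Problem sizes and tolerances in the test suite

The suite exercises: 10,000-record generator runs for taxon-mix
convergence (±2 %); 400 random lengths for tiling/closed-form agreement
plus full reassembly on a 40-gene designed fixture; 200-peptide design runs
for the constraint criteria; 30,000 mutate replicates for error-count and
spectrum convergence; 1,500–4,992-gene screening runs against the closed
forms at 3 Monte-Carlo standard errors (3.29 where nine conditions are
tested jointly, to keep the family-wise error near 1 %); isotope-engine
agreement at 1e-6 on a C30H50N10O10S4-scale composition; mass additivity
at 1e-6 Da. These sizes were chosen to make the statistical checks
decisive at desk scale.

## Known limitations

- The optimizer is greedy per step; it can flag (honestly) designs a global
  solver could still satisfy only in the narrow AT-rich/cysteine-balance
  corner described above.
- The exact commercial oligo designer's anchoring is unknown; this
  package's scheme is one deterministic realization of the stated geometry
  and reproduces the reference mean and minimum primer counts, but its
  worst-case count for the longest genes can exceed a length-balanced
  variant by one oligo.
- No mRNA secondary-structure, codon-pair or 5'-UTR optimization; no
  melting-temperature scoring; no disulphide connectivity prediction; no
  raw-spectrum deconvolution. These are out of scope by design.
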