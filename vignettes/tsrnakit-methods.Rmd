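---
title: "Models and methods behind tsrnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tsrnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrnakit)
library(dplyr)
```

# The biology and the pipeline at a glance

Transfer-RNA-derived small RNAs (tsRNAs) are fragments of at most about
50 nt cleaved from mature or precursor tRNAs. Cleavage position defines
six types. On the mature tRNA, fragments anchored at the 5' end are tRF-5
when they stop before the anticodon loop and tiRNA-5 (a stress-induced 5'
half) when they reach into or beyond it; symmetrically, 3'-anchored
fragments are tRF-3 (T-arm region to the CCA end) or tiRNA-3; fragments
anchored at neither end are i-tRFs. tRF-1 species derive from the
uracil-rich 3' trailer of the precursor transcript, immediately
downstream of the mature 3' boundary. (Some older literature describes
this trailer as "upstream"; the 3'-trailer convention is the one used
here and in the tRF databases.)

`tsrnakit` implements a complete desk-scale analysis of such fragments
from small-RNA sequencing: adapter trimming and length filtering,
alignment to a structure-annotated tRNA reference, six-way
classification with a systematic naming scheme, TPM quantification,
two-group differential calling, a three-rule consensus target
prediction, intersection with differentially expressed mRNAs,
accumulative hypergeometric pathway enrichment, and export of the
tsRNA–mRNA–pathway network. A synthetic-data generator with planted
ground truth drives all validation.

# Reference model

References are read from a three-line dialect (header, mature sequence,
dot-bracket structure) so that one plain-text file carries everything
classification needs. Coordinates are 1-based closed intervals, on the
mature sequence (trailer spans live on the trailer's own coordinates):
this matches how tRNA positions are written in the structural
literature. Mature sequences are stored with the CCA tail appended and
flagged, because tRF-3 species carry CCA; the classifier therefore
treats the last three bases as part of the 3' terminus.

Hairpin loops are located purely from the dot-bracket string: a hairpin
loop is a maximal unpaired run whose immediate flanks pair with each
other. The first, second and last hairpin are taken as the D, anticodon
and T loops. Taking the *last* rather than the third loop makes the rule
robust to long-variable-arm tRNAs (Ser, Leu), which can present a fourth
hairpin between the anticodon and T arms. `>`/`<` are accepted as
dot-bracket aliases to tolerate tRNAscan-SE output styles.

# Read preparation

The length filter keeps reads with `15 < length <= 50` nt — the lower
bound is exclusive, honouring "more than 15 nt" literally, and the upper
bound is the small-RNA size selection of the library. Quality strings
are carried through untouched; no quality filtering is applied.

Adapter trimming is a deterministic three-pass rule rather than a
heuristic aligner, so that every trimming decision is reproducible and
unit-testable:

1. cut at the earliest **exact** occurrence of the first 8 nt of the 3'
   adapter;
2. failing that, cut the longest exact adapter **prefix** (at least
   3 nt) lying flush with the read's 3' terminus — this rescues reads
   whose insert is long enough that the sequencer saw fewer than 8
   adapter bases;
3. failing that, cut at the earliest seed window with at most one
   substitution — this rescues reads whose adapter seed carries
   sequencing errors.

The ordering matters and was chosen deliberately: running the tolerant
scan before the terminal-prefix pass false-trims a few percent of long
inserts at chance near-matches, which is measurable as a loss of insert
recovery on simulated reads (the package's recovery property requires at
least 99% at a 1% uniform error rate). Reads with no adapter evidence at
all are kept untrimmed and flagged, not dropped; the length filter then
disposes of them if they are implausibly long. Adapter sequences are
configuration only — none are baked into results; the simulator's
default is the Illumina TruSeq small-RNA 3' adapter.

# Classification and naming

Distinct read sequences (not read copies, and not per-gene hits) are the
unit of analysis. A fragment's alignments across isodecoders vote on its
amino-acid family (majority, alphabetical tie-break), mirroring the fact
that published tsRNA names carry a single amino acid. Anchoring
tolerances default to 1 nt at the 5' end and 3 nt at the 3' end (CCA
slack). A trailer hit counts as tRF-1 only when it begins within 2 nt of
the mature 3' boundary, which separates genuine trailer fragments from
spurious precursor matches. Fragments anchored at both ends are
full-length tRNAs and are excluded from tsRNA output.

5'-anchored fragments ending anywhere *at or beyond* the anticodon-loop
start are tiRNA-5 (and symmetrically for tiRNA-3): halves are defined by
anticodon-loop cleavage with no upper bound on length, so the loop is
treated as the minimum cut point.

Names follow `organism-typecode-AminoAcid-<length><variant>` with type
codes `tiR5, tiR3, tRF5, tRF3, tRFi, tRF1` (e.g. `rno-tRFi-Ser-25a`).
Within a (type, amino acid, length) group, variant letters are assigned
by descending total abundance with lexicographic sequence order as the
tie-break. The published material never states its variant rule;
abundance-then-sequence is deterministic, which the round-trip property
(`parse(render(x)) == x`) requires. More than 26 variants in one group
is an error rather than a silent wrap-around.

# Quantification and differential calling

Expression is tag counts per million of total aligned tRNA reads (TPM):
`count / aligned_total * 1e6` per sample, so TPM sums to exactly one
million per sample by construction. No further normalisation (TMM,
size factors) is applied — the analysis deliberately stays within tRNA
space.

Differential calling is a two-sided unpaired pooled-variance Student's t
test on TPM (not log-TPM), taken literally. Fold change is computed on
group means with a pseudocount of 0.01 TPM — roughly the smallest
meaningful TPM at these sequencing depths — applied to the fold change
only, never to the test. Significance is the published two-gate rule,
`|log2FC| > log2(1.5)` and `P < 0.05`, with **no** multiple-testing
correction because that is the convention this pipeline mirrors; the
enrichment module, by contrast, emits a Benjamini–Hochberg column for
information. When both groups are constant and equal the statistic is
undefined and `p = 1` by convention (no evidence of change).

Detection for profile membership and Venn counts is a nonzero raw count
in at least one replicate of the group; the source material does not
state its rule, and this is the weakest defensible one.

# Consensus target prediction

Three independently implemented rules stand in for the external
TargetScan / miRanda / RNAhybrid consensus; a gene is a consensus target
when one site passes all three.

**Seed matching.** 7-nt windows slide 5'→3' along the tsRNA. A site is a
`7mer` where the 3'UTR contains the window's reverse complement, or a
`7mer-1a` where it contains the reverse complement of window positions
2–7 followed by an A opposite position 1 (the miRNA 7mer-A1
convention). When tsRNA position 1 is a U the two patterns coincide and
the site is reported once, as a `7mer`.

**Strict 5'-end pairing.** Perfect Watson–Crick complementarity at tsRNA
positions 2–11 and at most 4 non-complementary opposing bases at
positions 12–21. G:U wobble counts as a mismatch here — the rule's
language is "perfect pairing" — whereas the energy model below scores it
as weakly stabilising; the two engines intentionally disagree about
wobble. For tsRNAs shorter than 21 nt the 12–21 span is truncated and
the budget prorated as `floor(4 * span/10)`: a defined truncation beats
undefined behaviour for 16-nt fragments.

**Duplex free energy.** A deterministic, ungapped nearest-neighbor
model: initiation penalty (+4.09 kcal/mol) plus published Turner-set
Watson–Crick stack energies over the best antiparallel registration,
+1.0 kcal/mol per mismatch, and a single weak value (−0.5 kcal/mol) for
any stack containing a G:U pair. A site passes below −20 kcal/mol. This
is *not* a full hybridisation folder — no bulges, no internal-loop
thermodynamics — and is documented as such; its virtue is that an
independent summation oracle can verify it to 1e-9, which a DP folder
would not allow at this code size.

# Integration, enrichment and the network

Validated targets are the plain set intersection of consensus-predicted
genes with significantly changed mRNAs from an external DE table (same
two-gate rule). Enrichment uses the accumulative (upper-tail)
hypergeometric distribution; the enrichment factor is observed count
over `list_size * term_size / universe_size`, and a term passes at
`P < 0.01`, count ≥ 3 and factor > 1.5. The universe defaults to all
genes in the annotation file (configurable), since the original
web-tool's internal default is unrecoverable. Term clustering by
membership similarity is deliberately not implemented — the output is a
flat term list. The network export is a bipartite-by-kind edge list
(tsRNA→mRNA `targets`, mRNA→term `member_of`) in a TSV any graph viewer
imports.

# The synthetic-data generator

The generator defines the study conditions, not a tuning surface. Its
defaults mirror the published design wherever that design states a
number: two groups of three replicates; a type mixture calibrated to the
published sham composition (tiRNA-5 38.36%, tRF-3 21.29%, tRF-1 0.12%,
the remaining 40.23% split evenly across tRF-5, i-tRF and tiRNA-3, which
the text does not break down); fragment lengths concentrated in the
16–23 and 29–45 nt bands through the endpoint rules themselves.

Each tRNA is a 76-nt canonical cloverleaf on a fixed paired scaffold
with randomised loop and stem bases (stem 3' sides are complements of
the 5' sides), CCA-terminated, with a 16–20 nt trailer built with a U
fraction of at least 0.6 by construction. Trailers sit at the upper end
of the realistic 12–20 nt band so that tRF-1 fragments can survive the
">15 nt" filter at all. Fragment endpoints are drawn conditional on
type (e.g. tiRNA-5: start 1, end uniform in the anticodon loop).
Replicate counts are negative-binomial with `size = 1/CV^2` —
overdispersion is the norm for count data and stresses the t test
realistically. Planted fold changes (default ±2 log2 units on 10
fragments) define the differential truth. Planted UTR sites are reverse
complements of the tsRNA's first ≤21 nt with 0–2 substitutions confined
to the tolerated span, re-drawn until they clear the −20 kcal/mol
threshold (AU-rich tsRNAs may need the perfect-complement fallback; a
bounded retry then errors honestly). The first annotation term is seeded
with the planted validated genes and kept small (10 genes) so the
planted signal clears the P < 0.01 gate at the default list size.

Three RNG streams (references, reads, targets) are derived from one
master seed, so perturbing one stage never reshuffles another; the whole
pipeline is byte-identical across reruns at a fixed seed.

What the generator does **not** emulate: sequencing quality profiles,
PCR duplicates, tRNA-modification read-through artifacts, mitochondrial
tRNAs, and realistic isodecoder sequence similarity (references are
random within the scaffold, so multi-mapping is rarer than in a real
genome). Passing tests therefore demonstrate the correctness of the
algorithms under the stated model, not performance on real libraries.

# Problem sizes and numerical choices

The packaged tests run the generator at 60–150 fragments and 4–70
thousand reads per sample, which keeps the full suite in a few minutes
while leaving every statistical check comfortably powered (the
composition-recovery check uses about 2×10^5 reads, where multinomial
sampling error is far below the ±0.03 assertion). Ties in variant
assignment break lexicographically; ties in amino-acid votes break
alphabetically; the degenerate constant-and-equal t case returns p = 1;
TPM denominators must be positive or the sample errors out. The
hypergeometric tail is delegated to `stats::phyper` and verified against
exhaustive enumeration for every universe size up to 60.

# Known limitations

Alignment is substitution-only (no indels) and forward-strand, which is
appropriate for stranded small-RNA libraries but will miss
modification-induced deletions. The duplex model's G:U treatment is a
single flat stack value. The t test on raw TPM with n = 3 has limited
power for low-abundance fragments and no error-rate control across
fragments — both faithful to the mirrored convention rather than
statistical best practice. The enrichment universe choice materially
affects P values and is left to the user when a platform universe is
available.
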