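---
title: "Methods: pooled Hawaiian-SNP mapping, its simulator, and the design choices behind hawmap"
author: "hawmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled Hawaiian-SNP mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The mapping model

A recessive lesion is induced by EMS on the N2 background, the mutant is
crossed to the Hawaiian isolate CB4856, and ~200 F2 progeny are singled.
F2s expressing the recessive phenotype are homozygous N2 at the causal
locus; 20–50 such lines are pooled and sequenced at ~22× coverage. At a
Hawaiian marker SNP, the pooled alternate-allele frequency equals the
fraction of pooled chromosomes with Hawaiian ancestry at that position:
~1/2 genome-wide, decaying to exactly 0 at the causal locus because of the
selection step. The mapping interval is read off as the span without
Hawaiian SNPs, and candidates are the novel, homozygous, nonsynonymous
variants inside it.

Under the crossover model below, the Hawaiian frequency at a marker a
genetic distance $d$ (cM) from the causal locus, conditional on N2 at the
locus, is $d/2L$ for a chromosome of total genetic length $L$; the test
suite checks the simulator against an independent enumeration of this
quantity rather than trusting either implementation.

# The crossover model

Gametes from the fully heterozygous N2/HAW F1 are simulated with **one
obligate crossover per bivalent and complete interference**, the norm for
*C. elegans* meiosis: with probability 1/2 the gamete is non-recombinant
(whole chromosome N2 or HAW, equiprobable), otherwise it carries a single
breakpoint uniform in genetic (cM) coordinates with random orientation.
This makes the recombinant-gamete fraction exactly 1/2 and keeps every
marginal and conditional ancestry probability available in closed form or
by cheap enumeration — the property the oracle tests exploit.

The genetic map is piecewise linear in bp↔cM. The default is uniform
(50 cM per chromosome, the canonical *C. elegans* genetic length under
complete interference). An optional `three_domain` map mimics the real
chromosome structure — high-recombination arms, low-recombination centre —
by giving each outer physical quarter 40% of the genetic length. The
physical width of a mapping interval depends strongly on this choice; the
genetic width does not, which is why interval *selection* uses genetic
width.

# The synthetic data generator

`buildReferenceModel()` fixes the reference state; its defaults are the
study conditions every acceptance simulation uses:

| setting | default | unit | rationale |
|---|---|---|---|
| chromosomes | 6, 13.8–20.9 Mb | bp | *C. elegans* karyotype and scale |
| genetic length | 50 per chromosome | cM | complete interference |
| Hawaiian SNP density | 1e-3 | SNPs/bp | ~1 marker/kb, dense enough that gap edges are marker-limited only at the ~0.003 cM scale |
| parental background variants | 200 | count | a handful of pre-mutagenesis strain differences |
| induced mutations | 300 | count | a typical EMS load; one is causal |
| mutation spectrum | `ems` | – | G:C→A:T transitions only, matching the observed lesion spectrum |
| causal locus | chrV:6,500,000 | bp | mid-arm placement on the largest chromosome |
| coding fraction of induced hits | 0.15 | – | gives occasional competing coding candidates |
| F2s singled / lines pooled | 200 / 20–50 | count | the emulated protocol; the drawn pool size is capped at the mutant plates actually available |
| coverage / error | 22× / 0.001 | – | minimum reported coverage; symmetric per-read flip error |

The causal lesion is engineered, not sampled: a toy gene is built around
the causal position with a GGA glycine codon whose first base is the
causal site, so the G→A change is always a Gly→Arg missense — the
classic EMS lesion. Other toy genes (single- and two-exon, both strands)
are placed at random; only their loci carry reference sequence
(`RegionalGenome`), since effect annotation never needs sequence outside
genes. Read sampling is Poisson site depth × binomial alternate count at
frequency $f(1-e) + (1-f)e$.

**What the generator does not emulate.** Alignment artifacts, mapping
bias, base-quality structure, indel-rich regions, CNVs; linked selection
other than the single causal locus; the one-to-two generations of
expansion of the pooled F2 lines (selfing a homozygous mutant leaves the
linked allele frequencies at the locus unchanged and only mildly pushes
heterozygous background sites toward fixation, so it is omitted);
heterozygous escapers from phenotype mis-scoring (the hook for a
contamination parameter exists in the design but is not modelled —
frequencies at the causal locus are exactly 0). Passing tests therefore
demonstrate the statistical logic of the method, not robustness to
alignment- or library-level artifacts of real data.

# Classification and interval detection

* Catalog matching is **allele-exact** on (chrom, pos, alt): a novel
  allele arising at a polymorphic site must not inherit the catalog label.
* Homozygosity is a **strict** alt-fraction threshold (>0.85), read
  directly off the AD field.
* A Hawaiian catalog SNP is *present* when supported by at least
  `minAltReads` reads (default 2, to resist isolated error reads at 22×).
* The interval is the **exact maximal gap** between consecutive present
  SNPs — bins are for plotting only — with chromosome ends acting as open
  flanks and the endpoints excluding the flanking present SNPs themselves.
  Chromosome selection uses the largest genetic width, which normalises
  for chromosome length. Ties break by chromosome name, then start.
* The secondary **reduction mode** (longest run of bins with present count
  ≤ k, default k = 0) is for pools where markers are depleted rather than
  absent; how such intervals were delimited originally is not documented,
  so this mode is this package's own construction.

**Behaviour at 22×.** A region where a single pooled chromosome carries
Hawaiian ancestry has marker frequency 1/2n ≈ 0.01–0.05 and an expected
alternate read count of ~0.5 per site, so most of its sites are invisible
at 22×. The detected gap is consequently wider than the true zero-
frequency gap, and occasionally the largest detected gap sits inside the
broad low-frequency region slightly off the causal locus. The acceptance
suite quantifies this under the study conditions: the selected interval
contains the causal locus, and the causal lesion survives candidate
filtering, in at least 95 of 100 seeded default simulations. Oracle
comparisons of gap widths and linked allele frequencies are instead run in
a deep-coverage regime (error 0, `minAltReads = 1`, depth 300–400), where
a frequency-1/2n site is missed with probability $e^{-\mathrm{depth}/2n}$
— negligible — and presence becomes equivalent to ancestry; at 22× the
binomial dropout of low-frequency sites scatters absences and the
equivalence deliberately fails.

# Effect annotation

The annotator is codon-local: the affected codon is translated before and
after the change (minus-strand genes through the reverse complement),
giving synonymous/missense/nonsense/start-loss/stop-loss; coding indels
with length change ≢ 0 (mod 3) are frameshift, in-frame coding indels are
reported missense (they alter the protein; a finer class is out of scope);
an SNV within 2 intronic bases of a CDS boundary (the GT/AG positions) is
splice. This splice definition is intentionally minimal and is not a
reimplementation of any production annotator's exact rules. Models whose
CDS length is not divisible by 3 are flagged unusable rather than guessed
at. A property test drives the codon-local path against a brute-force
whole-CDS translation oracle on 1,000 random toy-gene variants.

`checkSubstitutionConsistency()` validates published mutation descriptors
("G->A, Gly42Arg") without transcript sequences by enumerating all codons
of the source amino acid and accepting the printed base change on either
strand — necessary because published tables report the change on the
genomic plus strand while the gene may lie on either strand.

`truncationLength()` returns codons strictly C-terminal to a premature
stop (length − stop position; 1227 − 1062 = 165 for the MUS-101 case).
The matching published figure is printed in bp units ("165-bp region");
165 is the codon count, and the package uses codon units throughout rather
than guessing an alternative arithmetic.

# Viability statistics

Percent hatching is hatched/eggs × 100 per brood. Summaries average
per-brood percentages within replicate experiments first and report mean ±
SD across replicate means (the convention used for published error bars);
`acrossBroods = TRUE` gives the all-brood alternative since the published
wording does not fully pin this down. The group comparison reports a Welch
t test on per-brood percentages as primary — the brood is the natural
experimental unit — and a Fisher exact test on pooled counts as secondary;
the published "P < 0.0001" never names its test. The type-I error of the
primary test under a simulated binomial null is checked at α = 0.05 over
2,000 replicates. Complementation verdicts use fail < 10% and complement
> 50% hatching, chosen to separate the observed failing crosses (0–4.9%)
from complementing ones (78.6–98%) with a wide ambiguous band between;
sterility of surviving progeny is carried as an annotation, never folded
into the verdict.

# CRISPR edit verification

Only SpCas9 NGG is modelled; guides of 17–20 nt are accepted. The blunt
cut is placed between the 3rd and 4th base 5′ of the PAM, reported as a
between-base coordinate mapped to the plus strand. Published prose
distances between the cut and nearby edits ("one nucleotide away", "34
bases away") are not reproducible under any single counting convention we
could anchor, so the package reports coordinates under its stated
convention and does not force agreement. Restriction-site scanning honours
IUPAC degeneracy through Biostrings fixed = FALSE matching; EaeI (YGGCCR)
is its own reverse complement, so one strand suffices for it.
PAM-silencing proposals enumerate single-base changes at the two PAM G
positions, keep those synonymous in the supplied gene frame (any such
change destroys the NGG), and rank options that create a diagnostic
restriction site first.

# Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere inside the package (VCF/GFF
  convention); conversion to 0-based half-open happens only at the BED
  boundary.
* Randomness: every public simulation entry point takes a seed and derives
  fixed per-component substreams from it, so catalog construction, pool
  formation and read sampling are independently reproducible and VCF
  output is byte-identical under a repeated seed.
* Multiallelic VCF records are split per alternate allele; the depths of
  the other alternates are ignored with a warning.
* Degenerate inputs: zero total depth is an error for homozygosity calls
  and silently dropped (with a message) during candidate filtering; a
  chromosome without present Hawaiian SNPs returns the whole chromosome
  flagged ambiguous; a 0 cM chromosome never recombines.
* Problem sizes in the test suite were chosen to keep oracle comparisons
  statistically meaningful at small cost: 100 seeded pool simulations for
  the recovery properties, 40 replicates per pool size (10/25/50) against
  a 4,000-replicate crossover oracle for gap widths, 25 replicates × 5
  genetic distances for the frequency decay, 1,000 random variants for the
  annotation oracle, and 2,000 null replicates for the test-size check.

# Known limitations

* Single causal locus only; two-mutation mapping and statistical
  confidence intervals on the interval are out of scope.
* The annotator handles one gene model per locus (no isoform set), the
  standard nuclear code only, and classifies in-frame indels coarsely.
* Simulated reads are site-level counts; there is no read-level FASTQ
  simulation, and alignment/calling upstream of the VCF is consumed, not
  reproduced.
* Guide efficiency, off-target scoring and co-conversion marker modelling
  are out of scope for the CRISPR module.
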