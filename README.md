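# hawmap

Hawaiian SNP mapping-by-sequencing for *C. elegans* mutant identification.

## The problem

Hundreds of *C. elegans* mutants isolated in classical screens — embryonic
lethal, maternal-effect lethal, eggshell defective — were characterised
decades ago but the causative DNA lesion was never identified. The modern
one-step approach crosses the mutant (an EMS-mutagenized N2 background) to
the polymorphic Hawaiian isolate CB4856, re-isolates homozygous-mutant F2
recombinants, and sequences them as a single pool at modest coverage
(~22×). Because every pooled animal was selected to be homozygous N2 at the
causal locus, Hawaiian marker SNPs are present at frequency ~1/2 everywhere
in the genome *except* in the region linked to the mutation, where they are
absent. The mapping interval is the chromosomal span devoid of Hawaiian
SNPs, and the causal lesion is a novel, homozygous (>85% alt-read
fraction), nonsynonymous variant inside it.

`hawmap` implements this pipeline for people doing (or teaching) pooled
mapping-by-sequencing:

* **Classification** of pooled VCF calls against Hawaiian and
  pre-mutagenesis background catalogs (allele-exact matching), with the
  >85% homozygosity rule and a read-support presence criterion.
* **Interval detection**: per chromosome, the maximal gap between present
  Hawaiian SNPs; the selected interval is the gap with the largest genetic
  (cM) width. A bin-count "reduction" mode handles pools where markers are
  depleted rather than absent. SNP-density profiles for plotting.
* **Candidate annotation**: a minimal codon-level effect annotator
  (missense/nonsense/synonymous/splice/frameshift, strand-aware), a
  genetic-code consistency checker for published mutation descriptors, and
  EMS-spectrum (G:C→A:T) flags.
* **Viability statistics**: percent hatching, replicate-aware brood
  summaries, Welch + exact tests, complementation-test verdicts, Mendelian
  expectations.
* **CRISPR HDR verification**: protospacer/NGG location, blunt cut sites,
  repair-oligo edit and homology-arm accounting, IUPAC restriction-site
  scanning (EaeI etc.), and synonymous PAM-silencing edit proposals.
* **A truth-tagged simulator** of the whole experiment — meiosis with one
  obligate crossover per bivalent, F2 selection, pooling, and Poisson /
  binomial read sampling — so every stage is testable without any external
  sequencing data.

## Worked example

Simulate the default experiment (six 13–21 Mb chromosomes, Hawaiian
catalog at 1 SNP/kb, 300 EMS-induced mutations with one causal missense
lesion at chrV:6,500,000, 200 singled F2s, 22× coverage) and map it back:

```r
library(hawmap)
model <- buildReferenceModel(seed = 1)
pool  <- simulateMutantPool(model, nF2 = 200, seed = 1)
calls <- simulatePoolCalls(pool, model, meanDepth = 22,
                           errorRate = 0.001, seed = 1)
calls <- classifyVariants(calls, model@hawaiian, model@parental)
#> classified 99965 calls: hawaiian=99465 parental=200 novel=300 unclassified=0

intervals <- detectInterval(calls, model@hawaiian,
                            chromLengths(model@map), map = model@map)
sel  <- selectedInterval(intervals)
cand <- filterCandidates(calls, sel, model@genes, model@genome)
intervalReport(sel, cand)
#>   chrom   start     end widthMb nCandidates
#> 1  chrV 6409865 7610474 1.20061           2
```

The selected interval is a 1.2 Mb Hawaiian-SNP desert on chrV containing
the causal locus. The two candidates are both homozygous EMS-style
missense changes in the interval; the second is the planted causal lesion:

```r
#>       pos        gene    change   effect altFrac  ems causal
#> 1 6499851 causal_gene Ala117Val missense       1 TRUE  FALSE
#> 2 6500000 causal_gene Gly167Arg missense       1 TRUE   TRUE
```

In real use the inputs come from files rather than the simulator:
`runMap("pool.vcf", "hawaiian.tsv", "parental.tsv", outdir = "map",
genes = "genes.gff3", genome = "genome.fa")` writes the interval BED,
candidate TSV, density profile and summary. A thin command-line wrapper
with `simulate | map | broods | crispr` subcommands is installed at
`inst/scripts/hawmap.R`.

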