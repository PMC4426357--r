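#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet matchPattern reverseComplement subseq GENETIC_CODE
#'   AMINO_ACID_CODE
#' @importClassesFrom Biostrings DNAStringSet
NULL

.VARIANT_LABELS <- c("hawaiian", "parental", "novel", "unclassified")
.ANCESTRIES <- c("N2", "HAW")
.EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "frameshift",
                     "splice", "noncoding", "start_loss", "stop_loss")
.NONSYNONYMOUS <- c("missense", "nonsense", "frameshift", "splice",
                    "start_loss", "stop_loss")

#' VariantCalls: pooled-sequencing variant calls with allelic depths
#'
#' A \linkS4class{GRanges} subclass holding one row per biallelic variant
#' call. Required metadata columns are \code{ref}, \code{alt} (allele
#' strings), \code{refDepth}, \code{altDepth} (read counts) and \code{label}
#' (one of \code{hawaiian}, \code{parental}, \code{novel},
#' \code{unclassified}). Positions are 1-based; indels are left-anchored at
#' the first affected base, VCF style, and the range width equals
#' \code{nchar(ref)}.
#'
#' @seealso [readVariantCalls()], [classifyVariants()], [altFraction()]
#' @exportClass VariantCalls
setClass("VariantCalls", contains = "GRanges")

setValidity("VariantCalls", function(object) {
  mc <- mcols(object)
  need <- c("ref", "alt", "refDepth", "altDepth", "label")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (any(mc$ref == mc$alt))
    return("ref allele equals alt allele for at least one call")
  if (any(mc$refDepth < 0L) || any(mc$altDepth < 0L))
    return("negative read depth")
  if (!all(mc$label %in% .VARIANT_LABELS))
    return(paste("label must be one of", paste(.VARIANT_LABELS, collapse = "/")))
  TRUE
})

#' SnpCatalog: known strain-background polymorphisms
#'
#' A \linkS4class{GRanges} subclass listing the (chrom, pos, ref, alt)
#' entries of a strain background catalog, either the Hawaiian (CB4856)
#' marker SNPs or the pre-mutagenesis parental variants. Entries are unique
#' by (chrom, pos, alt).
#'
#' @slot source character, \code{"hawaiian"} or \code{"parental"}.
#' @seealso [readSnpCatalog()], [classifyVariants()]
#' @exportClass SnpCatalog
setClass("SnpCatalog", contains = "GRanges",
         representation(source = "character"))

setValidity("SnpCatalog", function(object) {
  if (length(object@source) != 1L ||
      !object@source %in% c("hawaiian", "parental"))
    return("source must be 'hawaiian' or 'parental'")
  mc <- mcols(object)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    return("missing metadata column(s): ref/alt")
  if (length(object) == 0L) return(TRUE)
  if (any(start(object) < 1L)) return("positions must be >= 1")
  key <- paste(as.character(seqnames(object)), start(object), mc$alt)
  if (anyDuplicated(key)) return("duplicate (chrom, pos, alt) entry")
  TRUE
})

#' GeneticMap: monotone piecewise-linear bp/cM maps per chromosome
#'
#' Physical-to-genetic coordinate maps used by the crossover simulator.
#' Each chromosome has a physical length in bp and a strictly nondecreasing
#' piecewise-linear map from bp to cM with cM(0) = 0 and cM(length) = total
#' genetic length.
#'
#' @slot chromLengths named numeric, physical length (bp) per chromosome.
#' @slot points named list; per chromosome a data.frame with columns
#'   \code{bp} and \code{cM} giving the interpolation knots.
#' @seealso [geneticMap()], [cmAt()], [bpAt()]
#' @exportClass GeneticMap
setClass("GeneticMap",
         representation(chromLengths = "numeric", points = "list"))

setValidity("GeneticMap", function(object) {
  if (is.null(names(object@chromLengths)) ||
      !setequal(names(object@chromLengths), names(object@points)))
    return("chromLengths and points must share chromosome names")
  for (chrom in names(object@points)) {
    p <- object@points[[chrom]]
    if (!all(c("bp", "cM") %in% colnames(p))) return("points need bp and cM")
    if (p$bp[1] != 0 || p$cM[1] != 0) return("maps must start at (0, 0)")
    if (p$bp[nrow(p)] != object@chromLengths[[chrom]])
      return("last bp knot must equal the chromosome length")
    if (is.unsorted(p$bp, strictly = TRUE) || is.unsorted(p$cM))
      return("map knots must be increasing in bp and nondecreasing in cM")
  }
  TRUE
})

#' RecombinantChromosome: one simulated gamete chromosome
#'
#' An ancestry mosaic along one chromosome: ordered breakpoints partition
#' \code{[1, length]} into segments whose ancestries alternate between
#' \code{"N2"} and \code{"HAW"}.
#'
#' @slot chrom chromosome name.
#' @slot length physical length in bp.
#' @slot breakpoints numeric, strictly increasing positions in
#'   \code{(1, length)}; segment i ends at \code{breakpoints[i]} (inclusive).
#' @slot ancestry character of length \code{length(breakpoints) + 1}.
#' @seealso [simulateGamete()], [ancestryAt()]
#' @exportClass RecombinantChromosome
setClass("RecombinantChromosome",
         representation(chrom = "character", length = "numeric",
                        breakpoints = "numeric", ancestry = "character"))

setValidity("RecombinantChromosome", function(object) {
  if (object@length < 1) return("chromosome length must be >= 1 bp")
  if (length(object@ancestry) != length(object@breakpoints) + 1L)
    return("ancestry must have one more element than breakpoints")
  if (!all(object@ancestry %in% .ANCESTRIES))
    return("ancestry values must be 'N2' or 'HAW'")
  n <- length(object@ancestry)
  if (n > 1L && any(object@ancestry[-1] == object@ancestry[-n]))
    return("ancestries must alternate across breakpoints")
  if (length(object@breakpoints) &&
      (is.unsorted(object@breakpoints, strictly = TRUE) ||
       any(object@breakpoints <= 1) || any(object@breakpoints > object@length)))
    return("breakpoints must be strictly increasing within (1, length]")
  TRUE
})

#' GeneModel: a minimal protein-coding gene model
#'
#' CDS segments are stored as 1-based inclusive intervals in translation
#' order (first codon first; minus-strand genes therefore list CDS segments
#' in decreasing genomic coordinate). A model whose total CDS length is not
#' a multiple of 3 is flagged unusable for effect annotation.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot cds \linkS4class{IRanges} of CDS segments in translation order.
#' @slot proteinLength integer or NA; protein length in aa (excluding stop).
#' @slot usable logical; FALSE when the model cannot be annotated.
#' @seealso [readGeneModels()], [annotateEffect()]
#' @exportClass GeneModel
setClass("GeneModel",
         representation(geneId = "character", chrom = "character",
                        strand = "character", cds = "IRanges",
                        proteinLength = "integer", usable = "logical"))

setValidity("GeneModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (length(object@cds) == 0L) return("gene model needs at least one CDS segment")
  starts <- start(object@cds)
  if (length(starts) > 1L) {
    ord <- if (object@strand == "+") starts else rev(starts)
    if (is.unsorted(ord, strictly = TRUE))
      return("CDS segments must be in translation order for the strand")
    srt <- sort(object@cds)
    if (any(start(srt)[-1] <= end(srt)[-length(srt)]))
      return("CDS segments must not overlap")
  }
  total <- sum(width(object@cds))
  if (!is.na(object@proteinLength) && total %% 3L != 0L)
    return("total CDS length must be divisible by 3 when protein length given")
  TRUE
})

#' RegionalGenome: reference sequence for a set of named regions
#'
#' Reference sequence storage that works both for complete assemblies
#' (one region per chromosome) and for sparse region sets (for example only
#' the gene loci of a simulated genome). Lookups outside any stored region
#' are an error.
#'
#' @slot regions \linkS4class{GRanges} of covered spans (1-based inclusive).
#' @slot seqs \linkS4class{DNAStringSet}, parallel to \code{regions}.
#' @seealso [readGenome()], [getRefSequence()]
#' @exportClass RegionalGenome
setClass("RegionalGenome",
         representation(regions = "GRanges", seqs = "DNAStringSet"))

setValidity("RegionalGenome", function(object) {
  if (length(object@regions) != length(object@seqs))
    return("regions and seqs must be parallel")
  if (length(object@regions) &&
      !all(width(object@regions) == Biostrings::width(object@seqs)))
    return("sequence lengths must match region widths")
  TRUE
})

#' CrossModel: the reference state of a simulated mapping cross
#'
#' Bundles everything [buildReferenceModel()] generates: the genetic map,
#' Hawaiian and parental SNP catalogs, EMS-induced mutations (including the
#' single causal lesion), toy gene models with their reference sequence, and
#' the configuration/seed used.
#'
#' @slot map \linkS4class{GeneticMap}.
#' @slot hawaiian,parental \linkS4class{SnpCatalog}.
#' @slot induced \linkS4class{GRanges} with mcols ref, alt, causal (logical).
#' @slot genes list of \linkS4class{GeneModel}.
#' @slot genome \linkS4class{RegionalGenome} covering the gene loci.
#' @slot causalChrom,causalPos location of the causal lesion.
#' @slot config list of generator settings; \code{seed} integer master seed.
#' @seealso [buildReferenceModel()], [simulateMutantPool()]
#' @exportClass CrossModel
setClass("CrossModel",
         representation(map = "GeneticMap", hawaiian = "SnpCatalog",
                        parental = "SnpCatalog", induced = "GRanges",
                        genes = "list", genome = "RegionalGenome",
                        causalChrom = "character", causalPos = "numeric",
                        config = "list", seed = "integer"))

#' CrossPool: a pooled set of homozygous-mutant F2 lines
#'
#' The result of simulating the mapping cross: per pooled F2 line and per
#' chromosome, the two recombinant haplotypes, together with the causal
#' locus at which every line is homozygous N2.
#'
#' @slot haplotypes named list (per chromosome) of lists of
#'   \linkS4class{RecombinantChromosome}; line i contributes elements
#'   \code{2i - 1} and \code{2i}.
#' @slot nLines number of pooled F2 lines.
#' @slot causalChrom,causalPos the selected locus.
#' @slot seed integer seed used for the simulation.
#' @seealso [simulateMutantPool()], [hawFrequency()], [poolTruth()]
#' @exportClass CrossPool
setClass("CrossPool",
         representation(haplotypes = "list", nLines = "integer",
                        causalChrom = "character", causalPos = "numeric",
                        seed = "integer", nF2 = "integer",
                        nMutant = "integer"))

setValidity("CrossPool", function(object) {
  if (!object@causalChrom %in% names(object@haplotypes))
    return("causal chromosome not among pooled haplotypes")
  haps <- object@haplotypes[[object@causalChrom]]
  if (length(haps) != 2L * object@nLines)
    return("each line must contribute two haplotypes per chromosome")
  anc <- vapply(haps, ancestryAt, character(1), pos = object@causalPos)
  if (any(anc != "N2"))
    return("every pooled haplotype must be N2 at the causal locus")
  TRUE
})

#' GuideSite: a located CRISPR protospacer with its PAM
#'
#' Coordinates are 1-based on the plus strand of the searched target
#' sequence regardless of the strand carrying the protospacer. The blunt
#' SpCas9 cut falls between bases \code{cutAfter} and \code{cutAfter + 1},
#' 3 bp 5' of the PAM.
#'
#' @slot protospacer the matched guide sequence (as given).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot pam the NGG triplet on the protospacer strand.
#' @slot start,end plus-strand span of the protospacer.
#' @slot cutAfter between-base cut coordinate on the plus strand.
#' @seealso [locateProtospacer()], [cutSite()]
#' @exportClass GuideSite
setClass("GuideSite",
         representation(protospacer = "character", strand = "character",
                        pam = "character", start = "numeric", end = "numeric",
                        cutAfter = "numeric"))

setValidity("GuideSite", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (object@end < object@start) return("end < start")
  if (substr(object@pam, 2, 3) != "GG") return("PAM must match NGG")
  if (object@cutAfter < object@start || object@cutAfter >= object@end)
    return("cut coordinate must fall inside the protospacer span")
  TRUE
})
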