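.AA3 <- local({
  x <- Biostrings::AMINO_ACID_CODE  # one-letter -> three-letter
  c(x, "*" = "stop")
})

.aa1From3 <- function(code) {
  if (tolower(code) == "stop") return("*")
  hit <- names(.AA3)[match(tolower(code), tolower(.AA3))]
  if (is.na(hit)) stop("unknown amino-acid code: ", code)
  hit
}

.translateCodon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Effect classes counted as nonsynonymous
#' @return character vector of effect-class names.
#' @export
nonsynonymousClasses <- function() .NONSYNONYMOUS

# Coding sequence of a gene model in translation order (sense strand).
.codingSequence <- function(gene, genome) {
  segs <- vapply(seq_along(gene@cds), function(i)
    getRefSequence(genome, gene@chrom, start(gene@cds)[i],
                   end(gene@cds)[i]), character(1))
  if (gene@strand == "+") paste(segs, collapse = "")
  else paste(vapply(segs, .revcomp, character(1)), collapse = "")
}

# CDS (spliced, translation-order) coordinate of a genomic position.
.cdsCoordinate <- function(gene, pos) {
  offset <- 0L
  for (i in seq_along(gene@cds)) {
    s <- start(gene@cds)[i]; e <- end(gene@cds)[i]
    if (pos >= s && pos <= e) {
      within <- if (gene@strand == "+") pos - s + 1L else e - pos + 1L
      return(offset + within)
    }
    offset <- offset + e - s + 1L
  }
  NA_integer_
}

# Splice-site positions: the two intronic bases on each side of every
# internal CDS boundary (the GT/AG dinucleotide positions).
.spliceSites <- function(gene) {
  if (length(gene@cds) < 2L) return(numeric())
  srt <- sort(gene@cds)
  donors <- end(srt)[-length(srt)]
  acceptors <- start(srt)[-1]
  c(as.vector(outer(donors, 1:2, `+`)),
    as.vector(outer(acceptors, 1:2, `-`)))
}

#' Annotate the coding effect of one variant
#'
#' A minimal codon-level effect annotator. An SNV inside a CDS is
#' classified by translating the affected codon before and after the change
#' (minus-strand genes via the reverse complement); an SNV within 2 bp of
#' an intron boundary is \code{splice}; a coding indel whose length change
#' is not a multiple of 3 is \code{frameshift} (in-frame coding indels are
#' reported \code{missense} as they alter the protein); anything outside
#' CDS and splice positions is \code{noncoding}. Amino-acid numbering is
#' 1-based from the initiator Met.
#'
#' @param variant a length-one \linkS4class{VariantCalls}.
#' @param geneModels list of \linkS4class{GeneModel} (unusable models are
#'   skipped).
#' @param genome a \linkS4class{RegionalGenome}. The reference base(s) at
#'   the variant position must match the variant's ref allele, otherwise an
#'   error is raised.
#' @return list with \code{effect}, \code{geneId}, \code{codonFrom},
#'   \code{codonTo}, \code{aaFrom}, \code{aaTo}, \code{aaPos},
#'   \code{aaChange} (e.g. \code{"Gly42Arg"}; NA where not applicable).
#' @examples
#' ## a G->A change at the first position of a GGA (Gly) codon is the
#' ## classic EMS missense Gly -> Arg
#' @export
annotateEffect <- function(variant, geneModels, genome) {
  stopifnot(length(variant) == 1L)
  chrom <- as.character(seqnames(variant))
  pos <- start(variant)
  ref <- mcols(variant)$ref
  alt <- mcols(variant)$alt
  blank <- list(effect = "noncoding", geneId = NA_character_,
                codonFrom = NA_character_, codonTo = NA_character_,
                aaFrom = NA_character_, aaTo = NA_character_,
                aaPos = NA_integer_, aaChange = NA_character_)
  for (gene in geneModels) {
    if (!gene@usable || gene@chrom != chrom) next
    span <- pos:(pos + nchar(ref) - 1L)
    inCds <- any(vapply(span, function(p)
      any(p >= start(gene@cds) & p <= end(gene@cds)), logical(1)))
    isSnv <- nchar(ref) == 1L && nchar(alt) == 1L
    if (!inCds) {
      if (isSnv && pos %in% .spliceSites(gene)) {
        out <- blank
        out$effect <- "splice"; out$geneId <- gene@geneId
        return(out)
      }
      next
    }
    refSeq <- getRefSequence(genome, chrom, pos, pos + nchar(ref) - 1L)
    if (!identical(refSeq, ref))
      stop("variant ref allele ", ref, " does not match reference ", refSeq,
           " at ", chrom, ":", pos)
    if (!isSnv) {
      shift <- abs(nchar(ref) - nchar(alt)) %% 3L
      out <- blank
      out$effect <- if (shift != 0L) "frameshift" else "missense"
      out$geneId <- gene@geneId
      return(out)
    }
    cdsPos <- .cdsCoordinate(gene, pos)
    coding <- .codingSequence(gene, genome)
    codonIdx <- (cdsPos - 1L) %/% 3L + 1L
    posInCodon <- cdsPos - 3L * (codonIdx - 1L)
    codonFrom <- substr(coding, 3L * codonIdx - 2L, 3L * codonIdx)
    senseAlt <- if (gene@strand == "+") alt else .complementBase(alt)
    codonTo <- codonFrom
    substr(codonTo, posInCodon, posInCodon) <- senseAlt
    aaFrom <- .translateCodon(codonFrom)
    aaTo <- .translateCodon(codonTo)
    effect <- if (aaFrom == aaTo) "synonymous"
      else if (aaTo == "*") "nonsense"
      else if (aaFrom == "*") "stop_loss"
      else if (codonIdx == 1L && aaFrom == "M") "start_loss"
      else "missense"
    return(list(effect = effect, geneId = gene@geneId,
                codonFrom = codonFrom, codonTo = codonTo,
                aaFrom = aaFrom, aaTo = aaTo, aaPos = codonIdx,
                aaChange = paste0(.AA3[[aaFrom]], codonIdx, .AA3[[aaTo]])))
  }
  blank
}

#' Filter the candidate lesion list
#'
#' Applies the mapping-by-sequencing candidate definition: calls that are
#' (a) inside the mapping interval, (b) novel (not in the Hawaiian or
#' parental background), (c) homozygous at the >\code{threshold} alt-read
#' fraction, and (d) nonsynonymous per [annotateEffect()]. Calls with zero
#' total depth cannot be assessed and are dropped with a message.
#'
#' @param calls classified \linkS4class{VariantCalls}.
#' @param interval a length-one \linkS4class{GRanges} (e.g.
#'   [selectedInterval()] output).
#' @param geneModels list of \linkS4class{GeneModel}.
#' @param genome a \linkS4class{RegionalGenome}.
#' @param threshold homozygosity threshold (default 0.85, strict).
#' @return \linkS4class{VariantCalls} sorted by position with metadata
#'   columns \code{geneId}, \code{effect}, \code{aaChange},
#'   \code{emsTransition}.
#' @export
filterCandidates <- function(calls, interval, geneModels, genome,
                             threshold = 0.85) {
  stopifnot(length(interval) == 1L)
  keep <- as.character(seqnames(calls)) ==
    as.character(seqnames(interval))[1] &
    start(calls) >= start(interval) & start(calls) <= end(interval) &
    mcols(calls)$label == "novel"
  cand <- calls[keep]
  tot <- mcols(cand)$refDepth + mcols(cand)$altDepth
  if (any(tot == 0L)) {
    message("dropping ", sum(tot == 0L), " zero-depth call(s)")
    cand <- cand[tot > 0L]
  }
  cand <- cand[isHomozygous(cand, threshold)]
  if (length(cand) == 0L) return(.emptyCandidates(cand))
  ann <- lapply(seq_along(cand), function(i)
    annotateEffect(cand[i], geneModels, genome))
  eff <- vapply(ann, `[[`, character(1), "effect")
  ns <- eff %in% .NONSYNONYMOUS
  cand <- cand[ns]
  mcols(cand)$geneId <- vapply(ann[ns], `[[`, character(1), "geneId")
  mcols(cand)$effect <- eff[ns]
  mcols(cand)$aaChange <- vapply(ann[ns], `[[`, character(1), "aaChange")
  mcols(cand)$emsTransition <- emsFlag(mcols(cand)$ref, mcols(cand)$alt)
  sort(cand)
}

.emptyCandidates <- function(cand) {
  mcols(cand)$geneId <- character(0)
  mcols(cand)$effect <- character(0)
  mcols(cand)$aaChange <- character(0)
  mcols(cand)$emsTransition <- logical(0)
  cand
}

#' Genetic-code consistency of a reported substitution
#'
#' Tests whether an amino-acid change is reachable from a single-base
#' nucleotide change as printed in a mutation table, allowing the printed
#' base change to refer to either strand: a codon for \code{aaFrom} must
#' admit a substitution \code{ntFrom -> ntTo} or
#' \code{complement(ntFrom) -> complement(ntTo)} producing a codon for
#' \code{aaTo}. Used to validate mutation-table transcriptions without
#' transcript sequences.
#'
#' @param aaFrom,aaTo 3-letter amino-acid codes or \code{"stop"}.
#' @param ntFrom,ntTo single bases in A/C/G/T.
#' @return list with \code{consistent} (logical) and \code{witnesses}
#'   (data.frame of codonFrom, codonTo, position, strand).
#' @examples
#' checkSubstitutionConsistency("Gly", "Arg", "G", "A")  # GGA -> AGA
#' @export
checkSubstitutionConsistency <- function(aaFrom, aaTo, ntFrom, ntTo) {
  if (!all(c(ntFrom, ntTo) %in% c("A", "C", "G", "T")))
    stop("nucleotides must be one of A/C/G/T")
  a1 <- .aa1From3(aaFrom)
  a2 <- .aa1From3(aaTo)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a1]
  wit <- list()
  for (codon in codons) {
    for (p in 1:3) {
      base <- substr(codon, p, p)
      for (strand in c("+", "-")) {
        from <- if (strand == "+") ntFrom else .complementBase(ntFrom)
        to <- if (strand == "+") ntTo else .complementBase(ntTo)
        if (base != from) next
        mutant <- codon
        substr(mutant, p, p) <- to
        if (.translateCodon(mutant) == a2)
          wit[[length(wit) + 1L]] <- data.frame(
            codonFrom = codon, codonTo = mutant, position = p,
            strand = strand)
      }
    }
  }
  wit <- if (length(wit)) unique(do.call(rbind, wit)) else
    data.frame(codonFrom = character(), codonTo = character(),
               position = integer(), strand = character())
  list(consistent = nrow(wit) > 0L, witnesses = wit)
}

#' Parse a mutation-table descriptor
#'
#' Parses descriptors in the style of published candidate tables:
#' \code{"G->A, Gly42Arg"} (missense), \code{"G->A, Trp1062stop"}
#' (nonsense) and \code{"Insertion of a C between nucleotide 207 and 208;
#' frameshift"}. Unrecognised text is an error quoting the input.
#'
#' @param text descriptor string.
#' @return list with \code{effect} and, for substitutions, \code{ntFrom},
#'   \code{ntTo}, \code{aaFrom}, \code{aaTo}, \code{aaPos}.
#' @export
classifyDescriptor <- function(text) {
  m <- regmatches(text, regexec(
    "^([ACGT])->([ACGT]),\\s*([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|stop)$",
    text))[[1]]
  if (length(m)) {
    effect <- if (m[6] == "stop") "nonsense" else "missense"
    return(list(effect = effect, ntFrom = m[2], ntTo = m[3],
                aaFrom = m[4], aaPos = as.integer(m[5]), aaTo = m[6]))
  }
  if (grepl("frameshift", text, ignore.case = TRUE) &&
      grepl("insertion|deletion", text, ignore.case = TRUE))
    return(list(effect = "frameshift", ntFrom = NA, ntTo = NA,
                aaFrom = NA, aaPos = NA, aaTo = NA))
  stop("unrecognised mutation descriptor: \"", text, "\"")
}

#' Codons removed by a premature stop
#'
#' The number of codons strictly C-terminal to a premature stop position:
#' \code{proteinLength - stopPosition}.
#'
#' @param proteinLength full-length protein size in aa.
#' @param stopPosition 1-based codon position of the premature stop; must
#'   lie within the protein.
#' @return integer count of removed codons.
#' @examples
#' truncationLength(1227, 1062)  # 165
#' @export
truncationLength <- function(proteinLength, stopPosition) {
  if (stopPosition < 1 || stopPosition > proteinLength)
    stop("stop position must lie within [1, proteinLength]")
  as.integer(proteinLength - stopPosition)
}

#' EMS transition flag
#'
#' EMS mutagenesis produces predominantly G:C to A:T transitions; a
#' substitution is flagged when it is G->A or C->T on either strand.
#'
#' @param ref,alt single-base vectors.
#' @return logical vector.
#' @export
emsFlag <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Packaged legacy mutant candidate tables
#'
#' The transcribed candidate-variant tables of the seven legacy mutant
#' strains (columns strain, gene, mutation_text, description, causal).
#'
#' @return data.frame of 38 candidate rows.
#' @export
legacyVariantTable <- function() {
  utils::read.delim(system.file("extdata", "legacy_variant_tables.tsv",
                                package = "hawmap"),
                    stringsAsFactors = FALSE)
}

#' Packaged complementation-test results
#'
#' The printed trans-heterozygote hatching percentages and verdicts of the
#' complementation crosses (columns strain, tester, percent_hatching, n,
#' printed_verdict, note).
#'
#' @return data.frame of complementation outcomes.
#' @export
complementationTable <- function() {
  utils::read.delim(system.file("extdata", "complementation_results.tsv",
                                package = "hawmap"),
                    stringsAsFactors = FALSE)
}
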