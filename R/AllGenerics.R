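#' @include AllClasses.R
NULL

#' Alt-read fraction of variant calls
#'
#' The fraction of reads supporting the alternate allele,
#' \code{altDepth / (refDepth + altDepth)}. Sites with zero total depth
#' return \code{NA}.
#'
#' @param x a \linkS4class{VariantCalls} object.
#' @return numeric vector in \code{[0, 1]} (or NA at zero depth).
#' @export
setGeneric("altFraction", function(x) standardGeneric("altFraction"))

#' @describeIn altFraction method for VariantCalls
#' @export
setMethod("altFraction", "VariantCalls", function(x) {
  tot <- mcols(x)$refDepth + mcols(x)$altDepth
  ifelse(tot > 0L, mcols(x)$altDepth / tot, NA_real_)
})

#' Catalog source accessor
#' @param x a \linkS4class{SnpCatalog}.
#' @return \code{"hawaiian"} or \code{"parental"}.
#' @export
setGeneric("catalogSource", function(x) standardGeneric("catalogSource"))

#' @describeIn catalogSource method for SnpCatalog
#' @export
setMethod("catalogSource", "SnpCatalog", function(x) x@source)

#' Ancestry of a recombinant chromosome at given positions
#'
#' @param x a \linkS4class{RecombinantChromosome}.
#' @param pos numeric vector of 1-based positions.
#' @return character vector of \code{"N2"} / \code{"HAW"}.
#' @export
setGeneric("ancestryAt", function(x, pos) standardGeneric("ancestryAt"))

#' @describeIn ancestryAt segment lookup by breakpoint interval
#' @export
setMethod("ancestryAt", "RecombinantChromosome", function(x, pos) {
  if (any(pos < 1 | pos > x@length))
    stop("position outside chromosome ", x@chrom)
  x@ancestry[findInterval(pos, x@breakpoints, left.open = TRUE) + 1L]
})

setMethod("show", "VariantCalls", function(object) {
  lab <- table(factor(mcols(object)$label, levels = .VARIANT_LABELS))
  cat("VariantCalls with", length(object), "calls (",
      paste(names(lab), lab, sep = ":", collapse = " "), ")\n")
  callNextMethod()
})

setMethod("show", "SnpCatalog", function(object) {
  cat("SnpCatalog [", object@source, "] with ", length(object),
      " entries on ", length(unique(as.character(seqnames(object)))),
      " chromosome(s)\n", sep = "")
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap over", length(object@chromLengths), "chromosome(s):\n")
  for (chrom in names(object@chromLengths)) {
    p <- object@points[[chrom]]
    cat(sprintf("  %s: %.2f Mb, %.1f cM (%d knots)\n", chrom,
                object@chromLengths[[chrom]] / 1e6, p$cM[nrow(p)], nrow(p)))
  }
})

setMethod("show", "RecombinantChromosome", function(object) {
  cat("RecombinantChromosome", object@chrom,
      if (length(object@breakpoints) == 0L) paste0("non-recombinant [",
                                                   object@ancestry, "]")
      else paste0(paste(object@ancestry, collapse = "|"), " at bp ",
                  paste(round(object@breakpoints), collapse = ", ")), "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s) %d CDS segment(s), %d bp CDS%s\n",
              object@geneId, object@chrom, object@strand, length(object@cds),
              sum(width(object@cds)),
              if (object@usable) "" else " [unusable]"))
})

setMethod("show", "CrossModel", function(object) {
  cat("CrossModel:", length(object@map@chromLengths), "chromosomes,",
      length(object@hawaiian), "Hawaiian SNPs,",
      length(object@parental), "parental variants,",
      length(object@induced), "induced mutations,",
      length(object@genes), "gene models\n")
  cat("  causal locus:", object@causalChrom, "at",
      format(object@causalPos, big.mark = ","), "bp; seed", object@seed, "\n")
})

setMethod("show", "CrossPool", function(object) {
  cat("CrossPool of", object@nLines, "homozygous-mutant F2 lines;",
      "causal locus", object@causalChrom, "at",
      format(object@causalPos, big.mark = ","), "bp\n")
})

setMethod("show", "GuideSite", function(object) {
  cat(sprintf("GuideSite %s strand %s at %d..%d PAM %s cut after %d\n",
              object@protospacer, object@strand, as.integer(object@start),
              as.integer(object@end), object@pam, as.integer(object@cutAfter)))
})
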