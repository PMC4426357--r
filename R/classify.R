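#' Classify variant calls by strain origin
#'
#' Labels each call by allele-exact matching of (chrom, pos, alt) against
#' the Hawaiian and parental background catalogs: \code{hawaiian} if the
#' call matches a Hawaiian catalog entry, else \code{parental} if it
#' matches the pre-mutagenesis background, else \code{novel}. A call at a
#' catalog position but with a different alternate allele is \emph{novel}
#' (position-only matching would mislabel new alleles arising at
#' polymorphic sites). Every call receives exactly one label.
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param hawaiian Hawaiian \linkS4class{SnpCatalog}.
#' @param parental parental \linkS4class{SnpCatalog} (may be empty).
#' @return the calls with \code{label} filled in; per-class counts are
#'   reported via \code{message()}.
#' @export
classifyVariants <- function(calls, hawaiian, parental = NULL) {
  key <- .variantKey(as.character(seqnames(calls)), start(calls),
                     mcols(calls)$alt)
  hawKey <- .variantKey(as.character(seqnames(hawaiian)), start(hawaiian),
                        mcols(hawaiian)$alt)
  label <- rep("novel", length(calls))
  label[key %in% hawKey] <- "hawaiian"
  if (!is.null(parental) && length(parental)) {
    parKey <- .variantKey(as.character(seqnames(parental)), start(parental),
                          mcols(parental)$alt)
    label[label == "novel" & key %in% parKey] <- "parental"
  }
  mcols(calls)$label <- label
  counts <- table(factor(label, levels = .VARIANT_LABELS))
  message("classified ", length(calls), " calls: ",
          paste(names(counts), counts, sep = "=", collapse = " "))
  calls
}

#' Homozygosity call from allelic depths
#'
#' A variant is called homozygous when its alt-read fraction strictly
#' exceeds the threshold; the conventional cutoff for pooled
#' mapping-by-sequencing candidate filtering is >85\% variant call.
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param threshold fraction in (0, 1); default 0.85, applied strictly
#'   (a fraction exactly at the threshold is not homozygous).
#' @return logical vector. Zero total depth at any call is an error.
#' @export
isHomozygous <- function(calls, threshold = 0.85) {
  tot <- mcols(calls)$refDepth + mcols(calls)$altDepth
  if (any(tot == 0L))
    stop("zero total depth at ",
         .variantKey(as.character(seqnames(calls)), start(calls),
                     mcols(calls)$alt)[which(tot == 0L)[1]])
  altFraction(calls) > threshold
}

#' Presence of a Hawaiian catalog SNP in the pool
#'
#' A catalog SNP counts as present when it is supported by at least
#' \code{minAltReads} alternate reads. The default of 2 resists isolated
#' sequencing-error reads at ~22x coverage; with error-free data
#' \code{minAltReads = 1} makes presence equivalent to at least one pooled
#' chromosome carrying Hawaiian ancestry at the site.
#'
#' @param calls \linkS4class{VariantCalls}, all labeled \code{hawaiian}
#'   (anything else is an error).
#' @param minAltReads minimum supporting reads (default 2).
#' @return logical vector.
#' @export
hawaiianPresent <- function(calls, minAltReads = 2) {
  if (any(mcols(calls)$label != "hawaiian"))
    stop("hawaiianPresent() expects calls labeled 'hawaiian'")
  mcols(calls)$altDepth >= minAltReads
}
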