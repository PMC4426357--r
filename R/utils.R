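# Internal helpers shared across modules.

# Derived RNG substreams: one master seed, one deterministic 31-bit child
# per component index, so independent stages do not share a stream.
.substream <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 1103 + index * 7919) %%
               2147483647)
}

.variantKey <- function(chrom, pos, alt) {
  paste(chrom, as.integer(pos), alt, sep = ":")
}

# Constructor used throughout: builds a validated VariantCalls object.
#' Construct a VariantCalls object
#'
#' @param chrom,pos,ref,alt,refDepth,altDepth parallel vectors describing
#'   one biallelic call per element; \code{pos} is 1-based.
#' @param label classification label, recycled; defaults to
#'   \code{"unclassified"}.
#' @param ... further metadata columns (e.g. truth tags from the simulator).
#' @return a \linkS4class{VariantCalls} object.
#' @examples
#' VariantCalls("chrI", c(100, 200), c("A", "G"), c("T", "A"),
#'              refDepth = c(3, 15), altDepth = c(27, 15))
#' @export
VariantCalls <- function(chrom, pos, ref, alt, refDepth, altDepth,
                         label = "unclassified", ...) {
  gr <- GRanges(chrom, IRanges(as.numeric(pos),
                               width = pmax(1L, nchar(ref))))
  mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt),
                         refDepth = as.integer(refDepth),
                         altDepth = as.integer(altDepth),
                         label = rep_len(as.character(label), length(gr)),
                         ...)
  new("VariantCalls", gr)
}

#' Construct a SnpCatalog
#'
#' Duplicate (chrom, pos, alt) rows are removed.
#'
#' @param chrom,pos,ref,alt parallel vectors; \code{pos} is 1-based.
#' @param source \code{"hawaiian"} or \code{"parental"}.
#' @return a \linkS4class{SnpCatalog}.
#' @export
SnpCatalog <- function(chrom, pos, ref, alt, source) {
  if (length(pos) && any(pos < 1))
    stop("catalog positions must be >= 1")
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  keep <- !duplicated(.variantKey(chrom, pos, alt))
  gr <- GRanges(chrom[keep], IRanges(as.numeric(pos)[keep], width = 1L))
  mcols(gr) <- DataFrame(ref = ref[keep], alt = alt[keep])
  new("SnpCatalog", gr, source = source)
}

.complementBase <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
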