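#' Hawaiian SNP density profile along a chromosome
#'
#' Bins the chromosome and counts, per bin, the Hawaiian catalog SNPs that
#' are present in the pooled calls (the quantity plotted against chromosome
#' position to visualise the mapping interval) next to the total number of
#' catalog SNPs in the bin. Bins tile \code{[1, chromLength]}; the last bin
#' may be short.
#'
#' @param calls classified \linkS4class{VariantCalls}.
#' @param catalog Hawaiian \linkS4class{SnpCatalog}.
#' @param chrom chromosome name.
#' @param binSize bin width in bp (default 100 kb); must be positive.
#' @param chromLength chromosome length in bp; defaults to the largest
#'   catalog or call position on the chromosome.
#' @param minAltReads presence threshold, see [hawaiianPresent()].
#' @return data.frame with columns \code{chrom}, \code{binStart},
#'   \code{binEnd}, \code{present}, \code{catalogTotal}.
#' @export
densityProfile <- function(calls, catalog, chrom, binSize = 1e5,
                           chromLength = NULL, minAltReads = 2) {
  if (binSize <= 0) stop("binSize must be > 0")
  hawCalls <- calls[mcols(calls)$label == "hawaiian" &
                    as.character(seqnames(calls)) == chrom]
  catPos <- start(catalog)[as.character(seqnames(catalog)) == chrom]
  if (is.null(chromLength))
    chromLength <- max(c(catPos, start(hawCalls), 1))
  presentPos <- start(hawCalls)[hawaiianPresent(hawCalls, minAltReads)]
  binStart <- seq(1, chromLength, by = binSize)
  binEnd <- pmin(binStart + binSize - 1, chromLength)
  bin <- function(pos) tabulate(findInterval(pos, binStart),
                                nbins = length(binStart))
  data.frame(chrom = chrom, binStart = binStart, binEnd = binEnd,
             present = bin(presentPos), catalogTotal = bin(catPos))
}

#' Detect the mapping interval from Hawaiian SNP depletion
#'
#' For each chromosome the mapping interval is the maximal span devoid of
#' \emph{present} Hawaiian SNPs: the largest gap between consecutive
#' present catalog SNPs, with the interval endpoints one base inside the
#' flanking present SNPs (chromosome ends act as open flanks). Among the
#' per-chromosome gaps, the selected interval is the one with the largest
#' genetic (cM) width under \code{map} -- which normalises for chromosome
#' length -- falling back to physical width when no map is given; ties are
#' broken by chromosome name, then lower start.
#'
#' A secondary \code{"reduction"} mode handles pools where Hawaiian SNPs
#' are reduced rather than absent (e.g. phenotype mis-scoring or
#' contamination): the interval is the longest run of \code{binSize} bins
#' whose present-SNP count is at most \code{k}.
#'
#' @param calls classified \linkS4class{VariantCalls}; an empty set is an
#'   error.
#' @param catalog Hawaiian \linkS4class{SnpCatalog}.
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param map optional \linkS4class{GeneticMap} used for interval selection.
#' @param minAltReads presence threshold, see [hawaiianPresent()].
#' @param mode \code{"absence"} (exact gaps, default) or \code{"reduction"}.
#' @param binSize,k reduction-mode bin width and maximum per-bin present
#'   count (defaults 100 kb and 0).
#' @return a \linkS4class{GRanges} with one interval per chromosome and
#'   metadata columns \code{flankLeft}/\code{flankRight} (positions of the
#'   flanking present SNPs, NA at chromosome ends), \code{nCatalogInside},
#'   \code{geneticWidthCM}, \code{ambiguous} (TRUE when the chromosome had
#'   no present SNPs at all) and \code{selected}.
#' @seealso [intervalReport()], [writeIntervalBed()]
#' @export
detectInterval <- function(calls, catalog, chromLengths, map = NULL,
                           minAltReads = 2, mode = c("absence", "reduction"),
                           binSize = 1e5, k = 0) {
  mode <- match.arg(mode)
  if (length(calls) == 0L) stop("empty call set")
  hawCalls <- calls[mcols(calls)$label == "hawaiian"]
  present <- hawCalls[hawaiianPresent(hawCalls, minAltReads)]
  if (length(present) == 0L && mode == "absence")
    warning("no present Hawaiian SNPs genome-wide; all intervals degenerate")
  rows <- lapply(names(chromLengths), function(chrom) {
    L <- chromLengths[[chrom]]
    pos <- sort(unique(start(present)[
      as.character(seqnames(present)) == chrom]))
    if (mode == "absence") .absenceGap(chrom, pos, L)
    else .reductionRun(chrom, pos, L, binSize, k)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) stop("no interval detectable")
  gw <- if (!is.null(map)) {
    vapply(seq_len(nrow(tab)), function(i)
      cmAt(map, tab$chrom[i], tab$end[i]) -
        cmAt(map, tab$chrom[i], tab$start[i]), numeric(1))
  } else rep(NA_real_, nrow(tab))
  measure <- if (!is.null(map)) gw else tab$end - tab$start + 1
  ord <- order(-measure, tab$chrom, tab$start)
  selected <- seq_len(nrow(tab)) == ord[1]
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
  catChrom <- as.character(seqnames(catalog))
  nIn <- vapply(seq_len(nrow(tab)), function(i)
    sum(catChrom == tab$chrom[i] & start(catalog) >= tab$start[i] &
        start(catalog) <= tab$end[i]), numeric(1))
  mcols(gr) <- DataFrame(flankLeft = tab$flankLeft,
                         flankRight = tab$flankRight,
                         nCatalogInside = as.integer(nIn),
                         geneticWidthCM = gw, ambiguous = tab$ambiguous,
                         selected = selected)
  gr
}

.absenceGap <- function(chrom, pos, L) {
  if (length(pos) == 0L)
    return(data.frame(chrom = chrom, start = 1, end = L,
                      flankLeft = NA_real_, flankRight = NA_real_,
                      ambiguous = TRUE))
  bounds <- c(0, pos, L + 1)  # virtual present SNPs just outside the ends
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1] - 1
  ok <- ends >= starts
  if (!any(ok)) return(NULL)
  starts <- starts[ok]; ends <- ends[ok]
  flankL <- (bounds[-length(bounds)])[ok]
  flankR <- (bounds[-1])[ok]
  widest <- which.max(ends - starts)
  data.frame(chrom = chrom, start = starts[widest], end = ends[widest],
             flankLeft = ifelse(flankL[widest] == 0, NA, flankL[widest]),
             flankRight = ifelse(flankR[widest] == L + 1, NA,
                                 flankR[widest]),
             ambiguous = FALSE)
}

.reductionRun <- function(chrom, pos, L, binSize, k) {
  binStart <- seq(1, L, by = binSize)
  counts <- tabulate(findInterval(pos, binStart), nbins = length(binStart))
  low <- counts <= k
  if (!any(low))
    return(data.frame(chrom = chrom, start = 1, end = L,
                      flankLeft = NA_real_, flankRight = NA_real_,
                      ambiguous = TRUE))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  data.frame(chrom = chrom, start = binStart[starts[best]],
             end = min(binStart[ends[best]] + binSize - 1, L),
             flankLeft = NA_real_, flankRight = NA_real_,
             ambiguous = all(low))
}

#' Extract the selected mapping interval
#' @param intervals result of [detectInterval()].
#' @return a length-one \linkS4class{GRanges}.
#' @export
selectedInterval <- function(intervals) {
  intervals[mcols(intervals)$selected]
}

#' Summary table of mapping results
#'
#' One row per interval: chromosome, bounds, width in Mb and the number of
#' candidate lesions falling inside -- the columns of a mapping-summary
#' figure panel.
#'
#' @param intervals a \linkS4class{GRanges} of mapping intervals.
#' @param candidates a \linkS4class{GRanges}/\linkS4class{VariantCalls} of
#'   candidate variants (may be empty).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{widthMb}, \code{nCandidates}.
#' @export
intervalReport <- function(intervals, candidates = GRanges()) {
  nC <- if (length(candidates))
    GenomicRanges::countOverlaps(intervals, candidates) else
      rep(0L, length(intervals))
  data.frame(chrom = as.character(seqnames(intervals)),
             start = start(intervals), end = end(intervals),
             widthMb = (end(intervals) - start(intervals) + 1) / 1e6,
             nCandidates = as.integer(nC))
}
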