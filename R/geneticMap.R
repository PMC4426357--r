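#' Build a genetic map
#'
#' Constructs per-chromosome monotone piecewise-linear maps between physical
#' (bp) and genetic (cM) coordinates. Two shapes are available:
#' \code{"uniform"} (constant recombination rate) and \code{"three_domain"},
#' which mimics the *C. elegans* pattern of high-recombination arms and a
#' low-recombination center: the two outer quarters of the chromosome each
#' carry 40\% of the genetic length, the central half only 20\%.
#'
#' @param chromLengths named numeric vector of physical lengths (bp).
#' @param totalCM total genetic length per chromosome in cM; a single value
#'   is recycled. Default 50, the canonical length of a *C. elegans*
#'   chromosome under complete crossover interference.
#' @param type \code{"uniform"} or \code{"three_domain"}.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' geneticMap(c(chrI = 15e6, chrII = 16e6))
#' @export
geneticMap <- function(chromLengths, totalCM = 50,
                       type = c("uniform", "three_domain")) {
  type <- match.arg(type)
  if (is.null(names(chromLengths)))
    stop("chromLengths must be named by chromosome")
  totalCM <- rep_len(totalCM, length(chromLengths))
  pts <- lapply(seq_along(chromLengths), function(i) {
    L <- chromLengths[[i]]; total <- totalCM[[i]]
    if (type == "uniform") {
      data.frame(bp = c(0, L), cM = c(0, total))
    } else {
      data.frame(bp = c(0, 0.25 * L, 0.75 * L, L),
                 cM = c(0, 0.4, 0.6, 1) * total)
    }
  })
  names(pts) <- names(chromLengths)
  new("GeneticMap", chromLengths = chromLengths, points = pts)
}

.mapPoints <- function(map, chrom) {
  p <- map@points[[chrom]]
  if (is.null(p)) stop("chromosome ", chrom, " not in genetic map")
  p
}

#' Convert physical to genetic coordinates
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome name.
#' @param bp numeric vector of physical positions.
#' @return genetic positions in cM.
#' @export
cmAt <- function(map, chrom, bp) {
  p <- .mapPoints(map, chrom)
  stats::approx(p$bp, p$cM, xout = bp, rule = 2)$y
}

#' Convert genetic to physical coordinates
#'
#' Inverts the piecewise-linear map; on flat (0 cM/bp) stretches the
#' leftmost physical position is returned.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome name.
#' @param cM numeric vector of genetic positions.
#' @return physical positions in bp.
#' @export
bpAt <- function(map, chrom, cM) {
  p <- .mapPoints(map, chrom)
  stats::approx(p$cM, p$bp, xout = cM, rule = 2, ties = "min")$y
}

#' Total genetic length of a chromosome
#' @inheritParams cmAt
#' @return total cM.
#' @export
totalCM <- function(map, chrom) {
  p <- .mapPoints(map, chrom)
  p$cM[nrow(p)]
}

#' Physical chromosome lengths of a map
#' @param map a \linkS4class{GeneticMap}.
#' @return named numeric vector (bp).
#' @export
chromLengths <- function(map) map@chromLengths
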