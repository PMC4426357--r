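#' Percent embryonic hatching
#'
#' The number of hatched larvae divided by the total number of eggs laid,
#' as a percentage.
#'
#' @param hatched,eggsLaid nonnegative counts (vectorised).
#' @return numeric percentage(s) in \code{[0, 100]}.
#' @examples
#' percentHatching(1, 1906)  # ~0.052
#' @export
percentHatching <- function(hatched, eggsLaid) {
  if (any(eggsLaid == 0)) stop("eggs laid must be > 0")
  if (any(hatched > eggsLaid)) stop("hatched exceeds eggs laid")
  if (any(hatched < 0 | eggsLaid < 0)) stop("counts must be nonnegative")
  100 * hatched / eggsLaid
}

#' Read a brood-count table
#'
#' TSV with columns \code{genotype}, \code{temperature}, \code{eggs_laid},
#' \code{hatched} and \code{replicate} -- one row per single hermaphrodite
#' brood.
#'
#' @param path TSV path.
#' @return data.frame of brood records.
#' @export
readBroodTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "temperature", "eggs_laid", "hatched", "replicate")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("brood TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$hatched > tab$eggs_laid | tab$hatched < 0))
    stop("invalid brood counts (hatched must be in [0, eggs_laid])")
  tab
}

#' Summarise brood viability per genotype and temperature
#'
#' Per-brood hatching percentages are first averaged within each replicate
#' experiment; the reported mean and SD are then taken across the replicate
#' means (the convention of error bars representing the SD of the average
#' percentage of replicate experiments). \code{acrossBroods = TRUE}
#' switches to mean and SD across all individual broods instead.
#'
#' @param records brood data.frame (see [readBroodTable()]).
#' @param acrossBroods logical; alternative aggregation (default FALSE).
#' @return data.frame with columns \code{genotype}, \code{temperature},
#'   \code{meanPercent}, \code{sdPercent}, \code{nBroods},
#'   \code{totalEggs}.
#' @export
summarizeBroods <- function(records, acrossBroods = FALSE) {
  if (nrow(records) == 0L) stop("no brood records")
  records$pct <- percentHatching(records$hatched, records$eggs_laid)
  groups <- split(records, list(records$genotype, records$temperature),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (acrossBroods) {
      m <- mean(g$pct); s <- stats::sd(g$pct)
    } else {
      repMeans <- tapply(g$pct, g$replicate, mean)
      m <- mean(repMeans)
      s <- if (length(repMeans) > 1L) stats::sd(repMeans) else 0
    }
    data.frame(genotype = g$genotype[1], temperature = g$temperature[1],
               meanPercent = m, sdPercent = s, nBroods = nrow(g),
               totalEggs = sum(g$eggs_laid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$genotype, out$temperature), , drop = FALSE]
}

#' Compare embryonic viability of two groups
#'
#' Two tests are reported: a Welch two-sample t test on the per-brood
#' hatching percentages (primary; the brood is the experimental unit) and a
#' two-sided Fisher exact test on the pooled hatched/dead counts
#' (secondary). When both groups have zero variance, the primary p-value is
#' 1 for equal means and 0 otherwise.
#'
#' @param groupA,groupB brood data.frames with columns \code{eggs_laid}
#'   and \code{hatched}; at least two broods each for the primary test.
#' @return list with \code{statistic}, \code{pValue} (primary Welch),
#'   \code{pValueExact} (secondary) and the group means.
#' @export
compareViability <- function(groupA, groupB) {
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("need at least two broods per group")
  pa <- percentHatching(groupA$hatched, groupA$eggs_laid)
  pb <- percentHatching(groupB$hatched, groupB$eggs_laid)
  if (stats::var(pa) == 0 && stats::var(pb) == 0) {
    stat <- NA_real_
    p <- if (isTRUE(all.equal(mean(pa), mean(pb)))) 1 else 0
  } else {
    tt <- stats::t.test(pa, pb)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  counts <- matrix(c(sum(groupA$hatched),
                     sum(groupA$eggs_laid) - sum(groupA$hatched),
                     sum(groupB$hatched),
                     sum(groupB$eggs_laid) - sum(groupB$hatched)),
                   nrow = 2)
  pExact <- stats::fisher.test(counts)$p.value
  list(statistic = stat, pValue = p, pValueExact = pExact,
       meanA = mean(pa), meanB = mean(pb))
}

#' Complementation verdict from trans-heterozygote viability
#'
#' Scores the hatching percentage of trans-heterozygote progeny at the
#' restrictive temperature: below \code{failMax} the two mutations fail to
#' complement (same gene), above \code{compMin} they complement (different
#' genes), in between the test is ambiguous. The defaults (10 and 50)
#' separate the observed failing crosses (0--4.9\% hatching) from the
#' complementing ones (78.6--98\%). A sterility annotation of surviving
#' progeny is carried alongside the verdict, not folded into it.
#'
#' @param percentHatching viability percentage in \code{[0, 100]}.
#' @param failMax,compMin verdict thresholds; \code{failMax < compMin}
#'   required.
#' @param sterilityNote optional annotation string.
#' @return list with \code{verdict} (\code{fails}/\code{complements}/
#'   \code{ambiguous}) and \code{note}.
#' @export
complementationVerdict <- function(percentHatching, failMax = 10,
                                   compMin = 50, sterilityNote = NULL) {
  if (failMax >= compMin) stop("thresholds inverted: failMax must be < compMin")
  if (percentHatching < 0 || percentHatching > 100)
    stop("viability must be in [0, 100]")
  verdict <- if (percentHatching < failMax) "fails"
    else if (percentHatching > compMin) "complements"
    else "ambiguous"
  list(verdict = verdict,
       note = if (is.null(sterilityNote)) NA_character_ else sterilityNote)
}

#' Mendelian genotype fractions of standard crosses
#'
#' Exact expected genotype fractions for a recessive mutation:
#' a selfed heterozygote yields 1/4 homozygous mutant (the ~25\% of F2
#' animals showing the phenotype after an edit or outcross), a
#' heterozygote x homozygote cross 1/2, a heterozygote x wild-type cross
#' none.
#'
#' @param scheme one of \code{"het_self"}, \code{"het_x_hom"},
#'   \code{"het_x_wt"}.
#' @return named numeric: \code{homMutant}, \code{het}, \code{homWt};
#'   sums to 1.
#' @export
mendelianFraction <- function(scheme = c("het_self", "het_x_hom",
                                         "het_x_wt")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         het_self = c(homMutant = 0.25, het = 0.5, homWt = 0.25),
         het_x_hom = c(homMutant = 0.5, het = 0.5, homWt = 0),
         het_x_wt = c(homMutant = 0, het = 0.5, homWt = 0.5))
}
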