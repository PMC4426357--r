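#' Built-in restriction enzyme recognition table
#'
#' IUPAC-degenerate recognition sites; extensible by passing a modified
#' table to the scanning functions. EaeI (YGGCCR) is its own reverse
#' complement.
#'
#' @return named character vector of recognition sequences.
#' @export
restrictionEnzymes <- function() {
  c(EaeI = "YGGCCR", EcoRI = "GAATTC", HindIII = "AAGCTT",
    BamHI = "GGATCC", XhoI = "CTCGAG", DraI = "TTTAAA", AvrII = "CCTAGG")
}

.checkGuide <- function(guide) {
  guide <- toupper(guide)
  if (grepl("[^ACGT]", guide))
    stop("guide contains ambiguous bases: ", guide)
  if (nchar(guide) < 17L || nchar(guide) > 20L)
    stop("guide must be 17-20 nt, got ", nchar(guide))
  guide
}

#' Locate a CRISPR protospacer with its NGG PAM
#'
#' Searches both strands of the target for exact matches of the guide
#' immediately 5' of an NGG PAM (SpCas9). All hits are returned;
#' coordinates are 1-based on the plus strand of the target. The blunt cut
#' coordinate (between-base, 3 bp 5' of the PAM) is precomputed per site.
#'
#' @param guide 17-20 nt guide sequence, A/C/G/T only (ambiguous bases are
#'   an error).
#' @param target target sequence (character or DNAString).
#' @return list of \linkS4class{GuideSite} (empty when no valid site).
#' @examples
#' locateProtospacer("ATGTCTCTCAATGTTTCGG",
#'                   "AAATGTCTCTCAATGTTTCGGCGGTT")
#' @export
locateProtospacer <- function(guide, target) {
  guide <- .checkGuide(guide)
  target <- toupper(as.character(target))
  len <- nchar(target)
  glen <- nchar(guide)
  sites <- list()
  scan <- function(seqStr, strand) {
    hits <- Biostrings::matchPattern(guide, Biostrings::DNAString(seqStr))
    for (i in seq_along(hits)) {
      e <- end(hits)[i]
      if (e + 3L > nchar(seqStr)) next
      pam <- substr(seqStr, e + 1L, e + 3L)
      if (substr(pam, 2L, 3L) != "GG") next
      s <- start(hits)[i]
      if (strand == "+") {
        sites[[length(sites) + 1L]] <<- new(
          "GuideSite", protospacer = guide, strand = "+", pam = pam,
          start = s, end = e, cutAfter = e - 3L)
      } else {
        sites[[length(sites) + 1L]] <<- new(
          "GuideSite", protospacer = guide, strand = "-", pam = pam,
          start = len - e + 1L, end = len - s + 1L,
          cutAfter = len - e + 3L)
      }
    }
  }
  scan(target, "+")
  scan(.revcomp(target), "-")
  sites
}

#' Blunt cut coordinate of a guide site
#'
#' SpCas9 cuts bluntly between the 3rd and 4th base 5' of the PAM. The
#' returned between-base coordinate i means the cut falls between plus
#' strand positions i and i + 1; it always lies inside the protospacer
#' span.
#'
#' @param site a \linkS4class{GuideSite}.
#' @return numeric between-base coordinate.
#' @export
cutSite <- function(site) site@cutAfter

#' Compare a repair oligo against its partner or reference
#'
#' Lists the differing positions (the planted edits) between an edited
#' oligo and either a second oligo of the same length or a reference
#' sequence containing the oligo's footprint. Homology arms are the exact
#' match stretches outside the edits: the 5' arm is the bases before the
#' first edit, the 3' arm the bases after the last.
#'
#' @param oligo the edited oligo sequence.
#' @param reference same-length sequence to compare against, or a longer
#'   reference in which the oligo is located (up to 10 mismatches).
#' @return list with \code{edits} (data.frame position/from/to, positions
#'   in oligo coordinates, \code{from} the reference base), \code{arm5},
#'   \code{arm3} (NA when the sequences are identical).
#' @details More than 10 differences is an error (likely misalignment).
#' @export
verifyRepairOligo <- function(oligo, reference) {
  oligo <- toupper(as.character(oligo))
  reference <- toupper(as.character(reference))
  if (nchar(oligo) == nchar(reference)) {
    window <- reference
  } else {
    if (nchar(reference) < nchar(oligo))
      stop("reference shorter than oligo")
    hits <- Biostrings::matchPattern(oligo, Biostrings::DNAString(reference),
                                     max.mismatch = 10L)
    if (length(hits) == 0L)
      stop("oligo not locatable in reference within 10 mismatches")
    mm <- vapply(seq_along(hits), function(i)
      sum(strsplit(as.character(hits[[i]]), "")[[1]] !=
            strsplit(oligo, "")[[1]]), integer(1))
    window <- as.character(hits[[which.min(mm)]])
  }
  a <- strsplit(oligo, "")[[1]]
  b <- strsplit(window, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) > 10L)
    stop(length(diffs), " differences found; sequences likely misaligned")
  edits <- data.frame(position = diffs, from = b[diffs], to = a[diffs])
  if (length(diffs) == 0L)
    return(list(edits = edits, arm5 = NA_integer_, arm3 = NA_integer_))
  list(edits = edits, arm5 = min(diffs) - 1L,
       arm3 = length(a) - max(diffs))
}

#' Scan a sequence for restriction sites
#'
#' Matches the enzyme's IUPAC-degenerate recognition sequence on the given
#' strand of the input.
#'
#' @param sequence character or DNAString (may be empty).
#' @param enzyme enzyme name present in \code{enzymes}.
#' @param enzymes recognition table, default [restrictionEnzymes()].
#' @return integer vector of 1-based match start positions.
#' @examples
#' scanRestrictionSites("TTCGGCCGTT", "EaeI")  # CGGCCG matches YGGCCR
#' @export
scanRestrictionSites <- function(sequence, enzyme,
                                 enzymes = restrictionEnzymes()) {
  if (!enzyme %in% names(enzymes))
    stop("unknown enzyme: ", enzyme)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) return(integer())
  hits <- Biostrings::matchPattern(enzymes[[enzyme]],
                                   Biostrings::DNAString(sequence),
                                   fixed = FALSE)
  start(hits)
}

.regionBounds <- function(genome, chrom, pos) {
  hit <- which(as.character(seqnames(genome@regions)) == chrom &
               start(genome@regions) <= pos & end(genome@regions) >= pos)
  if (length(hit) == 0L)
    stop("no reference sequence stored around ", chrom, ":", pos)
  c(start(genome@regions)[hit[1]], end(genome@regions)[hit[1]])
}

#' Propose synonymous PAM-destroying edits
#'
#' Enumerates single-base changes at the two G positions of the NGG PAM
#' that are synonymous in the supplied gene's reading frame -- the standard
#' trick for protecting an HDR repair template from recutting. Each option
#' is annotated with the restriction sites it creates or destroys in a
#' 17-bp window (a created site doubles as a genotyping diagnostic, so
#' site-creating options are ranked first). Any change at a PAM G position
#' destroys the NGG match.
#'
#' @param site a \linkS4class{GuideSite} located on the plus-strand
#'   sequence of the gene's chromosome.
#' @param geneModel the \linkS4class{GeneModel} whose frame applies; the
#'   PAM must overlap its CDS (error otherwise).
#' @param genome a \linkS4class{RegionalGenome}.
#' @param enzymes recognition table, default [restrictionEnzymes()].
#' @param offset plus-strand genomic position of base 1 of the sequence the
#'   site was located in (default 1, i.e. the site coordinates are already
#'   genomic).
#' @return data.frame of options (position, ref, alt, createsSites,
#'   destroysSites), site-creating first; empty with a warning when no
#'   synonymous option exists.
#' @export
proposePamSilencingEdit <- function(site, geneModel, genome,
                                    enzymes = restrictionEnzymes(),
                                    offset = 1) {
  ggPos <- if (site@strand == "+")
    site@end + c(2L, 3L) else site@start - c(3L, 2L)
  ggPos <- ggPos + offset - 1
  inCds <- vapply(ggPos, function(p)
    any(p >= start(geneModel@cds) & p <= end(geneModel@cds)), logical(1))
  if (!any(inCds))
    stop("PAM does not overlap the CDS of ", geneModel@geneId)
  chrom <- geneModel@chrom
  opts <- list()
  for (p in ggPos[inCds]) {
    ref <- getRefSequence(genome, chrom, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- VariantCalls(chrom, p, ref, alt, refDepth = 1L, altDepth = 1L)
      ann <- annotateEffect(v, list(geneModel), genome)
      if (!identical(ann$effect, "synonymous")) next
      bounds <- .regionBounds(genome, chrom, p)
      ws <- max(bounds[1], p - 8); we <- min(bounds[2], p + 8)
      before <- getRefSequence(genome, chrom, ws, we)
      after <- before
      substr(after, p - ws + 1, p - ws + 1) <- alt
      created <- destroyed <- character()
      for (enz in names(enzymes)) {
        nB <- length(scanRestrictionSites(before, enz, enzymes))
        nA <- length(scanRestrictionSites(after, enz, enzymes))
        if (nA > nB) created <- c(created, enz)
        if (nA < nB) destroyed <- c(destroyed, enz)
      }
      opts[[length(opts) + 1L]] <- data.frame(
        position = p, ref = ref, alt = alt,
        createsSites = paste(created, collapse = ","),
        destroysSites = paste(destroyed, collapse = ","))
    }
  }
  if (length(opts) == 0L) {
    warning("no synonymous PAM-destroying edit available")
    return(data.frame(position = numeric(), ref = character(),
                      alt = character(), createsSites = character(),
                      destroysSites = character()))
  }
  out <- do.call(rbind, opts)
  out[order(out$createsSites == "", out$position), , drop = FALSE]
}
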