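#' Read a flat key=value pipeline configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Numeric values are parsed as numbers; \code{chrom_lengths} accepts
#' \code{name:length} pairs separated by commas. Keys must be valid
#' generator settings (see [defaultCrossConfig()]); an unknown key is an
#' error naming it.
#'
#' @param path config file path.
#' @return named list suitable for [buildReferenceModel()].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (grepl(":", val, fixed = TRUE)) {
      pairs <- strsplit(strsplit(val, ",")[[1]], ":")
      v <- vapply(pairs, function(p) as.numeric(trimws(p[2])), numeric(1))
      names(v) <- vapply(pairs, function(p) trimws(p[1]), character(1))
      cfg[[key]] <- v
    } else {
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (is.na(num)) val else num
    }
  }
  .mergeConfig(cfg)  # validates keys
  cfg
}

#' Run the cross/sequencing simulation stage
#'
#' Builds the reference model, simulates the pooled mutant F2 sample and
#' its sequencing, and writes every artifact downstream stages need:
#' \code{pool.vcf}, \code{truth.tsv}, \code{hawaiian.tsv},
#' \code{parental.tsv}, \code{genes.gff3}, \code{genome.fa} and a
#' \code{provenance.json} recording the full configuration and seed.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config list (or path to a key=value file) of generator settings.
#' @param seed integer master seed.
#' @param outdir output directory; refusing to overwrite an existing one
#'   unless \code{force = TRUE}.
#' @param nF2,nPooled,meanDepth,errorRate cross and sequencing settings,
#'   see [simulateMutantPool()] and [simulatePoolCalls()].
#' @param force overwrite an existing outdir.
#' @return invisibly, a list with the model, pool, calls and file paths.
#' @export
runSimulate <- function(config = list(), seed = 1, outdir,
                        nF2 = 200, nPooled = NULL, meanDepth = 22,
                        errorRate = 0.001, force = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (dir.exists(outdir) && !force)
    stop("output directory exists (use force = TRUE): ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- buildReferenceModel(config, seed = seed)
  pool <- simulateMutantPool(model, nF2 = nF2, nPooled = nPooled,
                             seed = seed)
  calls <- simulatePoolCalls(pool, model, meanDepth = meanDepth,
                             errorRate = errorRate, seed = seed)
  files <- list(
    vcf = file.path(outdir, "pool.vcf"),
    truth = file.path(outdir, "truth.tsv"),
    hawaiian = file.path(outdir, "hawaiian.tsv"),
    parental = file.path(outdir, "parental.tsv"),
    genes = file.path(outdir, "genes.gff3"),
    genome = file.path(outdir, "genome.fa"),
    provenance = file.path(outdir, "provenance.json"))
  writeVariantVcf(calls, files$vcf,
                  contigLengths = model@map@chromLengths)
  writePoolTruth(pool, files$truth)
  writeSnpCatalog(model@hawaiian, files$hawaiian)
  writeSnpCatalog(model@parental, files$parental)
  writeGeneModelsGff(model@genes, files$genes)
  writeGenomeFasta(model@genome, files$genome)
  cfgOut <- model@config
  cfgOut$chrom_lengths <- as.list(cfgOut$chrom_lengths)
  jsonlite::write_json(
    list(config = cfgOut, seed = seed, n_f2 = nF2,
         n_pooled = pool@nLines, mean_depth = meanDepth,
         error_rate = errorRate,
         causal = list(chrom = model@causalChrom, pos = model@causalPos),
         package = as.character(utils::packageVersion("hawmap"))),
    files$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, pool = pool, calls = calls, files = files))
}

#' Run the mapping stage: classify, map, filter, report
#'
#' Reads pooled variant calls and the background catalogs, classifies the
#' calls, detects the mapping interval from Hawaiian SNP depletion, filters
#' candidate lesions and writes the interval BED, candidate TSV, per
#' chromosome density TSV and a mapping summary.
#'
#' @param vcf path to the pooled calls (VCF or TSV).
#' @param hawaiian,parental catalog paths (parental optional).
#' @param outdir output directory (created if needed).
#' @param chromLengths named vector; defaults to the per-chromosome maxima
#'   of the Hawaiian catalog.
#' @param map optional \linkS4class{GeneticMap} for interval selection.
#' @param genes,genome optional GFF3 and FASTA paths enabling effect
#'   annotation; without them candidates are the novel homozygous calls in
#'   the interval, with no nonsynonymous filter.
#' @param threshold homozygosity threshold (default 0.85).
#' @param minAltReads Hawaiian presence threshold (default 2).
#' @param binSize density-profile bin size (default 100 kb).
#' @return invisibly, a list with calls, intervals, candidates, summary
#'   and file paths.
#' @export
runMap <- function(vcf, hawaiian, parental = NULL, outdir,
                   chromLengths = NULL, map = NULL, genes = NULL,
                   genome = NULL, threshold = 0.85, minAltReads = 2,
                   binSize = 1e5) {
  hawCat <- readSnpCatalog(hawaiian, "hawaiian")
  parCat <- if (!is.null(parental)) readSnpCatalog(parental, "parental")
  calls <- readVariantCalls(vcf)
  calls <- classifyVariants(calls, hawCat, parCat)
  if (is.null(chromLengths)) {
    chromLengths <- tapply(start(hawCat),
                           as.character(seqnames(hawCat)), max)
    chromLengths <- stats::setNames(as.numeric(chromLengths),
                                    names(chromLengths))
  }
  intervals <- detectInterval(calls, hawCat, chromLengths, map = map,
                              minAltReads = minAltReads)
  sel <- selectedInterval(intervals)
  if (!is.null(genes) && !is.null(genome)) {
    candidates <- filterCandidates(calls, sel, readGeneModels(genes),
                                   readGenome(genome),
                                   threshold = threshold)
  } else {
    message("no gene models/genome supplied; skipping effect annotation")
    keep <- as.character(seqnames(calls)) == as.character(seqnames(sel)) &
      start(calls) >= start(sel) & start(calls) <= end(sel) &
      mcols(calls)$label == "novel"
    candidates <- calls[keep]
    tot <- mcols(candidates)$refDepth + mcols(candidates)$altDepth
    candidates <- candidates[tot > 0L]
    candidates <- candidates[isHomozygous(candidates, threshold)]
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list(bed = file.path(outdir, "intervals.bed"),
                candidates = file.path(outdir, "candidates.tsv"),
                density = file.path(outdir, "density.tsv"),
                summary = file.path(outdir, "summary.tsv"))
  writeIntervalBed(intervals, files$bed)
  candTab <- data.frame(chrom = as.character(seqnames(candidates)),
                        pos = start(candidates),
                        ref = mcols(candidates)$ref,
                        alt = mcols(candidates)$alt,
                        altFraction = round(altFraction(candidates), 4))
  for (col in c("geneId", "effect", "aaChange", "emsTransition"))
    if (!is.null(mcols(candidates)[[col]]))
      candTab[[col]] <- mcols(candidates)[[col]]
  utils::write.table(candTab, files$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dens <- do.call(rbind, lapply(names(chromLengths), function(chrom)
    densityProfile(calls, hawCat, chrom, binSize = binSize,
                   chromLength = chromLengths[[chrom]],
                   minAltReads = minAltReads)))
  utils::write.table(dens, files$density, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- intervalReport(sel, candidates)
  utils::write.table(summary, files$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("selected interval ", summary$chrom, ":", summary$start, "-",
          summary$end, " (", round(summary$widthMb, 2), " Mb, ",
          summary$nCandidates, " candidate(s); threshold=", threshold,
          ", minAltReads=", minAltReads, ")")
  invisible(list(calls = calls, intervals = intervals,
                 candidates = candidates, summary = summary,
                 files = files))
}

#' Run the brood-statistics stage
#'
#' @param broods path to a brood TSV (see [readBroodTable()]).
#' @param out optional output path for the summary TSV.
#' @return the summary data.frame (see [summarizeBroods()]).
#' @export
runBroods <- function(broods, out = NULL) {
  tab <- readBroodTable(broods)
  summary <- summarizeBroods(tab)
  if (!is.null(out))
    utils::write.table(summary, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  summary
}

#' Run the CRISPR oligo verification stage
#'
#' Reads a FASTA containing a guide plus two repair oligos (edited and
#' partner/reference), reports the edits between the oligos with homology
#' arm lengths, locates the guide (with NGG PAM) in each, and scans each
#' for restriction sites of every enzyme in the table.
#'
#' @param fasta FASTA path; the guide sequence must be named \code{guide},
#'   the remaining two records are the oligos.
#' @param out optional output path for the report TSV.
#' @param enzymes recognition table, default [restrictionEnzymes()].
#' @return list with \code{comparison} (see [verifyRepairOligo()]),
#'   \code{guideSites} (per-oligo count of valid guide+NGG sites) and
#'   \code{enzymeSites} (per-oligo, per-enzyme site counts).
#' @export
runCrispr <- function(fasta, out = NULL, enzymes = restrictionEnzymes()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!"guide" %in% names(seqs))
    stop("FASTA must contain a sequence named 'guide'")
  guide <- as.character(seqs[["guide"]])
  oligos <- seqs[setdiff(names(seqs), "guide")]
  if (length(oligos) != 2L)
    stop("expected exactly two oligo sequences besides the guide")
  cmp <- verifyRepairOligo(as.character(oligos[[1]]),
                           as.character(oligos[[2]]))
  guideSites <- vapply(seq_along(oligos), function(i)
    length(locateProtospacer(guide, as.character(oligos[[i]]))), integer(1))
  names(guideSites) <- names(oligos)
  enzymeSites <- do.call(rbind, lapply(names(oligos), function(nm) {
    counts <- vapply(names(enzymes), function(enz)
      length(scanRestrictionSites(as.character(oligos[[nm]]), enz,
                                  enzymes)), integer(1))
    data.frame(oligo = nm, enzyme = names(enzymes), sites = counts,
               row.names = NULL)
  }))
  if (!is.null(out)) {
    rpt <- data.frame(
      item = c("edits", "arm5", "arm3",
               paste0("guide_sites_", names(guideSites)),
               paste0(enzymeSites$enzyme, "_sites_", enzymeSites$oligo)),
      value = c(nrow(cmp$edits), cmp$arm5, cmp$arm3, guideSites,
                enzymeSites$sites))
    utils::write.table(rpt, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(comparison = cmp, guideSites = guideSites,
       enzymeSites = enzymeSites)
}
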