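#' Read pooled-sequencing variant calls
#'
#' Reads a VCF 4.x file (allelic depths taken from the \code{AD} FORMAT
#' field of the first sample) or a tab-separated fallback with header
#' \code{chrom pos ref alt ref_depth alt_depth}. Multiallelic VCF records
#' are split into one biallelic call per alternate allele; the depths of the
#' other alternates are ignored with a warning. All calls are returned with
#' \code{label = "unclassified"}; see [classifyVariants()].
#'
#' @param path path to a VCF or TSV file.
#' @return a \linkS4class{VariantCalls} object, one element per biallelic
#'   record, in file order.
#' @details Input is accepted unsorted but a message flags it, since
#'   downstream interval detection sorts internally. A VCF record without
#'   allelic-depth information is an error naming the record.
#' @seealso [writeVariantVcf()], [classifyVariants()]
#' @export
readVariantCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (.isVcf(path)) .readCallsVcf(path) else .readCallsTsv(path)
}

.isVcf <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) && grepl("^##fileformat=VCF", first)
}

.readCallsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (nrow(vcf) == 0L)
    return(VariantCalls(character(), numeric(), character(), character(),
                        integer(), integer()))
  nAltPer <- lengths(VariantAnnotation::alt(vcf))
  if (any(nAltPer > 1L))
    warning(sum(nAltPer > 1L), " multiallelic record(s) split into ",
            "biallelic calls; depths of other alternate alleles ignored")
  vcf <- VariantAnnotation::expand(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad))
    stop("VCF carries no AD (allelic depth) FORMAT field: ", path)
  rd <- as.integer(ad[, 1L, 1L])
  adp <- as.integer(ad[, 1L, 2L])
  rr <- SummarizedExperiment::rowRanges(vcf)
  bad <- which(is.na(rd) | is.na(adp))
  if (length(bad))
    stop("missing allelic depth at record ",
         as.character(seqnames(rr))[bad[1]], ":", start(rr)[bad[1]])
  chrom <- as.character(seqnames(rr))
  if (!identical(order(chrom, start(rr)), seq_along(chrom)))
    message("input VCF is not coordinate-sorted; accepted as-is")
  VariantCalls(chrom, start(rr),
               as.character(VariantAnnotation::ref(vcf)),
               as.character(VariantAnnotation::alt(vcf)),
               refDepth = rd, altDepth = adp)
}

.readCallsTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("variant TSV lacks column(s): ", paste(miss, collapse = ", "))
  VariantCalls(tab$chrom, tab$pos, tab$ref, tab$alt,
               refDepth = tab$ref_depth, altDepth = tab$alt_depth)
}

#' Write variant calls as a minimal VCF
#'
#' Emits VCF 4.2 with a single sample (\code{POOL}) carrying the \code{AD}
#' FORMAT field. Classification labels other than \code{unclassified} are
#' re-emitted as a \code{CLASS} INFO tag. Output is deterministic
#' (byte-identical for identical input).
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param path output path.
#' @param contigLengths optional named vector for \code{##contig} headers.
#' @return \code{path}, invisibly.
#' @export
writeVariantVcf <- function(calls, path, contigLengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hawmap",
           paste0("##INFO=<ID=CLASS,Number=1,Type=String,",
                  "Description=\"Variant origin classification\">"),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"))
  if (!is.null(contigLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigLengths), as.integer(contigLengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "POOL", sep = "\t"))
  mc <- mcols(calls)
  info <- ifelse(mc$label == "unclassified", ".",
                 paste0("CLASS=", mc$label))
  body <- if (length(calls)) {
    paste(as.character(seqnames(calls)), start(calls), ".", mc$ref, mc$alt,
          ".", ".", info, "AD", paste0(mc$refDepth, ",", mc$altDepth),
          sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a strain-background SNP catalog
#'
#' Accepts a VCF or a 4-column TSV with header \code{chrom pos ref alt}.
#' Duplicate entries are removed; the resulting size is reported.
#'
#' @param path input path.
#' @param source \code{"hawaiian"} or \code{"parental"}.
#' @return a \linkS4class{SnpCatalog}.
#' @export
readSnpCatalog <- function(path, source = c("hawaiian", "parental")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (.isVcf(path)) {
    vcf <- VariantAnnotation::expand(
      VariantAnnotation::readVcf(path, genome = "unknown"))
    rr <- SummarizedExperiment::rowRanges(vcf)
    tab <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      ref = as.character(VariantAnnotation::ref(vcf)),
                      alt = as.character(VariantAnnotation::alt(vcf)))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("chrom", "pos", "ref", "alt"), colnames(tab))
    if (length(miss))
      stop("catalog TSV lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warning("empty catalog read from ", path)
    return(SnpCatalog(character(), numeric(), character(), character(),
                      source = source))
  }
  if (any(tab$pos < 1)) stop("catalog position < 1 in ", path)
  cat <- SnpCatalog(tab$chrom, tab$pos, tab$ref, tab$alt, source = source)
  message("read ", length(cat), " unique ", source, " catalog entries")
  cat
}

#' Write a SNP catalog as TSV
#' @param catalog a \linkS4class{SnpCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSnpCatalog <- function(catalog, path) {
  tab <- data.frame(chrom = as.character(seqnames(catalog)),
                    pos = start(catalog), ref = mcols(catalog)$ref,
                    alt = mcols(catalog)$alt)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mapping intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED uses 0-based half-open,
#' so a written line covers \code{start - 1} to \code{end}. Extra columns
#' (name, selected flag) follow the three BED fields.
#'
#' @param intervals a \linkS4class{GRanges} (as from [detectInterval()]) or
#'   a data.frame with columns chrom/start/end.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntervalBed <- function(intervals, path) {
  if (is(intervals, "GRanges")) {
    tab <- data.frame(chrom = as.character(seqnames(intervals)),
                      start = start(intervals), end = end(intervals))
    tab$selected <- if (!is.null(mcols(intervals)$selected))
      mcols(intervals)$selected else FALSE
  } else {
    tab <- as.data.frame(intervals)
    if (is.null(tab$selected)) tab$selected <- FALSE
  }
  if (any(tab$end < tab$start)) stop("interval end < start")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", tab$chrom,
                   as.integer(tab$start) - 1L, as.integer(tab$end),
                   sprintf("%s:%d-%d", tab$chrom, as.integer(tab$start),
                           as.integer(tab$end)),
                   ifelse(tab$selected, "selected", "."))
  writeLines(lines, path)
  invisible(path)
}

#' Read intervals written by [writeIntervalBed()]
#' @param path BED path.
#' @return a \linkS4class{GRanges} with 1-based inclusive coordinates and a
#'   \code{selected} metadata column.
#' @export
readIntervalBed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
  mcols(gr)$selected <- if (ncol(tab) >= 5) tab[[5]] == "selected" else FALSE
  gr
}

#' Read gene models from GFF3
#'
#' Builds one \linkS4class{GeneModel} per CDS parent feature. CDS segments
#' are ordered 5' to 3' in translation order (reverse genomic order on the
#' minus strand). Models whose total CDS length is not a multiple of 3 are
#' flagged unusable with a warning and skipped by the effect annotator.
#'
#' @param path GFF3 path.
#' @return named list of \linkS4class{GeneModel} objects.
#' @seealso [annotateEffect()], [writeGeneModelsGff()]
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  parent <- vapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    if (length(p)) p[[1]] else if (!is.null(cds$ID)) cds$ID[i] else NA_character_
  }, character(1))
  if (anyNA(parent)) stop("CDS feature without Parent or ID in ", path)
  plen <- rep(NA_integer_, length(cds))
  if (!is.null(gff$protein_length)) {
    anno <- gff[!is.na(gff$protein_length)]
    key <- if (!is.null(anno$ID)) anno$ID else character()
    plen <- as.integer(anno$protein_length[match(parent, key)])
  }
  models <- lapply(split(seq_along(cds), parent), function(idx) {
    sub <- cds[idx]
    strand <- as.character(strand(sub))[1]
    ord <- order(start(sub), decreasing = strand == "-")
    sub <- sub[ord]
    total <- sum(width(sub))
    usable <- total %% 3L == 0L
    if (!usable)
      warning("CDS length of ", parent[idx[1]], " not divisible by 3; ",
              "model flagged unusable for annotation")
    new("GeneModel", geneId = parent[idx[1]],
        chrom = as.character(seqnames(sub))[1], strand = strand,
        cds = IRanges(start(sub), end(sub)),
        proteinLength = if (usable) plen[idx[1]] else NA_integer_,
        usable = usable)
  })
  models[order(names(models))]
}

#' Write gene models as GFF3
#' @param genes list of \linkS4class{GeneModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelsGff <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    span <- range(c(start(g@cds), end(g@cds)))
    gene <- GRanges(g@chrom, IRanges(span[1], span[2]), strand = g@strand)
    gene$type <- "gene"; gene$ID <- g@geneId; gene$Parent <- NA_character_
    gene$protein_length <- g@proteinLength
    cds <- GRanges(g@chrom, sort(IRanges(start(g@cds), end(g@cds))),
                   strand = g@strand)
    cds$type <- "CDS"; cds$ID <- NA_character_; cds$Parent <- g@geneId
    cds$protein_length <- NA_integer_
    c(gene, cds)
  })
  gr <- do.call(c, unname(rows))
  gr$type <- factor(gr$type, levels = c("gene", "CDS"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read reference sequence from FASTA
#'
#' Sequence names of the form \code{chrom:start-end} are interpreted as
#' sparse regions (used for simulated genomes that only materialise gene
#' loci); bare names are whole chromosomes starting at position 1.
#'
#' @param path FASTA path.
#' @return a \linkS4class{RegionalGenome}.
#' @export
readGenome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(nm, regexec("^(.+):(\\d+)-(\\d+)$", nm))
  chrom <- vapply(seq_along(nm), function(i)
    if (length(m[[i]])) m[[i]][2] else nm[i], character(1))
  starts <- vapply(seq_along(nm), function(i)
    if (length(m[[i]])) as.numeric(m[[i]][3]) else 1, numeric(1))
  regions <- GRanges(chrom, IRanges(starts,
                                    width = Biostrings::width(seqs)))
  new("RegionalGenome", regions = regions, seqs = seqs)
}

#' Write a RegionalGenome as FASTA
#' @param genome a \linkS4class{RegionalGenome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  seqs <- genome@seqs
  names(seqs) <- sprintf("%s:%d-%d", as.character(seqnames(genome@regions)),
                         start(genome@regions), end(genome@regions))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Extract reference sequence for a span
#'
#' @param genome a \linkS4class{RegionalGenome}.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive span; must fall inside one stored
#'   region, otherwise an error is raised.
#' @return character string of the sequence.
#' @export
getRefSequence <- function(genome, chrom, start, end = start) {
  hit <- which(as.character(seqnames(genome@regions)) == chrom &
               GenomicRanges::start(genome@regions) <= start &
               GenomicRanges::end(genome@regions) >= end)
  if (length(hit) == 0L)
    stop("no reference sequence stored for ", chrom, ":", start, "-", end)
  reg <- genome@regions[hit[1]]
  as.character(Biostrings::subseq(genome@seqs[[hit[1]]],
                                  start - GenomicRanges::start(reg) + 1L,
                                  end - GenomicRanges::start(reg) + 1L))
}
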