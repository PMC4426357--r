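suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
  library(GenomicRanges)
  library(Biostrings)
})

# ---- cached simulation fixtures (built lazily, reused across files) -------

.fixtures <- new.env()

# full default reference model (the study conditions)
defaultModel <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- suppressWarnings(buildReferenceModel(seed = 42))
  .fixtures$default
}

# single-chromosome model: 17 Mb / 50 cM, causal mid-chromosome, dense
# catalog; used for oracle comparisons and truth-tagged classification
lineModel <- function() {
  if (is.null(.fixtures$line))
    .fixtures$line <- suppressWarnings(buildReferenceModel(
      list(chrom_lengths = c(chrC = 17e6), causal_chrom = "chrC",
           causal_pos = 8.5e6, gene_count = 5, n_induced = 20,
           n_parental = 30),
      seed = 7))
  .fixtures$line
}

simulateClassified <- function(model, seed, nF2 = 200, nPooled = NULL,
                               meanDepth = 22, errorRate = 0.001) {
  pool <- simulateMutantPool(model, nF2 = nF2, nPooled = nPooled,
                             seed = seed)
  calls <- simulatePoolCalls(pool, model, meanDepth = meanDepth,
                             errorRate = errorRate, seed = seed)
  calls <- suppressMessages(
    classifyVariants(calls, model@hawaiian, model@parental))
  list(pool = pool, calls = calls)
}

# ---- hand-built annotation fixtures ---------------------------------------

# Three tiny genes with fully hand-designed sequences:
#  tg1 chrT  (+, single exon) codons ATG GGA CAA GGA CTT TAA, CDS 11..28
#  tg2 chrT2 (+, two exons)   codons ATG AAA GGA TGC TAA, the third codon
#             spans the exon junction (exon1 ends inside it)
#  tg3 chrT3 (-, single exon) sense codons ATG GGA TGC TAA
toyGeneFixture <- function() {
  if (!is.null(.fixtures$toy)) return(.fixtures$toy)
  seq1 <- paste0("GATTACAGAT", "ATGGGACAAGGACTTTAA", "TTACAGATTA")
  tg1 <- new("GeneModel", geneId = "tg1", chrom = "chrT", strand = "+",
             cds = IRanges(11, 28), proteinLength = 5L, usable = TRUE)
  sense2 <- "ATGAAAGGATGCTAA"
  intron <- "GTACGTAG"
  seq2 <- paste0("CCCCC", substr(sense2, 1, 7), intron,
                 substr(sense2, 8, 15), "GGGGG")
  # exon1: 6..12 (7 bases), intron 13..20, exon2: 21..28
  tg2 <- new("GeneModel", geneId = "tg2", chrom = "chrT2", strand = "+",
             cds = IRanges(c(6, 21), c(12, 28)), proteinLength = 4L,
             usable = TRUE)
  sense3 <- "ATGGGATGCTAA"
  seq3 <- as.character(reverseComplement(DNAString(
    paste0("AAAA", sense3, "CCCC"))))
  # region length 20; sense construct position c maps to plus 21 - c, so
  # sense-CDS position s sits at plus position 17 - s
  tg3 <- new("GeneModel", geneId = "tg3", chrom = "chrT3", strand = "-",
             cds = IRanges(5, 16), proteinLength = 3L, usable = TRUE)
  genome <- new("RegionalGenome",
                regions = GRanges(c("chrT", "chrT2", "chrT3"),
                                  IRanges(1, c(nchar(seq1), nchar(seq2),
                                               nchar(seq3)))),
                seqs = DNAStringSet(c(seq1, seq2, seq3)))
  .fixtures$toy <- list(models = list(tg1 = tg1, tg2 = tg2, tg3 = tg3),
                        genome = genome)
  .fixtures$toy
}

# random toy gene for property tests, constructed independently of the
# package's own generator
randomGeneCase <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  nCod <- sample(5:30, 1)
  cds <- paste(c("ATG", sample(codons, nCod - 1, TRUE), "TAA"),
               collapse = "")
  strand <- sample(c("+", "-"), 1)
  twoExon <- sample(c(TRUE, FALSE), 1)
  flank <- paste(sample(bases, 8, TRUE), collapse = "")
  if (twoExon) {
    cut <- sample(4:(nchar(cds) - 4), 1)
    intron <- paste0("GT", paste(sample(bases, 6, TRUE), collapse = ""),
                     "AG")
    sense <- paste0(flank, substr(cds, 1, cut), intron,
                    substr(cds, cut + 1, nchar(cds)), flank)
    senseExons <- rbind(c(9, 8 + cut),
                        c(9 + cut + 10, 8 + nchar(cds) + 10))
  } else {
    sense <- paste0(flank, cds, flank)
    senseExons <- rbind(c(9, 8 + nchar(cds)))
  }
  M <- nchar(sense)
  if (strand == "+") {
    plusSeq <- sense
    ex <- senseExons
  } else {
    plusSeq <- as.character(reverseComplement(DNAString(sense)))
    ex <- cbind(M - senseExons[, 2] + 1, M - senseExons[, 1] + 1)
  }
  ord <- if (strand == "+") order(ex[, 1]) else order(-ex[, 1])
  model <- new("GeneModel", geneId = "rg", chrom = "chrR", strand = strand,
               cds = IRanges(ex[ord, 1], ex[ord, 2]),
               proteinLength = as.integer(nCod), usable = TRUE)
  genome <- new("RegionalGenome",
                regions = GRanges("chrR", IRanges(1, M)),
                seqs = DNAStringSet(plusSeq))
  list(model = model, genome = genome, sense = sense,
       senseExons = senseExons, strand = strand, M = M)
}

# brute-force effect oracle: apply the variant to the genomic sequence,
# re-extract and translate the whole CDS, diff the proteins
bruteForceEffect <- function(case, pos, alt) {
  plus <- as.character(case$genome@seqs[[1]])
  mutant <- plus
  substr(mutant, pos, pos) <- alt
  senseOf <- function(s) {
    if (case$strand == "-") s <- as.character(reverseComplement(DNAString(s)))
    paste(substr(rep(s, nrow(case$senseExons)), case$senseExons[, 1],
                 case$senseExons[, 2]), collapse = "")
  }
  aaOf <- function(s) as.character(translate(DNAString(senseOf(s)),
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
  a0 <- aaOf(plus)
  a1 <- aaOf(mutant)
  if (a0 == a1) return("synonymous")
  d <- which(strsplit(a0, "")[[1]] != strsplit(a1, "")[[1]])[1]
  mutAA <- substr(a1, d, d)
  origAA <- substr(a0, d, d)
  if (mutAA == "*") "nonsense"
  else if (origAA == "*") "stop_loss"
  else if (d == 1 && origAA == "M") "start_loss"
  else "missense"
}

mkHawCalls <- function(chrom, pos, altDepth, refDepth = 20) {
  VariantCalls(chrom, pos, "A", "T", refDepth = refDepth,
               altDepth = altDepth, label = "hawaiian")
}
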