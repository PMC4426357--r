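#' Default configuration of the simulated mapping cross
#'
#' Returns the study conditions the simulator emulates: six chromosomes of
#' *C. elegans*-like physical lengths (13--21 Mb), 50 cM genetic length
#' each, a Hawaiian marker catalog at 1 SNP/kb, 200 pre-mutagenesis parental
#' background variants, 300 EMS-induced mutations (G:C to A:T transitions)
#' of which exactly one -- placed inside a coding sequence so the change is
#' nonsynonymous -- is the causal lesion.
#'
#' @return named list of generator settings; any subset can be overridden
#'   through the \code{config} argument of [buildReferenceModel()].
#' @export
defaultCrossConfig <- function() {
  list(
    chrom_lengths = c(chrI = 15072000, chrII = 15279000, chrIII = 13784000,
                      chrIV = 17494000, chrV = 20924000, chrX = 17719000),
    total_cM = 50,
    map_type = "uniform",
    hawaiian_density = 1e-3,
    n_parental = 200,
    n_induced = 300,
    spectrum = "ems",
    causal_chrom = "chrV",
    causal_pos = 6500000,
    gene_count = 40,
    coding_fraction = 0.15
  )
}

.mergeConfig <- function(config) {
  def <- defaultCrossConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  def
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build one toy gene: designed coding sequence (ATG ... stop), optional
# two-exon structure with a GT..AG intron, 40 bp flanks, either strand.
# codonOverride: named numeric->codon replacements (used for the causal gene).
.toyGene <- function(id, chrom, regionStart, strand, nCodons, nExons = 1L,
                     codonOverride = NULL, chromLevels = chrom) {
  sense <- .allCodons()
  sense <- sense[!sense %in% .STOP_CODONS]
  codons <- c("ATG", sample(sense, nCodons - 1L, replace = TRUE), "TAA")
  if (!is.null(codonOverride))
    codons[as.integer(names(codonOverride))] <- codonOverride
  cdsSeq <- paste(codons, collapse = "")
  cdsLen <- nchar(cdsSeq)
  flank <- 40L
  if (nExons == 2L) {
    cut <- sample(seq(30L, cdsLen - 30L), 1L)
    intron <- paste0("GT", .randomBases(56L), "AG")
    construct <- paste0(.randomBases(flank), substr(cdsSeq, 1L, cut), intron,
                        substr(cdsSeq, cut + 1L, cdsLen), .randomBases(flank))
    senseExons <- rbind(c(flank + 1L, flank + cut),
                        c(flank + cut + 61L, flank + cdsLen + 60L))
  } else {
    construct <- paste0(.randomBases(flank), cdsSeq, .randomBases(flank))
    senseExons <- rbind(c(flank + 1L, flank + cdsLen))
  }
  M <- nchar(construct)
  if (strand == "+") {
    plusSeq <- construct
    exonStarts <- regionStart + senseExons[, 1L] - 1L
    exonEnds <- regionStart + senseExons[, 2L] - 1L
  } else {
    plusSeq <- .revcomp(construct)
    exonStarts <- regionStart + M - senseExons[, 2L]
    exonEnds <- regionStart + M - senseExons[, 1L]
  }
  model <- new("GeneModel", geneId = id, chrom = chrom, strand = strand,
               cds = IRanges(exonStarts, exonEnds),
               proteinLength = as.integer(nCodons), usable = TRUE)
  list(model = model,
       region = GRanges(factor(chrom, levels = chromLevels),
                        IRanges(regionStart, regionStart + M - 1L)),
       seq = plusSeq)
}

#' Build the reference state of a simulated mapping cross
#'
#' Generates, deterministically for a fixed seed, everything the pooled
#' mapping-by-sequencing simulation needs: the genetic map, a Hawaiian SNP
#' catalog placed as a Poisson process along each chromosome, parental
#' (pre-mutagenesis) background variants, EMS-induced mutations including
#' one causal lesion engineered inside a coding sequence so that its G to A
#' change is missense, toy gene models, and the reference sequence of the
#' gene loci.
#'
#' @param config list overriding entries of [defaultCrossConfig()];
#'   unknown keys are an error.
#' @param seed integer master seed; per-component substreams are derived
#'   from it.
#' @return a \linkS4class{CrossModel}.
#' @examples
#' model <- buildReferenceModel(list(n_induced = 50), seed = 1)
#' model
#' @export
buildReferenceModel <- function(config = list(), seed = 1) {
  cfg <- .mergeConfig(config)
  lens <- cfg$chrom_lengths
  if (!cfg$causal_chrom %in% names(lens))
    stop("causal chromosome ", cfg$causal_chrom, " not among chromosomes")
  L <- lens[[cfg$causal_chrom]]
  if (cfg$causal_pos < 1 || cfg$causal_pos > L)
    stop("causal position outside chromosome ", cfg$causal_chrom)
  if (cfg$causal_pos < 600 || cfg$causal_pos > L - 900)
    stop("causal position too close to a chromosome end to host a gene")
  map <- geneticMap(lens, cfg$total_cM, cfg$map_type)

  # --- gene models -------------------------------------------------------
  set.seed(.substream(seed, 11L))
  causalCodon <- 167L  # causal base = first base of this codon
  cdsStart <- cfg$causal_pos - 3L * (causalCodon - 1L)
  causal <- .toyGene("causal_gene", cfg$causal_chrom, cdsStart - 40L, "+",
                     nCodons = 250L, codonOverride = c("167" = "GGA"),
                     chromLevels = names(lens))
  genes <- list(causal)
  nOther <- max(0L, cfg$gene_count - 1L)
  taken <- causal$region
  for (i in seq_len(nOther)) {
    repeat {
      chrom <- sample(names(lens), 1L)
      nCod <- sample(120:400, 1L)
      nEx <- if (i %% 3L == 0L) 2L else 1L
      span <- 3L * nCod + 3L + 80L + if (nEx == 2L) 60L else 0L
      rs <- sample.int(lens[[chrom]] - span, 1L)
      cand <- GRanges(factor(chrom, levels = names(lens)),
                      IRanges(rs, rs + span - 1L))
      if (!any(GenomicRanges::countOverlaps(cand, taken))) break
    }
    g <- .toyGene(sprintf("gene_%03d", i), chrom, rs,
                  sample(c("+", "-"), 1L), nCod, nEx,
                  chromLevels = names(lens))
    taken <- c(taken, g$region)
    genes[[length(genes) + 1L]] <- g
  }
  models <- lapply(genes, `[[`, "model")
  names(models) <- vapply(models, function(m) m@geneId, character(1))
  genome <- new("RegionalGenome",
                regions = do.call(c, unname(lapply(genes, `[[`, "region"))),
                seqs = Biostrings::DNAStringSet(
                  vapply(genes, `[[`, character(1), "seq")))

  # --- Hawaiian catalog --------------------------------------------------
  set.seed(.substream(seed, 12L))
  hawTabs <- lapply(names(lens), function(chrom) {
    n <- stats::rpois(1L, lens[[chrom]] * cfg$hawaiian_density)
    pos <- sort(unique(sample.int(lens[[chrom]], n)))
    pos <- pos[!(chrom == cfg$causal_chrom & pos == cfg$causal_pos)]
    bases <- c("A", "C", "G", "T")
    refIdx <- sample.int(4L, length(pos), replace = TRUE)
    altIdx <- ((refIdx - 1L + sample.int(3L, length(pos),
                                         replace = TRUE)) %% 4L) + 1L
    data.frame(chrom = chrom, pos = pos, ref = bases[refIdx],
               alt = bases[altIdx])
  })
  haw <- do.call(rbind, hawTabs)
  hawaiian <- SnpCatalog(haw$chrom, haw$pos, haw$ref, haw$alt,
                         source = "hawaiian")

  # --- parental background variants --------------------------------------
  set.seed(.substream(seed, 13L))
  usedPos <- .variantKey(haw$chrom, haw$pos, "")
  parTab <- .samplePositions(cfg$n_parental, lens, usedPos)
  parTab$ref <- sample(c("A", "C", "G", "T"), nrow(parTab), replace = TRUE)
  parTab$ref <- .matchStoredBase(genome, parTab)
  parTab$alt <- vapply(parTab$ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  parental <- SnpCatalog(parTab$chrom, parTab$pos, parTab$ref, parTab$alt,
                         source = "parental")

  # --- induced mutations (incl. causal) ----------------------------------
  set.seed(.substream(seed, 14L))
  usedPos <- c(usedPos, .variantKey(parTab$chrom, parTab$pos, ""),
               .variantKey(cfg$causal_chrom, cfg$causal_pos, ""))
  ind <- .placeInduced(cfg, models, genome, lens, usedPos)
  induced <- GRanges(c(cfg$causal_chrom, ind$chrom),
                     IRanges(c(cfg$causal_pos, ind$pos), width = 1L))
  mcols(induced) <- DataFrame(ref = c("G", ind$ref), alt = c("A", ind$alt),
                              causal = c(TRUE, rep(FALSE, nrow(ind))))
  induced <- sort(induced)

  new("CrossModel", map = map, hawaiian = hawaiian, parental = parental,
      induced = induced, genes = models, genome = genome,
      causalChrom = cfg$causal_chrom, causalPos = cfg$causal_pos,
      config = cfg, seed = as.integer(seed))
}

.samplePositions <- function(n, lens, usedPos) {
  probs <- lens / sum(lens)
  chrom <- sample(names(lens), n, replace = TRUE, prob = probs)
  pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1L), numeric(1))
  keep <- !.variantKey(chrom, pos, "") %in% usedPos &
    !duplicated(.variantKey(chrom, pos, ""))
  data.frame(chrom = chrom[keep], pos = pos[keep], row.names = NULL)
}

# Where a sampled position falls inside a stored gene region, the ref
# allele must match the stored base.
.matchStoredBase <- function(genome, tab) {
  for (i in seq_len(nrow(tab))) {
    base <- tryCatch(getRefSequence(genome, tab$chrom[i], tab$pos[i]),
                     error = function(e) NULL)
    if (!is.null(base)) tab$ref[i] <- base
  }
  tab$ref
}

.placeInduced <- function(cfg, models, genome, lens, usedPos) {
  nOther <- cfg$n_induced - 1L
  if (nOther < 0L) stop("n_induced must be >= 1 (the causal lesion)")
  ems <- identical(cfg$spectrum, "ems")
  empty <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character())
  if (nOther == 0L) return(empty)
  nCds <- sum(stats::runif(nOther) < cfg$coding_fraction & length(models) > 0L)

  # coding hits: pick a gene, then a CDS base (G/C under the EMS spectrum)
  cdsRows <- lapply(seq_len(nCds), function(i) {
    repeat {
      g <- models[[sample.int(length(models), 1L)]]
      cdsPos <- unlist(lapply(seq_along(g@cds), function(j)
        seq(start(g@cds)[j], end(g@cds)[j])))
      pos <- sample(cdsPos, 1L)
      ref <- getRefSequence(genome, g@chrom, pos)
      if (!ems || ref %in% c("G", "C"))
        return(data.frame(chrom = g@chrom, pos = pos, ref = ref,
                          alt = NA_character_))
    }
  })
  cdsTab <- if (nCds) do.call(rbind, cdsRows) else empty

  # intergenic hits: vectorised uniform placement; positions that happen to
  # fall inside a stored gene region take the stored base (resampled when
  # the EMS spectrum requires a G/C site)
  nInter <- nOther - nCds
  interTab <- empty
  if (nInter > 0L) {
    chrom <- sample(names(lens), nInter, replace = TRUE,
                    prob = lens / sum(lens))
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1L), numeric(1))
    ref <- if (ems) sample(c("G", "C"), nInter, replace = TRUE)
           else sample(c("A", "C", "G", "T"), nInter, replace = TRUE)
    hits <- GenomicRanges::findOverlaps(
      GRanges(factor(chrom, levels = names(lens)), IRanges(pos, width = 1L)),
      genome@regions)
    for (i in unique(S4Vectors::queryHits(hits))) {
      repeat {
        base <- getRefSequence(genome, chrom[i], pos[i])
        if (!ems || base %in% c("G", "C")) { ref[i] <- base; break }
        pos[i] <- sample.int(lens[[chrom[i]]], 1L)
        if (!length(.regionHit(genome, chrom[i], pos[i]))) break
      }
    }
    interTab <- data.frame(chrom = chrom, pos = pos, ref = ref,
                           alt = NA_character_, row.names = NULL)
  }
  tab <- rbind(cdsTab, interTab)
  keep <- !.variantKey(tab$chrom, tab$pos, "") %in% usedPos &
    !duplicated(.variantKey(tab$chrom, tab$pos, ""))
  tab <- tab[keep, , drop = FALSE]
  tab$alt <- if (ems) c(G = "A", C = "T")[tab$ref]
             else vapply(tab$ref, function(b)
               sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  tab
}

.regionHit <- function(genome, chrom, pos) {
  which(as.character(seqnames(genome@regions)) == chrom &
        start(genome@regions) <= pos & end(genome@regions) >= pos)
}

#' Simulate F1 gametes under the obligate-single-crossover model
#'
#' One meiosis in the fully heterozygous N2/Hawaiian F1 produces, per
#' chromosome: with probability 1/2 a non-recombinant gamete (whole
#' chromosome N2 or Hawaiian, equiprobable), otherwise a single crossover
#' at a position uniform in genetic (cM) coordinates with random
#' orientation. This is complete crossover interference, the norm for
#' *C. elegans* bivalents. A chromosome with 0 cM total genetic length
#' never recombines.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param chrom chromosome name.
#' @param n number of gametes.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return data.frame with columns \code{breakpoint} (bp, NA when
#'   non-recombinant), \code{left} and \code{right} ancestry; the segment
#'   \code{[1, breakpoint]} carries the left ancestry.
#' @seealso [simulateGamete()] for a single \linkS4class{RecombinantChromosome}
#' @export
simulateGametes <- function(map, chrom, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- map@chromLengths[[chrom]]
  if (is.null(L)) stop("chromosome ", chrom, " not in genetic map")
  if (L < 1) stop("degenerate chromosome of length < 1 bp")
  total <- totalCM(map, chrom)
  rec <- if (total > 0) stats::runif(n) < 0.5 else rep(FALSE, n)
  anc <- sample(.ANCESTRIES, n, replace = TRUE)
  out <- data.frame(breakpoint = rep(NA_real_, n), left = anc, right = anc)
  nr <- sum(rec)
  if (nr > 0L) {
    bp <- bpAt(map, chrom, stats::runif(nr, 0, total))
    flip <- sample(c(TRUE, FALSE), nr, replace = TRUE)
    out$breakpoint[rec] <- bp
    out$left[rec] <- ifelse(flip, "N2", "HAW")
    out$right[rec] <- ifelse(flip, "HAW", "N2")
    degenerate <- rec & (out$breakpoint <= 1 | out$breakpoint >= L)
    if (any(degenerate)) {
      atEnd <- !is.na(out$breakpoint) & out$breakpoint >= L
      out$right[degenerate & atEnd] <- out$left[degenerate & atEnd]
      out$left[degenerate & !atEnd] <- out$right[degenerate & !atEnd]
      out$breakpoint[degenerate] <- NA_real_
    }
  }
  out
}

#' Simulate one gamete chromosome
#' @inheritParams simulateGametes
#' @return a \linkS4class{RecombinantChromosome}.
#' @export
simulateGamete <- function(map, chrom, seed = NULL) {
  g <- simulateGametes(map, chrom, 1L, seed = seed)
  .gameteAsChromosome(g, 1L, chrom, map@chromLengths[[chrom]])
}

.gameteAsChromosome <- function(g, i, chrom, L) {
  if (is.na(g$breakpoint[i])) {
    new("RecombinantChromosome", chrom = chrom, length = L,
        breakpoints = numeric(), ancestry = g$left[i])
  } else {
    new("RecombinantChromosome", chrom = chrom, length = L,
        breakpoints = g$breakpoint[i],
        ancestry = c(g$left[i], g$right[i]))
  }
}

#' Simulate the pooled homozygous-mutant F2 sample
#'
#' F2 individuals are formed by pairing two independent F1 gametes per
#' chromosome. An F2 is a phenotypic mutant if and only if both causal
#' chromosome haplotypes are N2 at the causal locus (a recessive lesion on
#' the mutagenized N2 background); the first \code{nPooled} mutant lines are
#' pooled, emulating the singling of ~200 F2 progeny and pooling of the
#' 20--50 plates segregating the mutant phenotype.
#'
#' @param model a \linkS4class{CrossModel}.
#' @param nF2 number of singled F2 individuals (default 200).
#' @param nPooled number of pooled mutant lines; default drawn uniformly
#'   from 20--50.
#' @param seed integer seed.
#' @return a \linkS4class{CrossPool}. The realised number of mutant F2s is
#'   available via \code{nMutantF2()}; the expected fraction is the
#'   Mendelian 1/4.
#' @export
simulateMutantPool <- function(model, nF2 = 200, nPooled = NULL, seed = 1) {
  set.seed(.substream(seed, 21L))
  drawPool <- is.null(nPooled)
  if (drawPool) nPooled <- sample(20:50, 1L)
  lens <- model@map@chromLengths
  causal <- model@causalChrom
  g <- simulateGametes(model@map, causal, 2L * nF2)
  ancAtCausal <- ifelse(is.na(g$breakpoint),
                        g$left,
                        ifelse(model@causalPos <= g$breakpoint,
                               g$left, g$right))
  isN2 <- ancAtCausal == "N2"
  mutant <- isN2[seq(1L, 2L * nF2, by = 2L)] & isN2[seq(2L, 2L * nF2, by = 2L)]
  nMut <- sum(mutant)
  # with the default draw, pool whatever mutant plates are available (as in
  # the emulated protocol, 20-50 plates); an explicit request that cannot be
  # met is an error
  if (drawPool) nPooled <- min(nPooled, nMut)
  if (nMut < nPooled)
    stop("only ", nMut, " homozygous-mutant F2s among ", nF2,
         "; increase n_f2 or lower n_pooled")
  sel <- which(mutant)[seq_len(nPooled)]
  gidx <- as.vector(rbind(2L * sel - 1L, 2L * sel))
  haplotypes <- list()
  haplotypes[[causal]] <- lapply(gidx, function(i)
    .gameteAsChromosome(g, i, causal, lens[[causal]]))
  for (chrom in setdiff(names(lens), causal)) {
    go <- simulateGametes(model@map, chrom, 2L * nPooled)
    haplotypes[[chrom]] <- lapply(seq_len(2L * nPooled), function(i)
      .gameteAsChromosome(go, i, chrom, lens[[chrom]]))
  }
  new("CrossPool", haplotypes = haplotypes,
      nLines = as.integer(nPooled), causalChrom = causal,
      causalPos = model@causalPos, seed = as.integer(seed),
      nF2 = as.integer(nF2), nMutant = as.integer(nMut))
}

#' Number of mutant F2s observed during pool construction
#' @param pool a \linkS4class{CrossPool}.
#' @return integer count (of \code{nF2()} singled F2s).
#' @export
nMutantF2 <- function(pool) pool@nMutant

#' @rdname nMutantF2
#' @export
nF2 <- function(pool) pool@nF2

#' Pooled Hawaiian allele frequency at positions
#'
#' The fraction of the 2n pooled chromosomes carrying Hawaiian ancestry at
#' each position.
#'
#' @param pool a \linkS4class{CrossPool}.
#' @param chrom chromosome name.
#' @param pos numeric vector of positions.
#' @return numeric vector in \code{[0, 1]}.
#' @export
hawFrequency <- function(pool, chrom, pos) {
  haps <- pool@haplotypes[[chrom]]
  if (is.null(haps)) stop("chromosome ", chrom, " not in pool")
  counts <- numeric(length(pos))
  for (h in haps) counts <- counts + (ancestryAt(h, pos) == "HAW")
  counts / length(haps)
}

#' Per-line ancestry truth record of a pool
#'
#' @param pool a \linkS4class{CrossPool}.
#' @return data.frame with one row per haplotype and chromosome: line
#'   index, chromosome, haplotype (1/2), breakpoint (NA when
#'   non-recombinant), left and right ancestry.
#' @export
poolTruth <- function(pool) {
  rows <- lapply(names(pool@haplotypes), function(chrom) {
    haps <- pool@haplotypes[[chrom]]
    data.frame(
      line = rep(seq_len(pool@nLines), each = 2L),
      chrom = chrom,
      hap = rep(1:2, pool@nLines),
      breakpoint = vapply(haps, function(h)
        if (length(h@breakpoints)) h@breakpoints[1] else NA_real_, numeric(1)),
      left = vapply(haps, function(h) h@ancestry[1], character(1)),
      right = vapply(haps, function(h)
        h@ancestry[length(h@ancestry)], character(1)))
  })
  do.call(rbind, rows)
}

#' Write the pool truth record as TSV
#' @param pool a \linkS4class{CrossPool}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePoolTruth <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# causal_chrom=", pool@causalChrom),
               paste0("# causal_pos=", pool@causalPos),
               paste0("# n_lines=", pool@nLines),
               paste0("# seed=", pool@seed)), con)
  utils::write.table(poolTruth(pool), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate pooled short-read variant calls
#'
#' At every Hawaiian-catalog, parental and induced site, the site depth is
#' Poisson(\code{meanDepth}) and the alternate read count Binomial(depth,
#' f') where f is the pooled allele frequency (Hawaiian ancestry fraction
#' for catalog SNPs, N2 ancestry fraction for parental and induced sites,
#' since those ride on the mutagenized N2 founder haplotype) and
#' f' = f(1 - e) + (1 - f)e applies the symmetric per-read error rate e.
#' The causal site has f = 1 exactly, by the pool-selection invariant.
#'
#' @param pool a \linkS4class{CrossPool}.
#' @param model the \linkS4class{CrossModel} the pool was drawn from.
#' @param meanDepth mean sequencing depth (default 22, the minimum genome
#'   coverage of the emulated experiment).
#' @param errorRate per-read allele flip probability in \code{[0, 0.05]}
#'   (default 0.001).
#' @param seed integer seed.
#' @param emitZero keep sites with zero alternate reads (default TRUE;
#'   required for Hawaiian-SNP presence/absence testing).
#' @return a \linkS4class{VariantCalls} object with truth metadata columns
#'   \code{truth_origin} (\code{hawaiian}/\code{parental}/\code{induced}),
#'   \code{truth_freq} (pre-error pooled allele frequency) and
#'   \code{truth_causal}.
#' @export
simulatePoolCalls <- function(pool, model, meanDepth = 22, errorRate = 0.001,
                              seed = 1, emitZero = TRUE) {
  if (meanDepth <= 0) stop("meanDepth must be > 0")
  if (errorRate < 0 || errorRate > 0.05)
    stop("errorRate must be in [0, 0.05]")
  set.seed(.substream(seed, 31L))
  haw <- model@hawaiian
  par <- model@parental
  ind <- model@induced
  tab <- data.frame(
    chrom = c(as.character(seqnames(haw)), as.character(seqnames(par)),
              as.character(seqnames(ind))),
    pos = c(start(haw), start(par), start(ind)),
    ref = c(mcols(haw)$ref, mcols(par)$ref, mcols(ind)$ref),
    alt = c(mcols(haw)$alt, mcols(par)$alt, mcols(ind)$alt),
    origin = rep(c("hawaiian", "parental", "induced"),
                 c(length(haw), length(par), length(ind))),
    causal = c(rep(FALSE, length(haw) + length(par)), mcols(ind)$causal))
  freq <- numeric(nrow(tab))
  for (chrom in unique(tab$chrom)) {
    i <- tab$chrom == chrom
    hf <- hawFrequency(pool, chrom, tab$pos[i])
    freq[i] <- ifelse(tab$origin[i] == "hawaiian", hf, 1 - hf)
  }
  depth <- stats::rpois(nrow(tab), meanDepth)
  fAdj <- freq * (1 - errorRate) + (1 - freq) * errorRate
  altReads <- stats::rbinom(nrow(tab), depth, fAdj)
  keep <- if (emitZero) rep(TRUE, nrow(tab)) else altReads > 0L
  ord <- order(match(tab$chrom, names(model@map@chromLengths)), tab$pos)
  ord <- ord[keep[ord]]
  VariantCalls(tab$chrom[ord], tab$pos[ord], tab$ref[ord], tab$alt[ord],
               refDepth = depth[ord] - altReads[ord],
               altDepth = altReads[ord],
               truth_origin = tab$origin[ord], truth_freq = freq[ord],
               truth_causal = tab$causal[ord])
}
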