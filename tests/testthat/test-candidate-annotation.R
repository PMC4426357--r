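test_that("codon-level SNV effects on a hand-built plus-strand gene", {
  fx <- toyGeneFixture()
  ann <- function(pos, ref, alt)
    annotateEffect(VariantCalls("chrT", pos, ref, alt, 1L, 20L),
                   fx$models, fx$genome)
  # codon 2 GGA, G->A at its first base: Gly -> Arg (the EMS classic)
  a <- ann(14, "G", "A")
  expect_equal(a$effect, "missense")
  expect_equal(a$aaChange, "Gly2Arg")
  expect_equal(a$codonFrom, "GGA")
  expect_equal(a$codonTo, "AGA")
  # codon 3 CAA, C->T: Gln -> stop
  b <- ann(17, "C", "T")
  expect_equal(b$effect, "nonsense")
  expect_equal(b$aaChange, "Gln3stop")
  # third-position GGA -> GGG is synonymous
  c3 <- ann(16, "A", "G")
  expect_equal(c3$effect, "synonymous")
  # outside any gene
  expect_equal(ann(2, "A", "T")$effect, "noncoding")
  # ref allele must match the reference base
  expect_error(ann(14, "C", "A"), "does not match reference")
})

test_that("junction codons, splice sites, frameshifts and minus-strand
           genes annotate correctly", {
  fx <- toyGeneFixture()
  ann <- function(chrom, pos, ref, alt)
    annotateEffect(VariantCalls(chrom, pos, ref, alt, 1L, 20L),
                   fx$models, fx$genome)
  # tg2: exon1 = 6..12 ends inside codon 3 (GGA split G|GA)
  # exon1 position 12 is the G at codon-3 position 1: G->C gives CGA (Arg)
  j <- ann("chrT2", 12, "G", "C")
  expect_equal(j$effect, "missense")
  expect_equal(j$aaChange, "Gly3Arg")
  # first intronic base after the donor is a splice position
  s <- ann("chrT2", 13, "G", "A")
  expect_equal(s$effect, "splice")
  s2 <- ann("chrT2", 19, "A", "C")  # acceptor -2
  expect_equal(s2$effect, "splice")
  expect_equal(ann("chrT2", 16, "C", "T")$effect, "noncoding")  # deep intron
  # coding indel with length change not divisible by 3
  f <- annotateEffect(VariantCalls("chrT2", 9, "AA", "A", 1L, 20L),
                      fx$models, fx$genome)
  expect_equal(f$effect, "frameshift")
  # tg3 minus strand: plus position 13 is sense codon 2 base 1 (G); the
  # plus-strand change C->T is sense G->A, Gly -> Arg
  m <- ann("chrT3", 13, "C", "T")
  expect_equal(m$effect, "missense")
  expect_equal(m$aaChange, "Gly2Arg")
})

test_that("annotation agrees with a whole-CDS translation oracle on random
           toy genes", {
  set.seed(91)
  mismatches <- character()
  for (i in 1:1000) {
    case <- randomGeneCase()
    cdsPos <- unlist(lapply(seq_along(case$model@cds), function(j)
      seq(start(case$model@cds)[j], end(case$model@cds)[j])))
    pos <- sample(cdsPos, 1)
    ref <- getRefSequence(case$genome, "chrR", pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- annotateEffect(VariantCalls("chrR", pos, ref, alt, 1L, 20L),
                          list(case$model), case$genome)$effect
    want <- bruteForceEffect(case, pos, alt)
    if (!identical(got, want))
      mismatches <- c(mismatches,
                      sprintf("case %d pos %d %s>%s: %s vs %s", i, pos,
                              ref, alt, got, want))
  }
  expect_identical(mismatches, character(0))
})

.hasCand <- function(cand, other) {
  if (length(other) == 0) return(FALSE)
  paste(seqnames(cand), start(cand)) %in% paste(seqnames(other), start(other))
}

test_that("candidate filtering applies interval, novelty, homozygosity and
           nonsynonymous rules", {
  m <- lineModel()
  sim <- simulateClassified(m, seed = 29)
  iv <- detectInterval(sim$calls, m@hawaiian, chromLengths(m@map),
                       map = m@map)
  sel <- selectedInterval(iv)
  cand <- filterCandidates(sim$calls, sel, m@genes, m@genome)
  expect_true(any(mcols(cand)$truth_causal))
  expect_true(all(mcols(cand)$label == "novel"))
  expect_true(all(altFraction(cand) > 0.85))
  expect_true(all(mcols(cand)$effect %in% nonsynonymousClasses()))
  expect_true(all(start(cand) >= start(sel) & start(cand) <= end(sel)))

  # boundary call one base outside the interval is excluded
  edge <- VariantCalls(as.character(seqnames(sel)), end(sel) + 1,
                       "G", "A", 1L, 30L, label = "novel")
  combined <- suppressWarnings(c(sim$calls, edge))
  cand2 <- filterCandidates(combined, sel, m@genes, m@genome)
  expect_false(any(start(cand2) == end(sel) + 1))

  # a hawaiian-labeled homozygous call inside the interval is excluded
  hawIn <- sim$calls[mcols(sim$calls)$label == "hawaiian" &
                     start(sim$calls) >= start(sel) &
                     start(sim$calls) <= end(sel)]
  expect_false(any(.hasCand(cand, hawIn)))
})

test_that("substitution consistency enumerates witness codons on both
           strands", {
  g <- checkSubstitutionConsistency("Gly", "Arg", "G", "A")
  expect_true(g$consistent)
  expect_true(any(g$witnesses$codonFrom == "GGA" &
                  g$witnesses$codonTo == "AGA"))
  # Ala -> Thr via C->T only works through the complementary strand
  a <- checkSubstitutionConsistency("Ala", "Thr", "C", "T")
  expect_true(a$consistent)
  expect_true(all(a$witnesses$strand == "-"))
  # brute-force double-check of an arbitrary pair over all 64 codons
  bruteOK <- function(aa1, aa2, nf, nt) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    codes <- Biostrings::GENETIC_CODE
    three <- c(Biostrings::AMINO_ACID_CODE, "*" = "stop")
    found <- FALSE
    for (cod in names(codes)) {
      if (three[[codes[[cod]]]] != aa1) next
      for (p in 1:3) for (su in list(c(nf, nt), c(comp[[nf]], comp[[nt]]))) {
        if (substr(cod, p, p) != su[1]) next
        mut <- cod; substr(mut, p, p) <- su[2]
        if (three[[codes[[mut]]]] == aa2) found <- TRUE
      }
    }
    found
  }
  for (pair in list(c("Gly", "Trp", "A", "C"), c("Leu", "Ile", "C", "A"),
                    c("Lys", "Arg", "T", "C"), c("Met", "Pro", "G", "A"))) {
    expect_identical(
      checkSubstitutionConsistency(pair[1], pair[2], pair[3], pair[4])$consistent,
      bruteOK(pair[1], pair[2], pair[3], pair[4]),
      info = paste(pair, collapse = " "))
  }
  expect_error(checkSubstitutionConsistency("Xyz", "Arg", "G", "A"),
               "unknown amino-acid")
  expect_error(checkSubstitutionConsistency("Gly", "Arg", "G", "N"),
               "nucleotides")
})

test_that("mutation descriptors parse into effect classes", {
  expect_equal(classifyDescriptor("G->A, Trp1062stop")$effect, "nonsense")
  expect_equal(classifyDescriptor(
    "Insertion of a C between nucleotide 207 and 208; frameshift")$effect,
    "frameshift")
  d <- classifyDescriptor("G->A, Ala14Thr")
  expect_equal(d$effect, "missense")
  expect_equal(d$aaPos, 14L)
  expect_equal(d$ntFrom, "G")
  expect_error(classifyDescriptor("banana"), "unrecognised")
})

test_that("truncation arithmetic counts codons beyond the premature stop", {
  expect_equal(truncationLength(1227, 1062), 165L)
  expect_equal(truncationLength(367, 52), 315L)
  expect_equal(truncationLength(100, 100), 0L)
  expect_error(truncationLength(100, 101), "within")
})

test_that("EMS flags mark G:C -> A:T transitions", {
  expect_true(emsFlag("G", "A"))
  expect_true(emsFlag("C", "T"))
  expect_false(emsFlag("A", "C"))
  expect_identical(emsFlag(c("G", "A"), c("A", "G")), c(TRUE, FALSE))
})

test_that("the packaged mutation tables parse and are genetically
           consistent", {
  tab <- legacyVariantTable()
  expect_equal(nrow(tab), 38L)
  expect_equal(length(unique(tab$strain)), 7L)
  parsed <- lapply(tab$mutation_text, classifyDescriptor)
  effects <- vapply(parsed, `[[`, character(1), "effect")
  expect_true(all(effects %in% c("missense", "nonsense", "frameshift")))
  for (i in which(effects != "frameshift")) {
    p <- parsed[[i]]
    expect_true(checkSubstitutionConsistency(p$aaFrom, p$aaTo, p$ntFrom,
                                             p$ntTo)$consistent,
                info = tab$mutation_text[i])
  }
  # every causal lesion in the tables is an EMS-style transition
  causal <- parsed[tab$causal]
  expect_length(causal, 7L)
  expect_true(all(vapply(causal, function(p)
    emsFlag(p$ntFrom, p$ntTo), logical(1))))
})
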