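test_that("reference model generation is deterministic for a fixed seed", {
  cfg <- list(chrom_lengths = c(chrA = 2e6), causal_chrom = "chrA",
              causal_pos = 1e6, gene_count = 4, n_induced = 10,
              n_parental = 10)
  m1 <- suppressWarnings(buildReferenceModel(cfg, seed = 5))
  m2 <- suppressWarnings(buildReferenceModel(cfg, seed = 5))
  expect_identical(start(m1@hawaiian), start(m2@hawaiian))
  expect_identical(mcols(m1@hawaiian)$alt, mcols(m2@hawaiian)$alt)
  expect_identical(start(m1@induced), start(m2@induced))
  expect_identical(as.character(m1@genome@seqs), as.character(m2@genome@seqs))
  m3 <- suppressWarnings(buildReferenceModel(cfg, seed = 6))
  expect_false(identical(start(m3@hawaiian), start(m1@hawaiian)))
})

test_that("Hawaiian catalog size follows the Poisson placement density", {
  m <- suppressWarnings(buildReferenceModel(
    list(chrom_lengths = c(chrA = 10e6), causal_chrom = "chrA",
         causal_pos = 5e6, hawaiian_density = 1e-3, gene_count = 2,
         n_induced = 5, n_parental = 5), seed = 11))
  expect_lt(abs(length(m@hawaiian) - 10000), 3 * sqrt(10000))
})

test_that("the EMS spectrum restricts induced changes to G:C -> A:T", {
  m <- lineModel()
  ind <- m@induced
  expect_true(all((mcols(ind)$ref == "G" & mcols(ind)$alt == "A") |
                  (mcols(ind)$ref == "C" & mcols(ind)$alt == "T")))
  expect_equal(sum(mcols(ind)$causal), 1L)
  # the causal lesion is engineered to be nonsynonymous
  causal <- ind[mcols(ind)$causal]
  v <- VariantCalls(as.character(seqnames(causal)), start(causal),
                    mcols(causal)$ref, mcols(causal)$alt, 0L, 20L)
  ann <- annotateEffect(v, m@genes, m@genome)
  expect_true(ann$effect %in% nonsynonymousClasses())
})

test_that("causal positions outside chromosomes and unknown keys error", {
  expect_error(buildReferenceModel(
    list(chrom_lengths = c(chrA = 1e6), causal_chrom = "chrA",
         causal_pos = 2e6), seed = 1), "outside chromosome")
  expect_error(buildReferenceModel(
    list(chrom_lengths = c(chrA = 1e6), causal_chrom = "chrB",
         causal_pos = 5e5), seed = 1), "not among chromosomes")
  expect_error(buildReferenceModel(list(not_a_key = 1), seed = 1),
               "not_a_key")
})

test_that("a 0 cM chromosome never recombines", {
  map <- geneticMap(c(chrA = 1e6), totalCM = 0)
  g <- simulateGametes(map, "chrA", 500, seed = 3)
  expect_true(all(is.na(g$breakpoint)))
  expect_error(simulateGametes(geneticMap(c(chrA = 0.5)), "chrA", 1),
               "degenerate")
})

test_that("the recombinant gamete fraction is 1/2 under obligate crossover", {
  map <- geneticMap(c(chrA = 15e6), totalCM = 50)
  g <- simulateGametes(map, "chrA", 1e5, seed = 9)
  frac <- mean(!is.na(g$breakpoint))
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(frac - 0.5), 3 * se)
  # marginal ancestry at any point is 1/2 Hawaiian
  rc <- simulateGamete(map, "chrA", seed = 1)
  expect_s4_class(rc, "RecombinantChromosome")
  anc <- vapply(1:2000, function(i)
    ancestryAt(simulateGamete(map, "chrA"), 7.5e6), character(1))
  expect_lt(abs(mean(anc == "HAW") - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("conditional Hawaiian frequency at a linked marker matches the
           enumeration oracle", {
  # oracle: numeric enumeration over the gamete classes and a fine
  # breakpoint grid, independent of the simulator
  enumFreq <- function(cCM, mCM, L, grid = 2e5) {
    b <- (seq_len(grid) - 0.5) / grid * L
    w <- 1 / (4 * grid)
    num <- sum(w * ((cCM <= b) & (mCM > b))) +
      sum(w * ((cCM > b) & (mCM <= b)))
    den <- 0.25 + sum(w * (cCM <= b)) + sum(w * (cCM > b))
    num / den
  }
  map <- geneticMap(c(chrA = 15e6), totalCM = 50)
  cPos <- bpAt(map, "chrA", 25)
  set.seed(21)
  g <- simulateGametes(map, "chrA", 6e4)
  ancAt <- function(pos) ifelse(is.na(g$breakpoint), g$left,
                                ifelse(pos <= g$breakpoint, g$left, g$right))
  n2AtC <- ancAt(cPos) == "N2"
  for (d in c(3, 10, 20)) {
    mPos <- bpAt(map, "chrA", 25 + d)
    emp <- mean(ancAt(mPos)[n2AtC] == "HAW")
    expected <- enumFreq(25, 25 + d, 50)
    se <- sqrt(expected * (1 - expected) / sum(n2AtC))
    expect_lt(abs(emp - expected), 3 * se)
  }
})

test_that("mutant F2 fraction matches the Mendelian quarter", {
  m <- lineModel()
  nMut <- vapply(1:25, function(i)
    nMutantF2(simulateMutantPool(m, nF2 = 200, seed = 100 + i)), integer(1))
  frac <- sum(nMut) / (25 * 200)
  se <- sqrt(0.25 * 0.75 / (25 * 200))
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("every pooled line is homozygous N2 at the causal locus", {
  m <- lineModel()
  pool <- simulateMutantPool(m, seed = 13)
  expect_identical(hawFrequency(pool, m@causalChrom, m@causalPos), 0)
  anc <- vapply(pool@haplotypes[[m@causalChrom]], ancestryAt, character(1),
                pos = m@causalPos)
  expect_true(all(anc == "N2"))
  expect_error(simulateMutantPool(m, nF2 = 40, nPooled = 30, seed = 1),
               "increase n_f2")
})

test_that("unlinked chromosomes keep the background Hawaiian frequency 1/2", {
  m <- defaultModel()
  unlinked <- setdiff(names(chromLengths(m@map)), m@causalChrom)[1]
  mid <- chromLengths(m@map)[[unlinked]] / 2
  freqs <- vapply(1:8, function(i)
    hawFrequency(simulateMutantPool(m, seed = 200 + i), unlinked, mid),
    numeric(1))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
})

test_that("pooled read sampling reflects the pool allele frequencies", {
  m <- lineModel()
  pool <- simulateMutantPool(m, seed = 17)
  calls <- simulatePoolCalls(pool, m, meanDepth = 22, errorRate = 0,
                             seed = 17)
  causal <- calls[mcols(calls)$truth_causal]
  expect_equal(altFraction(causal), 1)           # homozygous in all lines
  expect_equal(mcols(causal)$truth_freq, 1)
  # mean alt fraction over distal Hawaiian sites ~ their mean truth
  # frequency (binomial sampling is unbiased)
  haw <- calls[mcols(calls)$truth_origin == "hawaiian"]
  distal <- haw[abs(start(haw) - m@causalPos) > 6e6]
  expect_gt(length(distal), 1000)
  expect_lt(abs(mean(altFraction(distal), na.rm = TRUE) -
                mean(mcols(distal)$truth_freq)),
            3 * sd(altFraction(distal) - mcols(distal)$truth_freq,
                   na.rm = TRUE) / sqrt(length(distal)))
  # zero-frequency sites get no alternate reads at error 0
  gap <- haw[mcols(haw)$truth_freq == 0]
  expect_true(all(mcols(gap)$altDepth == 0L))
})

test_that("identical seeds give byte-identical simulated VCF output", {
  m <- lineModel()
  paths <- vapply(1:2, function(i) {
    pool <- simulateMutantPool(m, seed = 33)
    calls <- simulatePoolCalls(pool, m, seed = 33)
    p <- tempfile(fileext = ".vcf")
    writeVariantVcf(calls, p, contigLengths = chromLengths(m@map))
    p
  }, character(1))
  expect_identical(readLines(paths[1]), readLines(paths[2]))
  unlink(paths)
})

test_that("pool truth records round-trip the per-line ancestry mosaics", {
  m <- lineModel()
  pool <- simulateMutantPool(m, seed = 3)
  truth <- poolTruth(pool)
  expect_equal(nrow(truth), 2L * pool@nLines)
  path <- tempfile(fileext = ".tsv")
  writePoolTruth(pool, path)
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(back$breakpoint, truth$breakpoint)
  expect_equal(back$left, truth$left)
  unlink(path)
})
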