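vcfHeader <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chrI,length=1000000>",
  '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", "POOL", sep = "\t"))

writeTempVcf <- function(body) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcfHeader, body), path)
  path
}

test_that("VCF reading yields one biallelic call per record with depths", {
  path <- writeTempVcf(c(
    "chrI\t100\t.\tA\tT\t.\t.\t.\tAD\t3,27",
    "chrI\t200\t.\tG\tA\t.\t.\t.\tAD\t15,15"))
  calls <- readVariantCalls(path)
  expect_s4_class(calls, "VariantCalls")
  expect_length(calls, 2)
  expect_equal(start(calls), c(100, 200))
  expect_equal(altFraction(calls), c(0.9, 0.5))
  expect_equal(mcols(calls)$label, c("unclassified", "unclassified"))
})

test_that("header-only VCF gives an empty call set", {
  path <- writeTempVcf(character())
  expect_length(readVariantCalls(path), 0)
})

test_that("records without allelic depth are an error naming the record", {
  path <- writeTempVcf("chrI\t100\t.\tA\tT\t.\t.\t.\tAD\t.")
  expect_error(readVariantCalls(path), "chrI:100")
  noAd <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader[c(1, 2)],
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               vcfHeader[4],
               "chrI\t100\t.\tA\tT\t.\t.\t.\tGT\t1/1"), noAd)
  expect_error(readVariantCalls(noAd), "AD")
})

test_that("multiallelic records are split per alternate with a warning", {
  path <- writeTempVcf("chrI\t200\t.\tG\tA,C\t.\t.\t.\tAD\t15,15,2")
  expect_warning(calls <- readVariantCalls(path), "multiallelic")
  expect_length(calls, 2)
  expect_equal(mcols(calls)$alt, c("A", "C"))
  expect_equal(mcols(calls)$altDepth, c(15L, 2L))
})

test_that("unsorted VCF input is accepted but flagged", {
  path <- writeTempVcf(c(
    "chrI\t200\t.\tG\tA\t.\t.\t.\tAD\t15,15",
    "chrI\t100\t.\tA\tT\t.\t.\t.\tAD\t3,27"))
  expect_message(calls <- readVariantCalls(path), "not coordinate-sorted")
  expect_length(calls, 2)
})

test_that("TSV fallback round-trips through the VCF writer", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tref_depth\talt_depth",
               "chrII\t500\tG\tA\t10\t12",
               "chrII\t900\tAT\tA\t4\t18"), tsv)
  calls <- readVariantCalls(tsv)
  expect_equal(mcols(calls)$ref, c("G", "AT"))
  out <- withr::local_tempfile(fileext = ".vcf")
  writeVariantVcf(calls, out, contigLengths = c(chrII = 1e6))
  back <- readVariantCalls(out)
  expect_equal(start(back), start(calls))
  expect_equal(mcols(back)$ref, mcols(calls)$ref)
  expect_equal(mcols(back)$alt, mcols(calls)$alt)
  expect_equal(mcols(back)$refDepth, mcols(calls)$refDepth)
  expect_equal(mcols(back)$altDepth, mcols(calls)$altDepth)
})

test_that("SNP catalogs deduplicate, warn when empty, and round-trip", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chrI\t100\tA\tT",
               "chrI\t100\tA\tT",
               "chrI\t200\tG\tC"), tsv)
  cat1 <- suppressMessages(readSnpCatalog(tsv, "hawaiian"))
  expect_length(cat1, 2)
  expect_equal(catalogSource(cat1), "hawaiian")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt", empty)
  expect_warning(cat0 <- readSnpCatalog(empty, "parental"), "empty")
  expect_length(cat0, 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chrI\t0\tA\tT"), bad)
  expect_error(readSnpCatalog(bad, "hawaiian"), "position")

  rt <- withr::local_tempfile(fileext = ".tsv")
  writeSnpCatalog(cat1, rt)
  cat2 <- suppressMessages(readSnpCatalog(rt, "hawaiian"))
  expect_equal(start(cat2), start(cat1))
  expect_equal(mcols(cat2)$alt, mcols(cat1)$alt)
})

test_that("BED export is 0-based half-open and round-trips", {
  gr <- GRanges("chrI", IRanges(1, 100))
  mcols(gr)$selected <- TRUE
  bed <- withr::local_tempfile(fileext = ".bed")
  writeIntervalBed(gr, bed)
  line <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(line[1:3], c("chrI", "0", "100"))

  gr2 <- GRanges("chrV", IRanges(1000001, 2300000))
  writeIntervalBed(gr2, bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(f[3]) - as.integer(f[2]), 1300000L)

  back <- readIntervalBed(bed)
  expect_equal(start(back), start(gr2))
  expect_equal(end(back), end(gr2))

  expect_error(writeIntervalBed(data.frame(chrom = "chrI", start = 10,
                                           end = 5), bed), "end < start")
})

test_that("gene models round-trip through GFF3 with strand-aware CDS order", {
  model <- lineModel()
  gff <- withr::local_tempfile(fileext = ".gff3")
  suppressWarnings(writeGeneModelsGff(model@genes, gff))
  back <- readGeneModels(gff)
  expect_setequal(names(back), names(model@genes))
  for (id in names(back)) {
    g <- model@genes[[id]]; h <- back[[id]]
    expect_identical(h@strand, g@strand)
    expect_identical(start(h@cds), start(g@cds))
    expect_identical(end(h@cds), end(g@cds))
    expect_identical(h@proteinLength, g@proteinLength)
    if (g@strand == "-" && length(g@cds) > 1)
      expect_true(all(diff(start(h@cds)) < 0))
  }
})

test_that("CDS length not divisible by 3 flags the model unusable", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrZ\t.\tgene\t1\t100\t.\t+\t.\tID=badgene",
               "chrZ\t.\tCDS\t10\t31\t.\t+\t0\tParent=badgene"), gff)
  expect_warning(models <- readGeneModels(gff), "divisible by 3")
  expect_false(models[["badgene"]]@usable)
})

test_that("regional genome FASTA round-trips and errors on missing spans", {
  model <- lineModel()
  fa <- withr::local_tempfile(fileext = ".fa")
  writeGenomeFasta(model@genome, fa)
  back <- readGenome(fa)
  expect_equal(start(back@regions), start(model@genome@regions))
  g <- model@genes[[1]]
  expect_identical(getRefSequence(back, g@chrom, start(g@cds)[1],
                                  start(g@cds)[1] + 5),
                   getRefSequence(model@genome, g@chrom, start(g@cds)[1],
                                  start(g@cds)[1] + 5))
  expect_error(getRefSequence(back, "chrMissing", 1, 10),
               "no reference sequence")
})
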