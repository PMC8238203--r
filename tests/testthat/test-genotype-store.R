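test_that("GT strings encode to the sparse integer codes", {
  expect_identical(encodeGenotype(c("0/0", "0/1", "1|0", "1/1")), c(0L, 1L, 1L, 2L))
  expect_identical(encodeGenotype(c("./.", "0/.", "./1", NA)), c(-1L, -1L, -1L, -1L))
  expect_error(encodeGenotype("0/2"), "multi-allelic")
  expect_error(encodeGenotype("0-1"), "malformed")
})

test_that("VCF round trip through the store is lossless", {
  store <- tinyStore()
  vcf <- tempfile(fileext = ".vcf"); meta <- tempfile(fileext = ".tsv")
  writeStoreVcf(store, vcf, meta)
  back <- readVcfGenotypes(vcf, readSampleMetadata(meta))
  expect_identical(denseCodes(back), denseCodes(store))
  expect_identical(lociInfo(back)$gene, lociInfo(store)$gene)
  # all-reference locus is present but stores zero entries
  expect_true("19:400:C" %in% locusKeys(back))
  expect_identical(sum(genoCodes(back)[4, ] != 0), 0L)
})

test_that("multi-allelic records are skipped with a warning; missing samples error", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
               "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
               "1\t200\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/2\t1/1"), vcf)
  meta <- data.frame(sample_id = c("s1", "s2"), cohort = "X",
                     status = c("case", "control"), age = c(70, 80))
  expect_warning(store <- readVcfGenotypes(vcf, meta), "multi-allelic")
  expect_equal(nrow(store), 1L)
  expect_identical(as.vector(denseCodes(store)), c(1L, 2L))
  badMeta <- rbind(meta, data.frame(sample_id = "s9", cohort = "X",
                                    status = "case", age = 60))
  expect_error(suppressWarnings(readVcfGenotypes(vcf, badMeta)), "s9")
})

test_that("nss container round trip is lossless and byte-stable", {
  store <- smallCohort()$store
  f1 <- tempfile(fileext = ".nss"); f2 <- tempfile(fileext = ".nss")
  writeGenotypeStore(store, f1)
  back <- readGenotypeStore(f1)
  expect_identical(denseCodes(back), denseCodes(store))
  expect_identical(lociInfo(back), lociInfo(store))
  expect_equal(sampleInfo(back)$age, sampleInfo(store)$age)
  writeGenotypeStore(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # gzip option round-trips too
  fz <- tempfile(fileext = ".nss.gz")
  writeGenotypeStore(store, fz, compress = TRUE)
  expect_identical(denseCodes(readGenotypeStore(fz)), denseCodes(store))
})

test_that("minor-allele statistics count chromosomes and exclude missing", {
  store <- tinyStore()
  st <- minorAlleleStats(store)
  # locus 1: codes 0,0,1,2,0 -> alt 3/10
  expect_equal(st$maf[1], 0.3)
  expect_true(st$mfaIsAlt[1])
  # locus 2: codes 2,2,2,1,2 -> alt 9/10, minor is reference
  expect_equal(st$af[2], 0.9)
  expect_equal(st$maf[2], 0.1)
  expect_false(st$mfaIsAlt[2])
  # locus 3: codes 0,-1,1,0,0 -> denominator 8, alt 1
  expect_equal(st$af[3], 1 / 8)
  # spec worked example: codes [0,0,1,2] over 4 samples
  st4 <- minorAlleleStats(store, ids = c("s1", "s2", "s3", "s4"))
  expect_equal(st4$maf[1], 0.375)
  # codes [0,-1,1] -> 4 alleles, alt 1, MAF 0.25
  st3 <- minorAlleleStats(store, ids = c("s1", "s2", "s3"))
  expect_equal(st3$af[3], 0.25)
  expect_error(minorAlleleStats(store, ids = character(0)), "non-empty")
})

test_that("all-missing loci are flagged undefined", {
  codes <- rbind(c(-1, -1), c(0, 1))
  loci <- data.frame(chr = "1", pos = c(1L, 2L), ref = "A", alt = "T")
  samples <- data.frame(sample_id = c("a", "b"), cohort = "X",
                        status = c("case", "control"), age = c(70, 80))
  st <- minorAlleleStats(GenotypeStore(codes, loci, samples))
  expect_false(st$defined[1])
  expect_true(is.na(st$maf[1]))
})

test_that("sparse store statistics match a dense recomputation", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 30; L <- 25
    codes <- matrix(sample(c(-1, 0, 0, 0, 1, 2), n * L, TRUE), L, n)
    loci <- data.frame(chr = "1", pos = seq_len(L), ref = "A", alt = "T")
    samples <- data.frame(sample_id = paste0("s", 1:n), cohort = "X",
                          status = sample(c("case", "control"), n, TRUE),
                          age = 70)
    store <- GenotypeStore(codes, loci, samples)
    expect_identical(denseCodes(store), matrix(as.integer(codes), L, n,
                                               dimnames = dimnames(denseCodes(store))))
    st <- minorAlleleStats(store)
    altDense <- apply(codes, 1, function(r) sum(r[r > 0]))
    nDense <- apply(codes, 1, function(r) 2 * sum(r >= 0))
    expect_equal(st$altCount, altDense)
    expect_equal(st$nAlleles, nDense)
  }
})

test_that("store validity rejects bad codes and duplicate loci", {
  loci <- data.frame(chr = "1", pos = c(1L, 2L), ref = "A", alt = "T")
  samples <- data.frame(sample_id = c("a", "b"), cohort = "X",
                        status = c("case", "control"), age = c(70, 80))
  expect_error(GenotypeStore(rbind(c(3, 0), c(0, 1)), loci, samples), "codes")
  dup <- data.frame(chr = "1", pos = c(1L, 1L), ref = "A", alt = "T")
  expect_error(GenotypeStore(rbind(c(1, 0), c(0, 1)), dup, samples), "unique")
})
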