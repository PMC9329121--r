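test_that("classification follows the pyrimidine-strand convention", {
  g <- ref_genome(c(chr1 = "AACGTGCTT"))
  ## pos 3: context ACG, C>T -> already pyrimidine-centred
  r1 <- make_records(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  cl <- classify_sbs(r1, g)
  expect_equal(cl$class6, "C>T")
  expect_equal(cl$class96, "A[C>T]G")
  expect_false(cl$collapsed)
  ## pos 6: plus strand reads TGC centred G; G>A collapses to G[C>T]A
  r2 <- make_records(chrom = "chr1", pos = 6, ref = "G", alt = "A")
  cl2 <- classify_sbs(r2, g)
  expect_equal(cl2$class96, "G[C>T]A")
  expect_true(cl2$collapsed)
  ## purine-to-pyrimidine collapsing of the class6 label
  r3 <- make_records(chrom = "chr1", pos = 2, ref = "A", alt = "C")
  expect_equal(classify_sbs(r3, g)$class6, "T>G")
})

test_that("reference mismatch raises; opposite-strand statements are accepted", {
  g <- ref_genome(c(chr1 = "AACGTGCTT"))
  bad <- make_records(chrom = "chr1", pos = 3, ref = "T", alt = "A")
  expect_error(classify_sbs(bad, g), class = "apomut_ref_mismatch")
  ## same mutation stated on each strand classifies identically
  plus <- make_records(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  minus <- make_records(chrom = "chr1", pos = 3, ref = "G", alt = "A")
  expect_equal(classify_sbs(plus, g)[, 1:4], classify_sbs(minus, g)[, 1:4])
})

test_that("N or boundary flanks exclude records with a tally", {
  g <- ref_genome(c(chr1 = "ACNGTACGT"))
  r <- make_records(n = 2, chrom = "chr1", pos = c(2, 7), ref = "C",
                    alt = "T")
  cl <- classify_sbs(r, g)
  expect_true(is.na(cl$class96[1]))   # N in the 5-bp window
  expect_false(is.na(cl$class96[2]))
  expect_equal(attr(cl, "excluded"), 1)
})

test_that("channel systems have the right sizes and structure", {
  expect_length(channels(6), 6)
  expect_length(channels(96), 96)
  expect_length(channels(288), 288)
  expect_length(channels(1536), 1536)
  expect_error(channels(192), class = "apomut_bad_system")
  expect_equal(channels(96)[1], "A[C>A]A")
  expect_true(all(substring(channels(288), 1, 1) %in% c("T", "U", "N")))
})

test_that("build_matrix counts per sample and channel", {
  g <- ref_genome(c(chr1 = "AACGTGCTT"))
  r <- make_records(n = 3, chrom = "chr1", pos = 3, ref = "C", alt = "T")
  m <- build_matrix(r, 96, g)
  expect_equal(sum(m), 3)
  expect_equal(unname(m["s1", "A[C>T]G"]), 3L)
  r2 <- rbind(r, make_records(sample_id = "s2", chrom = "chr1", pos = 6,
                              ref = "G", alt = "A"))
  m2 <- build_matrix(sbs_records(r2), 96, g)
  expect_equal(dim(m2), c(2L, 96L))
  expect_equal(unname(rowSums(m2)), c(3, 1))
  m0 <- build_matrix(r[0, ], 96, g, samples = "s1")
  expect_equal(sum(m0), 0)
})

test_that("1536 -> 96 -> 6 collapsing is exact on random records", {
  g <- random_genome(50000, 7)
  r <- random_records(g, 2000, seed = 8)
  m1536 <- build_matrix(r, 1536, g)
  m96 <- build_matrix(r, 96, g)
  m6 <- build_matrix(r, 6, g)
  m288 <- build_matrix(r, 288, g)
  expect_equal(unclass(collapse_catalog(m1536, 96)), unclass(m96),
               ignore_attr = TRUE)
  expect_equal(unclass(collapse_catalog(m96, 6)), unclass(m6),
               ignore_attr = TRUE)
  expect_equal(unclass(collapse_catalog(m1536, 6)), unclass(m6),
               ignore_attr = TRUE)
  expect_equal(unclass(collapse_catalog(m288, 96)), unclass(m96),
               ignore_attr = TRUE)
  expect_equal(sum(m96), nrow(r))
})

test_that("strand re-expression of records leaves matrices unchanged", {
  g <- random_genome(20000, 9)
  r <- random_records(g, 500, seed = 10)
  flipped <- r
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped$ref <- comp[r$ref]
  flipped$alt <- comp[r$alt]
  expect_equal(unclass(build_matrix(sbs_records(flipped), 96, g)),
               unclass(build_matrix(r, 96, g)), ignore_attr = TRUE)
})

test_that("transcription-strand categories split the 288 system", {
  g <- ref_genome(c(chr1 = "AACGTGCTT"))
  tx_plus <- data.frame(chrom = "chr1", start = 1, end = 9, strand = "+")
  r_unc <- make_records(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  r_col <- make_records(chrom = "chr1", pos = 6, ref = "G", alt = "A")
  ## pyrimidine on plus strand = coding strand of a + gene -> U
  expect_match(classify_sbs(r_unc, g, tx_plus)$class288, "^U:")
  ## collapsed: pyrimidine on minus = template of a + gene -> T
  expect_match(classify_sbs(r_col, g, tx_plus)$class288, "^T:")
  ## genes on both strands -> ambiguous N
  tx_both <- rbind(tx_plus, data.frame(chrom = "chr1", start = 1, end = 9,
                                       strand = "-"))
  expect_match(classify_sbs(r_unc, g, tx_both)$class288, "^N:")
  ## no annotation -> N
  expect_match(classify_sbs(r_unc, g)$class288, "^N:")
})

test_that("record validation catches malformed tables", {
  expect_error(sbs_records(data.frame(sample_id = "s")),
               class = "apomut_missing_field")
  expect_error(make_records(ref = "C", alt = "C"),
               class = "apomut_bad_allele")
  expect_error(make_records(mut_fwd = 50, mut_rev = 50, depth = 20),
               class = "apomut_bad_counts")
})

test_that("mutation tables and catalogue matrices round-trip through TSV", {
  g <- random_genome(20000, 11)
  r <- random_records(g, 50, seed = 12)
  f <- withr::local_tempfile()
  write_mutation_table(r, f)
  expect_equal(as.data.frame(read_mutation_table(f)), as.data.frame(r))
  m <- build_matrix(r, 96, g)
  f2 <- withr::local_tempfile()
  write_catalog(m, f2)
  back <- read_catalog(f2)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_equal(attr(back, "system"), 96L)
})

test_that("the minimal VCF subset reads into records", {
  skip_if_not_installed("VariantAnnotation")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##INFO=<ID=ASMD,Number=1,Type=Float,Description="alignment score">',
    '##INFO=<ID=CLPM,Number=1,Type=Float,Description="clipping index">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="depth">',
    '##FORMAT=<ID=MF,Number=1,Type=Integer,Description="mutant fwd">',
    '##FORMAT=<ID=MR,Number=1,Type=Integer,Description="mutant rev">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1\tP1",
    paste("chr1", 42, ".", "C", "T", ".", "PASS", "ASMD=141;CLPM=0",
          "DP:MF:MR", "30:7:6", "28:0:0", sep = "\t"),
    paste("chr1", 99, ".", "G", "A", ".", "LOWQ", "ASMD=120;CLPM=1",
          "DP:MF:MR", "25:3:0", "30:1:0", sep = "\t")),
    f)
  r <- read_vcf_min(f)
  expect_s3_class(r, "sbs_records")
  expect_equal(nrow(r), 2)
  expect_equal(r$pos, c(42L, 99L))
  expect_equal(r$mut_fwd, c(7L, 3L))
  expect_equal(r$ref_sample_depth, c(28L, 30L))
  expect_equal(r$ref_sample_mut, c(0L, 1L))
  expect_equal(r$asmd, c(141, 120))
  expect_equal(r$pass_flag, c(TRUE, FALSE))
  expect_equal(r$sample_id, c("D1", "D1"))
})
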