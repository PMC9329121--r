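toy_manifest <- function() {
  clone_manifest(data.frame(
    cell_line = "CL1",
    clone_id = c("P1", "P1.D1", "P1.D2", "P2", "P2.D1", "P2.D2"),
    role = c("parent", "daughter", "daughter", "parent", "daughter",
             "daughter"),
    lineage_id = c("L1", "L1", "L1", "L2", "L2", "L2"),
    parent_id = c(NA, "P1", "P1", NA, "P2", "P2"),
    reference_id = c("NORM", "P1", "P1", "NORM", "P2", "P2"),
    stringsAsFactors = FALSE))
}

test_that("each locus filter removes exactly its designated record", {
  r <- make_records(n = 6)
  r$pass_flag[1] <- FALSE
  r$asmd[2] <- 130            # boundary: <= 130 is removed
  r$clpm[3] <- 1
  r$ref_sample_depth[4] <- 15 # boundary: 15 or fewer is removed
  r$mut_rev[5] <- 0
  out <- apply_locus_filters(r)
  expect_equal(unname(out$report[c("f0_pass", "f1_asmd", "f2_clpm",
                                   "f3_refcov", "f4_direction",
                                   "retained")]),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(nrow(out$retained), 1)
  ## boundary cases on the keep side
  r2 <- make_records(n = 2)
  r2$asmd <- c(131, 140); r2$ref_sample_depth <- c(16, 30)
  expect_equal(nrow(apply_locus_filters(r2)$retained), 2)
})

test_that("filter conservation and order-independence hold on random tables", {
  set.seed(101)
  n <- 10000
  r <- make_records(n)
  r$pass_flag <- runif(n) > 0.05
  r$asmd <- sample(100:160, n, replace = TRUE)
  r$clpm <- rbinom(n, 1, 0.08)
  r$ref_sample_depth <- sample(5:40, n, replace = TRUE)
  r$mut_fwd <- rbinom(n, 10, 0.8)
  r$mut_rev <- rbinom(n, 10, 0.8)
  r$depth <- 40
  out <- apply_locus_filters(r)
  removed_total <- sum(vapply(out$removed, nrow, integer(1)))
  expect_equal(removed_total + nrow(out$retained), n)
  ## naive per-record re-check: the retained set is every all-pass record,
  ## regardless of attribution order
  pass <- r$pass_flag & r$asmd > 130 & r$clpm == 0 &
    r$ref_sample_depth >= 16 & r$mut_fwd >= 1 & r$mut_rev >= 1
  expect_equal(sort(as.integer(rownames(out$retained))), which(pass))
  ## every removed record fails its attributed filter and passed the
  ## earlier ones
  expect_true(all(out$removed$f1_asmd$asmd <= 130))
  expect_true(all(out$removed$f2_clpm$clpm > 0 &
                  out$removed$f2_clpm$asmd > 130))
  expect_true(all(out$removed$f4_direction$ref_sample_depth >= 16))
  expect_error(apply_locus_filters(r[, setdiff(names(r), "asmd")]),
               class = "apomut_missing_field")
})

test_that("genotype presence uses the one-read rule", {
  gt <- data.frame(locus = rep(c("l1", "l2", "l3"), each = 2),
                   clone_id = rep(c("c1", "c2"), 3),
                   mut_reads = c(0, 1, 5, 0, 0, 0),
                   total_reads = 30)
  p <- genotype_presence(gt)
  expect_equal(p["l1", ], c(c1 = FALSE, c2 = TRUE))
  expect_equal(p["l2", ], c(c1 = TRUE, c2 = FALSE))
  expect_false(any(p["l3", ]))
  expect_error(genotype_presence(transform(gt, mut_reads = 99)),
               class = "apomut_bad_counts")
})

test_that("lineage filters apply the reference and strict >50% rules", {
  man <- toy_manifest()
  r <- make_records(n = 3, sample_id = "P1.D1", chrom = "chr1",
                    pos = c(10, 20, 30))
  keys <- paste("chr1", c(10, 20, 30), "C", "T", sep = ":")
  clones <- c("P1", "P1.D1", "P1.D2", "P2", "P2.D1", "P2.D2", "NORM")
  presence <- matrix(FALSE, 3, 7, dimnames = list(keys, clones))
  presence[1, "P1"] <- TRUE            # in reference sample -> f5
  presence[2, c("P2", "P2.D1", "P2.D2")] <- TRUE  # 3/3 other lineage -> f6
  out <- derive_de_novo("P1.D1", r, presence, man)
  expect_equal(unname(out$report["f5_ref_reads"]), 1)
  expect_equal(unname(out$report["f6_other_lineages"]), 1)
  expect_equal(out$de_novo$pos, 30)
  expect_equal(sort(out$bulk_proxy$pos), c(10, 20))
  ## exactly 50% of other-lineage clones is NOT removed (strict inequality)
  presence[2, ] <- FALSE
  presence[2, c("P2", "P2.D1")] <- TRUE  # wait: 2 of 3 is > 50%
  presence[2, "P2.D1"] <- FALSE          # 1 of 3: retained
  out2 <- derive_de_novo("P1.D1", r, presence, man)
  expect_equal(sort(out2$de_novo$pos), c(20, 30))
  expect_error(derive_de_novo("ghost", r, presence, man),
               class = "apomut_unknown_clone")
  expect_error(derive_de_novo("P1.D1", make_records(pos = 999), presence,
                              man),
               class = "apomut_missing_genotype")
})

test_that("the 50% boundary is strict over an even clone count", {
  ## 4 other-lineage clones: present in 2 (50%) retained, in 3 (75%) removed
  man <- clone_manifest(data.frame(
    cell_line = "CL1",
    clone_id = c("P1", "P1.D1", "P2", "P2.D1", "P2.D2", "P2.D3"),
    role = c("parent", "daughter", "parent", rep("daughter", 3)),
    lineage_id = c("L1", "L1", "L2", "L2", "L2", "L2"),
    parent_id = c(NA, "P1", NA, "P2", "P2", "P2"),
    reference_id = c("NORM", "P1", "NORM", "P2", "P2", "P2")))
  r <- make_records(n = 2, sample_id = "P1.D1", pos = c(10, 20))
  keys <- paste("chr1", c(10, 20), "C", "T", sep = ":")
  other <- c("P2", "P2.D1", "P2.D2", "P2.D3")
  presence <- matrix(FALSE, 2, 6,
                     dimnames = list(keys, c("P1", "P1.D1", other)))
  presence[1, other[1:2]] <- TRUE   # 2/4 = 50%
  presence[2, other[1:3]] <- TRUE   # 3/4 = 75%
  out <- derive_de_novo("P1.D1", r, presence, man)
  expect_equal(out$de_novo$pos, 10)
  expect_equal(out$bulk_proxy$pos, 20)
})

test_that("shared-daughter flagging uses asymmetric shared fractions", {
  ident <- list(d1 = paste0("l", 1:50), d2 = paste0("l", 1:50))
  out <- flag_shared_daughters(ident)
  expect_setequal(out$flags, c("d1", "d2"))
  expect_equal(out$shared["d1", "d2"], 1.0)
  disj <- flag_shared_daughters(list(d1 = paste0("a", 1:30),
                                     d2 = paste0("b", 1:30)))
  expect_length(disj$flags, 0)
  part <- flag_shared_daughters(list(d1 = paste0("l", 1:100),
                                     d2 = c(paste0("l", 1:40),
                                            paste0("x", 1:160))))
  ## d1: 40/100 shared -> flagged; d2: 40/200 = 0.2 -> not flagged
  expect_equal(part$flags, "d1")
  expect_equal(part$shared["d1", "d2"], 0.40)
  expect_equal(part$shared["d2", "d1"], 0.20)
  expect_length(flag_shared_daughters(list(d1 = "l1"))$flags, 0)
})

test_that("VAF clonality diagnostic separates clonal from mixed clones", {
  set.seed(7)
  clonal <- rbinom(400, 30, 0.5) / 30
  d1 <- vaf_clonality_diagnostic(clonal)
  expect_equal(d1$mode_count, 1)
  expect_equal(d1$label, "clonal")
  mixed <- c(rbinom(250, 60, 0.5) / 60, rbinom(250, 60, 0.22) / 60)
  d2 <- vaf_clonality_diagnostic(mixed)
  expect_gte(d2$mode_count, 2)
  expect_equal(d2$label, "possible_subclonality")
  d3 <- vaf_clonality_diagnostic(clonal[1:10])
  expect_equal(d3$label, "underpowered")
  expect_true(is.na(d3$mode_count))
  expect_equal(sum(d1$histogram$count), 400)
})

test_that("manifests validate lineage structure and round-trip", {
  man <- toy_manifest()
  f <- withr::local_tempfile()
  write_manifest(man, f)
  expect_equal(as.data.frame(read_manifest(f)), as.data.frame(man))
  bad <- as.data.frame(man)
  bad$parent_id[2] <- "P9"
  expect_error(clone_manifest(bad), class = "apomut_bad_manifest")
  expect_error(clone_manifest(bad[, -1]), class = "apomut_missing_field")
})
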