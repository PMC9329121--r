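test_that("background replicates preserve counts and contexts exactly", {
  g <- random_genome(40000, 31, chroms = c("chr1", "chr2"))
  r <- random_records(g, 300, seed = 32)
  bg <- simulate_background(r, g, n = 5, seed = 33)
  m_obs <- build_matrix(r, 96, g, samples = "s1")
  for (rep_df in bg$replicates) {
    ## per-chromosome totals preserved
    expect_equal(table(rep_df$chrom), table(r$chrom))
    ## 96-channel catalogue preserved
    sim <- make_records(n = nrow(rep_df), chrom = rep_df$chrom,
                        pos = rep_df$pos, ref = rep_df$ref,
                        alt = rep_df$alt)
    expect_equal(unclass(build_matrix(sim, 96, g, samples = "s1")),
                 unclass(m_obs), ignore_attr = TRUE)
    ## without replacement: no duplicated site within a chromosome
    expect_false(any(duplicated(paste(rep_df$chrom, rep_df$pos))))
  }
})

test_that("background simulation is reproducible and seed-sensitive", {
  g <- random_genome(20000, 34)
  r <- random_records(g, 100, seed = 35)
  idx <- build_context_index(g)
  b1 <- simulate_background(r, g, n = 3, seed = 9, index = idx)
  b2 <- simulate_background(r, g, n = 3, seed = 9, index = idx)
  b3 <- simulate_background(r, g, n = 3, seed = 10, index = idx)
  expect_identical(b1$replicates, b2$replicates)
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("a context with a single genomic site stays in place", {
  ## exactly one TCA/TGA-free context match: CCC appears once (centre pos 3)
  g <- ref_genome(c(chr1 = "ACCCATATATATATA"))
  r <- make_records(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  bg <- simulate_background(r, g, n = 3, seed = 1)
  for (rep_df in bg$replicates) expect_equal(rep_df$pos, 3L)
})

test_that("the IMD cutoff recovers injected clusters and stays null-safe", {
  g <- random_genome(2e6, 41)
  s <- unclass(g)[["chr1"]]
  idx <- build_context_index(g)
  set.seed(42)
  scatter <- random_records(g, 300, seed = 43)
  ## inject 10 kataegis runs of 8 members with IMDs in [2, 20]
  inj <- list()
  for (k in 1:10) {
    start <- 150000 * k + sample.int(1000, 1)
    pos <- start + cumsum(c(0, sample(2:20, 7, replace = TRUE)))
    ref <- substring(s, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1), character(1))
    inj[[k]] <- data.frame(pos = pos, ref = ref, alt = alt)
  }
  inj_df <- do.call(rbind, inj)
  r <- rbind(scatter,
             make_records(n = nrow(inj_df), chrom = "chr1",
                          pos = inj_df$pos, ref = inj_df$ref,
                          alt = inj_df$alt))
  r <- sbs_records(r)
  bg <- simulate_background(r, g, n = 100, seed = 44, index = idx)
  cut <- derive_imd_cutoff(r, bg)
  expect_gte(cut$global_cutoff, 21)
  expect_gte(cut$achieved_purity, 0.90)
  cl <- call_clusters(r, cut, genome = g)
  recovered <- 0
  for (k in 1:10) {
    hit <- cl$events$class == "kataegis" &
      cl$events$start <= min(inj[[k]]$pos) & cl$events$end >= max(inj[[k]]$pos)
    recovered <- recovered + any(hit)
  }
  expect_gte(recovered, 9)
  ## null: the same background process yields no (or chance-level) clusters
  null_cut <- derive_imd_cutoff(scatter, simulate_background(
    scatter, g, n = 100, seed = 45, index = idx))
  null_cl <- call_clusters(scatter, null_cut, genome = g)
  expect_lte(nrow(null_cl$members) / nrow(scatter), 0.02)
})

test_that("cutoff edge cases behave", {
  g <- random_genome(10000, 51)
  r1 <- random_records(g, 1, seed = 52)
  bg1 <- simulate_background(r1, g, n = 5, seed = 53)
  expect_equal(derive_imd_cutoff(r1, bg1)$global_cutoff, 0L)
  ## purity 1 demands a threshold below which simulations place nothing
  r <- random_records(g, 60, seed = 54)
  bg <- simulate_background(r, g, n = 20, seed = 55)
  cut1 <- derive_imd_cutoff(r, bg, purity = 1.0)
  if (cut1$global_cutoff > 0) {
    min_sim <- min(unlist(lapply(bg$replicates, apomut:::pooled_imds)))
    expect_lte(cut1$global_cutoff, min_sim)
  } else succeed()
})

test_that("cluster calling classifies the canonical run shapes", {
  cut <- fixed_cutoff(1000)
  mk <- function(pos, vaf) {
    make_records(n = length(pos), chrom = "chr1", pos = pos, depth = 100,
                 mut_fwd = as.integer(100 * vaf / 2),
                 mut_rev = as.integer(ceiling(100 * vaf / 2)))
  }
  kat <- call_clusters(mk(c(100, 250, 400, 480),
                          c(0.50, 0.52, 0.47, 0.49)), cut)
  expect_equal(kat$events$class, "kataegis")
  expect_equal(kat$events$n_members, 4L)
  dbl <- call_clusters(mk(c(500, 501), c(0.40, 0.42)), cut)
  expect_equal(dbl$events$class, "doublet")
  oth <- call_clusters(mk(c(1000, 1600), c(0.50, 0.20)), cut)
  expect_equal(oth$events$class, "other")
  omi <- call_clusters(mk(c(2000, 2100, 2150), c(0.5, 0.5, 0.5)), cut)
  expect_equal(omi$events$class, "omikli")
  mb <- call_clusters(mk(c(3000, 3001, 3002), c(0.5, 0.5, 0.5)), cut)
  expect_equal(mb$events$class, "multibase")
  ## a gap of exactly the cutoff breaks the run
  far <- call_clusters(mk(c(5000, 6000), c(0.5, 0.5)), cut)
  expect_equal(nrow(far$events), 0)
})

test_that("clustering is a partition of the clustered mutations", {
  g <- random_genome(1e5, 61)
  r <- random_records(g, 400, seed = 62)
  cl <- call_clusters(r, fixed_cutoff(300), genome = g)
  expect_false(any(duplicated(cl$members$record_row)))
  expect_equal(nrow(cl$members), sum(cl$events$n_members))
  by_class <- table(factor(cl$events$class,
                           c("kataegis", "omikli", "doublet", "multibase",
                             "other")))
  expect_equal(sum(cl$events$n_members), nrow(cl$members))
  expect_equal(sum(by_class), nrow(cl$events))
})

test_that("the APOBEC3 partition keys on cytosines in TCN context", {
  g <- ref_genome(c(chr1 = "ATCAGGACTTTCCA"))
  ## pos 3: T[C>T]A (APOBEC3); pos 8: A[C>G]T (not)
  r <- make_records(n = 2, chrom = "chr1", pos = c(3, 8), ref = "C",
                    alt = c("T", "G"))
  cl <- call_clusters(r, fixed_cutoff(100), genome = g)
  cl <- partition_apobec(cl)
  expect_equal(cl$members$apobec3, c(TRUE, FALSE))
  expect_equal(cl$events$apobec3_members, 1L)
  cl2 <- call_clusters(r, fixed_cutoff(100))
  expect_error(partition_apobec(cl2), class = "apomut_missing_field")
})

test_that("clustered TMB counts SBSs and events separately", {
  g <- random_genome(50000, 71)
  ## 5 kataegis events of 6 members each: 30 SBSs, 5 events
  pos <- unlist(lapply(0:4, function(k) 5000 * (k + 1) + cumsum(
    c(0, rep(10, 5)))))
  ref <- substring(unclass(g)[["chr1"]], pos, pos)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  r <- make_records(n = 30, chrom = "chr1", pos = pos, ref = ref, alt = alt)
  cl <- partition_apobec(call_clusters(r, fixed_cutoff(100), genome = g))
  tmb <- clustered_tmb(cl, 10)
  kat <- tmb[tmb$class == "kataegis" & tmb$partition == "all", ]
  expect_equal(kat$n_sbs, 30)
  expect_equal(kat$n_events, 5)
  expect_equal(kat$sbs_tmb, 3.0)
  expect_equal(kat$event_tmb, 0.5)
  tot <- tmb[tmb$class == "total" & tmb$partition == "all", ]
  expect_equal(tot$n_sbs, 30)
  ## APOBEC3 + non-APOBEC3 partition the SBS count
  parts <- tmb[tmb$class == "total" & tmb$partition != "all", "n_sbs"]
  expect_equal(sum(parts), 30)
  expect_error(clustered_tmb(cl, 0), class = "apomut_bad_genome_size")
  empty <- call_clusters(r[0, ], fixed_cutoff(100))
  expect_true(all(clustered_tmb(empty, 10)$sbs_tmb == 0))
})

test_that("regional correction targets mutation-rich windows only", {
  g <- random_genome(3e6, 81)
  idx <- build_context_index(g)
  ## homogeneous catalogue: no corrected window
  r <- random_records(g, 400, seed = 82)
  bg <- simulate_background(r, g, n = 30, seed = 83, index = idx)
  cut <- derive_imd_cutoff(r, bg)
  cut$global_cutoff <- max(cut$global_cutoff, 200L)  # ensure callable
  corr <- regional_correction(r, bg, cut, window = 1e6)
  expect_equal(nrow(corr$window_cutoffs), 0)
  ## pile 10x density into the first window
  set.seed(84)
  dense_pos <- sort(sample.int(9e5, 2000) + 3L)
  s <- unclass(g)[["chr1"]]
  ref <- substring(s, dense_pos, dense_pos)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  r2 <- sbs_records(rbind(r, make_records(n = length(dense_pos),
                                          chrom = "chr1", pos = dense_pos,
                                          ref = ref, alt = alt)))
  bg2 <- simulate_background(r2, g, n = 30, seed = 85, index = idx)
  cut2 <- derive_imd_cutoff(r2, bg2)
  cut2$global_cutoff <- max(cut2$global_cutoff, 200L)
  corr2 <- regional_correction(r2, bg2, cut2, window = 1e6)
  expect_gte(nrow(corr2$window_cutoffs), 1)
  expect_true(all(corr2$window_cutoffs$cutoff <= cut2$global_cutoff))
  ## window-specific cutoffs apply inside their window
  ac <- apomut:::applicable_cutoff(corr2, "chr1",
                                   c(5e5, 2.5e6))
  expect_equal(ac[1], corr2$window_cutoffs$cutoff[
    corr2$window_cutoffs$window_start == 0][1])
  expect_equal(ac[2], cut2$global_cutoff)
})

test_that("rainfall export tags clustered mutations by class", {
  g <- random_genome(50000, 91)
  pos <- c(100, 150, 200, 40000)
  ref <- substring(unclass(g)[["chr1"]], pos, pos)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  r <- make_records(n = 4, chrom = "chr1", pos = pos, ref = ref, alt = alt)
  cl <- call_clusters(r, fixed_cutoff(1000), genome = g)
  rf <- rainfall_data(r, cl)
  expect_equal(nrow(rf), 4)
  expect_true(is.na(rf$imd[1]))
  expect_equal(rf$class[1:3], rep(cl$events$class[1], 3))
  expect_equal(rf$class[4], "none")
})
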