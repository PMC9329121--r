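# shared fixture builders; everything is generated in code

# a minimal valid record table; defaults pass every locus filter
make_records <- function(n = 1, sample_id = "s1", chrom = "chr1", pos = 3,
                         ref = "C", alt = "T", mut_fwd = 5, mut_rev = 5,
                         depth = 20, ref_sample_depth = 30,
                         ref_sample_mut = 0, asmd = 140, clpm = 0,
                         pass_flag = TRUE, vaf_target = NULL) {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, mut_fwd = mut_fwd,
                   mut_rev = mut_rev, depth = depth,
                   ref_sample_depth = ref_sample_depth,
                   ref_sample_mut = ref_sample_mut, asmd = asmd,
                   clpm = clpm, pass_flag = pass_flag,
                   stringsAsFactors = FALSE)
  df <- df[rep(seq_len(nrow(df)), length.out = max(n, nrow(df))), ,
           drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(vaf_target)) {
    df$mut_fwd <- as.integer(round(df$depth * vaf_target / 2))
    df$mut_rev <- as.integer(round(df$depth * vaf_target)) - df$mut_fwd
  }
  sbs_records(df)
}

random_genome <- function(len, seed, chroms = "chr1") {
  simulate_genome(sim_config(chrom_lengths = setNames(rep(len,
    length(chroms)), chroms)), seed = seed)
}

# draw n records at uniformly random interior positions of a genome, with a
# random non-reference alt; clean quality fields, fixed VAF
random_records <- function(genome, n, seed, sample_id = "s1", vaf = 0.5) {
  set.seed(seed)
  lens <- seq_lengths(genome)
  ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(ch, function(c2) sample.int(lens[[c2]] - 4L, 1) + 2L,
                integer(1))
  ref <- mapply(function(c2, p)
    substr(unclass(genome)[[c2]], p, p), ch, pos, USE.NAMES = FALSE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
    USE.NAMES = FALSE)
  make_records(n, sample_id = sample_id, chrom = ch, pos = as.integer(pos),
               ref = ref, alt = alt, depth = 30,
               mut_fwd = as.integer(30 * vaf / 2),
               mut_rev = as.integer(30 * vaf / 2))
}

# independent brute-force context-count oracle: walk every window
naive_count_contexts <- function(seqs, flank = 1) {
  rc1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(x) paste(rev(rc1[strsplit(x, "")[[1]]]), collapse = "")
  counts <- list()
  for (s in seqs) {
    L <- nchar(s)
    w <- 2 * flank + 1
    if (L < w) next
    for (p in (1 + flank):(L - flank)) {
      win <- substr(s, p - flank, p + flank)
      if (grepl("N", win)) next
      centre <- substr(win, flank + 1, flank + 1)
      key <- if (centre %in% c("A", "G")) rc(win) else win
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a manually assembled imd_cutoff for call_clusters tests
fixed_cutoff <- function(cutoff) {
  structure(list(global_cutoff = cutoff, achieved_purity = NA_real_,
                 purity = 0.9, q_threshold = 0.01, window_cutoffs = NULL,
                 candidates = NULL), class = "imd_cutoff")
}
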