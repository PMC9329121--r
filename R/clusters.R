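## trinucleotide -> pyrimidine-strand key lookup for all 64 ACGT trinucs
PYR_TRI_MAP <- local({
  tri <- do.call(paste0, expand.grid(BASES, BASES, BASES,
                                     stringsAsFactors = FALSE)[, 3:1])
  key <- tri
  pur <- substring(tri, 2, 2) %in% c("A", "G")
  ## revcomp without Biostrings at load time
  rc <- function(x) {
    sp <- strsplit(chartr("ACGT", "TGCA", x), "")
    vapply(sp, function(z) paste(rev(z), collapse = ""), character(1))
  }
  key[pur] <- rc(tri[pur])
  setNames(key, tri)
})

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## sample, per context key, `need[key]` distinct positions (2..L-1) on one
## chromosome whose pyrimidine-strand trinucleotide context equals the key.
## Batch rejection against the sequence, with an exhaustive scan fallback
## for rare contexts. Returns list(positions = named list, short = named
## count of positions that could not be placed).
sample_context_positions <- function(seq, need, max_batches = 40L) {
  need <- unlist(need)
  need <- setNames(as.integer(need), names(need))
  L <- nchar(seq)
  got <- setNames(lapply(need, function(x) integer(0)), names(need))
  remaining <- need
  inner <- L - 2L
  if (inner < 1) return(list(positions = got, short = remaining))
  batches <- 0L
  while (sum(remaining) > 0 && batches < max_batches) {
    batches <- batches + 1L
    m <- min(max(4L * sum(remaining), 4096L), 4e6)
    p <- sample.int(inner, m, replace = TRUE) + 1L
    ctx <- PYR_TRI_MAP[substring(seq, p - 1L, p + 1L)]
    for (k in names(remaining)[remaining > 0]) {
      cand <- unique(p[!is.na(ctx) & ctx == k])
      cand <- setdiff(cand, got[[k]])
      take <- utils::head(cand, remaining[[k]])
      got[[k]] <- c(got[[k]], take)
      remaining[[k]] <- remaining[[k]] - length(take)
    }
  }
  if (sum(remaining) > 0) {
    ## exhaustive overlapping-match scan for contexts rejection missed
    for (k in names(remaining)[remaining > 0]) {
      pos <- context_site_scan(seq, k)
      pool <- setdiff(pos, got[[k]])
      n <- min(length(pool), remaining[[k]])
      take <- if (n > 0) sample(pool, n) else integer(0)
      got[[k]] <- c(got[[k]], take)
      remaining[[k]] <- remaining[[k]] - n
    }
  }
  list(positions = got, short = remaining)
}

## all centre positions on `seq` whose pyrimidine-strand context is `key`
context_site_scan <- function(seq, key) {
  hits <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) + 1L
  }
  sort(unique(c(hits(key), hits(revcomp(key)))))
}

#' Index genomic positions by pyrimidine-strand trinucleotide context
#'
#' Builds, per chromosome, the pool of positions carrying each of the 32
#' pyrimidine-centred trinucleotide contexts (N-containing windows
#' excluded). The index makes context-preserving background simulation a
#' matter of uniform sampling from precomputed pools; build it once and pass
#' it to [simulate_background()] when simulating many samples or replicates
#' against the same genome. Sequences are processed in chunks to bound
#' memory on long chromosomes.
#'
#' @param genome a `ref_genome`
#' @param chromosomes chromosomes to index (default all)
#' @param chunk chunk length in bp (default 5e6)
#' @return a `context_index`: per-chromosome list of 32 integer position
#'   vectors
#' @export
build_context_index <- function(genome, chromosomes = NULL, chunk = 5e6) {
  if (is.null(chromosomes)) chromosomes <- names(genome)
  ctx32 <- all_contexts(1)
  base_map <- rep(NA_integer_, 128)
  base_map[utf8ToInt("A")] <- 0L; base_map[utf8ToInt("C")] <- 1L
  base_map[utf8ToInt("G")] <- 2L; base_map[utf8ToInt("T")] <- 3L
  tri64 <- names(PYR_TRI_MAP)
  code_of <- function(tri) {
    b <- base_map[utf8ToInt(tri)]
    16L * b[1] + 4L * b[2] + b[3]
  }
  collapse_idx <- rep(NA_integer_, 64)
  collapse_idx[vapply(tri64, code_of, integer(1)) + 1L] <-
    match(PYR_TRI_MAP, ctx32)
  pools <- list()
  for (ch in chromosomes) {
    seq <- get_chrom(genome, ch)
    L <- nchar(seq)
    acc <- lapply(seq_len(32), function(i) list())
    if (L >= 3) {
      for (s in seq(2L, L - 1L, by = as.integer(chunk))) {
        e <- min(L - 1L, s + as.integer(chunk) - 1L)  # centres s..e
        b <- base_map[utf8ToInt(substring(seq, s - 1L, e + 1L))]
        m <- length(b)
        code <- 16L * b[1:(m - 2)] + 4L * b[2:(m - 1)] + b[3:m]
        idx <- collapse_idx[code + 1L]
        keep <- !is.na(idx)
        pos <- (s:e)[keep]
        idx <- idx[keep]
        sp <- split(pos, idx)
        for (k in names(sp))
          acc[[as.integer(k)]][[length(acc[[as.integer(k)]]) + 1L]] <- sp[[k]]
      }
    }
    pools[[ch]] <- setNames(lapply(acc, function(x)
      if (length(x)) unlist(x, use.names = FALSE) else integer(0)), ctx32)
  }
  structure(list(pools = pools), class = "context_index")
}

#' Context-preserving background simulation of a mutation catalogue
#'
#' To measure which intermutation distances could arise by chance, the
#' observed catalogue of a sample is re-scattered across the genome `n`
#' times. Each replicate preserves, per chromosome, the exact number of
#' mutations and each mutation's pyrimidine-strand +/-1 bp sequence context:
#' a mutation is reassigned to a uniformly random position on its own
#' chromosome sharing its trinucleotide context, without replacement within
#' a replicate. The substitution class of each mutation is carried to its
#' new site, so every replicate reproduces the observed 96-channel catalogue
#' exactly. A mutation whose context has no alternative position on the
#' chromosome stays at its observed site (tallied in `kept_in_place`).
#'
#' @param records `sbs_records` of one sample
#' @param genome a `ref_genome`
#' @param n number of replicates (default 100)
#' @param seed RNG seed; the simulation is fully reproducible from it
#' @param index optional prebuilt [build_context_index()] (built on the fly
#'   otherwise)
#' @return a `background_sim`: list with `replicates` (each a data.frame
#'   `chrom`, `pos`, `ref`, `alt` sorted by position), `n`, `seed`,
#'   `kept_in_place`
#' @export
simulate_background <- function(records, genome, n = 100, seed = NULL,
                                index = NULL) {
  if (is.null(index))
    index <- build_context_index(genome, unique(records$chrom))
  cl <- classify_sbs(records, genome)
  ## pyrimidine-strand context and alt of every record
  ctx <- ifelse(is.na(cl$class96), NA,
                paste0(substring(cl$class96, 1, 1),
                       substring(cl$class96, 3, 3),
                       substring(cl$class96, 7, 7)))
  pyr_alt <- substring(cl$class6, 3, 3)
  kept <- 0L
  ## per-chromosome grouping done once, outside the replicate loop
  groups <- list()
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    placeable <- i[!is.na(ctx[i])]
    groups[[ch]] <- list(
      fixed = setdiff(i, placeable),
      by_ctx = split(placeable, ctx[placeable]),
      seq = NULL)
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n), function(r) {
      out <- list()
      for (ch in names(groups)) {
        gr <- groups[[ch]]
        pools <- index$pools[[ch]]
        if (is.null(pools))
          stop(errorCondition(paste0("chromosome not indexed: ", ch),
                              class = c("apomut_unknown_chrom", "error")))
        seq <- get_chrom(genome, ch)
        pos <- integer(0); ref <- character(0); alt <- character(0)
        for (k in names(gr$by_ctx)) {
          members <- gr$by_ctx[[k]]
          pool <- pools[[k]]
          n_k <- length(members)
          newpos <- if (length(pool) <= n_k) pool
                    else sample(pool, n_k)
          n_new <- length(newpos)
          ## members that cannot be re-placed keep their observed site
          stay <- if (n_k > n_new) members[(n_new + 1):n_k] else integer(0)
          kept <<- kept + length(stay)
          placed <- members[seq_len(n_new)]
          centre <- substring(seq, newpos, newpos)
          is_pyr <- centre %in% c("C", "T")
          a <- ifelse(is_pyr, pyr_alt[placed], comp_base(pyr_alt[placed]))
          pos <- c(pos, newpos, records$pos[stay])
          ref <- c(ref, centre, records$ref[stay])
          alt <- c(alt, a, records$alt[stay])
        }
        fixed <- gr$fixed
        pos <- c(pos, records$pos[fixed])
        ref <- c(ref, records$ref[fixed])
        alt <- c(alt, records$alt[fixed])
        o <- order(pos)
        out[[ch]] <- data.frame(chrom = rep(ch, length(pos)),
                                pos = pos[o], ref = ref[o], alt = alt[o],
                                stringsAsFactors = FALSE)
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0))
    })
  })
  structure(list(replicates = reps, n = n, seed = seed,
                 kept_in_place = kept),
            class = "background_sim")
}

pooled_imds <- function(df) {
  unlist(lapply(split(df$pos, df$chrom), function(p) {
    if (length(p) < 2) return(integer(0))
    diff(sort(p))
  }), use.names = FALSE)
}

#' Derive the sample-dependent intermutation-distance (IMD) cutoff
#'
#' Scans candidate thresholds (one past each distinct observed IMD) and
#' keeps a threshold `t` if (i) the expected chance fraction — mean
#' simulated count of IMDs below `t`, divided by the observed count — is at
#' most `1 - purity`, so that at least `purity` of sub-threshold mutations
#' are clustered with respect to the simulated model, and (ii) the empirical
#' probability across replicates that the simulated count reaches the
#' observed count is below `q` after Benjamini-Hochberg correction over all
#' candidates. The cutoff is the largest qualifying threshold; if none
#' qualifies the cutoff is 0 and no clusters are callable.
#'
#' @param records observed `sbs_records` of one sample
#' @param background a `background_sim` for the same records
#' @param purity required fraction of sub-cutoff mutations not explained by
#'   chance (default 0.90)
#' @param q significance threshold on the BH-corrected empirical exceedance
#'   probability (default 0.01)
#' @param max_candidates the candidate grid is thinned to at most this many
#'   thresholds (quantile-spaced) to bound compute (default 2000)
#' @return an `imd_cutoff`: list with `global_cutoff` (bp; 0 when nothing
#'   qualifies), `achieved_purity`, `purity`, `q_threshold`,
#'   `window_cutoffs` (NULL until [regional_correction()]), and the
#'   `candidates` table (threshold, obs, sim_mean, ratio, p, q)
#' @export
derive_imd_cutoff <- function(records, background, purity = 0.90, q = 0.01,
                              max_candidates = 2000) {
  empty <- structure(list(global_cutoff = 0L, achieved_purity = NA_real_,
                          purity = purity, q_threshold = q,
                          window_cutoffs = NULL,
                          candidates = NULL),
                     class = "imd_cutoff")
  obs <- sort(pooled_imds(records))
  if (length(obs) < 1) return(empty)
  cand <- unique(obs) + 1L
  if (length(cand) > max_candidates)
    cand <- unique(as.integer(quantile(cand, seq(0, 1,
                                                 length.out = max_candidates))))
  obs_counts <- findInterval(cand - 1L, obs)
  sim_sorted <- lapply(background$replicates, function(df)
    sort(pooled_imds(df)))
  sim_counts <- vapply(sim_sorted, function(s) findInterval(cand - 1L, s),
                       numeric(length(cand)))
  sim_counts <- matrix(sim_counts, nrow = length(cand))
  sim_mean <- rowMeans(sim_counts)
  ratio <- ifelse(obs_counts > 0, sim_mean / obs_counts, Inf)
  ## empirical exceedance across replicates; a threshold no replicate
  ## reaches gets p = 0, matching the replicate-count contract of the
  ## source method (100 replicates cannot resolve p below 1/100)
  exceed <- rowSums(sim_counts >= obs_counts)
  p <- exceed / ncol(sim_counts)
  qv <- bh_fdr(p)
  ok <- obs_counts > 0 & ratio <= (1 - purity) & qv < q
  tab <- data.frame(threshold = cand, obs = obs_counts, sim_mean = sim_mean,
                    ratio = ratio, p = p, q = qv)
  if (!any(ok)) { empty$candidates <- tab; return(empty) }
  cut <- max(cand[ok])
  structure(list(global_cutoff = cut,
                 achieved_purity = 1 - ratio[match(cut, cand)],
                 purity = purity, q_threshold = q,
                 window_cutoffs = NULL, candidates = tab),
            class = "imd_cutoff")
}

#' @export
print.imd_cutoff <- function(x, ...) {
  cat("<imd_cutoff> global=", x$global_cutoff, " bp",
      if (!is.na(x$achieved_purity))
        sprintf(" (achieved purity %.3f)", x$achieved_purity),
      if (!is.null(x$window_cutoffs) && nrow(x$window_cutoffs))
        sprintf(", %d corrected window(s)", nrow(x$window_cutoffs)),
      "\n", sep = "")
  invisible(x)
}

#' Correct the IMD cutoff for mutation-rich 10-Mb windows
#'
#' Genomic mutation rates are heterogeneous; a region locally dense in
#' mutations produces short IMDs by chance. Fixed windows (`[0,10Mb)`,
#' `[10,20Mb)`, ... per chromosome) whose observed mutation count exceeds
#' the `pct` quantile (default 99th) of the simulated window counts get a
#' window-specific cutoff, re-derived from within-window observed and
#' simulated IMDs and never larger than the global cutoff. All other
#' windows inherit the global cutoff.
#'
#' @param records observed `sbs_records` of one sample
#' @param background a `background_sim`
#' @param cutoff an `imd_cutoff` with a derived global cutoff
#' @param window window size in bp (default 1e7)
#' @param pct quantile of simulated window counts flagging mutation-rich
#'   windows (default 0.99)
#' @return the `imd_cutoff` with `window_cutoffs` filled (data.frame
#'   `chrom`, `window_start`, `cutoff`; rows only for corrected windows)
#' @export
regional_correction <- function(records, background, cutoff,
                                window = 1e7, pct = 0.99) {
  win_of <- function(pos) as.integer((pos - 1) %/% window)
  wc <- list()
  for (ch in unique(records$chrom)) {
    obs_w <- table(win_of(records$pos[records$chrom == ch]))
    wins <- as.integer(names(obs_w))
    sim_w <- vapply(background$replicates, function(df) {
      p <- df$pos[df$chrom == ch]
      as.numeric(table(factor(win_of(p), levels = wins)))
    }, numeric(length(wins)))
    sim_w <- matrix(sim_w, nrow = length(wins))
    thr <- apply(sim_w, 1, quantile, probs = pct)
    rich <- wins[as.numeric(obs_w) > thr]
    for (w in rich) {
      inw <- function(df) {
        sel <- df$chrom == ch & win_of(df$pos) == w
        df[sel, , drop = FALSE]
      }
      sub_bg <- structure(list(
        replicates = lapply(background$replicates, inw),
        n = background$n, seed = background$seed, kept_in_place = 0L),
        class = "background_sim")
      sub_cut <- derive_imd_cutoff(inw(records), sub_bg,
                                   purity = cutoff$purity,
                                   q = cutoff$q_threshold)
      wc[[length(wc) + 1]] <- data.frame(
        chrom = ch, window_start = w * window,
        cutoff = min(cutoff$global_cutoff, sub_cut$global_cutoff))
    }
  }
  cutoff$window_cutoffs <- if (length(wc)) do.call(rbind, wc)
                           else data.frame(chrom = character(0),
                                           window_start = numeric(0),
                                           cutoff = numeric(0))
  attr(cutoff$window_cutoffs, "window") <- window
  cutoff
}

applicable_cutoff <- function(cutoff, chrom, pos) {
  out <- rep(cutoff$global_cutoff, length(pos))
  wcs <- cutoff$window_cutoffs
  if (is.null(wcs) || nrow(wcs) == 0) return(out)
  window <- attr(wcs, "window")
  ws <- (pos - 1) %/% window * window
  key <- paste(chrom, ws)
  hit <- match(key, paste(wcs$chrom, wcs$window_start))
  out[!is.na(hit)] <- wcs$cutoff[hit[!is.na(hit)]]
  out
}

#' Call clustered mutation events under an IMD cutoff
#'
#' Maximal runs of consecutive same-chromosome mutations whose successive
#' IMDs are all below the applicable cutoff (window-specific where a
#' regional correction exists, global elsewhere) are candidate events. A run
#' is VAF-consistent when every successive pair differs in VAF by less than
#' `vaf_tol`; consistent runs are classified as
#' \itemize{
#'   \item `doublet`: 2 adjacent mutations (IMD 1);
#'   \item `multibase`: 3 or more mutations, all adjacent;
#'   \item `omikli`: 2-3 mutations, at least one IMD > 1;
#'   \item `kataegis`: 4 or more mutations, at least one IMD > 1;
#' }
#' and runs failing VAF consistency are class `other`. Every mutation
#' belongs to at most one event.
#'
#' @param records `sbs_records` of one sample
#' @param cutoff an `imd_cutoff`
#' @param vaf_tol allowed VAF difference between subsequent members
#'   (default 0.10)
#' @param genome optional `ref_genome`; when given, members are annotated
#'   with their 96-channel class (needed by [partition_apobec()])
#' @return a `cluster_set`: list with `events` (data.frame `event_id`,
#'   `chrom`, `start`, `end`, `class`, `n_members`, `vaf_consistent`,
#'   `mean_vaf`) and `members` (data.frame `event_id`, `record_row`,
#'   `chrom`, `pos`, `vaf`, and `class96` when a genome is supplied)
#' @export
call_clusters <- function(records, cutoff, vaf_tol = 0.10, genome = NULL) {
  ord <- order(records$chrom, records$pos)
  rec <- records[ord, , drop = FALSE]
  cls96 <- if (!is.null(genome)) classify_sbs(rec, genome)$class96 else NULL
  ev_rows <- list(); mem_rows <- list(); eid <- 0L
  for (ch in unique(rec$chrom)) {
    i <- which(rec$chrom == ch)
    if (length(i) < 2) next
    pos <- rec$pos[i]
    imd <- diff(pos)
    cuts <- applicable_cutoff(cutoff, ch, pos[-length(pos)])
    linked <- imd < cuts
    if (!any(linked)) next
    r <- rle(linked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      mem <- i[starts[k]:(ends[k] + 1L)]
      gaps <- diff(rec$pos[mem])
      vafs <- rec$vaf[mem]
      consistent <- all(abs(diff(vafs)) < vaf_tol)
      n <- length(mem)
      cls <- if (!consistent) "other"
        else if (all(gaps == 1)) { if (n == 2) "doublet" else "multibase" }
        else if (n <= 3) "omikli" else "kataegis"
      eid <- eid + 1L
      ev_rows[[eid]] <- data.frame(
        event_id = eid, chrom = ch, start = rec$pos[mem[1]],
        end = rec$pos[mem[n]], class = cls, n_members = n,
        vaf_consistent = consistent, mean_vaf = mean(vafs))
      mem_rows[[eid]] <- data.frame(
        event_id = eid, record_row = ord[mem], chrom = ch,
        pos = rec$pos[mem], vaf = vafs,
        class96 = if (is.null(cls96)) NA_character_ else cls96[mem])
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = integer(0), chrom = character(0),
               start = integer(0), end = integer(0), class = character(0),
               n_members = integer(0), vaf_consistent = logical(0),
               mean_vaf = numeric(0))
  members <- if (length(mem_rows)) do.call(rbind, mem_rows) else
    data.frame(event_id = integer(0), record_row = integer(0),
               chrom = character(0), pos = integer(0), vaf = numeric(0),
               class96 = character(0))
  structure(list(events = events, members = members,
                 vaf_tol = vaf_tol, cutoff = cutoff),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", nrow(x$events), " event(s), ",
      nrow(x$members), " clustered SBS\n", sep = "")
  if (nrow(x$events)) print(table(x$events$class))
  invisible(x)
}

#' Partition clustered mutations into APOBEC3 and non-APOBEC3
#'
#' Clustered SBSs at cytosine bases in TCN trinucleotide contexts
#' (pyrimidine-strand 5' neighbour T) are classified as APOBEC3; all other
#' clustered mutations as non-APOBEC3.
#'
#' @param clusters a `cluster_set` whose members carry `class96` (call
#'   [call_clusters()] with a genome)
#' @return the `cluster_set` with `members$apobec3` (logical) and
#'   `events$apobec3_members` filled
#' @export
partition_apobec <- function(clusters) {
  m <- clusters$members
  if (nrow(m) > 0 && anyNA(m$class96))
    stop(errorCondition("members lack class96; run call_clusters with genome",
                        class = c("apomut_missing_field", "error")))
  apo <- substring(m$class96, 1, 1) == "T" & substring(m$class96, 3, 3) == "C"
  clusters$members$apobec3 <- as.logical(apo)
  clusters$events$apobec3_members <- integer(nrow(clusters$events))
  if (nrow(m) > 0) {
    counts <- tapply(clusters$members$apobec3, clusters$members$event_id, sum)
    idx <- match(names(counts), as.character(clusters$events$event_id))
    clusters$events$apobec3_members[idx] <- as.integer(counts)
  }
  clusters
}

#' Clustered tumour mutational burden (TMB)
#'
#' Burden of clustered mutations per megabase, reported both as clustered
#' SBSs (single mutations) and clustered events (local groupings: one
#' kataegis event of 6 SBSs contributes 6 to the SBS burden and 1 to the
#' event burden), per class (plus `total`, the sum over all classes) and
#' per APOBEC3 partition.
#'
#' @param clusters a `cluster_set`, ideally after [partition_apobec()]
#' @param callable_genome_size_mb genome size in megabases (> 0)
#' @return data.frame with `class`, `partition` (`all` / `apobec3` /
#'   `non_apobec3`), `n_sbs`, `n_events`, `sbs_tmb`, `event_tmb`
#'   (`n_events`/`event_tmb` are NA for the partition rows, which split
#'   single mutations, not events)
#' @export
clustered_tmb <- function(clusters, callable_genome_size_mb) {
  if (!is.numeric(callable_genome_size_mb) || callable_genome_size_mb <= 0)
    stop(errorCondition("callable genome size must be > 0",
                        class = c("apomut_bad_genome_size", "error")))
  cls_levels <- c("kataegis", "omikli", "doublet", "multibase", "other")
  ev <- clusters$events
  m <- clusters$members
  has_part <- "apobec3" %in% names(m)
  rows <- list()
  for (cl in c("total", cls_levels)) {
    sel_ev <- if (cl == "total") rep(TRUE, nrow(ev)) else ev$class == cl
    ids <- ev$event_id[sel_ev]
    sel_m <- m$event_id %in% ids
    rows[[length(rows) + 1]] <- data.frame(
      class = cl, partition = "all", n_sbs = sum(sel_m),
      n_events = sum(sel_ev),
      sbs_tmb = sum(sel_m) / callable_genome_size_mb,
      event_tmb = sum(sel_ev) / callable_genome_size_mb)
    if (has_part) {
      for (p in c("apobec3", "non_apobec3")) {
        n <- sum(sel_m & (m$apobec3 == (p == "apobec3")))
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, partition = p, n_sbs = n, n_events = NA_integer_,
          sbs_tmb = n / callable_genome_size_mb, event_tmb = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Export clustered events as BED-like TSV
#' @param clusters a `cluster_set`
#' @param path output path
#' @return `path` invisibly
#' @export
write_clusters <- function(clusters, path) {
  ev <- clusters$events
  df <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                   class = ev$class, n_members = ev$n_members,
                   apobec3_members = if ("apobec3_members" %in% names(ev))
                     ev$apobec3_members else NA_integer_,
                   mean_vaf = ev$mean_vaf)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rainfall-plot data: per-mutation IMD on log10 scale with cluster class
#'
#' @param records `sbs_records` of one sample
#' @param clusters optional `cluster_set` used to colour clustered mutations
#'   by class (non-clustered mutations are `"none"`)
#' @return data.frame `chrom`, `pos`, `imd`, `log10_imd`, `class`
#' @export
rainfall_data <- function(records, clusters = NULL) {
  ord <- order(records$chrom, records$pos)
  rec <- records[ord, , drop = FALSE]
  imd <- unlist(lapply(split(rec$pos, rec$chrom)[unique(rec$chrom)],
                       function(p) c(NA, diff(p))), use.names = FALSE)
  cls <- rep("none", nrow(rec))
  if (!is.null(clusters) && nrow(clusters$members) > 0) {
    hit <- match(ord, clusters$members$record_row)
    ev <- match(clusters$members$event_id[hit],
                clusters$events$event_id)
    cls[!is.na(hit)] <- clusters$events$class[ev[!is.na(hit)]]
  }
  data.frame(chrom = rec$chrom, pos = rec$pos, imd = imd,
             log10_imd = log10(imd), class = cls)
}
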