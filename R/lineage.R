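#' Validate a clone-lineage manifest
#'
#' The manifest describes the experimental design: single-cell-derived parent
#' clones expanded in vitro, each re-cloned into daughter clones, so that the
#' mutations private to a daughter were acquired during the propagation
#' interval bounded by the two cloning events. Each clone names the sample
#' that was used as the reference genome when its mutations were called
#' (daughters: their parent; parents: an unrelated normal).
#'
#' @param df data.frame with columns `cell_line`, `clone_id`,
#'   `role` (`parent`/`daughter`), `lineage_id`, `parent_id` (NA for
#'   parents), `reference_id`, and optionally `days_propagated` and `group`
#'   (genotype label used by downstream comparisons)
#' @return the validated data.frame, class `clone_manifest`
#' @export
clone_manifest <- function(df) {
  df <- as.data.frame(df)
  need <- c("cell_line", "clone_id", "role", "lineage_id", "parent_id",
            "reference_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(errorCondition(paste0("missing manifest column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("apomut_missing_field", "error")))
  if (anyDuplicated(df$clone_id))
    stop(errorCondition("duplicate clone_id in manifest",
                        class = c("apomut_bad_manifest", "error")))
  if (!all(df$role %in% c("parent", "daughter")))
    stop(errorCondition("role must be 'parent' or 'daughter'",
                        class = c("apomut_bad_manifest", "error")))
  d <- df[df$role == "daughter", , drop = FALSE]
  parents <- df[df$role == "parent", , drop = FALSE]
  ok <- mapply(function(p, cl) {
    any(parents$clone_id == p & parents$cell_line == cl)
  }, d$parent_id, d$cell_line)
  if (!all(ok))
    stop(errorCondition(
      paste0("daughter(s) with unknown parent in their cell line: ",
             paste(d$clone_id[!ok], collapse = ", ")),
      class = c("apomut_bad_manifest", "error")))
  class(df) <- c("clone_manifest", "data.frame")
  df
}

#' Read / write a clone manifest (TSV)
#' @param path file path
#' @return a `clone_manifest` (reader); `path` invisibly (writer)
#' @export
read_manifest <- function(path) {
  clone_manifest(read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest a `clone_manifest`
#' @export
write_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

locus_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

#' Locus-level quality filters for SBS calls (step one)
#'
#' Non-PASS records (panel-of-normals flag) are removed first (filter 0).
#' Four post-hoc filters then remove calls at low-quality loci, in order:
#' \enumerate{
#'   \item `f1_asmd`: median alignment score of mutation-reporting reads
#'     (ASMD) less than or equal to `asmd_max_removed` (default 130);
#'   \item `f2_clpm`: clipping index (CLPM) greater than 0;
#'   \item `f3_refcov`: locus covered by fewer than `refcov_min` (default 16,
#'     i.e. "15 or less") reads in the comparison reference sample;
#'   \item `f4_direction`: mutation not reported by at least one read of each
#'     sequencing direction.
#' }
#' Each removed record is attributed to the first filter that rejects it;
#' the retained set is independent of filter order.
#'
#' @param records an `sbs_records` data.frame
#' @param thresholds list with `asmd_max_removed` and `refcov_min`
#' @return list with `retained` (records), `removed` (named list of records
#'   per filter f0..f4) and `report` (named removal counts + retained count)
#' @export
apply_locus_filters <- function(records,
                                thresholds = list(asmd_max_removed = 130,
                                                  refcov_min = 16)) {
  need <- c("asmd", "clpm", "ref_sample_depth", "mut_fwd", "mut_rev",
            "pass_flag")
  for (f in need) {
    if (!f %in% names(records) || anyNA(records[[f]]))
      stop(errorCondition(paste0("missing or NA quality field: ", f),
                          class = c("apomut_missing_field", "error")))
  }
  asmd_max <- thresholds$asmd_max_removed
  refcov_min <- thresholds$refcov_min
  fail <- cbind(
    f0_pass = !records$pass_flag,
    f1_asmd = records$asmd <= asmd_max,
    f2_clpm = records$clpm > 0,
    f3_refcov = records$ref_sample_depth < refcov_min,
    f4_direction = records$mut_fwd < 1 | records$mut_rev < 1
  )
  first <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
  labels <- colnames(fail)
  removed <- lapply(seq_along(labels), function(k)
    records[first == k, , drop = FALSE])
  names(removed) <- labels
  retained <- records[first == 0L, , drop = FALSE]
  report <- c(input = nrow(records),
              setNames(vapply(removed, nrow, integer(1)), labels),
              retained = nrow(retained))
  list(retained = retained, removed = removed, report = report)
}

#' Genotype-presence matrix from re-counted reads
#'
#' Candidate loci are genotyped across every clone of a cell line by counting
#' mutant and wild-type reads (cgpVAF-style). A mutation is "present" in a
#' clone if it is supported by at least `min_mut_reads` reads — one read
#' suffices under the literal "presented in any reads" rule.
#'
#' @param genotypes data.frame with columns `locus`, `clone_id`, `mut_reads`,
#'   `total_reads`
#' @param min_mut_reads minimum mutant reads for presence (default 1)
#' @return logical matrix loci x clones
#' @export
genotype_presence <- function(genotypes, min_mut_reads = 1) {
  if (any(genotypes$mut_reads > genotypes$total_reads) ||
      any(genotypes$mut_reads < 0))
    stop(errorCondition("mut_reads must lie in [0, total_reads]",
                        class = c("apomut_bad_counts", "error")))
  loci <- unique(genotypes$locus)
  clones <- unique(genotypes$clone_id)
  m <- matrix(FALSE, length(loci), length(clones),
              dimnames = list(loci, clones))
  m[cbind(match(genotypes$locus, loci),
          match(genotypes$clone_id, clones))] <-
    genotypes$mut_reads >= min_mut_reads
  m
}

#' Lineage filters: derive the de novo catalogue of one clone (step two)
#'
#' Applied to the locus-filtered records of a clone, using the genotype
#' presence matrix across all clones of its cell line:
#' \enumerate{
#'   \item `f5_ref_reads`: the locus carries mutant reads in the clone's
#'     reference sample (pre-existing, not acquired in the interval);
#'   \item `f6_other_lineages`: the locus is present in strictly more than
#'     50\% of genotyped clones belonging to other parental lineages of the
#'     same cell line (germline or shared pre-existing variation).
#' }
#' Records removed by either filter are returned as the clone's contribution
#' to the bulk-proxy catalogue — pooled across clones, these approximate the
#' mutation catalogue of the bulk cell line before cloning.
#'
#' @param clone_id focal clone
#' @param records locus-filtered `sbs_records` of that clone
#' @param presence logical loci x clones matrix from [genotype_presence()];
#'   row names must be locus keys `chrom:pos:ref:alt`
#' @param manifest a `clone_manifest`
#' @param other_lineage_fraction removal threshold for filter 6 (strict
#'   inequality; default 0.5)
#' @return list `de_novo` (records), `bulk_proxy` (records removed by f5/f6),
#'   `report` (counts per filter)
#' @export
derive_de_novo <- function(clone_id, records, presence, manifest,
                           other_lineage_fraction = 0.5) {
  row <- manifest[manifest$clone_id == clone_id, , drop = FALSE]
  if (nrow(row) != 1)
    stop(errorCondition(paste0("clone not in manifest: ", clone_id),
                        class = c("apomut_unknown_clone", "error")))
  ref_id <- row$reference_id
  same_line <- manifest[manifest$cell_line == row$cell_line, , drop = FALSE]
  other <- same_line$clone_id[same_line$lineage_id != row$lineage_id]
  other <- intersect(other, colnames(presence))
  keys <- locus_key(records)
  missing <- setdiff(keys, rownames(presence))
  if (length(missing))
    stop(errorCondition(
      paste0(length(missing), " locus/loci not genotyped"),
      class = c("apomut_missing_genotype", "error")))
  in_ref <- if (ref_id %in% colnames(presence)) presence[keys, ref_id]
            else rep(FALSE, length(keys))
  frac_other <- if (length(other))
    rowMeans(presence[keys, other, drop = FALSE]) else rep(0, length(keys))
  f5 <- in_ref
  f6 <- !f5 & frac_other > other_lineage_fraction
  list(
    de_novo = records[!f5 & !f6, , drop = FALSE],
    bulk_proxy = records[f5 | f6, , drop = FALSE],
    report = c(input = nrow(records), f5_ref_reads = sum(f5),
               f6_other_lineages = sum(f6), retained = sum(!f5 & !f6),
               n_other_lineage_clones = length(other))
  )
}

#' Flag sibling daughters sharing high fractions of de novo mutations
#'
#' Daughters of one parent whose de novo catalogues overlap substantially
#' (while absent from the parent) were most likely established from a common
#' subclone that arose during parent cultivation; they are flagged for
#' exclusion from burden statistics. The shared fraction of daughter d
#' against sibling e is |catalog(d) intersect catalog(e)| / |catalog(d)| —
#' asymmetric, so a small catalogue nested inside a large sibling is still
#' flagged.
#'
#' @param catalogs named list (one element per sibling daughter) of locus-key
#'   character vectors, or of `sbs_records` data.frames
#' @param threshold flag when any pairwise shared fraction exceeds this
#'   (default 0.30)
#' @return list `flags` (character vector of daughters to exclude) and
#'   `shared` (numeric matrix of pairwise shared fractions, rows = focal)
#' @export
flag_shared_daughters <- function(catalogs, threshold = 0.30) {
  sets <- lapply(catalogs, function(x) {
    if (is.data.frame(x)) unique(locus_key(x)) else unique(as.character(x))
  })
  k <- length(sets)
  nm <- names(sets)
  shared <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (k >= 2) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      shared[i, j] <- if (length(sets[[i]]) == 0) 0
        else length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
    }
  }
  flags <- if (k >= 2) nm[apply(shared > threshold, 1, any, na.rm = TRUE)]
           else character(0)
  list(flags = flags, shared = shared)
}

#' VAF clonality diagnostic for one clone
#'
#' Single-cell-derived clones carry clonal heterozygous mutations whose VAF
#' distribution is unimodal (near 0.5 in diploid regions; polyploidy shifts
#' but does not split the peak). A second mode indicates subclonal mutation
#' acquisition. Modes are local maxima of a kernel-smoothed VAF density that
#' exceed 10\% of the global maximum.
#'
#' @param vafs numeric vector of VAFs in \[0,1\] (or an `sbs_records`
#'   data.frame, from which the `vaf` column is taken)
#' @param bin_width width of the reported histogram bins (default 0.02)
#' @param smoothing_bandwidth kernel bandwidth of the density (default 0.05)
#' @param min_n below this many records the diagnostic is reported as
#'   underpowered, not evaluated (default 50)
#' @return list `histogram` (data.frame bin_mid, count), `mode_count`,
#'   `mode_positions`, `label` in `clonal` / `possible_subclonality` /
#'   `underpowered`
#' @export
vaf_clonality_diagnostic <- function(vafs, bin_width = 0.02,
                                     smoothing_bandwidth = 0.05,
                                     min_n = 50) {
  if (is.data.frame(vafs)) vafs <- vafs$vaf
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(pmin(pmax(vafs, 0), 1), breaks = breaks, plot = FALSE)
  hist_df <- data.frame(bin_mid = h$mids, count = h$counts)
  if (length(vafs) < min_n)
    return(list(histogram = hist_df, mode_count = NA_integer_,
                mode_positions = numeric(0), label = "underpowered"))
  d <- density(vafs, bw = smoothing_bandwidth, from = 0, to = 1, n = 512)
  y <- d$y
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  modes <- d$x[is_max & y > 0.1 * max(y)]
  list(histogram = hist_df,
       mode_count = length(modes),
       mode_positions = modes,
       label = if (length(modes) <= 1) "clonal" else "possible_subclonality")
}

#' Assemble and serialize a filter report
#'
#' @param locus_report named counts from [apply_locus_filters()]
#' @param lineage_reports named list (per clone) of reports from
#'   [derive_de_novo()]
#' @param shared result of [flag_shared_daughters()] or NULL
#' @param path optional path; when given the report is written as JSON
#' @return the report list, invisibly when written
#' @export
filter_report <- function(locus_report, lineage_reports = list(),
                          shared = NULL, path = NULL) {
  rep <- list(locus = as.list(locus_report),
              lineage = lapply(lineage_reports, as.list),
              shared_daughter_flags = if (is.null(shared)) character(0)
                                      else shared$flags,
              shared_fractions = if (is.null(shared)) NULL
                                 else as.data.frame(shared$shared))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(rep))
  }
  rep
}
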