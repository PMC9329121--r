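#' Assemble a pipeline run configuration
#'
#' Inputs may be given as file paths (FASTA / TSV, read lazily) or as
#' in-memory objects. Every stage parameter defaults to the value used
#' throughout the analysis; the configuration (minus in-memory objects)
#' round-trips through JSON unchanged.
#'
#' @param genome `ref_genome` or FASTA path
#' @param mutations `sbs_records` or mutation-table TSV path (all clones in
#'   one table)
#' @param manifest `clone_manifest` or TSV path
#' @param genotypes genotype data.frame (`locus`, `clone_id`, `mut_reads`,
#'   `total_reads`) or TSV path
#' @param signatures `signature_set` or COSMIC-format TSV path
#' @param out_dir output directory (created); NULL disables file output
#' @param seed master seed; stage-scoped sub-seeds are derived from it so
#'   stages are independently reproducible
#' @param params named overrides of stage parameters (see defaults in the
#'   returned object: `asmd_max_removed`, `refcov_min`, `min_mut_reads`,
#'   `other_lineage_fraction`, `shared_threshold`, `n_replicates`,
#'   `imd_purity`, `imd_q`, `vaf_tol`, `regional_window`, `add_penalty`,
#'   `remove_penalty`, `comparison_tail`, `chromosomes`)
#' @return a `run_config` list
#' @export
run_config <- function(genome, mutations, manifest, genotypes = NULL,
                       signatures = NULL, out_dir = NULL, seed = 1,
                       params = list()) {
  defaults <- list(
    asmd_max_removed = 130, refcov_min = 16, min_mut_reads = 1,
    other_lineage_fraction = 0.5, shared_threshold = 0.30,
    n_replicates = 100, imd_purity = 0.90, imd_q = 0.01, vaf_tol = 0.10,
    regional_window = 1e7, add_penalty = 0.005, remove_penalty = 0.001,
    comparison_tail = "two", chromosomes = NULL)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop(errorCondition(paste0("unknown parameter(s): ",
                               paste(unknown, collapse = ", ")),
                        class = c("apomut_bad_config", "error")))
  defaults[names(params)] <- params
  structure(list(genome = genome, mutations = mutations,
                 manifest = manifest, genotypes = genotypes,
                 signatures = signatures, out_dir = out_dir,
                 seed = as.integer(seed), params = defaults),
            class = "run_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

config_hash <- function(config) {
  ser <- list(params = config$params, seed = config$seed,
              paths = Filter(function(x)
                               is.character(x) && length(x) == 1 &&
                               is.null(oldClass(x)),
                             config[c("genome", "mutations", "manifest",
                                      "genotypes", "signatures")]))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(ser, auto_unbox = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

stage_seeds <- function(master, n = 8) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full analysis pipeline
#'
#' Stages run in the order of the underlying protocol: locus filters →
#' lineage filters (de novo catalogues, bulk proxy, shared-daughter flags,
#' VAF diagnostics) → catalogue matrices → motif enrichment → clustered
#' mutation detection → signature attribution → group comparisons. Every
#' output carries the configuration hash and master seed; reruns with an
#' identical configuration are bit-identical for deterministic stages and
#' reproducible for seeded ones.
#'
#' @param config a [run_config()]
#' @return a result bundle: list with `filter_report`, `de_novo` (named list
#'   of `sbs_records`), `bulk_proxy`, `vaf_diagnostics`, `matrix96`,
#'   `matrix6`, `enrichment` (per clone), `clusters` (per clone),
#'   `tmb` (per clone), `activities` (per clone `signature_activity`),
#'   `comparisons`, `meta` (`config_hash`, `seed`)
#' @export
run_pipeline <- function(config) {
  p <- config$params
  genome <- resolve_input(config$genome, read_genome_fasta)
  mutations <- resolve_input(config$mutations, read_mutation_table)
  manifest <- resolve_input(config$manifest, read_manifest)
  genotypes <- resolve_input(config$genotypes, function(f)
    read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  signatures <- resolve_input(config$signatures, read_signatures)
  seeds <- stage_seeds(config$seed)

  offenders <- setdiff(unique(mutations$sample_id), manifest$clone_id)
  if (length(offenders))
    stop(errorCondition(
      paste0("sample(s) in mutation table missing from manifest: ",
             paste(offenders, collapse = ", ")),
      class = c("apomut_sample_mismatch", "error")))

  ## ---- stage 1+2: locus and lineage filters ---------------------------
  locus <- apply_locus_filters(mutations,
                               list(asmd_max_removed = p$asmd_max_removed,
                                    refcov_min = p$refcov_min))
  presence <- if (!is.null(genotypes))
    genotype_presence(genotypes, p$min_mut_reads) else NULL
  de_novo <- list(); bulk <- list(); lineage_reports <- list()
  for (clone in manifest$clone_id) {
    rec <- locus$retained[locus$retained$sample_id == clone, , drop = FALSE]
    if (!is.null(presence)) {
      dd <- derive_de_novo(clone, rec, presence, manifest,
                           p$other_lineage_fraction)
      de_novo[[clone]] <- dd$de_novo
      bulk[[clone]] <- dd$bulk_proxy
      lineage_reports[[clone]] <- dd$report
    } else de_novo[[clone]] <- rec
  }
  bulk_proxy <- if (length(bulk)) do.call(rbind, bulk) else NULL
  shared <- list()
  for (par in unique(manifest$parent_id[manifest$role == "daughter"])) {
    sibs <- manifest$clone_id[manifest$role == "daughter" &
                              manifest$parent_id == par]
    if (length(sibs) >= 2)
      shared[[par]] <- flag_shared_daughters(de_novo[sibs],
                                             p$shared_threshold)
  }
  shared_flags <- unlist(lapply(shared, `[[`, "flags"), use.names = FALSE)
  vaf_diag <- lapply(de_novo, vaf_clonality_diagnostic)

  ## ---- catalogue matrices ---------------------------------------------
  all_dn <- do.call(rbind, de_novo)
  matrix96 <- build_matrix(all_dn, 96, genome, samples = manifest$clone_id)
  matrix6 <- collapse_catalog(matrix96, 6)

  ## ---- motif enrichment -----------------------------------------------
  chroms <- if (is.null(p$chromosomes)) names(genome) else p$chromosomes
  inventory <- count_contexts(genome, chroms, flank = 2)
  enrichment <- lapply(de_novo, function(rec)
    c(lapply(c("TCN", "TCA", "YTCA", "RTCA"), function(mo)
        compute_enrichment(rec, inventory, mo, genome, chroms))))

  ## ---- clustered mutations --------------------------------------------
  genome_mb <- sum(seq_lengths(genome)[chroms]) / 1e6
  clusters <- list(); tmb <- list()
  clone_seeds <- with_seed(seeds[4],
                           sample.int(.Machine$integer.max - 1L,
                                      length(de_novo)))
  for (i in seq_along(de_novo)) {
    clone <- names(de_novo)[i]
    rec <- de_novo[[clone]]
    if (nrow(rec) < 2) { clusters[clone] <- list(NULL); next }
    bg <- simulate_background(rec, genome, n = p$n_replicates,
                              seed = clone_seeds[i])
    cut <- derive_imd_cutoff(rec, bg, p$imd_purity, p$imd_q)
    if (cut$global_cutoff > 0)
      cut <- regional_correction(rec, bg, cut, p$regional_window)
    cl <- call_clusters(rec, cut, p$vaf_tol, genome)
    cl <- partition_apobec(cl)
    clusters[[clone]] <- cl
    tmb[[clone]] <- clustered_tmb(cl, genome_mb)
  }

  ## ---- signature attribution ------------------------------------------
  activities <- NULL
  if (!is.null(signatures)) {
    activities <- lapply(rownames(matrix96), function(s)
      nnls_refit(matrix96[s, ], signatures, p$add_penalty,
                 p$remove_penalty))
    names(activities) <- rownames(matrix96)
  }

  ## ---- group comparisons ----------------------------------------------
  comparisons <- NULL
  if (!is.null(activities) && "group" %in% names(manifest)) {
    dmask <- manifest$role == "daughter" &
      !manifest$clone_id %in% shared_flags
    dman <- manifest[dmask, , drop = FALSE]
    groups <- unique(dman$group)
    apo_act <- vapply(activities, function(a)
      sum(a$activities[c("SBS2L", "SBS13L")], na.rm = TRUE), numeric(1))
    if (length(groups) >= 2) {
      cmb <- combn(groups, 2, simplify = FALSE)
      comparisons <- comparison_report(lapply(cmb, function(gp) list(
        label = paste0("apobec_activity:", gp[1], "_vs_", gp[2]),
        a = apo_act[dman$clone_id[dman$group == gp[1]]],
        b = apo_act[dman$clone_id[dman$group == gp[2]]],
        tail = p$comparison_tail)))
    }
  }

  bundle <- list(
    filter_report = filter_report(locus$report, lineage_reports,
                                  if (length(shared)) shared[[1]] else NULL),
    de_novo = de_novo, bulk_proxy = bulk_proxy,
    shared_daughter_flags = shared_flags, vaf_diagnostics = vaf_diag,
    matrix96 = matrix96, matrix6 = matrix6,
    inventory = inventory, enrichment = enrichment,
    clusters = clusters, tmb = tmb, activities = activities,
    comparisons = comparisons,
    meta = list(config_hash = config_hash(config), seed = config$seed))

  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(c(bundle$filter_report, bundle$meta),
                       out("filter_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_catalog(bundle$matrix96, out("catalog96.tsv"))
  for (clone in names(bundle$de_novo))
    write_mutation_table(bundle$de_novo[[clone]],
                         out(paste0("denovo_", clone, ".tsv")))
  enr <- unlist(bundle$enrichment, recursive = FALSE)
  if (length(enr)) write_enrichment(enr, out("enrichment.tsv"))
  for (clone in names(bundle$clusters)) {
    if (is.null(bundle$clusters[[clone]])) next
    write_clusters(bundle$clusters[[clone]],
                   out(paste0("clusters_", clone, ".tsv")))
  }
  if (!is.null(bundle$activities))
    write_activities(bundle$activities, out("activities.tsv"))
  if (!is.null(bundle$comparisons))
    write.table(bundle$comparisons, out("comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(config$out_dir)
}
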