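#' Build a synthetic reference signature set
#'
#' Ships deterministic stand-ins for the signature shapes the analysis
#' assumes (no COSMIC data are bundled): `SBS2L`, APOBEC3-like C>T at TCN
#' contexts; `SBS13L`, APOBEC3-like C>G at TCN; `SBS5L`, a flat clock-like
#' profile; plus `n_extra` random peaked signatures (mass concentrated on a
#' few channels) for refitting benchmarks.
#'
#' @param n_extra number of additional random peaked signatures (default 0)
#' @param seed RNG seed for the random signatures
#' @return a `signature_set` (96 x (3 + n_extra))
#' @export
synthetic_signature_set <- function(n_extra = 0, seed = NULL) {
  chan <- channels(96)
  base <- 0.05 / 96
  mk_tcn <- function(cls) {
    v <- rep(base, 96)
    tcn <- paste0("T[", cls, "]", BASES)
    v[match(tcn, chan)] <- 0.95 * c(0.35, 0.15, 0.10, 0.40)
    v / sum(v)
  }
  sbs2 <- mk_tcn("C>T")
  sbs13 <- mk_tcn("C>G")
  ## flat profile with a mild pyrimidine-transition tilt
  flat <- rep(1, 96)
  flat[grepl("C>T|T>C", chan)] <- 1.6
  flat <- flat / sum(flat)
  m <- cbind(SBS2L = sbs2, SBS13L = sbs13, SBS5L = flat)
  if (n_extra > 0) {
    extra <- with_seed(seed, {
      vapply(seq_len(n_extra), function(i) {
        v <- rep(base, 96)
        peaks <- sample.int(96, 5)
        v[peaks] <- 0.95 * as.numeric(rmultinom(1, 100, rep(0.2, 5))) / 100
        v / sum(v)
      }, numeric(96))
    })
    colnames(extra) <- paste0("SBS96", LETTERS[seq_len(n_extra) %% 26 + 1],
                              ifelse(seq_len(n_extra) > 26,
                                     seq_len(n_extra), ""))
    m <- cbind(m, extra)
  }
  rownames(m) <- chan
  signature_set(m)
}

#' Default configuration of the synthetic clone-lineage study
#'
#' The defaults describe a small in vitro mutation-accumulation experiment:
#' two parent clones expanded and re-cloned into daughters, clonal VAFs near
#' 0.5 with binomial read sampling at ~30x depth, an SBS5-like flat mutation
#' background in every daughter, episodic APOBEC3-like (SBS2/SBS13) bursts
#' in a subset of daughters (heavy-tailed log-normal burden), shared
#' germline and parent-private variants that the lineage filters must
#' remove, a tunable artifact fraction exercising the locus filters, and
#' optionally injected kataegis/omikli clusters. Injected cluster IMDs
#' default to a short 2-20 bp range: the synthetic genome compresses
#' genomic scale while keeping desk-scale mutation counts, so cluster IMDs
#' are compressed by the same factor to preserve the chance-versus-clustered
#' contrast of real samples (see the package vignette).
#'
#' @param ... overrides of any default field
#' @return a `sim_config` list
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    n_parents = 2,
    daughters_per_parent = 4,
    days_propagated = 60,
    parent_groups = NULL,          # genotype label per parent, recycled
    flat_burden = 800,             # SBS5-like de novo SBS per daughter
    apobec_burden_meanlog = log(800),
    apobec_burden_sdlog = 0.6,     # episodic burst size (log-normal)
    episode_prob = 0.6,            # fraction of daughters with a burst
    apobec_groups = NULL,          # genotype groups capable of bursts
                                   # (NULL: all groups)
    apobec_ct_share = 0.6,         # SBS2L vs SBS13L split within a burst
    n_kataegis = 0, n_omikli = 0,  # injected clusters per daughter
    kataegis_members = 8:20,
    omikli_members = 2:3,
    cluster_imd_range = c(2, 20),
    cluster_apobec_prob = 0.8,     # aim cluster members at TC sites
    n_germline = 400,
    n_parent_private = 250,
    germline_leak = 0.15,          # fraction of germline loci leaking into
                                   # call tables (removed by filter 5)
    parent_leak = 0.10,
    depth_mean = 30,
    clonal_vaf = 0.5,
    subclone_mix = 0,              # fraction of de novo SBS at half VAF
    shared_subclone = FALSE,       # two daughters share an undeclared
                                   # subclone (shared fraction > 0.30)
    artifact_fraction = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(errorCondition(paste0("unknown sim_config field(s): ",
                               paste(unknown, collapse = ", ")),
                        class = c("apomut_bad_config", "error")))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. base sampling at the configured composition; deterministic from
#' the seed.
#'
#' @param config a `sim_config` (uses `chrom_lengths` and `composition`),
#'   or a named numeric vector of chromosome lengths
#' @param seed RNG seed
#' @return a `ref_genome`
#' @export
simulate_genome <- function(config, seed = NULL) {
  if (is.numeric(config)) config <- sim_config(chrom_lengths = config)
  lens <- config$chrom_lengths
  if (any(lens <= 0) || length(lens) == 0)
    stop(errorCondition("chromosome lengths must be positive",
                        class = c("apomut_bad_config", "error")))
  comp <- config$composition / sum(config$composition)
  seqs <- with_seed(seed, {
    lapply(lens, function(L)
      intToUtf8(utf8ToInt(paste(BASES, collapse = ""))[
        sample.int(4, L, replace = TRUE, prob = comp)]))
  })
  ref_genome(setNames(unlist(seqs), names(lens)))
}

## place n mutations channel-first: draw 96-channels from `probs`, then a
## uniformly random genomic site matching each channel's trinucleotide
## context. Returns data.frame(chrom, pos, ref, alt, class96).
place_by_channel <- function(n, probs, genome, sig_label = NA_character_) {
  chan <- channels(96)
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class96 = character(0), signature = character(0)))
  counts <- as.integer(rmultinom(1, n, probs))
  lens <- seq_lengths(genome)
  out <- list()
  for (j in which(counts > 0)) {
    lab <- chan[j]
    ctx <- paste0(substring(lab, 1, 1), substring(lab, 3, 3),
                  substring(lab, 7, 7))
    pyr_alt <- substring(lab, 5, 5)
    ## split the channel's mutations over chromosomes by length
    ch_of <- sample(names(lens), counts[j], replace = TRUE,
                    prob = lens / sum(lens))
    for (ch in unique(ch_of)) {
      k <- sum(ch_of == ch)
      seq <- get_chrom(genome, ch)
      res <- sample_context_positions(seq, setNames(list(k), ctx))
      pos <- res$positions[[ctx]]
      if (length(pos) == 0) next
      centre <- substring(seq, pos, pos)
      is_pyr <- centre %in% c("C", "T")
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, pos = pos, ref = centre,
        alt = ifelse(is_pyr, pyr_alt, comp_base(pyr_alt)),
        class96 = lab, signature = sig_label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class96 = character(0), signature = character(0)))
  do.call(rbind, out)
}

## one injected cluster: a run of `k` members with gaps drawn from
## imd_range, strand-coordinated (all pyrimidine-strand cytosine
## substitutions where the genome allows), preferentially at TC dinucleotide
## sites
place_cluster <- function(genome, k, imd_range, apobec_prob) {
  lens <- seq_lengths(genome)
  ch <- sample(names(lens), 1, prob = lens / sum(lens))
  seq <- get_chrom(genome, ch)
  gaps <- sample(seq(imd_range[1], imd_range[2]), k - 1, replace = TRUE)
  span <- sum(gaps)
  start <- sample.int(lens[[ch]] - span - 4L, 1) + 2L
  pos <- start + c(0L, cumsum(gaps))
  ref <- substring(seq, pos, pos)
  ## pyrimidine-strand C>T / C>G at C or G sites, T>C otherwise
  alt <- ifelse(ref == "C", sample(c("T", "G"), k, TRUE, c(0.7, 0.3)),
         ifelse(ref == "G", sample(c("A", "C"), k, TRUE, c(0.7, 0.3)),
         ifelse(ref == "T", "C", "G")))
  data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## sequencing-read model for one batch of variant records present in their
## own sample; guarantees locus-filter-clean quality fields. Clustered
## mutations arise together on one strand, so their members share the
## clonal fraction with only rounding noise (noiseless = TRUE) instead of
## independent binomial sampling.
read_model <- function(n, cfg, vaf = cfg$clonal_vaf, noiseless = FALSE) {
  depth <- pmax(rpois(n, cfg$depth_mean), 6L)
  mut <- if (noiseless) pmin(pmax(round(depth * vaf), 2L), depth)
         else pmin(pmax(rbinom(n, depth, vaf), 2L), depth)
  fwd <- 1L + rbinom(n, mut - 2L, 0.5)
  data.frame(
    depth = depth, mut_fwd = fwd, mut_rev = mut - fwd,
    asmd = sample(131:170, n, replace = TRUE),
    clpm = 0,
    ref_sample_depth = pmax(rpois(n, cfg$depth_mean), 16L),
    pass_flag = TRUE)
}

## degrade a fraction of records into locus-filter artifacts (one failure
## mode each, chosen uniformly)
apply_artifacts <- function(df, cfg) {
  n <- nrow(df)
  hit <- which(runif(n) < cfg$artifact_fraction)
  if (!length(hit)) { df$artifact <- FALSE; return(df) }
  type <- sample(c("asmd", "clpm", "refcov", "direction"),
                 length(hit), replace = TRUE)
  i <- hit[type == "asmd"]
  df$asmd[i] <- sample(90:130, length(i), replace = TRUE)
  i <- hit[type == "clpm"]
  df$clpm[i] <- sample(1:3, length(i), replace = TRUE)
  i <- hit[type == "refcov"]
  df$ref_sample_depth[i] <- sample(0:15, length(i), replace = TRUE)
  i <- hit[type == "direction"]
  flip <- runif(length(i)) < 0.5
  df$mut_fwd[i] <- ifelse(flip, df$mut_fwd[i] + df$mut_rev[i], 0L)
  df$mut_rev[i] <- ifelse(flip, 0L, df$mut_fwd[i] + df$mut_rev[i])
  df$artifact <- seq_len(n) %in% hit
  df
}

#' Simulate a complete clone-lineage study with recorded ground truth
#'
#' Generates, per clone, the caller-style mutation table the pipeline
#' consumes, together with the manifest, the cgpVAF-style genotype table
#' across all clones, and truth tables giving each emitted record's
#' provenance (germline / parental / de novo, generating signature, cluster
#' membership, artifact status). See [sim_config()] for the model.
#'
#' Germline variants are genotypable in every clone including the unrelated
#' normal; parent-private variants in their whole lineage; daughter de novo
#' mutations are drawn channel-first from the daughter's signature mixture
#' and placed at context-matched sites, so the generating mixture is exactly
#' the sampling distribution of the emitted 96-channel catalogue.
#'
#' @param config a `sim_config`
#' @param genome a `ref_genome` (e.g. from [simulate_genome()])
#' @param refs a `signature_set` containing at least `SBS2L`, `SBS13L`,
#'   `SBS5L` (see [synthetic_signature_set()])
#' @param seed RNG seed; the study is deterministic given it
#' @return list with `mutations` (one `sbs_records` table, all clones),
#'   `manifest` (`clone_manifest`), `genotypes` (locus x clone read counts),
#'   `truth` (per-record provenance), `genome_mb`
#' @export
simulate_study <- function(config, genome, refs, seed = NULL) {
  cfg <- config
  with_seed(seed, {
    ## ---- manifest -------------------------------------------------------
    parents <- paste0("P", seq_len(cfg$n_parents))
    groups <- if (is.null(cfg$parent_groups)) rep("WT", cfg$n_parents)
              else rep(cfg$parent_groups, length.out = cfg$n_parents)
    man <- list()
    for (i in seq_along(parents)) {
      man[[length(man) + 1]] <- data.frame(
        cell_line = "CL1", clone_id = parents[i], role = "parent",
        lineage_id = paste0("L", i), parent_id = NA_character_,
        reference_id = "NORM", days_propagated = cfg$days_propagated,
        group = groups[i])
      for (j in seq_len(cfg$daughters_per_parent)) {
        man[[length(man) + 1]] <- data.frame(
          cell_line = "CL1", clone_id = paste0(parents[i], ".D", j),
          role = "daughter", lineage_id = paste0("L", i),
          parent_id = parents[i], reference_id = parents[i],
          days_propagated = cfg$days_propagated, group = groups[i])
      }
    }
    manifest <- clone_manifest(do.call(rbind, man))
    daughters <- manifest$clone_id[manifest$role == "daughter"]

    ## ---- shared variant sets -------------------------------------------
    lens <- seq_lengths(genome)
    rand_sites <- function(n) {
      ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
      pos <- vapply(ch, function(c2) sample.int(lens[[c2]] - 4L, 1) + 2L,
                    integer(1))
      ref <- mapply(function(c2, p) substring(get_chrom(genome, c2), p, p),
                    ch, pos)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                    character(1))
      data.frame(chrom = ch, pos = as.integer(pos), ref = ref, alt = alt,
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    germline <- rand_sites(cfg$n_germline)
    parent_private <- setNames(
      lapply(parents, function(p) rand_sites(cfg$n_parent_private)),
      parents)

    ## carriers of each truth variant (for genotyping)
    carrier_sets <- list()
    add_carriers <- function(df, clones, origin) {
      if (nrow(df) == 0) return(invisible())
      carrier_sets[[length(carrier_sets) + 1]] <<- data.frame(
        locus = paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"),
        clones = I(rep(list(clones), nrow(df))), origin = origin)
    }
    all_clones <- c(manifest$clone_id, "NORM")
    add_carriers(germline, all_clones, "germline")
    for (p in parents) {
      lineage <- c(p, daughters[startsWith(daughters, paste0(p, "."))])
      add_carriers(parent_private[[p]], lineage, "parental")
    }

    ## ---- per-clone call tables -----------------------------------------
    mix_names <- c("SBS2L", "SBS13L", "SBS5L")
    stopifnot(all(mix_names %in% colnames(refs)))
    tables <- list(); truth <- list()
    emit <- function(sample_id, sites, origin, signature = NA, cluster_id = NA,
                     cluster_class = NA, vaf = cfg$clonal_vaf,
                     in_reference = FALSE, noiseless = FALSE) {
      n <- nrow(sites)
      if (n == 0) return(invisible())
      rm_ <- read_model(n, cfg, vaf, noiseless)
      rec <- data.frame(
        sample_id = sample_id, chrom = sites$chrom, pos = sites$pos,
        ref = sites$ref, alt = sites$alt,
        mut_fwd = rm_$mut_fwd, mut_rev = rm_$mut_rev, depth = rm_$depth,
        ref_sample_depth = rm_$ref_sample_depth,
        ref_sample_mut = if (in_reference)
          pmax(1L, rbinom(n, rm_$ref_sample_depth, cfg$clonal_vaf))
          else 0L,
        asmd = rm_$asmd, clpm = rm_$clpm, pass_flag = rm_$pass_flag,
        stringsAsFactors = FALSE)
      rec <- apply_artifacts(rec, cfg)
      tables[[length(tables) + 1]] <<- rec
      truth[[length(truth) + 1]] <<- data.frame(
        sample_id = sample_id,
        locus = paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                      sep = ":"),
        origin = origin,
        signature = if (length(signature) == 1) rep(signature, n)
                    else signature,
        cluster_id = if (length(cluster_id) == 1) rep(cluster_id, n)
                     else cluster_id,
        cluster_class = if (length(cluster_class) == 1)
          rep(cluster_class, n) else cluster_class,
        artifact = rec$artifact, stringsAsFactors = FALSE)
    }

    sig_mix <- function(n_apobec, n_flat) {
      ## per-mutation generating signature, then channel-first placement
      sigs <- c(rep("SBS2L", rbinom(1, n_apobec, cfg$apobec_ct_share)))
      sigs <- c(sigs, rep("SBS13L", n_apobec - length(sigs)),
                rep("SBS5L", n_flat))
      do.call(rbind, lapply(unique(sigs), function(s)
        place_by_channel(sum(sigs == s), unclass(refs)[, s], genome, s)))
    }

    cluster_counter <- 0L
    shared_pool <- NULL
    ## de novo sites must not collide with pre-existing loci (the filters
    ## would rightly treat them as inherited) nor with other clones'
    ## private sites
    site_key <- function(df) paste(df$chrom, df$pos, sep = ":")
    reserved <- c(site_key(germline),
                  unlist(lapply(parent_private, site_key)))
    claim_sites <- function(sites) {
      keep <- !duplicated(site_key(sites)) & !site_key(sites) %in% reserved
      sites <- sites[keep, , drop = FALSE]
      reserved <<- c(reserved, site_key(sites))
      sites
    }
    for (ci in seq_len(nrow(manifest))) {
      clone <- manifest$clone_id[ci]
      role <- manifest$role[ci]
      if (role == "parent") {
        emit(clone, parent_private[[clone]], "parental")
        leak <- germline[runif(nrow(germline)) < cfg$germline_leak, ,
                         drop = FALSE]
        emit(clone, leak, "germline", in_reference = TRUE)
      } else {
        capable <- is.null(cfg$apobec_groups) ||
          manifest$group[ci] %in% cfg$apobec_groups
        burst <- capable && runif(1) < cfg$episode_prob
        n_apo <- if (burst)
          round(stats::rlnorm(1, cfg$apobec_burden_meanlog,
                              cfg$apobec_burden_sdlog)) else 0L
        denovo <- claim_sites(sig_mix(n_apo, cfg$flat_burden))
        vafs <- rep(cfg$clonal_vaf, nrow(denovo))
        if (cfg$subclone_mix > 0)
          vafs[runif(length(vafs)) < cfg$subclone_mix] <- cfg$clonal_vaf / 2
        emit(clone, denovo[, c("chrom", "pos", "ref", "alt")], "denovo",
             signature = denovo$signature, vaf = vafs)
        ## injected clusters
        for (type in c("kataegis", "omikli")) {
          n_ev <- if (type == "kataegis") cfg$n_kataegis else cfg$n_omikli
          members_rng <- if (type == "kataegis") cfg$kataegis_members
                         else cfg$omikli_members
          for (e in seq_len(n_ev)) {
            cluster_counter <- cluster_counter + 1L
            k <- if (length(members_rng) == 1) members_rng
                 else sample(members_rng, 1)
            sites <- claim_sites(place_cluster(genome, k,
                                               cfg$cluster_imd_range,
                                               cfg$cluster_apobec_prob))
            emit(clone, sites, "denovo", signature = "cluster",
                 cluster_id = paste0("cl", cluster_counter),
                 cluster_class = type, noiseless = TRUE)
          }
        }
        ## undeclared shared subclone between the first two daughters
        if (isTRUE(cfg$shared_subclone) && clone %in% daughters[1:2]) {
          if (clone == daughters[1]) {
            n_sh <- max(1L, round(0.6 * (nrow(denovo) + 1)))
            shared_pool <- claim_sites(sig_mix(0, n_sh))
          }
          emit(clone, shared_pool[, c("chrom", "pos", "ref", "alt")],
               "shared_subclone", signature = shared_pool$signature)
        }
        ## leaked pre-existing variation (removed by filters 5/6)
        leak_g <- germline[runif(nrow(germline)) < cfg$germline_leak, ,
                           drop = FALSE]
        emit(clone, leak_g, "germline", in_reference = TRUE)
        pp <- parent_private[[manifest$parent_id[ci]]]
        leak_p <- pp[runif(nrow(pp)) < cfg$parent_leak, , drop = FALSE]
        emit(clone, leak_p, "parental", in_reference = TRUE)
      }
    }
    mutations <- sbs_records(do.call(rbind, tables))
    truth <- do.call(rbind, truth)

    ## ---- genotype table across all clones ------------------------------
    carriers <- if (length(carrier_sets)) do.call(rbind, carrier_sets)
                else data.frame(locus = character(0),
                                clones = I(list()), origin = character(0))
    ## de novo (incl. clusters, shared subclone) carried by emitting clone(s)
    dn <- truth[truth$origin %in% c("denovo", "shared_subclone"), ,
                drop = FALSE]
    dn_car <- tapply(dn$sample_id, dn$locus, function(s) unique(s))
    loci <- unique(c(carriers$locus, names(dn_car),
                     truth$locus))
    carrier_of <- setNames(vector("list", length(loci)), loci)
    for (i in seq_len(nrow(carriers)))
      carrier_of[[carriers$locus[i]]] <-
        union(carrier_of[[carriers$locus[i]]], carriers$clones[[i]])
    for (l in names(dn_car))
      carrier_of[[l]] <- union(carrier_of[[l]], dn_car[[l]])
    gt <- expand.grid(locus = loci, clone_id = all_clones,
                      stringsAsFactors = FALSE)
    present <- mapply(function(l, c2) c2 %in% carrier_of[[l]],
                      gt$locus, gt$clone_id)
    gt$total_reads <- pmax(rpois(nrow(gt), cfg$depth_mean), 8L)
    gt$mut_reads <- ifelse(present,
                           pmax(1L, rbinom(nrow(gt), gt$total_reads,
                                           cfg$clonal_vaf)), 0L)
    gt <- gt[, c("locus", "clone_id", "mut_reads", "total_reads")]

    list(mutations = mutations, manifest = manifest, genotypes = gt,
         truth = truth, genome_mb = sum(lens) / 1e6)
  })
}

#' Write truth tables as TSV
#' @param truth truth data.frame from [simulate_study()]
#' @param path output path
#' @return `path` invisibly
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
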