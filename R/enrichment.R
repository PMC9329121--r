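APOBEC_MOTIFS <- c("TCN", "TCA", "YTCA", "RTCA")

## availability of a motif from a context inventory
motif_availability <- function(inventory, motif) {
  tri <- inventory$tri_counts
  switch(motif,
    TCN = sum(tri[c("TCA", "TCC", "TCG", "TCT")]),
    TCA = unname(tri["TCA"]),
    YTCA = ,
    RTCA = {
      penta <- inventory$penta_counts
      if (is.null(penta))
        stop(errorCondition(
          "YTCA/RTCA availability needs a pentanucleotide inventory (flank=2)",
          class = c("apomut_bad_flank", "error")))
      two5 <- if (motif == "YTCA") c("C", "T") else c("A", "G")
      ## pentanucleotide keys x2 x1 C y1 y2: the motif fixes x2 in two5,
      ## x1 = T, y1 = A; the 3'-most base y2 is marginalized
      keys <- names(penta)
      sel <- substring(keys, 1, 1) %in% two5 &
             substring(keys, 2, 2) == "T" &
             substring(keys, 3, 3) == "C" &
             substring(keys, 4, 4) == "A"
      sum(penta[sel])
    },
    stop(errorCondition(paste0("unknown motif: ", motif),
                        class = c("apomut_bad_motif", "error")))
  )
}

## does a pyrimidine-strand context match a motif? ctx is the flank-2
## (pentanucleotide) context for YTCA/RTCA, flank-1 (trinucleotide) for
## TCN/TCA; central base is C for all qualifying mutations
motif_match <- function(ctx, motif) {
  switch(motif,
    TCN = substring(ctx, 1, 2) == "TC",
    TCA = ctx == "TCA",
    YTCA = substring(ctx, 1, 1) %in% c("C", "T") &
           substring(ctx, 2, 4) == "TCA",
    RTCA = substring(ctx, 1, 1) %in% c("A", "G") &
           substring(ctx, 2, 4) == "TCA")
}

#' Fold enrichment of cytosine mutations at an APOBEC3-associated motif
#'
#' Computes `E_motif = (Mut_motif / Con_motif) / (Mut_C / Con_C)` where
#' `Mut_motif` is the number of qualifying mutations whose pyrimidine-strand
#' context matches the motif, `Mut_C` the total number of qualifying
#' cytosine mutations, and `Con_motif`, `Con_C` the genome-wide availability
#' of the motif and of cytosine-centred sites from a [count_contexts()]
#' inventory. Qualifying mutations are pyrimidine-strand C>T and C>G only:
#' C>A at TCN is excluded because that class also arises from
#' non-APOBEC in vitro processes.
#'
#' YTCA/RTCA availability is marginalized from the pentanucleotide inventory
#' over the 3'-most base (the motif is 4 bp; identical to counting 4-mers
#' directly).
#'
#' @param records an `sbs_records` data.frame
#' @param inventory a `context_inventory` (flank 2 required for YTCA/RTCA)
#' @param motif one of `"TCN"`, `"TCA"`, `"YTCA"`, `"RTCA"`
#' @param genome a `ref_genome` (provides mutation contexts)
#' @param chromosomes optional record filter; use the same subset the
#'   inventory was counted on (e.g. autosomes)
#' @return an `enrichment_result`: list with `motif`, `mut_motif`, `mut_c`,
#'   `con_motif`, `con_c`, `e_value` and `status`
#'   (`ok` / `insufficient_data`). `e_value` is `NA` when a denominator is
#'   zero — never a division by zero.
#' @export
compute_enrichment <- function(records, inventory, motif, genome,
                               chromosomes = NULL) {
  motif <- match.arg(motif, APOBEC_MOTIFS)
  if (!is.null(chromosomes))
    records <- records[records$chrom %in% chromosomes, , drop = FALSE]
  flank <- if (motif %in% c("YTCA", "RTCA")) 2L else 1L
  con_motif <- motif_availability(inventory, motif)
  con_c <- inventory$c_total

  qual <- which(records$ref %in% c("C", "G") &
                !(paste0(records$ref, ">", records$alt) %in%
                  c("C>A", "G>T")))
  mut_c <- 0L; mut_motif <- 0L
  if (length(qual)) {
    q <- records[qual, , drop = FALSE]
    ctx <- rep(NA_character_, nrow(q))
    for (ch in unique(q$chrom)) {
      i <- which(q$chrom == ch)
      L <- nchar(get_chrom(genome, ch))
      inb <- q$pos[i] - flank >= 1 & q$pos[i] + flank <= L
      if (any(inb))
        ctx[i[inb]] <- context_at(genome, ch, q$pos[i][inb], flank)$context
    }
    ok <- !is.na(ctx)
    mut_c <- sum(ok)
    mut_motif <- sum(motif_match(ctx[ok], motif))
  }
  insufficient <- con_motif == 0 || mut_c == 0 || con_c == 0
  e <- if (insufficient) NA_real_
       else (mut_motif / con_motif) / (mut_c / con_c)
  structure(list(motif = motif, mut_motif = mut_motif, mut_c = mut_c,
                 con_motif = con_motif, con_c = con_c, e_value = e,
                 status = if (insufficient) "insufficient_data" else "ok"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> E_%s = %s  (Mut=%d/%d, Con=%g/%g) [%s]\n",
              x$motif, format(x$e_value, digits = 4), x$mut_motif, x$mut_c,
              x$con_motif, x$con_c, x$status))
  invisible(x)
}

#' YTCA vs RTCA enrichment profile
#'
#' Convenience wrapper contrasting the tetranucleotide preferences of
#' APOBEC3A (YTCA) and APOBEC3B (RTCA): returns both enrichments and their
#' ratio `E_YTCA / E_RTCA`. When `E_RTCA` is 0 with `E_YTCA` > 0 the ratio
#' is reported as `Inf` (flagged); undefined inputs propagate as `NA`.
#'
#' @inheritParams compute_enrichment
#' @return list with `E_YTCA`, `E_RTCA` ([compute_enrichment()] results) and
#'   `ratio`
#' @export
ytca_rtca_profile <- function(records, inventory, genome,
                              chromosomes = NULL) {
  ey <- compute_enrichment(records, inventory, "YTCA", genome, chromosomes)
  er <- compute_enrichment(records, inventory, "RTCA", genome, chromosomes)
  ratio <- if (is.na(ey$e_value) || is.na(er$e_value)) NA_real_
           else if (er$e_value == 0) Inf
           else ey$e_value / er$e_value
  list(E_YTCA = ey, E_RTCA = er, ratio = ratio)
}

#' Write enrichment results as TSV (all count fields, never E alone)
#' @param results list of `enrichment_result` objects
#' @param path file path
#' @return `path` invisibly
#' @export
write_enrichment <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(motif = r$motif, mut_motif = r$mut_motif, mut_c = r$mut_c,
               con_motif = r$con_motif, con_c = r$con_c,
               e_value = r$e_value, status = r$status)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
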