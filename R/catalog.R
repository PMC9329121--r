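BASES <- c("A", "C", "G", "T")
CLASS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
STRAND288 <- c("T", "U", "N")

MUTATION_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt",
                      "mut_fwd", "mut_rev", "depth",
                      "ref_sample_depth", "ref_sample_mut",
                      "asmd", "clpm", "pass_flag")

#' Validate a table of single-base substitution records
#'
#' An SBS record is one somatic substitution call carrying read-level quality
#' fields: mutant-supporting read counts by direction (`mut_fwd`, `mut_rev`),
#' total depth, depth and mutant reads in the comparison reference sample,
#' the median alignment score of mutation-reporting reads (`asmd`), the
#' clipping index (`clpm`) and the panel-of-normals PASS flag. The variant
#' allele fraction `vaf = (mut_fwd + mut_rev) / depth` is (re)computed here.
#'
#' @param df data.frame with the columns listed above plus `sample_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`
#' @return the validated data.frame with a `vaf` column, class `sbs_records`
#' @export
sbs_records <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(MUTATION_COLUMNS, names(df))
  if (length(missing))
    stop(errorCondition(paste0("missing mutation-table column(s): ",
                               paste(missing, collapse = ", ")),
                        class = c("apomut_missing_field", "error")))
  if (!all(df$ref %in% BASES) || !all(df$alt %in% BASES))
    stop(errorCondition("ref/alt must be single bases in {A,C,G,T}",
                        class = c("apomut_bad_allele", "error")))
  if (any(df$ref == df$alt))
    stop(errorCondition("ref must differ from alt",
                        class = c("apomut_bad_allele", "error")))
  if (any(df$mut_fwd + df$mut_rev > df$depth))
    stop(errorCondition("mutant reads exceed depth",
                        class = c("apomut_bad_counts", "error")))
  df$pos <- as.integer(df$pos)
  df$pass_flag <- as.logical(df$pass_flag)
  df$vaf <- ifelse(df$depth > 0, (df$mut_fwd + df$mut_rev) / df$depth, 0)
  class(df) <- c("sbs_records", "data.frame")
  df
}

#' Read / write mutation tables (TSV)
#'
#' Plain TSV with one row per SBS call and the column contract of
#' [sbs_records()].
#'
#' @param path file path
#' @return an `sbs_records` data.frame (reader); `path` invisibly (writer)
#' @export
read_mutation_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  sbs_records(df)
}

#' @rdname read_mutation_table
#' @param records an `sbs_records` data.frame
#' @export
write_mutation_table <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF into SBS records
#'
#' Accepts the small VCF subset used by somatic-caller exports: CHROM, POS,
#' REF, ALT plus INFO keys `ASMD` and `CLPM`, the FILTER column (PASS) and
#' per-sample FORMAT fields `DP` (depth), `MF`/`MR` (mutant reads forward /
#' reverse). The first genotype column is the test sample; the second, when
#' present, is the comparison reference sample (its DP and mutant total fill
#' `ref_sample_depth` / `ref_sample_mut`). Parsing is delegated to
#' VariantAnnotation.
#'
#' @param path VCF path (uncompressed or bgzipped)
#' @param sample_id sample identifier to assign; defaults to the first
#'   genotype column name
#' @return an `sbs_records` data.frame
#' @export
read_vcf_min <- function(path, sample_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_min() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  if (is.null(sample_id)) sample_id <- samples[1]
  ref_col <- if (length(samples) >= 2) 2L else NA_integer_
  df <- data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    mut_fwd = as.integer(geno$MF[, 1]),
    mut_rev = as.integer(geno$MR[, 1]),
    depth = as.integer(geno$DP[, 1]),
    ref_sample_depth = if (is.na(ref_col)) NA_integer_
                       else as.integer(geno$DP[, ref_col]),
    ref_sample_mut = if (is.na(ref_col)) NA_integer_
                     else as.integer(geno$MF[, ref_col]) +
                          as.integer(geno$MR[, ref_col]),
    asmd = as.numeric(info$ASMD),
    clpm = as.numeric(info$CLPM),
    pass_flag = rr$FILTER == "PASS",
    stringsAsFactors = FALSE
  )
  sbs_records(df)
}

#' Channel labels of the 6/96/288/1536 classification systems
#'
#' Orderings are fixed (alphabetical flanks within `C>A, C>G, C>T, T>A, T>C,
#' T>G` blocks; 288 = strand category `T:`/`U:`/`N:` times 96) so matrices
#' from different runs are directly comparable. Labels follow the
#' SigProfiler-style `A[C>A]A` convention.
#'
#' @param system 6, 96, 288 or 1536
#' @return character vector of channel labels in canonical order
#' @export
channels <- function(system) {
  system <- as.integer(system)
  if (system == 6L) return(CLASS6)
  if (system == 96L) {
    return(unlist(lapply(CLASS6, function(cl)
      as.vector(t(outer(BASES, BASES, function(f5, f3)
        paste0(f5, "[", cl, "]", f3)))))))
  }
  if (system == 288L) {
    return(unlist(lapply(STRAND288, function(s)
      paste0(s, ":", channels(96L)))))
  }
  if (system == 1536L) {
    di <- sort(do.call(paste0, expand.grid(BASES, BASES,
                                           stringsAsFactors = FALSE)))
    return(unlist(lapply(CLASS6, function(cl)
      as.vector(t(outer(di, di, function(f5, f3)
        paste0(f5, "[", cl, "]", f3)))))))
  }
  stop(errorCondition("system must be one of 6, 96, 288, 1536",
                      class = c("apomut_bad_system", "error")))
}

#' Classify SBS records into sequence-context channels
#'
#' Each substitution is expressed with the mutated base as the pyrimidine of
#' its base pair: purine reference bases are complemented and the flanking
#' window reverse-complemented before channel naming. The assignment carries
#' all four systems at once: `class6` (C>A..T>G), `class96`
#' (5'flank\[pyr>alt\]3'flank), `class1536` (two flanking bases each side)
#' and `class288` (`class96` crossed with the transcriptional strand
#' category).
#'
#' Strand categories require a stranded transcript annotation
#' (`tx_annotation`: data.frame `chrom`, `start`, `end`, `strand`). A
#' pyrimidine-strand mutation lying on the template (transcribed) strand of a
#' gene is `T`, on the coding strand `U`, outside genes `N`; positions
#' covered by genes on both strands are assigned `N` (ambiguous). Without an
#' annotation every record is `N`.
#'
#' @param records an `sbs_records` data.frame
#' @param genome a `ref_genome` (reference bases are checked against `ref`;
#'   a mismatch signals a wrong genome build and is an error)
#' @param tx_annotation optional stranded interval data.frame
#' @return data.frame with columns `class6`, `class96`, `class288`,
#'   `class1536`, `collapsed`. Records whose window contains N or falls
#'   within 2 bp of a sequence end carry NA classes; their count is in
#'   `attr(, "excluded")`.
#' @export
classify_sbs <- function(records, genome, tx_annotation = NULL) {
  n <- nrow(records)
  cls6 <- cls96 <- cls1536 <- strand <- rep(NA_character_, n)
  collapsed <- rep(NA, n)
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch)
    seq <- get_chrom(genome, ch)
    L <- nchar(seq)
    pos <- records$pos[idx]
    if (any(pos < 1L | pos > L))
      stop(errorCondition(paste0("position outside chromosome ", ch),
                          class = c("apomut_out_of_range", "error")))
    refbase <- substring(seq, pos, pos)
    stated_ref <- records$ref[idx]
    stated_alt <- records$alt[idx]
    ## records may be stated on either strand: accept the complement of the
    ## genome base and re-express on the plus strand before classification
    minus <- stated_ref != refbase & comp_base(stated_ref) == refbase
    stated_ref[minus] <- comp_base(stated_ref[minus])
    stated_alt[minus] <- comp_base(stated_alt[minus])
    bad <- refbase != stated_ref
    if (any(bad))
      stop(errorCondition(
        paste0("reference base mismatch at ", ch, ":",
               paste(utils::head(pos[bad], 3), collapse = ","),
               " (wrong genome build?)"),
        class = c("apomut_ref_mismatch", "error")))
    flip <- stated_ref %in% c("A", "G")
    alt <- stated_alt
    alt[flip] <- comp_base(alt[flip])
    ref <- stated_ref
    ref[flip] <- comp_base(ref[flip])
    mid <- paste0("[", ref, ">", alt, "]")
    cls6[idx] <- paste0(ref, ">", alt)
    collapsed[idx] <- flip
    ## 3-bp window for the 96 system, 5-bp for the 1536 system; a window
    ## that runs off the sequence or contains N drops only the systems
    ## that need it
    for (fl in c(1L, 2L)) {
      ok <- pos - fl >= 1L & pos + fl <= L
      win <- rep(NA_character_, length(pos))
      if (any(ok)) win[ok] <- substring(seq, pos[ok] - fl, pos[ok] + fl)
      win[grepl("N", win, fixed = TRUE)] <- NA
      use <- !is.na(win)
      w <- win
      if (any(use & flip)) w[use & flip] <- revcomp(win[use & flip])
      if (fl == 1L) {
        val <- rep(NA_character_, length(pos))
        val[use] <- paste0(substring(w[use], 1, 1), mid[use],
                           substring(w[use], 3, 3))
        cls96[idx] <- val
      } else {
        val <- rep(NA_character_, length(pos))
        val[use] <- paste0(substring(w[use], 1, 2), mid[use],
                           substring(w[use], 4, 5))
        cls1536[idx] <- val
      }
    }
    strand[idx] <- tx_strand_category(ch, records$pos[idx], flip,
                                      tx_annotation)
  }
  cls288 <- ifelse(is.na(cls96), NA, paste0(strand, ":", cls96))
  out <- data.frame(class6 = cls6, class96 = cls96, class288 = cls288,
                    class1536 = cls1536, collapsed = collapsed,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- sum(is.na(cls96))
  out
}

## strand category of the pyrimidine-strand mutation w.r.t. transcription:
## pyrimidine on the template strand of a gene -> "T" (transcribed),
## on the coding strand -> "U", intergenic or ambiguous (genes on both
## strands) -> "N"
tx_strand_category <- function(chrom, pos, flip, tx_annotation) {
  if (is.null(tx_annotation)) return(rep("N", length(pos)))
  tx <- tx_annotation[tx_annotation$chrom == chrom, , drop = FALSE]
  if (nrow(tx) == 0) return(rep("N", length(pos)))
  on_plus <- on_minus <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(tx))) {
    inside <- pos >= tx$start[i] & pos <= tx$end[i]
    if (tx$strand[i] == "+") on_plus <- on_plus | inside
    else on_minus <- on_minus | inside
  }
  out <- rep("N", length(pos))
  only_plus <- on_plus & !on_minus
  only_minus <- on_minus & !on_plus
  ## pyrimidine strand is '-' when flipped; template of a '+' gene is '-'
  out[only_plus] <- ifelse(flip[only_plus], "T", "U")
  out[only_minus] <- ifelse(flip[only_minus], "U", "T")
  out
}

#' Build a per-sample mutation-count matrix over a channel system
#'
#' @param records an `sbs_records` data.frame
#' @param system 6, 96, 288 or 1536
#' @param genome a `ref_genome`
#' @param tx_annotation optional stranded intervals (see [classify_sbs()])
#' @param samples optional sample ordering (defaults to order of appearance);
#'   samples with no records yield all-zero rows
#' @return a `catalog_matrix`: integer matrix samples x channels with
#'   attributes `system` and `excluded` (records lost to ambiguous contexts)
#' @export
build_matrix <- function(records, system, genome, tx_annotation = NULL,
                         samples = NULL) {
  chan <- channels(system)
  if (is.null(samples)) samples <- unique(records$sample_id)
  m <- matrix(0L, nrow = length(samples), ncol = length(chan),
              dimnames = list(samples, chan))
  excluded <- 0L
  if (nrow(records) > 0) {
    cl <- classify_sbs(records, genome, tx_annotation)
    key <- switch(as.character(system),
                  "6" = cl$class6, "96" = cl$class96,
                  "288" = cl$class288, "1536" = cl$class1536)
    excluded <- sum(is.na(key))
    keep <- !is.na(key)
    tab <- table(factor(records$sample_id[keep], levels = samples),
                 factor(key[keep], levels = chan))
    m[] <- as.integer(tab)
  }
  structure(m, system = as.integer(system), excluded = excluded,
            class = c("catalog_matrix", class(m)))
}

#' Collapse a catalogue matrix to a coarser channel system
#'
#' 1536- and 288-channel matrices collapse to 96; 96 collapses to 6. The
#' collapse is exact: row sums are preserved.
#'
#' @param mat a `catalog_matrix`
#' @param to target system (must be coarser than `attr(mat, "system")`)
#' @return a `catalog_matrix` over the target system
#' @export
collapse_catalog <- function(mat, to) {
  from <- attr(mat, "system")
  to <- as.integer(to)
  if (is.null(from)) stop("not a catalog_matrix")
  if (to >= from) stop("target system must be coarser")
  key <- colnames(mat)
  map <- switch(as.character(from),
    "1536" = paste0(substring(key, 2, 2), substring(key, 3, 7),
                    substring(key, 8, 8)),
    "288" = substring(key, 3),
    "96" = substring(key, 3, 5),
    stop("cannot collapse from system ", from))
  ## after the first collapse `map` is 96-style ("A[C>A]A"); the class6
  ## label sits at characters 3..5
  if (to == 6L && from != 96L) map <- substring(map, 3, 5)
  ## 1536 -> 96 leaves "A[C>A]A"; 96 -> 6 leaves "C>A"
  chan <- channels(to)
  out <- matrix(0L, nrow = nrow(mat), ncol = length(chan),
                dimnames = list(rownames(mat), chan))
  for (j in seq_along(key)) out[, map[j]] <- out[, map[j]] + mat[, j]
  structure(out, system = to, excluded = attr(mat, "excluded"),
            class = c("catalog_matrix", class(out)))
}

#' Write / read a catalogue matrix as TSV
#'
#' Channels are rows (column `MutationType`), samples are columns —
#' the layout used by signature toolchains.
#'
#' @param mat a `catalog_matrix`
#' @param path file path
#' @return `path` invisibly (writer); a `catalog_matrix` (reader; the system
#'   is inferred from the number of channel rows)
#' @export
write_catalog <- function(mat, path) {
  df <- data.frame(MutationType = colnames(mat),
                   t(unclass(mat)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  system <- nrow(df)
  chan <- channels(system)
  stopifnot(setequal(df$MutationType, chan))
  m <- t(as.matrix(df[match(chan, df$MutationType), -1, drop = FALSE]))
  colnames(m) <- chan
  storage.mode(m) <- "integer"
  structure(m, system = as.integer(system), excluded = NA_integer_,
            class = c("catalog_matrix", class(m)))
}
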