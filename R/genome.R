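#' @importFrom stats density rbinom rpois runif rmultinom quantile setNames
#' @importFrom utils read.table write.table combn
"_PACKAGE"

#' Construct a reference genome object
#'
#' A reference genome is a named set of uppercase nucleotide sequences over
#' the alphabet \{A,C,G,T,N\}, addressed with 1-based, fully closed
#' coordinates. Any FASTA (including fully synthetic sequences) can be used.
#'
#' @param sequences named character vector or list of sequences, one per
#'   chromosome. Lowercase letters are accepted and folded to uppercase.
#' @return an object of class `ref_genome`: a named character vector with the
#'   validated sequences.
#' @examples
#' g <- ref_genome(c(chr1 = "TTCATTCA"))
#' seq_lengths(g)
#' @export
ref_genome <- function(sequences) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("all sequences must be named by chromosome", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("chromosome names must be unique", call. = FALSE)
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence(s) contain letters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "), call. = FALSE)
  structure(sequences, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x), " sequence(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a reference genome
#' @param genome a `ref_genome`
#' @return named integer vector of sequence lengths
#' @export
seq_lengths <- function(genome) {
  vapply(unclass(genome), nchar, integer(1))
}

#' Read a reference genome from FASTA
#'
#' Multi-record, wrapped-line FASTA is supported (parsed with Biostrings).
#'
#' @param path path to a FASTA file
#' @return a `ref_genome`
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  ref_genome(setNames(as.character(ss), nm))
}

#' Write a reference genome to FASTA
#' @param genome a `ref_genome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorized; N is preserved.
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of single bases, vectorized, without DNAStringSet overhead
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

get_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop(errorCondition(paste0("unknown chromosome: ", chrom),
                        class = c("apomut_unknown_chrom", "error")))
  unclass(genome)[[chrom]]
}

#' Pyrimidine-strand sequence context at positions
#'
#' Returns the `2*flank + 1` window centred at each position, expressed on the
#' strand carrying the pyrimidine of the central base pair: if the central
#' reference base is a purine (A/G) the reverse complement of the window is
#' returned and the position is flagged as collapsed. This single kernel
#' drives both genome-wide context counting and per-mutation classification,
#' so availability counts and mutation channels are guaranteed to use the
#' same strand convention.
#'
#' @param genome a `ref_genome`
#' @param chrom chromosome name (scalar)
#' @param pos integer vector of 1-based positions
#' @param flank 1 (trinucleotide) or 2 (pentanucleotide)
#' @param on_ambiguous what to do when the window contains N: `"na"` returns
#'   `NA` for that position, `"error"` raises a condition of class
#'   `apomut_ambiguous_context`.
#' @return data.frame with columns `context` (pyrimidine-strand window) and
#'   `collapsed` (logical: was the window reverse-complemented)
#' @examples
#' g <- ref_genome(c(chr1 = "TTCATTCA"))
#' context_at(g, "chr1", 3:4)
#' @export
context_at <- function(genome, chrom, pos, flank = 1,
                       on_ambiguous = c("na", "error")) {
  on_ambiguous <- match.arg(on_ambiguous)
  if (!flank %in% c(1, 2))
    stop(errorCondition("flank must be 1 or 2",
                        class = c("apomut_bad_flank", "error")))
  seq <- get_chrom(genome, chrom)
  L <- nchar(seq)
  pos <- as.integer(pos)
  if (any(pos - flank < 1L | pos + flank > L))
    stop(errorCondition(
      paste0("position window outside sequence bounds on ", chrom),
      class = c("apomut_out_of_range", "error")))
  win <- substring(seq, pos - flank, pos + flank)
  centre <- substring(seq, pos, pos)
  amb <- grepl("N", win, fixed = TRUE)
  if (any(amb) && on_ambiguous == "error")
    stop(errorCondition("ambiguous context: window contains N",
                        class = c("apomut_ambiguous_context", "error")))
  collapsed <- centre %in% c("A", "G")
  out <- win
  if (any(collapsed & !amb)) {
    idx <- which(collapsed & !amb)
    out[idx] <- revcomp(win[idx])
  }
  out[amb] <- NA_character_
  data.frame(context = out, collapsed = ifelse(amb, NA, collapsed))
}

all_contexts <- function(flank) {
  ## pyrimidine-centred k-mers in lexicographic flank order
  centre <- c("C", "T")
  if (flank == 1) {
    combos <- expand.grid(f3 = BASES, c = centre, f5 = BASES,
                          stringsAsFactors = FALSE)
    sort(paste0(combos$f5, combos$c, combos$f3))
  } else {
    di <- sort(do.call(paste0, expand.grid(BASES, BASES,
                                           stringsAsFactors = FALSE)))
    combos <- expand.grid(f3 = di, c = centre, f5 = di,
                          stringsAsFactors = FALSE)
    sort(paste0(combos$f5, combos$c, combos$f3))
  }
}

## collapse a named kmer count vector (all 4^w ACGT kmers) onto
## pyrimidine-centred keys
collapse_kmer_counts <- function(counts, flank) {
  kmers <- names(counts)
  centre <- substring(kmers, flank + 1, flank + 1)
  pur <- centre %in% c("A", "G")
  key <- kmers
  key[pur] <- revcomp(kmers[pur])
  out <- tapply(counts, key, sum)
  full <- setNames(numeric(length(all_contexts(flank))), all_contexts(flank))
  full[names(out)] <- out
  full
}

#' Count genome-wide availability of mutation-target sequence contexts
#'
#' Every window whose central base is A/C/G/T and whose flanks contain no N
#' contributes one count to the pyrimidine-strand representation of its
#' context (purine-centred windows are reverse-complemented before counting).
#' Counting one strand under this collapsing rule quantifies both DNA
#' strands: a window and its reverse complement are the same target. Windows
#' overlapping sequence ends or containing N are skipped and tallied.
#'
#' The middle base of each counted window is a putative mutation target, so
#' the inventory measures how many sites of each context are available for
#' mutation — the denominator of motif-enrichment statistics (see
#' [compute_enrichment()]).
#'
#' @param genome a `ref_genome`
#' @param chromosomes chromosomes to count (default: all in `genome`). Use
#'   this to restrict to autosomes or any other subset.
#' @param flank 1 counts the 32 pyrimidine-centred trinucleotides; 2
#'   additionally counts the 512 pyrimidine-centred pentanucleotides.
#' @param mask optional include-mask as a data.frame with columns
#'   `chrom`, `start`, `end` (1-based closed); only windows whose centre lies
#'   inside a mask interval are counted.
#' @return a `context_inventory`: list with `tri_counts` (32), `penta_counts`
#'   (512 or NULL), `c_total` (available cytosine-centred sites, Con_C),
#'   `flank`, `region_spec`, `skipped` (window tally lost to N or ends).
#' @examples
#' inv <- count_contexts(ref_genome(c(chr1 = "TTCATTCA")))
#' inv$tri_counts[inv$tri_counts > 0]
#' @export
count_contexts <- function(genome, chromosomes = NULL, flank = 1,
                           mask = NULL) {
  if (!flank %in% c(1, 2))
    stop(errorCondition("flank must be 1 or 2",
                        class = c("apomut_bad_flank", "error")))
  if (is.null(chromosomes)) chromosomes <- names(genome)
  missing <- setdiff(chromosomes, names(genome))
  if (length(missing))
    stop(errorCondition(
      paste0("unknown chromosome: ", paste(missing, collapse = ", ")),
      class = c("apomut_unknown_chrom", "error")))

  pieces <- segment_sequences(genome, chromosomes, mask, flank)
  widths <- if (flank == 2) c(3L, 5L) else 3L
  raw <- lapply(widths, function(w) {
    if (length(pieces) == 0) return(setNames(numeric(0), character(0)))
    freq <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(pieces), width = w, step = 1L)
    colSums(freq)
  })
  tri <- collapse_kmer_counts(raw[[1]], 1L)
  penta <- if (flank == 2) collapse_kmer_counts(raw[[2]], 2L) else NULL

  n_windows <- sum(pmax(nchar(pieces) - 2L * flank, 0L))
  counted <- if (flank == 2) sum(raw[[2]]) else sum(raw[[1]])
  inv <- structure(list(
    tri_counts = tri,
    penta_counts = penta,
    c_total = sum(tri[substring(names(tri), 2, 2) == "C"]),
    flank = flank,
    region_spec = if (is.null(mask)) paste(chromosomes, collapse = ",")
                  else paste0(paste(chromosomes, collapse = ","), " [masked]"),
    skipped = n_windows - counted
  ), class = "context_inventory")
  inv
}

## slice chromosome sequences into the segments whose windows should be
## counted; a mask interval [s, e] keeps windows centred in [s, e], which is
## the subsequence [s - flank, e + flank] clipped to the chromosome
segment_sequences <- function(genome, chromosomes, mask, flank) {
  if (is.null(mask)) return(unclass(genome)[chromosomes])
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  out <- character(0)
  for (ch in chromosomes) {
    m <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) next
    m <- merge_intervals(m[order(m$start), c("start", "end")])
    seq <- unclass(genome)[[ch]]
    L <- nchar(seq)
    out <- c(out, substring(seq, pmax(1L, m$start - flank),
                            pmin(L, m$end + flank)))
  }
  out
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  s <- iv$start; e <- iv$end
  ks <- s[1]; ke <- e[1]; outs <- c(); oute <- c()
  for (i in 2:length(s)) {
    if (s[i] <= ke + 1) ke <- max(ke, e[i])
    else { outs <- c(outs, ks); oute <- c(oute, ke); ks <- s[i]; ke <- e[i] }
  }
  data.frame(start = c(outs, ks), end = c(oute, ke))
}

#' @export
print.context_inventory <- function(x, ...) {
  cat("<context_inventory> flank=", x$flank,
      " Con_C=", x$c_total,
      " tri windows=", sum(x$tri_counts),
      " skipped=", x$skipped,
      "\n  regions: ", x$region_spec, "\n", sep = "")
  invisible(x)
}

#' Write / read a context inventory
#'
#' The on-disk format is a two-column TSV (context, count) carrying tri- and
#' (when present) pentanucleotide keys, preceded by a JSON header line
#' (`# {...}`) recording `flank`, `region_spec` and `skipped`.
#'
#' @param inventory a `context_inventory`
#' @param path output path
#' @return `path` invisibly (writer); a `context_inventory` (reader)
#' @export
write_inventory <- function(inventory, path) {
  hdr <- jsonlite::toJSON(list(flank = inventory$flank,
                               region_spec = inventory$region_spec,
                               skipped = inventory$skipped,
                               c_total = inventory$c_total),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  df <- data.frame(context = c(names(inventory$tri_counts),
                               names(inventory$penta_counts)),
                   count = c(unname(inventory$tri_counts),
                             unname(inventory$penta_counts)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  first <- readLines(path, n = 1)
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  counts <- setNames(df$count, df$context)
  tri <- counts[nchar(names(counts)) == 3]
  penta <- counts[nchar(names(counts)) == 5]
  structure(list(
    tri_counts = tri,
    penta_counts = if (length(penta)) penta else NULL,
    c_total = hdr$c_total,
    flank = hdr$flank,
    region_spec = hdr$region_spec,
    skipped = hdr$skipped
  ), class = "context_inventory")
}
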