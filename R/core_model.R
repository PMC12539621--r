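## Core sequence domain types and coordinate conventions.
##
## All coordinates in this package are 0-based, half-open, reported on the
## forward strand with an explicit strand field. Circular replicons wrap.

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. The alphabet is A/C/G/T/N; `N` maps to `N`.
#'
#' @param x character vector of DNA strings (may include empty strings).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAG")  # "CTT"
#' @export
revcomp <- function(x) {
  if (!is.character(x)) stop("revcomp(): input must be character")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("revcomp(): non-nucleotide symbol in input (alphabet A/C/G/T/N): ",
         substr(x[bad][1], 1, 40))
  }
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Extract a (possibly wrapping) window from a replicon
#'
#' Returns the `length`-bp window starting at 0-based position `start`.
#' On a circular sequence the window wraps past the end; on a linear
#' sequence an overrun is a coordinate error. `strand = "-"` returns the
#' reverse complement of the forward-strand window (the window's sequence
#' read 5'->3' on the minus strand).
#'
#' @param seq DNA string.
#' @param start 0-based start position (0 <= start < nchar(seq)).
#' @param length window length in bp (>= 0); may exceed the sequence
#'   length on a circular replicon (the sequence repeats).
#' @param strand "+" or "-".
#' @param circular logical; does the sequence wrap?
#' @return DNA string of `length` characters.
#' @export
circular_window <- function(seq, start, length, strand = "+", circular = TRUE) {
  L <- nchar(seq)
  if (length < 0) stop("circular_window(): negative length")
  if (start < 0 || start >= L) {
    stop("circular_window(): start ", start, " out of range [0, ", L, ")")
  }
  if (!strand %in% c("+", "-")) stop("circular_window(): strand must be + or -")
  if (length == 0) return("")
  if (start + length > L) {
    if (!circular) {
      stop("circular_window(): window [", start, ", ", start + length,
           ") overruns linear sequence of length ", L)
    }
    seq <- paste0(seq, strrep(seq, ceiling((start + length - L) / L)))
  }
  w <- substr(seq, start + 1, start + length)
  if (strand == "-") revcomp(w) else w
}

#' Build a validated reference set (chromosome + plasmid)
#'
#' The mapping universe for protospacer assignment: one chromosome and one
#' plasmid sequence, each with a circularity flag, plus the plasmid copy
#' number used for molar-excess normalisation.
#'
#' @param chromosome,plasmid DNA strings (A/C/G/T only; uppercased).
#' @param chromosome_circular,plasmid_circular logical circularity flags.
#' @param plasmid_copy_number positive number of plasmid copies per
#'   chromosome equivalent (default 40, typical for pBAD-family vectors).
#' @param labels names used in reports.
#' @return object of class `ReferenceSet`.
#' @export
reference_set <- function(chromosome, plasmid,
                          chromosome_circular = TRUE, plasmid_circular = TRUE,
                          plasmid_copy_number = 40,
                          labels = c(chromosome = "chromosome",
                                     plasmid = "plasmid")) {
  chromosome <- toupper(chromosome)
  plasmid <- toupper(plasmid)
  for (nm in c("chromosome", "plasmid")) {
    s <- if (nm == "chromosome") chromosome else plasmid
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      stop("reference_set(): ", nm, " must be a single non-empty string")
    }
    if (grepl("[^ACGT]", s)) {
      stop("reference_set(): ", nm,
           " contains a symbol outside A/C/G/T (N is not allowed in references)")
    }
  }
  if (nchar(plasmid) >= nchar(chromosome)) {
    stop("reference_set(): plasmid must be shorter than the chromosome")
  }
  if (!is.numeric(plasmid_copy_number) || plasmid_copy_number <= 0) {
    stop("reference_set(): plasmid_copy_number must be positive")
  }
  structure(list(chromosome = chromosome, plasmid = plasmid,
                 chromosome_circular = isTRUE(chromosome_circular),
                 plasmid_circular = isTRUE(plasmid_circular),
                 plasmid_copy_number = plasmid_copy_number,
                 labels = labels),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet\n")
  cat(sprintf("  chromosome: %d bp (%s)\n", nchar(x$chromosome),
              if (x$chromosome_circular) "circular" else "linear"))
  cat(sprintf("  plasmid:    %d bp (%s), copy number %.1f\n",
              nchar(x$plasmid),
              if (x$plasmid_circular) "circular" else "linear",
              x$plasmid_copy_number))
  invisible(x)
}

## Default reporter-array constants used by the simulator and the parser.
## Repeat: E. coli K-12 type I-E CRISPR consensus direct repeat (29 nt).
## Leader anchor and amplicon primers follow the reporter construct design:
## the PCR amplicon spans the leader-repeat junction.
DEFAULT_REPEAT <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"
DEFAULT_LEADER_ANCHOR <- "ATTGGTTAATTGGTTGTAACACTG"
DEFAULT_PRIMER_FWD <- "GGTCTTAATGAATGGCCGGG"
DEFAULT_PRIMER_REV <- "CATGGATCCGAAGTCGAGC"

#' Describe the reporter CRISPR array
#'
#' Captures what the read parser looks for: the leader-proximal anchor on
#' the amplicon, the direct repeat, and the length conventions of one
#' repeat-spacer unit (61 bp by default: 29 bp repeat + 32 bp spacer).
#' `atg_window` and `frame_offset` define the in-frame window used by the
#' reading-frame analytics: only the first `atg_window` bp of a spacer can
#' contribute an in-frame ATG before the reading frame runs into the
#' downstream repeat.
#'
#' @param leader_anchor DNA string immediately upstream of the first repeat
#'   on the amplicon; used to orient reads.
#' @param repeat_seq direct repeat sequence (typically 28-29 nt).
#' @param unit_length length in bp of one repeat-spacer unit (default 61).
#' @param spacer_length_window inclusive `c(min, max)` of accepted spacer
#'   lengths; defaults to the expected length +/- 3 bp.
#' @param atg_window in-frame window in bp (default 30).
#' @param frame_offset frame of the spacer's first base relative to the
#'   reporter start codon, 0..2 (default 0).
#' @return object of class `CrisprArrayModel`.
#' @export
crispr_array_model <- function(leader_anchor = DEFAULT_LEADER_ANCHOR,
                               repeat_seq = DEFAULT_REPEAT,
                               unit_length = 61,
                               spacer_length_window = NULL,
                               atg_window = 30,
                               frame_offset = 0) {
  for (s in c(leader_anchor, repeat_seq)) {
    if (!is.character(s) || nchar(s) == 0 || grepl("[^ACGT]", toupper(s))) {
      stop("crispr_array_model(): anchor and repeat must be non-empty A/C/G/T strings")
    }
  }
  leader_anchor <- toupper(leader_anchor)
  repeat_seq <- toupper(repeat_seq)
  expected <- unit_length - nchar(repeat_seq)
  if (expected <= 0) {
    stop("crispr_array_model(): unit_length must exceed the repeat length")
  }
  if (is.null(spacer_length_window)) {
    spacer_length_window <- c(expected - 3L, expected + 3L)
  }
  if (length(spacer_length_window) != 2 ||
      spacer_length_window[1] > spacer_length_window[2]) {
    stop("crispr_array_model(): spacer_length_window must be c(min, max)")
  }
  if (expected < spacer_length_window[1] || expected > spacer_length_window[2]) {
    stop("crispr_array_model(): spacer_length_window must contain the expected spacer length")
  }
  if (!frame_offset %in% 0:2) stop("crispr_array_model(): frame_offset must be 0, 1 or 2")
  if (atg_window < 3) stop("crispr_array_model(): atg_window must be >= 3")
  structure(list(leader_anchor = leader_anchor,
                 repeat_seq = repeat_seq,
                 unit_length = as.integer(unit_length),
                 expected_spacer_length = as.integer(expected),
                 spacer_length_window = as.integer(spacer_length_window),
                 atg_window = as.integer(atg_window),
                 frame_offset = as.integer(frame_offset)),
            class = "CrisprArrayModel")
}

#' @export
print.CrisprArrayModel <- function(x, ...) {
  cat("CrisprArrayModel\n")
  cat(sprintf("  repeat: %s (%d nt)\n", x$repeat_seq, nchar(x$repeat_seq)))
  cat(sprintf("  unit %d bp -> expected spacer %d bp (accepted %d-%d)\n",
              x$unit_length, x$expected_spacer_length,
              x$spacer_length_window[1], x$spacer_length_window[2]))
  cat(sprintf("  ATG window %d bp, frame offset %d\n",
              x$atg_window, x$frame_offset))
  invisible(x)
}

## ---- FASTA / FASTQ I/O (Biostrings-backed) ----------------------------

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta(): file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("read_fasta(): no records in ", path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  out
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#' @param path file path.
#' @return data.frame with columns id, sequence, qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("read_fastq(): file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  data.frame(id = ids,
             sequence = toupper(as.character(ss)),
             qualities = as.character(S4Vectors::mcols(ss)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file (Sanger Phred+33)
#' @param reads data.frame with columns id, sequence, qualities.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "qualities") %in% names(reads)))
  if (any(nchar(reads$qualities) != nchar(reads$sequence))) {
    stop("write_fastq(): quality strings must match sequence lengths")
  }
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Load chromosome and plasmid FASTA files into a ReferenceSet
#'
#' Takes the first record of each file; sequences are uppercased and
#' validated (A/C/G/T only).
#'
#' @param chromosome_fasta,plasmid_fasta file paths.
#' @inheritParams reference_set
#' @return `ReferenceSet`.
#' @export
load_references <- function(chromosome_fasta, plasmid_fasta,
                            chromosome_circular = TRUE,
                            plasmid_circular = TRUE,
                            plasmid_copy_number = 40) {
  chrom <- read_fasta(chromosome_fasta)
  plas <- read_fasta(plasmid_fasta)
  reference_set(chrom[[1]], plas[[1]],
                chromosome_circular = chromosome_circular,
                plasmid_circular = plasmid_circular,
                plasmid_copy_number = plasmid_copy_number,
                labels = c(chromosome = names(chrom)[1],
                           plasmid = names(plas)[1]))
}

## internal: fetch one replicon + its circularity flag
ref_get <- function(refs, source) {
  switch(source,
         chromosome = list(seq = refs$chromosome,
                           circular = refs$chromosome_circular),
         plasmid = list(seq = refs$plasmid, circular = refs$plasmid_circular),
         stop("unknown source: ", source))
}
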