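## Hotspot bin maps, source-bias normalisation and PAM matrices.
##
## Two deduplication rules coexist deliberately: hotspot maps and PAM
## matrices are built from UNIQUE spacers, whereas chromosome-to-plasmid
## ratios use ALL spacers (duplicates included).

#' Bin unique protospacer hits along one replicon
#'
#' Hit at forward-strand start `s` goes to bin `floor(s / bin_width)`;
#' the last bin may be short. Conventional widths: 10 kb for the
#' chromosome, 50 bp for the plasmid.
#'
#' @param starts integer vector of 0-based hit starts (unique spacers,
#'   one replicon).
#' @param bin_width bin width in bp.
#' @param source_length replicon length in bp.
#' @return data.frame(bin_start, count) covering the whole replicon.
#' @export
bin_hits <- function(starts, bin_width, source_length) {
  stopifnot(bin_width > 0, source_length > 0)
  if (length(starts) > 0 &&
      (any(starts < 0) || any(starts >= source_length))) {
    stop("bin_hits(): hit start outside [0, source_length)")
  }
  n_bins <- ceiling(source_length / bin_width)
  counts <- tabulate(floor(starts / bin_width) + 1L, nbins = n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
             count = as.integer(counts))
}

#' Plasmid-derived fraction of spacers
#'
#' `n_plasmid / (n_plasmid + n_chromosome)`; ambiguous and unmapped
#' spacers are excluded by the caller. Computed from ALL spacers
#' (duplicates included) when reproducing source-bias ratios.
#'
#' @param n_chromosome,n_plasmid non-negative counts.
#' @return fraction in [0, 1].
#' @export
plasmid_fraction <- function(n_chromosome, n_plasmid) {
  if (n_chromosome < 0 || n_plasmid < 0) stop("plasmid_fraction(): negative count")
  if (n_chromosome + n_plasmid == 0) {
    stop("plasmid_fraction(): undefined for zero mapped spacers")
  }
  n_plasmid / (n_plasmid + n_chromosome)
}

#' Molar excess of chromosomal over plasmid DNA
#'
#' `genome_length / (copy_number * plasmid_length)`: how many fold more
#' chromosomal than plasmid DNA a cell contains, the neutral expectation
#' for spacer source sampling.
#'
#' @param genome_length,plasmid_length lengths in bp.
#' @param copy_number plasmid copies per chromosome equivalent.
#' @return fold excess (positive number).
#' @export
molar_excess <- function(genome_length, plasmid_length, copy_number) {
  if (genome_length <= 0 || plasmid_length <= 0 || copy_number <= 0) {
    stop("molar_excess(): all inputs must be positive")
  }
  genome_length / (copy_number * plasmid_length)
}

#' Source-bias summary with molar-excess normalisation
#'
#' The neutral plasmid share under proportional sampling of DNA content is
#' `s = c*p / (c*p + g)` for copy number `c`, plasmid length `p` and
#' genome length `g`. The bias index compares observed to neutral odds:
#' `[f/(1-f)] / [s/(1-s)]`; 1 means neutral sampling.
#'
#' @param n_chromosome,n_plasmid all-spacer counts (duplicates included).
#' @param refs a [reference_set()] supplying lengths and copy number.
#' @return object of class `BiasSummary` (list with n_chromosome,
#'   n_plasmid, plasmid_fraction, molar_excess, neutral_plasmid_share,
#'   bias_index, degenerate flag).
#' @export
bias_summary <- function(n_chromosome, n_plasmid, refs) {
  f <- plasmid_fraction(n_chromosome, n_plasmid)
  g <- nchar(refs$chromosome)
  p <- nchar(refs$plasmid)
  cc <- refs$plasmid_copy_number
  s <- (cc * p) / (cc * p + g)
  degenerate <- f %in% c(0, 1)
  bi <- if (f == 0) 0 else if (f == 1) Inf else (f / (1 - f)) / (s / (1 - s))
  structure(list(n_chromosome = n_chromosome, n_plasmid = n_plasmid,
                 plasmid_fraction = f,
                 molar_excess = molar_excess(g, p, cc),
                 neutral_plasmid_share = s,
                 bias_index = bi, degenerate = degenerate),
            class = "BiasSummary")
}

#' @export
print.BiasSummary <- function(x, ...) {
  cat("BiasSummary\n")
  cat(sprintf("  spacers: %d chromosome, %d plasmid (plasmid fraction %.3f)\n",
              x$n_chromosome, x$n_plasmid, x$plasmid_fraction))
  cat(sprintf("  molar excess (chromosome:plasmid DNA): %.1f-fold\n",
              x$molar_excess))
  cat(sprintf("  neutral plasmid share: %.4f; bias index: %.2f%s\n",
              x$neutral_plasmid_share, x$bias_index,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Build a PAM position-frequency matrix with information content
#'
#' @param pams character vector of equal-length PAM strings (conventionally
#'   from unique spacers).
#' @param pseudocount added to every cell before frequencies (default 0).
#' @return object of class `PamMatrix`: list(counts, frequencies,
#'   information, consensus). Information per column is `2 - H` bits,
#'   `H` the Shannon entropy of the column frequencies.
#' @export
build_pam_matrix <- function(pams, pseudocount = 0) {
  if (length(pams) == 0) stop("build_pam_matrix(): no PAM strings")
  W <- unique(nchar(pams))
  if (length(W) != 1) stop("build_pam_matrix(): PAM strings of unequal length")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(toupper(pams), "", fixed = TRUE)),
                ncol = W, byrow = TRUE)
  counts <- vapply(seq_len(W), function(j) {
    tabulate(factor(mat[, j], levels = bases), nbins = 4L)
  }, integer(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(bases, NULL))
  adj <- counts + pseudocount
  freq <- sweep(adj, 2, colSums(adj), "/")
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - ent
  consensus <- paste(bases[apply(counts, 2, which.max)], collapse = "")
  structure(list(counts = counts, frequencies = freq,
                 information = info, consensus = consensus,
                 n = length(pams), pseudocount = pseudocount),
            class = "PamMatrix")
}

#' @export
print.PamMatrix <- function(x, ...) {
  cat(sprintf("PamMatrix over %d PAMs; consensus %s; information (bits): %s\n",
              x$n, x$consensus,
              paste(sprintf("%.2f", x$information), collapse = " ")))
  print(x$counts)
  invisible(x)
}

#' Count perfect PAM motif sites on a replicon
#'
#' Counts every (position, strand) occurrence of `motif`; overlapping
#' occurrences are allowed and circular counting includes sites spanning
#' the origin. Both strands are counted by default (the convention used
#' for plasmid PAM-site saturation).
#'
#' @param sequence DNA string.
#' @param motif motif to count (default "AAG").
#' @param circular does the sequence wrap (default TRUE)?
#' @param strands "both" or "forward".
#' @return integer count.
#' @export
count_pam_sites <- function(sequence, motif = "AAG", circular = TRUE,
                            strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (nchar(motif) == 0) stop("count_pam_sites(): empty motif")
  sequence <- toupper(sequence)
  ext <- if (circular) {
    paste0(sequence, substr(sequence, 1, nchar(motif) - 1))
  } else sequence
  subject <- Biostrings::DNAString(ext)
  n <- Biostrings::countPattern(motif, subject)
  if (strands == "both") {
    n <- n + Biostrings::countPattern(revcomp(motif), subject)
  }
  as.integer(n)
}
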