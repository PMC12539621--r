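# Independent oracles shared by the frame-statistics and acceptance tests.

# Exact enumeration over all 64^k codon sequences, via codon-category
# sequences (ATG: 1 of 64, stop: 3, other: 60) with multiplicity weights.
enumerate_frame_probs <- function(k) {
  if (k == 0) return(c(atg_no_stop = 0, no_stop = 1))
  cats <- expand.grid(rep(list(c("atg", "stop", "other")), k),
                      stringsAsFactors = FALSE)
  wts <- c(atg = 1, stop = 3, other = 60)
  p_atg <- 0; p_nostop <- 0
  for (r in seq_len(nrow(cats))) {
    seq_cats <- unlist(cats[r, ])
    w <- prod(wts[seq_cats]) / 64^k
    has_stop <- "stop" %in% seq_cats
    if (!has_stop) p_nostop <- p_nostop + w
    atg_i <- which(seq_cats == "atg")
    stop_i <- which(seq_cats == "stop")
    if (length(atg_i) > 0 && (!has_stop || max(atg_i) > max(stop_i))) {
      p_atg <- p_atg + w
    }
  }
  c(atg_no_stop = p_atg, no_stop = p_nostop)
}

# Monte-Carlo over n random in-frame windows of k codons; returns the
# fraction with an ATG not followed by an in-frame stop, and the fraction
# free of stops. Vectorised; equivalent to sampling n random 3k-mers.
mc_frame_probs <- function(n, k) {
  codon <- matrix(sample.int(64L, n * k, replace = TRUE), nrow = n)
  # codon indices: 1 = ATG, 2..4 = stops, rest = other (uniform relabeling)
  is_atg <- codon == 1L
  is_stop <- codon >= 2L & codon <= 4L
  # last TRUE column index per row (0 if none), vectorised via pmax
  last_true <- function(m) {
    do.call(pmax, as.data.frame(m * col(m)))
  }
  last_atg <- last_true(is_atg)
  last_stop <- last_true(is_stop)
  c(atg_no_stop = mean(last_atg > 0L & last_atg > last_stop),
    no_stop = mean(last_stop == 0L))
}

# Synthetic stand-in plasmid: a circular sequence of the given length that
# carries exactly `n_sites` perfect copies of `motif` counted on both
# strands with wrap (no reverse-strand occurrences by construction).
# Stand-in for a reference plasmid that is not available; it validates the
# counting convention, not any real sequence.
synthetic_plasmid_with_motifs <- function(length_bp = 5300, n_sites = 152,
                                          motif = "AAG", seed = 1) {
  set.seed(seed)
  rc <- revcomp(motif)
  w <- nchar(motif)
  # background free of the motif on both strands
  repeat_bad <- TRUE
  bases <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  bg <- paste(bases, collapse = "")
  scrub <- function(s) {
    while (TRUE) {
      ext <- paste0(s, substr(s, 1, w - 1))
      hit <- c(Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(ext))),
               Biostrings::start(Biostrings::matchPattern(rc, Biostrings::DNAString(ext))))
      if (length(hit) == 0) return(s)
      pos <- ((hit[1] - 1L + 1L) %% nchar(s)) + 1L  # middle base, wrapped
      substr(s, pos, pos) <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  bg <- scrub(bg)
  # plant n_sites non-overlapping motif copies at spaced positions
  slots <- floor(seq(1, length_bp - w, length.out = n_sites))
  for (p in slots) substr(bg, p, p + w - 1L) <- motif
  # planting can only create motif copies at the planted positions for
  # AAG/CTT (no cross-junction hits), but re-scrub any stray reverse hits
  ext <- paste0(bg, substr(bg, 1, w - 1))
  stopifnot(Biostrings::countPattern(motif, Biostrings::DNAString(ext)) == n_sites,
            Biostrings::countPattern(rc, Biostrings::DNAString(ext)) == 0)
  bg
}
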