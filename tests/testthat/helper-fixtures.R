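# Shared fixtures: tiny deterministic references and a toy array model.

# fixed-seed random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small reference set with known planted windows
tiny_refs <- function(seed = 42, chrom_len = 2000, plas_len = 400) {
  set.seed(seed)
  reference_set(rand_dna(chrom_len), rand_dna(plas_len))
}

toy_model <- function() {
  crispr_array_model(
    leader_anchor = "TTGGTAGATTGTGACTGGCT",
    repeat_seq = "GTGTTCCCCGCGCCAGCGGGGATAAACCG",
    unit_length = 61)
}

# small, fast simulation config
quick_sim <- function(seed = 1, n_events = 40, error = c(0, 0, 0),
                      parental = 0.2, pi = 0.5, w = 1) {
  sim_config(seed = seed, n_events = n_events,
             chromosome_length = 20000L, plasmid_length = 2000L,
             plasmid_source_prob = pi, pam_bias = w,
             error_model = error_model(error[1], error[2], error[3]),
             parental_read_fraction = parental)
}

ref_get_test <- function(refs, src) spacertrace:::ref_get(refs, src)

# independent semi-global edit distance oracle: min over all substrings,
# via utils::adist (Levenshtein)
oracle_min_edit <- function(pattern, text) {
  m <- nchar(pattern); n <- nchar(text)
  best <- m
  for (i in seq_len(n)) {
    for (j in i:min(n, i + m + 5)) {
      d <- utils::adist(pattern, substr(text, i, j))[1, 1]
      if (d < best) best <- d
    }
  }
  best
}
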