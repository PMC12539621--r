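## Synthetic amplicon-pool generator.
##
## Emulates the sequencing input of the reporter assay: PCR amplicons over
## the leader-repeat junction of a CRISPR reporter array, a fraction of
## which carry a +1 repeat-spacer expansion with a protospacer drawn from
## chromosome or plasmid (AAG-PAM biased), duplicated per event and
## corrupted by nanopore-style substitution/insertion/deletion errors.
##
## Draw order under the single seeded RNG stream (documented so partial
## re-runs stay reproducible): chromosome bases, plasmid bases, downstream
## stub bases, cassette insertion point, then per event (source, strand,
## site, duplication count), then per read (orientation, errors).

#' Nanopore-style error model
#'
#' Per-base substitution, insertion and deletion rates applied
#' independently to every synthesised read. Defaults sum to a 2% total
#' error rate, a plain proxy for modern ONT chemistry after basecalling.
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base rates,
#'   each in [0, 0.2], jointly summing to < 0.5.
#' @return object of class `ErrorModel`.
#' @export
error_model <- function(substitution_rate = 0.01, insertion_rate = 0.005,
                        deletion_rate = 0.005) {
  r <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(r < 0) || any(r > 0.2) || sum(r) >= 0.5) {
    stop("error_model(): rates must lie in [0, 0.2] and sum to < 0.5")
  }
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate),
            class = "ErrorModel")
}

#' Simulation configuration
#'
#' The stated world of the generator: reference sizes, the planted plasmid
#' source probability `plasmid_source_prob`, the AAG-PAM site weighting
#' `pam_bias`, the per-event duplication distribution, the error model and
#' the fraction of parental (unexpanded) reads in the pool.
#'
#' @param seed integer seed for the single RNG stream.
#' @param chromosome_length,plasmid_length replicon lengths in bp.
#' @param gc_content GC fraction of random reference bases.
#' @param n_events number of planted acquisition events (>= 1).
#' @param plasmid_source_prob probability an event's protospacer comes
#'   from the plasmid.
#' @param pam_bias relative weight (>= 1) of protospacer start sites whose
#'   PAM is AAG versus all other sites.
#' @param duplication_distribution list(name = "geometric", mean = 3) or
#'   list(name = "constant", value = k); per-event read duplication counts
#'   (PCR + clonal amplification modelled jointly).
#' @param error_model an [error_model()].
#' @param parental_read_fraction fraction of reads with no expansion
#'   (default 0.9; expansion is rare in real amplicon pools).
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       chromosome_length = 100000L,
                       plasmid_length = 5300L,
                       gc_content = 0.5,
                       n_events = 500L,
                       plasmid_source_prob = 0.64,
                       pam_bias = 20,
                       duplication_distribution = list(name = "geometric", mean = 3),
                       error_model = spacertrace::error_model(),
                       parental_read_fraction = 0.9) {
  stopifnot(chromosome_length > 0, plasmid_length > 0,
            plasmid_length < chromosome_length, n_events >= 1)
  if (gc_content < 0 || gc_content > 1) stop("sim_config(): gc_content must be in [0,1]")
  if (plasmid_source_prob < 0 || plasmid_source_prob > 1) {
    stop("sim_config(): plasmid_source_prob must be in [0,1]")
  }
  if (parental_read_fraction < 0 || parental_read_fraction > 1) {
    stop("sim_config(): parental_read_fraction must be in [0,1]")
  }
  if (pam_bias < 1) stop("sim_config(): pam_bias must be >= 1")
  if (!inherits(error_model, "ErrorModel")) stop("sim_config(): bad error_model")
  structure(list(seed = as.integer(seed),
                 chromosome_length = as.integer(chromosome_length),
                 plasmid_length = as.integer(plasmid_length),
                 gc_content = gc_content,
                 n_events = as.integer(n_events),
                 plasmid_source_prob = plasmid_source_prob,
                 pam_bias = pam_bias,
                 duplication_distribution = duplication_distribution,
                 error_model = error_model,
                 parental_read_fraction = parental_read_fraction),
            class = "SimulationConfig")
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate seeded random references with an embedded reporter cassette
#'
#' Seeds the RNG from `config$seed` and draws a random chromosome and
#' plasmid. The reporter cassette (forward primer site + leader anchor +
#' one repeat + a lacZ stub ending in the reverse primer site) is spliced
#' into the chromosome at a random position, so self-targeting of the
#' reporter locus is representable. The parental amplicon template is the
#' cassette itself.
#'
#' @param config a [sim_config()].
#' @param model a [crispr_array_model()]; its anchor and repeat are used.
#' @return list with elements `refs` (ReferenceSet), `model`,
#'   `template` (list upstream/repeat/downstream of the parental amplicon),
#'   and `cassette_start` (0-based chromosome position).
#' @export
generate_references <- function(config, model = crispr_array_model()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  upstream <- paste0(DEFAULT_PRIMER_FWD, model$leader_anchor)
  stub_len <- 80L
  cassette_len <- nchar(upstream) + nchar(model$repeat_seq) + stub_len +
    nchar(DEFAULT_PRIMER_REV)
  chrom_bg <- random_dna(config$chromosome_length - cassette_len,
                         config$gc_content)
  plasmid <- random_dna(config$plasmid_length, config$gc_content)
  stub <- paste0(random_dna(stub_len, config$gc_content),
                 revcomp(DEFAULT_PRIMER_REV))
  downstream <- stub
  cassette <- paste0(upstream, model$repeat_seq, downstream)
  pos <- sample.int(nchar(chrom_bg) - 1L, 1L)
  chromosome <- paste0(substr(chrom_bg, 1, pos), cassette,
                       substr(chrom_bg, pos + 1, nchar(chrom_bg)))
  list(refs = reference_set(chromosome, plasmid),
       model = model,
       template = list(upstream = upstream, repeat_seq = model$repeat_seq,
                       downstream = downstream),
       cassette_start = pos)
}

## 0-based forward-strand protospacer start positions whose PAM is `motif`,
## for one replicon and strand, under the -2..0 PAM window convention.
pam_site_starts <- function(seq, strand, motif = "AAG") {
  L <- nchar(seq)
  w <- nchar(motif)
  ext <- paste0(seq, substr(seq, 1, w - 1))
  if (strand == "+") {
    # PAM occupies [s-w+1+ (w-1) ... ]: bases s-2..s for w=3 -> motif ends at s
    pos <- Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(ext)))
    ((pos - 1L) + w - 1L) %% L           # s = motif start + w - 1 (0-based)
  } else {
    # minus strand: 5' protospacer base at forward coord t, leftmost s=t-m+1;
    # PAM is revcomp(forward [t, t+w)) so forward text carries revcomp(motif).
    pos <- Biostrings::start(Biostrings::matchPattern(revcomp(motif), Biostrings::DNAString(ext)))
    (pos - 1L) %% L                      # t = match start (0-based)
  }
}

draw_duplications <- function(n, dist) {
  if (identical(dist$name, "geometric")) {
    if (dist$mean <= 1) return(rep(1L, n))
    stats::rgeom(n, prob = 1 / dist$mean) + 1L
  } else if (identical(dist$name, "constant")) {
    rep(as.integer(dist$value), n)
  } else {
    stop("unknown duplication distribution: ", dist$name)
  }
}

#' Plant acquisition events (the simulation ground truth)
#'
#' Each event picks plasmid vs chromosome with probability
#' `plasmid_source_prob`, a uniform strand, and a protospacer start site
#' weighted `pam_bias`-fold at positions whose PAM window reads AAG.
#' Duplication counts come from the configured distribution.
#'
#' For a minus-strand event, `start` is the forward-strand leftmost
#' coordinate of the protospacer window and `spacer` is the window's
#' reverse complement (the spacer as stored in the array).
#'
#' @param refgen output of [generate_references()] (continues its RNG
#'   stream; do not reseed between the two calls).
#' @param config a [sim_config()].
#' @return data.frame with columns event_id, source, start, strand,
#'   spacer, pam, duplication_count.
#' @export
plant_events <- function(refgen, config) {
  refs <- refgen$refs
  model <- refgen$model
  m <- model$expected_spacer_length
  w <- config$pam_bias
  aag <- list()
  for (src in c("chromosome", "plasmid")) {
    rg <- ref_get(refs, src)
    for (st in c("+", "-")) {
      key <- paste0(src, st)
      t0 <- pam_site_starts(rg$seq, st, "AAG")
      # store as leftmost forward-strand window start
      aag[[key]] <- if (st == "+") t0 else (t0 - m + 1L) %% nchar(rg$seq)
    }
  }
  n <- config$n_events
  source <- ifelse(stats::runif(n) < config$plasmid_source_prob,
                   "plasmid", "chromosome")
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  start <- integer(n)
  for (i in seq_len(n)) {
    rg <- ref_get(refs, source[i])
    L <- nchar(rg$seq)
    sites <- aag[[paste0(source[i], strand[i])]]
    nA <- length(sites)
    p_aag <- (w * nA) / (w * nA + (L - nA))
    fits <- function(s) rg$circular || (s + m) <= L
    if (nA > 0 && stats::runif(1) < p_aag) {
      repeat {
        s <- sites[sample.int(nA, 1L)]
        if (fits(s)) break
      }
      start[i] <- s
    } else {
      repeat {
        s <- sample.int(L, 1L) - 1L
        if (!(s %in% sites) && fits(s)) break
      }
      start[i] <- s
    }
  }
  dup <- draw_duplications(n, config$duplication_distribution)
  spacer <- character(n)
  pam <- character(n)
  for (i in seq_len(n)) {
    rg <- ref_get(refs, source[i])
    spacer[i] <- circular_window(rg$seq, start[i], m, strand[i], rg$circular)
    pam[i] <- pam_window(rg$seq, start[i], m, strand[i], rg$circular)
  }
  data.frame(event_id = sprintf("ev%05d", seq_len(n)),
             source = source, start = start, strand = strand,
             spacer = spacer, pam = pam, duplication_count = as.integer(dup),
             stringsAsFactors = FALSE)
}

## PAM window on the protospacer strand: positions offset..offset+width-1
## relative to the protospacer's first base (position 0), default -2..0.
pam_window <- function(seq, start, spacer_len, strand, circular,
                       offset = -2L, width = 3L) {
  L <- nchar(seq)
  if (strand == "+") {
    f <- (start + offset) %% L
    circular_window(seq, f, width, "+", circular)
  } else {
    t <- start + spacer_len - 1L             # forward coord of 5' base
    f <- (t - offset - width + 1L) %% L
    circular_window(seq, f, width, "-", circular)
  }
}

## Apply the error model to one character vector of bases.
## Order per base: substitution, then deletion, then insertion-after.
corrupt_one <- function(bases, em) {
  n <- length(bases)
  if (n == 0) return(bases)
  sub <- stats::runif(n) < em$substitution_rate
  if (any(sub)) {
    bases[sub] <- vapply(bases[sub], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  del <- stats::runif(n) < em$deletion_rate
  ins <- stats::runif(n) < em$insertion_rate
  if (!any(del) && !any(ins)) return(bases)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kept <- if (del[i]) character(0) else bases[i]
    if (ins[i]) kept <- c(kept, sample(c("A", "C", "G", "T"), 1L))
    out[[i]] <- kept
  }
  unlist(out, use.names = FALSE)
}

#' Synthesise FASTQ reads from planted events
#'
#' Emits `duplication_count` expanded reads per event
#' (upstream + repeat + spacer + repeat + downstream) plus enough parental
#' (unexpanded) reads that they make up `parental_read_fraction` of the
#' pool. Each read is independently reverse-complemented with probability
#' 1/2 and corrupted by the error model. Quality strings are constant
#' placeholders; no downstream stage consumes them.
#'
#' @param events data.frame from [plant_events()].
#' @param refgen output of [generate_references()].
#' @param config a [sim_config()].
#' @return data.frame of reads (id, sequence, qualities) plus attribute
#'   `truth` (the events table).
#' @export
synthesize_reads <- function(events, refgen, config) {
  tpl <- refgen$template
  parental <- paste0(tpl$upstream, tpl$repeat_seq, tpl$downstream)
  n_exp <- sum(events$duplication_count)
  f <- config$parental_read_fraction
  if (f >= 1) {
    templates <- rep(parental, max(n_exp, 1L))
    ids <- sprintf("parental_%05d", seq_along(templates))
  } else {
    expanded <- paste0(tpl$upstream, tpl$repeat_seq, events$spacer,
                       tpl$repeat_seq, tpl$downstream)
    templates <- rep(expanded, events$duplication_count)
    ids <- sprintf("%s_r%02d",
                   rep(events$event_id, events$duplication_count),
                   unlist(lapply(events$duplication_count, seq_len)))
    n_par <- round(f / (1 - f) * n_exp)
    if (n_par > 0) {
      templates <- c(templates, rep(parental, n_par))
      ids <- c(ids, sprintf("parental_%05d", seq_len(n_par)))
    }
  }
  em <- config$error_model
  flip <- stats::runif(length(templates)) < 0.5
  zero_err <- em$substitution_rate == 0 && em$insertion_rate == 0 &&
    em$deletion_rate == 0
  seqs <- character(length(templates))
  for (i in seq_along(templates)) {
    s <- templates[i]
    if (!zero_err) {
      s <- paste(corrupt_one(strsplit(s, "", fixed = TRUE)[[1]], em),
                 collapse = "")
    }
    if (flip[i]) s <- revcomp(s)
    seqs[i] <- s
  }
  reads <- data.frame(id = ids, sequence = seqs,
                      qualities = strrep("I", nchar(seqs)),
                      stringsAsFactors = FALSE)
  attr(reads, "truth") <- events
  reads
}

#' Run the full simulator (references, events, reads), optionally to disk
#'
#' Seeds once from `config$seed`; everything downstream is deterministic.
#' When `out_dir` is given, writes chromosome.fasta, plasmid.fasta,
#' reads.fastq, truth.tsv and config.json.
#'
#' @param config a [sim_config()].
#' @param model a [crispr_array_model()].
#' @param out_dir optional output directory (created if missing).
#' @return list(refgen, events, reads).
#' @export
simulate_run <- function(config, model = crispr_array_model(), out_dir = NULL) {
  refgen <- generate_references(config, model)   # seeds the stream
  events <- plant_events(refgen, config)
  reads <- synthesize_reads(events, refgen, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(c(chromosome = refgen$refs$chromosome), file.path(out_dir, "chromosome.fasta"))
    write_fasta(c(plasmid = refgen$refs$plasmid), file.path(out_dir, "plasmid.fasta"))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    utils::write.table(events, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    cfg$error_model <- unclass(cfg$error_model)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(refgen = refgen, events = events, reads = reads)
}
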