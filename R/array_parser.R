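`%||%` <- function(a, b) if (is.null(a)) b else a

## Repeat-anchored spacer extraction from amplicon reads.
##
## A parental (unexpanded) amplicon carries one repeat copy; a +1
## expansion carries two with the new spacer between them. The parser
## orients each read by the leader anchor, locates all approximate repeat
## copies by edit distance, and takes inter-repeat segments of plausible
## length as candidate spacers.

#' Orient a read by its leader anchor
#'
#' Compares the best approximate occurrence of the leader anchor in the
#' read and in its reverse complement; the orientation with the lower edit
#' distance wins (ties go to forward). If neither is within
#' `ceiling(max_edit_fraction * nchar(anchor))` edits the read is flagged
#' unparseable.
#'
#' @param sequence read sequence (A/C/G/T/N).
#' @param model a [crispr_array_model()].
#' @param max_edit_fraction maximum edit distance as a fraction of the
#'   anchor length (default 0.2).
#' @return list(sequence, orientation = "+"/"-", parseable, anchor_edits).
#' @export
orient_read <- function(sequence, model, max_edit_fraction = 0.2) {
  anchor <- model$leader_anchor
  maxd <- ceiling(max_edit_fraction * nchar(anchor))
  rc <- revcomp(sequence)
  d_f <- myers_scan_cpp(anchor, sequence, maxd)$best
  d_r <- myers_scan_cpp(anchor, rc, maxd)$best
  if (min(d_f, d_r) > maxd) {
    return(list(sequence = sequence, orientation = NA_character_,
                parseable = FALSE, anchor_edits = NA_integer_))
  }
  if (d_f <= d_r) {
    list(sequence = sequence, orientation = "+", parseable = TRUE,
         anchor_edits = d_f)
  } else {
    list(sequence = rc, orientation = "-", parseable = TRUE,
         anchor_edits = d_r)
  }
}

#' Find non-overlapping approximate repeat copies in an oriented read
#'
#' All occurrences of the repeat within
#' `ceiling(max_edit_fraction * nchar(repeat))` edits are enumerated by a
#' semi-global edit-distance scan, then selected greedily by ascending
#' edit distance (ties: leftmost) subject to non-overlap.
#'
#' @param sequence oriented read sequence.
#' @param repeat_seq repeat sequence.
#' @param max_edit_fraction edit tolerance as a fraction of repeat length.
#' @return data.frame(start, end, edits), 0-based half-open, sorted by
#'   position.
#' @export
find_repeat_matches <- function(sequence, repeat_seq, max_edit_fraction = 0.2) {
  maxd <- ceiling(max_edit_fraction * nchar(repeat_seq))
  repeat_locate_cpp(repeat_seq, sequence, maxd)
}

#' Extract candidate spacers between adjacent repeat copies
#'
#' For each adjacent pair of repeat matches the inter-repeat segment is a
#' candidate spacer, kept iff its length lies within the model's
#' `spacer_length_window`. Returned 5'->3' on the oriented read,
#' leader-proximal first. Overlapping match pairs are skipped.
#'
#' @param matches data.frame from [find_repeat_matches()].
#' @param sequence oriented read sequence.
#' @param model a [crispr_array_model()].
#' @return character vector of spacer sequences (possibly empty), with
#'   attribute `position_in_read` (0-based starts).
#' @export
extract_spacers <- function(matches, sequence, model) {
  if (nrow(matches) < 2) {
    out <- character(0)
    attr(out, "position_in_read") <- integer(0)
    return(out)
  }
  spacers <- character(0)
  pos <- integer(0)
  for (i in seq_len(nrow(matches) - 1L)) {
    gap_start <- matches$end[i]
    gap_end <- matches$start[i + 1L]
    if (gap_end < gap_start) next          # overlapping matches: skip pair
    len <- gap_end - gap_start
    if (len >= model$spacer_length_window[1] &&
        len <= model$spacer_length_window[2]) {
      spacers <- c(spacers, substr(sequence, gap_start + 1L, gap_end))
      pos <- c(pos, gap_start)
    }
  }
  attr(spacers, "position_in_read") <- pos
  spacers
}

#' Parse one read into its spacers
#'
#' @param sequence read sequence.
#' @param model a [crispr_array_model()].
#' @param max_edit_fraction edit tolerance for anchor and repeat matching.
#' @return list(orientation, parseable, repeat_matches, spacers,
#'   expansion_count).
#' @export
parse_read <- function(sequence, model, max_edit_fraction = 0.2) {
  ori <- orient_read(sequence, model, max_edit_fraction)
  if (!ori$parseable) {
    return(list(orientation = NA_character_, parseable = FALSE,
                repeat_matches = NULL, spacers = character(0),
                expansion_count = 0L))
  }
  rm <- find_repeat_matches(ori$sequence, model$repeat_seq, max_edit_fraction)
  sp <- extract_spacers(rm, ori$sequence, model)
  list(orientation = ori$orientation, parseable = TRUE,
       repeat_matches = rm, spacers = sp,
       expansion_count = max(0L, nrow(rm) - 1L))
}

#' Parse a pool of reads and tabulate extraction counters
#'
#' @param reads data.frame with columns id, sequence (e.g. from
#'   [read_fastq()]).
#' @param model a [crispr_array_model()].
#' @param max_edit_fraction edit tolerance.
#' @return list with `spacers` (data.frame read_id, orientation,
#'   expansion_count, spacer, position_in_read) and `counters`
#'   (total_reads, unparseable, parental, expanded, n_spacers).
#' @export
parse_reads <- function(reads, model, max_edit_fraction = 0.2) {
  n <- nrow(reads)
  acc_id <- vector("list", n); acc_ori <- vector("list", n)
  acc_exp <- vector("list", n); acc_sp <- vector("list", n)
  acc_pos <- vector("list", n)
  unparseable <- 0L; parental <- 0L; expanded <- 0L
  for (i in seq_len(n)) {
    pr <- parse_read(reads$sequence[i], model, max_edit_fraction)
    if (!pr$parseable) {
      unparseable <- unparseable + 1L
      next
    }
    k <- length(pr$spacers)
    if (pr$expansion_count == 0L || k == 0L) {
      parental <- parental + 1L
    } else {
      expanded <- expanded + 1L
    }
    if (k > 0) {
      acc_id[[i]] <- rep(reads$id[i], k)
      acc_ori[[i]] <- rep(pr$orientation, k)
      acc_exp[[i]] <- rep(pr$expansion_count, k)
      acc_sp[[i]] <- as.character(pr$spacers)
      acc_pos[[i]] <- attr(pr$spacers, "position_in_read")
    }
  }
  sp <- data.frame(read_id = unlist(acc_id) %||% character(0),
                   orientation = unlist(acc_ori) %||% character(0),
                   expansion_count = unlist(acc_exp) %||% integer(0),
                   spacer = unlist(acc_sp) %||% character(0),
                   position_in_read = unlist(acc_pos) %||% integer(0),
                   stringsAsFactors = FALSE)
  list(spacers = sp,
       counters = list(total_reads = n, unparseable = unparseable,
                       parental = parental, expanded = expanded,
                       n_spacers = nrow(sp)))
}

#' Collapse exact duplicate spacers into a tally
#'
#' Case-insensitive exact-match deduplication; duplication_count is the
#' number of reads contributing each sequence. The unique list preserves
#' first-seen order and the counts conserve the number of inputs.
#'
#' @param spacers character vector of extracted spacer sequences.
#' @return list(tally = data.frame(spacer, duplication_count),
#'   unique = character vector).
#' @export
collapse_duplicates <- function(spacers) {
  spacers <- toupper(spacers)
  u <- unique(spacers)
  cnt <- as.integer(table(factor(spacers, levels = u)))
  list(tally = data.frame(spacer = u, duplication_count = cnt,
                          stringsAsFactors = FALSE),
       unique = u)
}
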