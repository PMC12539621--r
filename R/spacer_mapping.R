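## Protospacer assignment: best edit-distance hit across chromosome and
## plasmid, both strands, with circular wrap, plus PAM window extraction.

## Precompute per-replicon scan texts (circular wrap appended once), so a
## batch of spacers does not re-copy a multi-kilobase reference per query.
build_map_context <- function(refs, wrap_len) {
  ctx <- list()
  for (src in c("chromosome", "plasmid")) {
    rg <- ref_get(refs, src)
    text <- if (rg$circular && wrap_len > 0) {
      paste0(rg$seq, substr(rg$seq, 1, wrap_len))
    } else rg$seq
    ctx[[src]] <- list(text = text, L = nchar(rg$seq), circular = rg$circular)
  }
  ctx
}

## Scan one precomputed replicon text for a pattern; returns data.frame of
## candidate sites (start [0-based forward leftmost, mod L], edits), or NULL.
## exact occurrences only (fast path); NULL when none
scan_replicon_exact <- function(pattern, ctx1) {
  if (nchar(pattern) > ctx1$L) return(NULL)
  exact <- find_exact_cpp(pattern, ctx1$text)
  if (length(exact) == 0) return(NULL)
  starts <- as.integer(exact %% ctx1$L)
  data.frame(start = starts[!duplicated(starts)], edits = 0L)
}

scan_replicon <- function(pattern, ctx1, max_edits) {
  max_edits <- as.integer(max_edits)
  L <- ctx1$L
  m <- nchar(pattern)
  if (m > L) return(NULL)
  text <- ctx1$text
  # exact-match fast path; identical to the edit-distance scan at best = 0
  ex <- scan_replicon_exact(pattern, ctx1)
  if (!is.null(ex)) return(ex)
  if (max_edits == 0L) return(NULL)
  hit <- myers_scan_cpp(pattern, text, max_edits)
  if (length(hit$end) == 0) return(NULL)
  best <- min(hit$score)
  ends <- hit$end[hit$score == best]
  # recover start coordinates by a local DP around each end
  starts <- integer(length(ends))
  for (k in seq_along(ends)) {
    e <- ends[k]
    w0 <- max(0L, e - m - max_edits)
    loc <- edit_locate_cpp(pattern, substr(text, w0 + 1L, e), max_edits)
    loc <- loc[loc$end == (e - w0) & loc$edits == best, , drop = FALSE]
    starts[k] <- if (nrow(loc) > 0) w0 + loc$start[1] else e - m
  }
  starts <- as.integer(starts %% L)
  keep <- !duplicated(starts)
  data.frame(start = starts[keep], edits = as.integer(best))
}

#' Map one spacer to its protospacer locus
#'
#' Searches both references on both strands for the best edit-distance
#' occurrence (circular wrap included). Exact matches are necessarily
#' preferred because the scan is exhaustive in edit distance. Among
#' equal-best hits: a single replicon gives that source (lowest start wins
#' within it, multiplicity recorded); hits on both replicons give
#' `ambiguous`; no hit within `max_edits` gives `unmapped`.
#'
#' Coordinates are 0-based forward-strand leftmost positions; a minus
#' strand hit means the spacer matches the reverse complement of the
#' forward window.
#'
#' @param spacer spacer sequence (A/C/G/T/N; N never matches).
#' @param refs a [reference_set()].
#' @param max_edits maximum edit distance (default 2).
#' @param pam_offset,pam_width PAM window relative to the protospacer
#'   start on the protospacer strand (defaults -2 and 3: two upstream
#'   bases plus the first protospacer base, the canonical AAG reading).
#' @return one-row data.frame: spacer, source, start, strand,
#'   edit_distance, pam, n_equal_best.
#' @export
map_spacer <- function(spacer, refs, max_edits = 2L,
                       pam_offset = -2L, pam_width = 3L, .ctx = NULL) {
  spacer <- toupper(spacer)
  if (is.null(.ctx)) {
    .ctx <- build_map_context(refs, nchar(spacer) + max_edits - 1L)
  }
  spacer_rc <- revcomp(spacer)
  hits <- vector("list", 4L)
  i <- 0L
  any_exact <- FALSE
  # exact pass over all four replicon/strand combinations first: if any
  # exact hit exists the global best is 0 and no edit-distance scan can
  # contribute an equal-best hit
  for (src in c("chromosome", "plasmid")) {
    for (st in c("+", "-")) {
      i <- i + 1L
      pattern <- if (st == "+") spacer else spacer_rc
      h <- scan_replicon_exact(pattern, .ctx[[src]])
      if (!is.null(h)) {
        h$source <- src; h$strand <- st
        hits[[i]] <- h
        any_exact <- TRUE
      }
    }
  }
  if (!any_exact && max_edits > 0) {
    i <- 0L
    for (src in c("chromosome", "plasmid")) {
      for (st in c("+", "-")) {
        i <- i + 1L
        pattern <- if (st == "+") spacer else spacer_rc
        h <- scan_replicon(pattern, .ctx[[src]], max_edits)
        if (!is.null(h)) {
          h$source <- src; h$strand <- st
          hits[[i]] <- h
        }
      }
    }
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  unmapped <- data.frame(spacer = spacer, source = "unmapped",
                         start = NA_integer_, strand = NA_character_,
                         edit_distance = NA_integer_, pam = "",
                         n_equal_best = 0L, stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(unmapped)
  best <- min(hits$edits)
  hits <- hits[hits$edits == best, , drop = FALSE]
  if (length(unique(hits$source)) > 1) {
    return(data.frame(spacer = spacer, source = "ambiguous",
                      start = NA_integer_, strand = NA_character_,
                      edit_distance = best, pam = "",
                      n_equal_best = nrow(hits), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  top <- hits[1, ]
  rg <- ref_get(refs, top$source)
  pam <- pam_window(rg$seq, top$start, nchar(spacer), top$strand,
                    rg$circular, offset = pam_offset, width = pam_width)
  data.frame(spacer = spacer, source = top$source, start = top$start,
             strand = top$strand, edit_distance = best, pam = pam,
             n_equal_best = nrow(hits), stringsAsFactors = FALSE)
}

#' Map a vector of spacers
#'
#' @param spacers character vector.
#' @inheritParams map_spacer
#' @return data.frame, one row per spacer, as in [map_spacer()].
#' @export
map_spacers <- function(spacers, refs, max_edits = 2L,
                        pam_offset = -2L, pam_width = 3L) {
  wrap <- if (length(spacers) > 0) {
    max(nchar(spacers)) + as.integer(max_edits) - 1L
  } else 0L
  ctx <- build_map_context(refs, wrap)
  rows <- lapply(spacers, map_spacer, refs = refs, max_edits = max_edits,
                 pam_offset = pam_offset, pam_width = pam_width, .ctx = ctx)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(spacer = character(0), source = character(0),
                      start = integer(0), strand = character(0),
                      edit_distance = integer(0), pam = character(0),
                      n_equal_best = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extract the PAM window of a mapped hit
#'
#' Returns, 5'->3' on the protospacer strand, the window at offsets
#' `pam_offset .. pam_offset + pam_width - 1` relative to the protospacer
#' start (position 0 = first protospacer base). The default (-2, 3) gives
#' the two genomic bases immediately upstream plus the first protospacer
#' base; circular wrap is applied.
#'
#' @param hit one-row data.frame from [map_spacer()] (must be mapped).
#' @param refs a [reference_set()].
#' @param spacer_length protospacer length; defaults to nchar(hit$spacer).
#' @param pam_offset,pam_width window definition.
#' @return PAM string.
#' @export
extract_pam <- function(hit, refs, spacer_length = nchar(hit$spacer),
                        pam_offset = -2L, pam_width = 3L) {
  if (!hit$source %in% c("chromosome", "plasmid")) {
    stop("extract_pam(): hit is not mapped to a single replicon")
  }
  rg <- ref_get(refs, hit$source)
  pam_window(rg$seq, hit$start, spacer_length, hit$strand, rg$circular,
             offset = pam_offset, width = pam_width)
}

#' Tabulate mapping categories
#'
#' @param hits data.frame from [map_spacers()].
#' @param weights optional per-hit weights (e.g. duplication counts) so
#'   the all-spacer rule can reuse hits mapped once per unique sequence.
#' @return named numeric vector: chromosome, plasmid, ambiguous, unmapped
#'   (sums to `sum(weights)`).
#' @export
classify_sources <- function(hits, weights = NULL) {
  cats <- c("chromosome", "plasmid", "ambiguous", "unmapped")
  if (is.null(weights)) weights <- rep(1, nrow(hits))
  stopifnot(length(weights) == nrow(hits))
  out <- vapply(cats, function(cc) sum(weights[hits$source == cc]), numeric(1))
  names(out) <- cats
  out
}
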