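## Reading-frame analytics: closed-form codon probabilities, per-spacer
## start/stop-codon annotation, and the duplication-frequency versus
## ATG-fraction trend.
##
## A repeat-spacer unit is a multiple of three bases, so an acquired
## spacer is read in a fixed frame into the reporter. Only the first
## `atg_window` bp (default 30, i.e. k = 10 codons) can contribute an
## in-frame ATG before translation runs into the downstream repeat.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Probability of an in-frame ATG with no downstream in-frame stop
#'
#' Under a uniform base model over `k` in-frame codons, the event is that
#' the last "special" codon (ATG or one of TAA/TAG/TGA) in the window is
#' an ATG. Reading codons right to left, ATG (1/64) must appear before
#' any stop (3/64):
#' `sum_{i=1..k} (60/64)^(i-1) * (1/64) = (1/4) * (1 - (60/64)^k)`.
#' At k = 10 this is ~0.119, the ~12% baseline of the reporter assay.
#'
#' @param k number of in-frame codons (>= 0).
#' @return probability.
#' @export
p_inframe_atg_no_stop <- function(k) {
  if (any(k < 0)) stop("p_inframe_atg_no_stop(): k must be >= 0")
  (1 / 4) * (1 - (60 / 64)^k)
}

#' Probability of no in-frame stop codon in k codons
#'
#' `(61/64)^k` under a uniform base model. At k = 10 this is ~0.619: the
#' theoretical detection limit of a reading-frame-restoration reporter,
#' since a spacer that introduces an in-frame stop cannot activate it.
#'
#' @param k number of in-frame codons (>= 0).
#' @return probability.
#' @export
p_no_inframe_stop <- function(k) {
  if (any(k < 0)) stop("p_no_inframe_stop(): k must be >= 0")
  (61 / 64)^k
}

#' Annotate a spacer's in-frame ATG/stop content
#'
#' Scans codons at positions `frame_offset`, `frame_offset + 3`, ...
#' within the first `atg_window` bp of the spacer. `has_inframe_atg` is
#' true iff some in-frame ATG has no in-frame stop codon after it within
#' the window (the definition matching the 12% baseline; set
#' `require_no_downstream_stop = FALSE` for the looser any-ATG rule).
#' Codons containing non-ACGT symbols are skipped and flagged.
#'
#' @param spacer spacer sequence.
#' @param model a [crispr_array_model()] supplying atg_window and
#'   frame_offset.
#' @param require_no_downstream_stop logical (default TRUE).
#' @return list(spacer, has_inframe_atg, has_inframe_stop, truncated,
#'   ambiguous_codons, k).
#' @export
annotate_frame <- function(spacer, model = crispr_array_model(),
                           require_no_downstream_stop = TRUE) {
  spacer <- toupper(spacer)
  win_start <- model$frame_offset + 1L
  win_end <- min(nchar(spacer), model$frame_offset + model$atg_window)
  truncated <- (nchar(spacer) - model$frame_offset) < model$atg_window
  window <- substr(spacer, win_start, win_end)
  k <- nchar(window) %/% 3L
  if (k == 0) {
    return(list(spacer = spacer, has_inframe_atg = FALSE,
                has_inframe_stop = FALSE, truncated = truncated,
                ambiguous_codons = 0L, k = 0L))
  }
  codons <- substring(window, 3L * (seq_len(k) - 1L) + 1L, 3L * seq_len(k))
  ok <- !grepl("[^ACGT]", codons)
  atg_pos <- which(ok & codons == "ATG")
  stop_pos <- which(ok & codons %in% STOP_CODONS)
  has_stop <- length(stop_pos) > 0
  has_atg <- if (require_no_downstream_stop) {
    length(atg_pos) > 0 && (!has_stop || max(atg_pos) > max(stop_pos))
  } else {
    length(atg_pos) > 0
  }
  list(spacer = spacer, has_inframe_atg = has_atg,
       has_inframe_stop = has_stop, truncated = truncated,
       ambiguous_codons = sum(!ok), k = k)
}

#' Annotate a vector of spacers
#'
#' @param spacers character vector.
#' @inheritParams annotate_frame
#' @return data.frame(spacer, has_inframe_atg, has_inframe_stop,
#'   truncated).
#' @export
annotate_frames <- function(spacers, model = crispr_array_model(),
                            require_no_downstream_stop = TRUE) {
  rows <- lapply(spacers, annotate_frame, model = model,
                 require_no_downstream_stop = require_no_downstream_stop)
  data.frame(spacer = vapply(rows, `[[`, character(1), "spacer"),
             has_inframe_atg = vapply(rows, `[[`, logical(1), "has_inframe_atg"),
             has_inframe_stop = vapply(rows, `[[`, logical(1), "has_inframe_stop"),
             truncated = vapply(rows, `[[`, logical(1), "truncated"),
             stringsAsFactors = FALSE)
}

## weighted rank correlation between x and y with weights w
weighted_rank_cor <- function(x, y, w) {
  if (length(x) < 2) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  mw <- function(v) sum(w * v) / sum(w)
  cx <- rx - mw(rx); cy <- ry - mw(ry)
  vx <- sum(w * cx^2); vy <- sum(w * cy^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * cx * cy) / sqrt(vx * vy)
}

bin_by_duplication <- function(dup, atg) {
  lv <- sort(unique(dup))
  n <- vapply(lv, function(d) sum(dup == d), integer(1))
  frac <- vapply(lv, function(d) mean(atg[dup == d]), numeric(1))
  data.frame(duplication_count = lv, n_spacers = n, atg_fraction = frac)
}

#' ATG fraction by duplication frequency, with a permutation trend test
#'
#' Groups unique spacers by duplication count (one bin per observed
#' count), computes the per-bin fraction carrying an in-frame ATG, and
#' tests for a trend using the rank correlation between duplication count
#' and ATG fraction weighted by bin size. The null distribution comes from
#' permuting duplication counts against annotations at the spacer level
#' (two-sided p-value).
#'
#' @param tally data.frame(spacer, duplication_count) from
#'   [collapse_duplicates()].
#' @param annotations data.frame from [annotate_frames()] covering every
#'   tallied spacer.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional seed for the permutation draw.
#' @return list(bins, trend, p_value, n_perm).
#' @export
atg_fraction_by_duplication <- function(tally, annotations, n_perm = 10000,
                                        seed = NULL) {
  if (nrow(tally) == 0) {
    return(list(bins = data.frame(duplication_count = integer(0),
                                  n_spacers = integer(0),
                                  atg_fraction = numeric(0)),
                trend = NA_real_, p_value = NA_real_, n_perm = 0L))
  }
  idx <- match(tally$spacer, annotations$spacer)
  if (anyNA(idx)) stop("atg_fraction_by_duplication(): unannotated spacer(s)")
  dup <- tally$duplication_count
  atg <- annotations$has_inframe_atg[idx]
  bins <- bin_by_duplication(dup, atg)
  stat <- function(d) {
    b <- bin_by_duplication(d, atg)
    weighted_rank_cor(b$duplication_count, b$atg_fraction, b$n_spacers)
  }
  obs <- stat(dup)
  if (is.na(obs) || n_perm == 0) {
    return(list(bins = bins, trend = obs, p_value = NA_real_, n_perm = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) perm[b] <- stat(sample(dup))
  perm <- perm[!is.na(perm)]
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (length(perm) + 1)
  list(bins = bins, trend = obs, p_value = p, n_perm = n_perm)
}
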