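# Dereplication at 100% identity with abundance tracking, frame-aware
# stop-codon filtering, and chimera + singleton removal.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a set of unique sequences
#'
#' @param seq character vector of distinct sequences.
#' @param size integer abundances (>= 1).
#' @param mode `"assembly"` or `"gap"`.
#' @param gap_junction junction coordinate shared by all members (gap
#'   mode only).
#' @return A data frame of class `unique_set` with attributes `mode` and
#'   `gap_junction`.
#' @export
unique_set <- function(seq, size, mode = c("assembly", "gap"),
                       gap_junction = NA_integer_) {
  mode <- match.arg(mode)
  if (anyDuplicated(seq)) stop("unique sequences must be distinct")
  if (length(size) && any(size < 1)) stop("abundances must be >= 1")
  out <- data.frame(seq = as.character(seq), size = as.integer(size),
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "gap_junction") <- as.integer(gap_junction)
  class(out) <- c("unique_set", "data.frame")
  out
}

#' Dereplicate amplicons at 100% identity
#'
#' Groups exactly identical sequences, keeping the read abundance as a
#' `size` annotation.  The output is sorted by abundance (descending),
#' ties broken lexicographically by sequence, and the sizes always sum
#' to the input count.
#'
#' @param amplicons an [amplicon_set] (all members one mode and, in gap
#'   mode, one junction coordinate) or a character vector of sequences.
#' @param mode,gap_junction used only when `amplicons` is a bare
#'   character vector.
#' @return A [unique_set].
#' @examples
#' dereplicate(amplicon_set(c("r1", "r2", "r3"), c("AC", "AC", "GT")))
#' @export
dereplicate <- function(amplicons, mode = c("assembly", "gap"),
                        gap_junction = NA_integer_) {
  if (inherits(amplicons, "amplicon_set")) {
    mode <- attr(amplicons, "mode")
    gap_junction <- attr(amplicons, "gap_junction")
    seqs <- amplicons$seq
  } else {
    mode <- match.arg(mode)
    seqs <- as.character(amplicons)
  }
  if (!length(seqs))
    return(unique_set(character(0), integer(0), mode, gap_junction))
  tab <- table(seqs)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  unique_set(names(tab)[ord], as.integer(tab)[ord], mode, gap_junction)
}

#' Frame-aware stop-codon filter
#'
#' Translates every unique sequence in the reading frame of the
#' reference gene and discards any that contains an in-frame stop codon
#' (TAA/TAG/TGA, standard code).  Assembly-mode sequences are translated
#' from `frame_offset` to the end, ignoring a trailing partial codon.
#' Gap-mode sequences are translated as two independent segments — the
#' forward segment `[frame_offset, gap_junction)` and the reverse
#' segment starting `rev_frame_offset` bases after the junction — so
#' that no codon ever spans the unsequenced gap.  Codons containing `N`
#' are skipped (counted but treated as neither stop nor non-stop).
#'
#' @param uniques a [unique_set].
#' @param frame_offset codon phase of position 1 (0, 1 or 2).
#' @param rev_frame_offset bases to skip after the gap junction so the
#'   reverse segment starts on a codon boundary (gap mode only).
#' @param stops stop codon set; override for non-standard codes.
#' @return A list with `kept` (a [unique_set]), `discarded` (data frame
#'   `seq`, `size`, `reason = "stop_codon"`) and `n_ambiguous_codons`
#'   (count of N-containing codons skipped).
#' @export
translation_filter <- function(uniques, frame_offset = 0L,
                               rev_frame_offset = 0L,
                               stops = STOP_CODONS) {
  stopifnot(inherits(uniques, "unique_set"), frame_offset %in% 0:2,
            rev_frame_offset %in% 0:2)
  mode <- attr(uniques, "mode")
  gj <- attr(uniques, "gap_junction")
  n_skip <- 0L
  has_stop <- logical(nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    s <- uniques$seq[i]
    if (mode == "assembly") {
      sc <- .scan_stops_with(s, frame_offset + 1L, nchar(s), stops)
      has_stop[i] <- sc$stop
      n_skip <- n_skip + sc$n_skipped
    } else {
      fwd <- .scan_stops_with(s, frame_offset + 1L, gj, stops)
      rev <- .scan_stops_with(s, gj + rev_frame_offset + 1L, nchar(s), stops)
      has_stop[i] <- fwd$stop || rev$stop
      n_skip <- n_skip + fwd$n_skipped + rev$n_skipped
    }
  }
  kept <- uniques[!has_stop, , drop = FALSE]
  attr(kept, "mode") <- mode
  attr(kept, "gap_junction") <- gj
  class(kept) <- c("unique_set", "data.frame")
  disc <- data.frame(seq = uniques$seq[has_stop],
                     size = uniques$size[has_stop],
                     reason = rep("stop_codon", sum(has_stop)),
                     stringsAsFactors = FALSE)
  list(kept = kept, discarded = disc, n_ambiguous_codons = n_skip)
}

.scan_stops_with <- function(seq, from, to, stops) {
  len <- to - from + 1L
  if (is.na(len) || len < 3L) return(list(stop = FALSE, n_skipped = 0L))
  starts <- seq.int(from, from + (len %/% 3L) * 3L - 3L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  has_n <- grepl("N", codons, fixed = TRUE)
  list(stop = any(codons[!has_n] %in% stops), n_skipped = sum(has_n))
}

#' De novo two-parent chimera flagging
#'
#' Flags a unique sequence as chimeric when two more abundant uniques A
#' and B (each with `size >= skew * candidate size`, `A != B`) and a
#' breakpoint `b` exist such that `A[1..b] + B[(b+1)..L]` reproduces the
#' candidate with at most `max_diffs` mismatches (both parent role
#' orders are covered by the pair search).  Only equal-length sequences
#' participate.  A candidate within `max_diffs` of a single more
#' abundant parent is never chimeric (it is a near-replicate, not a
#' breakpoint model).
#'
#' @param uniques a [unique_set] sorted by size descending (as produced
#'   by [dereplicate()]).
#' @param skew minimum parent/candidate abundance ratio (default 2).
#' @param max_diffs maximum mismatches of the best two-parent model
#'   (default 0).
#' @return Character vector, `"clean"` or `"chimeric"`, one per unique.
#' @export
flag_chimeras <- function(uniques, skew = 2.0, max_diffs = 0L) {
  stopifnot(inherits(uniques, "unique_set"))
  n <- nrow(uniques)
  out <- rep("clean", n)
  if (n < 3L) return(out)
  if (is.unsorted(-uniques$size))
    stop("uniques must be sorted by size descending")
  L <- nchar(uniques$seq)
  raws <- lapply(uniques$seq, charToRaw)
  for (i in 3:n) {
    parents <- which(uniques$size >= skew * uniques$size[i] &
                     seq_len(n) < i & L == L[i])
    if (length(parents) < 2L) next
    ci <- raws[[i]]
    # per-parent cumulative mismatch counts against the candidate
    pref <- vapply(parents, function(p) cumsum(raws[[p]] != ci),
                   numeric(L[i]))
    tot <- pref[L[i], ]
    if (any(tot <= max_diffs)) next       # matches a single parent
    suf <- -sweep(pref, 2L, tot)           # suf[b,] = diffs in (b..L]
    # best model over breakpoints 1..L-1 and ordered parent pairs A != B
    bs <- L[i] - 1L
    best <- Inf
    for (a in seq_along(parents)) {
      others <- setdiff(seq_along(parents), a)
      cand <- min(pref[seq_len(bs), a] +
                  apply(suf[seq_len(bs), others, drop = FALSE], 1L, min))
      best <- min(best, cand)
      if (best <= max_diffs) break
    }
    if (best <= max_diffs) out[i] <- "chimeric"
  }
  out
}

#' Drop singleton uniques
#'
#' Removes uniques with abundance 1.
#'
#' @param uniques a [unique_set].
#' @return The filtered [unique_set]; warns when everything was a
#'   singleton.
#' @export
remove_singletons <- function(uniques) {
  stopifnot(inherits(uniques, "unique_set"))
  keep <- uniques$size > 1L
  if (nrow(uniques) && !any(keep))
    warning("all uniques were singletons; result is empty")
  out <- uniques[keep, , drop = FALSE]
  attr(out, "mode") <- attr(uniques, "mode")
  attr(out, "gap_junction") <- attr(uniques, "gap_junction")
  class(out) <- c("unique_set", "data.frame")
  out
}

#' Denoise dereplicated uniques
#'
#' Applies, in pipeline order, the stop-codon translation filter,
#' two-parent chimera flagging and singleton removal, with per-step
#' abundance accounting.
#'
#' @param uniques a [unique_set] from [dereplicate()].
#' @inheritParams translation_filter
#' @inheritParams flag_chimeras
#' @param remove_chimeras set `FALSE` to skip chimera removal (ablation
#'   runs).
#' @return A list with `kept` (final [unique_set]) and `log` (data frame
#'   of per-step input/kept unique and abundance counts).
#' @export
denoise <- function(uniques, frame_offset = 0L, rev_frame_offset = 0L,
                    skew = 2.0, max_diffs = 0L, remove_chimeras = TRUE) {
  steps <- list()
  note <- function(stage, n_in, ab_in, n_out, ab_out) {
    steps[[length(steps) + 1L]] <<- data.frame(
      stage = stage, uniques_in = n_in, abundance_in = ab_in,
      uniques_kept = n_out, abundance_kept = ab_out,
      stringsAsFactors = FALSE)
  }
  tf <- translation_filter(uniques, frame_offset, rev_frame_offset)
  note("translation_filter", nrow(uniques), sum(uniques$size),
       nrow(tf$kept), sum(tf$kept$size))
  cur <- tf$kept
  if (remove_chimeras) {
    flags <- flag_chimeras(cur, skew = skew, max_diffs = max_diffs)
    nxt <- cur[flags == "clean", , drop = FALSE]
    attr(nxt, "mode") <- attr(cur, "mode")
    attr(nxt, "gap_junction") <- attr(cur, "gap_junction")
    class(nxt) <- c("unique_set", "data.frame")
    note("flag_chimeras", nrow(cur), sum(cur$size), nrow(nxt), sum(nxt$size))
    cur <- nxt
  }
  fin <- remove_singletons(cur)
  note("remove_singletons", nrow(cur), sum(cur$size), nrow(fin), sum(fin$size))
  list(kept = fin, log = do.call(rbind, steps))
}
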