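# The two read-joining strategies: scored overlap merging ("assembly")
# and reverse-complement concatenation ("gap"), plus post-merge amplicon
# truncation.

.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a set of processed amplicons
#'
#' @param read_id provenance read identifiers.
#' @param seq amplicon sequences.
#' @param mode `"assembly"` or `"gap"`.
#' @param gap_junction for gap mode, the 0-based index of the first base
#'   contributed by the reverse mate (identical for all members, since
#'   mates are truncated to a fixed length upstream); must be absent
#'   (`NA`) for assembly mode.
#' @return A data frame of class `amplicon_set` with attributes `mode`
#'   and `gap_junction`.
#' @export
amplicon_set <- function(read_id, seq, mode = c("assembly", "gap"),
                         gap_junction = NA_integer_) {
  mode <- match.arg(mode)
  if (mode == "gap") {
    if (is.na(gap_junction)) stop("gap mode requires a gap_junction")
    if (length(seq) && (gap_junction <= 0 || any(gap_junction >= nchar(seq))))
      stop("gap_junction must satisfy 0 < gap_junction < sequence length")
  } else if (!is.na(gap_junction)) {
    stop("assembly mode carries no gap_junction")
  }
  out <- data.frame(read_id = as.character(read_id),
                    seq = as.character(seq), stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "gap_junction") <- as.integer(gap_junction)
  class(out) <- c("amplicon_set", "data.frame")
  out
}

#' Merge one read pair by scored overlap
#'
#' Finds the ungapped overlap between the 3' end of the forward mate and
#' the 5' end of the reverse-complemented reverse mate, of length at
#' least `min_overlap`, maximising `matches - mismatches`, and requiring
#' fractional identity within the overlap of at least `min_identity`.
#' Score ties resolve to the longer overlap.  Candidate overlaps longer
#' than either mate are outside the search space (staggered
#' configurations are precluded by upstream truncation).  Within the
#' overlap, a mismatch is resolved in favour of the base with the higher
#' Phred score (forward wins ties) and that quality is kept; at matches
#' the quality is the maximum of the two.
#'
#' @param fwd_seq,fwd_qual forward mate sequence and Phred scores.
#' @param rev_seq,rev_qual reverse mate as sequenced (reverse
#'   complementing happens internally).
#' @param min_overlap minimum overlap length (default 10).
#' @param min_identity minimum fractional identity in the overlap
#'   (default 0.9).
#' @return A list with `seq`, `quals` and `overlap`, or `NULL` when no
#'   candidate overlap passes (`no_overlap`).
#' @export
merge_overlap <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                          min_overlap = 10L, min_identity = 0.9) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  rc_seq <- .revcomp(rev_seq)
  rc_qual <- rev(rev_qual)
  f <- charToRaw(fwd_seq)
  r <- charToRaw(rc_seq)
  nf <- length(f); nr <- length(r)
  omax <- min(nf, nr)
  if (omax < min_overlap) return(NULL)

  best_o <- 0L; best_score <- -Inf
  for (o in seq.int(min_overlap, omax)) {
    m <- sum(f[(nf - o + 1L):nf] == r[seq_len(o)])
    if (m / o < min_identity) next
    score <- 2L * m - o
    if (score > best_score || (score == best_score && o > best_o)) {
      best_score <- score; best_o <- o
    }
  }
  if (best_o == 0L) return(NULL)

  o <- best_o
  fi <- (nf - o + 1L):nf
  ri <- seq_len(o)
  fq <- fwd_qual[fi]; rq <- rc_qual[ri]
  ov_base <- f[fi]
  mism <- f[fi] != r[ri]
  take_rev <- mism & (rq > fq)
  ov_base[take_rev] <- r[ri][take_rev]
  ov_qual <- pmax(fq, rq)
  ov_qual[take_rev] <- rq[take_rev]
  ov_qual[mism & !take_rev] <- fq[mism & !take_rev]

  seq_out <- paste0(substr(fwd_seq, 1L, nf - o),
                    rawToChar(ov_base),
                    substr(rc_seq, o + 1L, nr))
  list(seq = seq_out,
       quals = c(fwd_qual[seq_len(nf - o)], ov_qual,
                 rc_qual[seq.int(o + 1L, length.out = nr - o)]),
       overlap = o)
}

#' Merge all pairs of a read set by overlap
#'
#' Applies [merge_overlap()] to every pair, memoising on the (forward,
#' reverse) sequence pair so that deeply replicated amplicon data incurs
#' one alignment per distinct pair.
#'
#' @param pairs a [paired_reads] object.
#' @inheritParams merge_overlap
#' @return A list with `amplicons` (an [amplicon_set] in assembly mode),
#'   `quals` (per-amplicon Phred lists, parallel to `amplicons`) and
#'   `failed` (ids of pairs with no acceptable overlap).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, min_identity = 0.9) {
  stopifnot(inherits(pairs, "paired_reads"))
  key <- paste(pairs$fwd_seq, pairs$rev_seq, sep = "\r")
  grp <- match(key, key)           # index of first occurrence
  firsts <- which(grp == seq_along(grp))
  cache <- vector("list", length(pairs))
  for (i in firsts) {
    cache[[i]] <- merge_overlap(pairs$fwd_seq[i], pairs$fwd_qual[[i]],
                                pairs$rev_seq[i], pairs$rev_qual[[i]],
                                min_overlap, min_identity)
  }
  res <- cache[grp]
  ok <- !vapply(res, is.null, logical(1))
  amp <- amplicon_set(pairs$id[ok],
                      vapply(res[ok], `[[`, character(1), "seq"),
                      mode = "assembly")
  list(amplicons = amp,
       quals = lapply(res[ok], `[[`, "quals"),
       failed = pairs$id[!ok])
}

#' Truncate merged amplicons to a fixed length
#'
#' Sequences at least `trunclen` long are cut to exactly `trunclen` from
#' the 5' end; shorter sequences are rejected.
#'
#' @param amplicons an [amplicon_set] (assembly mode) or character
#'   vector.
#' @param trunclen target length (default 448).
#' @return For an `amplicon_set`: a list with `kept` (truncated
#'   [amplicon_set]) and `rejected` (read ids).  For a character vector:
#'   the truncated sequences, with rejected entries dropped.
#' @export
truncate_amplicon <- function(amplicons, trunclen = 448L) {
  if (is.character(amplicons)) {
    keep <- nchar(amplicons) >= trunclen
    return(substr(amplicons[keep], 1L, trunclen))
  }
  stopifnot(inherits(amplicons, "amplicon_set"))
  keep <- nchar(amplicons$seq) >= trunclen
  kept <- amplicon_set(amplicons$read_id[keep],
                       substr(amplicons$seq[keep], 1L, trunclen),
                       mode = attr(amplicons, "mode"))
  list(kept = kept, rejected = amplicons$read_id[!keep])
}

#' Concatenate read pairs across an unsequenced gap
#'
#' The gap-route joining step: the reverse mate is reverse-complemented
#' and appended to the forward mate directly (no placeholder characters
#' are inserted); the junction coordinate is carried as metadata so that
#' translation and reporting can respect the two segments.  Both mates
#' must already be truncated to a common fixed length so the junction
#' sits at one coordinate for the whole set.
#'
#' @param pairs a [paired_reads] object with uniform mate lengths.
#' @return An [amplicon_set] in gap mode with `gap_junction` equal to
#'   the forward mate length.
#' @examples
#' p <- paired_reads("r1", "AAA", list(rep(40L, 3)), "TTT", list(rep(40L, 3)))
#' concat_gapped(p)$seq  # "AAAAAA"
#' @export
concat_gapped <- function(pairs) {
  stopifnot(inherits(pairs, "paired_reads"))
  if (!length(pairs)) stop("no read pairs to concatenate")
  if (any(!nzchar(pairs$fwd_seq)) || any(!nzchar(pairs$rev_seq)))
    stop("empty mate cannot be concatenated")
  fl <- unique(nchar(pairs$fwd_seq))
  rl <- unique(nchar(pairs$rev_seq))
  if (length(fl) != 1L || length(rl) != 1L)
    stop("mates must be truncated to a common length before concatenation")
  amplicon_set(pairs$id, paste0(pairs$fwd_seq, .revcomp(pairs$rev_seq)),
               mode = "gap", gap_junction = fl)
}
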