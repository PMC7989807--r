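# Per-read quality processing shared by both pipelines: 3' quality
# trimming, expected-error / N filtering, truncation and length selection.

#' Quality-control parameters
#'
#' Bundles the per-read filtering parameters used by both pipelines.
#'
#' @param trim_q Phred threshold for 3' quality trimming (default 15).
#' @param max_ee maximum expected errors per mate after truncation
#'   (default 2.0); a mate with expected errors strictly greater than
#'   `max_ee` is rejected, so a mate at exactly `max_ee` is kept.
#' @param max_n maximum number of ambiguous bases (`N`) per mate
#'   (default 0).
#' @param trunc_len truncation length per mate for the assembly route
#'   (default 229); mates shorter than this after trimming are rejected.
#' @param min_len minimum (and, by design, exact post-truncation) mate
#'   length for the gap route (default 200).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_q = 15L, max_ee = 2.0, max_n = 0L,
                      trunc_len = 229L, min_len = 200L) {
  stopifnot(trim_q >= 0, max_ee > 0, min_len >= 1)
  if (!is.null(trunc_len) && trunc_len < min_len)
    stop("trunc_len must be >= min_len")
  structure(list(trim_q = as.integer(trim_q), max_ee = as.numeric(max_ee),
                 max_n = as.integer(max_n),
                 trunc_len = if (is.null(trunc_len)) NULL else as.integer(trunc_len),
                 min_len = as.integer(min_len)),
            class = "qc_params")
}

#' 3' quality trimming
#'
#' Trims the 3' end of a read using the partial-sum algorithm used by
#' BWA and cutadapt: subtract `trim_q` from every quality, form running
#' sums from the 3' end, and cut at the position that minimises the
#' running sum (equivalently, keep the prefix that maximises the sum of
#' `qual - trim_q`; ties resolve to the shortest such prefix).  Never
#' lengthens a read; may return an empty read.
#'
#' @param seq DNA string.
#' @param quals integer Phred scores, same length as `seq`.
#' @param trim_q integer Phred threshold.
#' @return A list with elements `seq` and `quals` (the trimmed prefix).
#' @examples
#' quality_trim_3prime("ACGTT", c(40L, 40L, 2L, 2L, 2L), 15L)$seq
#' @export
quality_trim_3prime <- function(seq, quals, trim_q = 15L) {
  if (nchar(seq) != length(quals))
    stop("sequence and quality lengths differ")
  keep <- .trim_keep_length(quals, trim_q)
  list(seq = substr(seq, 1L, keep), quals = quals[seq_len(keep)])
}

# number of leading bases kept by the partial-sum trimmer: the prefix
# maximising sum(qual - trim_q), shortest prefix on ties (equivalently,
# cutting at the leftmost minimum of the 3'-end running sums)
.trim_keep_length <- function(quals, trim_q) {
  if (!length(quals)) return(0L)
  which.max(c(0, cumsum(quals - trim_q))) - 1L
}

#' Expected number of sequencing errors of a read
#'
#' The expected-error statistic underlying `maxEE` filtering:
#' \eqn{\sum_i 10^{-q_i/10}} over the read's Phred scores, i.e. the mean
#' number of erroneous bases implied by the qualities.
#'
#' @param quals integer Phred scores (empty gives 0).
#' @return A single non-negative number.
#' @examples
#' expected_errors(rep(20L, 100))  # 1.0
#' @export
expected_errors <- function(quals) {
  if (!length(quals)) return(0)
  sum(10^(-quals / 10))
}

#' Filter and truncate paired reads
#'
#' Applies the per-mate selection step of either pipeline to a set of
#' already quality-trimmed read pairs.  In `"assembly"` mode both mates
#' are truncated to exactly `trunc_len` (pairs with a shorter mate are
#' rejected); in `"gap"` mode both mates are truncated to exactly
#' `min_len` (pairs with a shorter mate are rejected).  After truncation
#' a pair is rejected if either mate's expected errors exceed `max_ee`
#' or its `N` count exceeds `max_n`.  Expected errors are computed on
#' the truncated read.
#'
#' @param pairs a [paired_reads] object (already 3'-trimmed).
#' @param params a [qc_params] object.
#' @param mode `"assembly"` or `"gap"`.
#' @return A list with elements `kept` (a [paired_reads]) and
#'   `rejections` (data frame with columns `id` and `reason`, reasons in
#'   `too_short`, `max_ee`, `max_n`).
#' @export
filter_and_truncate <- function(pairs, params = qc_params(),
                                mode = c("assembly", "gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pairs, "paired_reads"))
  target <- if (mode == "assembly") {
    if (is.null(params$trunc_len)) stop("assembly mode requires trunc_len")
    params$trunc_len
  } else params$min_len

  n <- length(pairs)
  reason <- rep(NA_character_, n)
  short <- nchar(pairs$fwd_seq) < target | nchar(pairs$rev_seq) < target
  reason[short] <- "too_short"

  ok <- which(!short)
  fseq <- substr(pairs$fwd_seq[ok], 1L, target)
  rseq <- substr(pairs$rev_seq[ok], 1L, target)
  fq <- lapply(pairs$fwd_qual[ok], function(q) q[seq_len(target)])
  rq <- lapply(pairs$rev_qual[ok], function(q) q[seq_len(target)])

  ee_bad <- vapply(fq, expected_errors, numeric(1)) > params$max_ee |
            vapply(rq, expected_errors, numeric(1)) > params$max_ee
  reason[ok[ee_bad]] <- "max_ee"
  left <- !ee_bad
  n_bad <- logical(length(ok))
  n_bad[left] <- .count_char(fseq[left], "N") > params$max_n |
                 .count_char(rseq[left], "N") > params$max_n
  reason[ok[n_bad]] <- "max_n"

  keep_local <- which(!ee_bad & !n_bad)
  kept <- structure(list(id = pairs$id[ok][keep_local],
                         fwd_seq = fseq[keep_local],
                         fwd_qual = fq[keep_local],
                         rev_seq = rseq[keep_local],
                         rev_qual = rq[keep_local]),
                    class = "paired_reads")
  rej <- which(!is.na(reason))
  list(kept = kept,
       rejections = data.frame(id = pairs$id[rej], reason = reason[rej],
                               stringsAsFactors = FALSE))
}

.count_char <- function(x, ch) {
  if (!length(x)) return(integer(0))
  nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
}

#' Trim and filter paired reads in one step
#'
#' Convenience wrapper running [quality_trim_3prime()] on both mates of
#' every pair followed by [filter_and_truncate()], i.e. the complete
#' per-read quality-control stage of either pipeline (trim, truncate,
#' then expected-error and N tests on the truncated read).
#'
#' @inheritParams filter_and_truncate
#' @return As [filter_and_truncate()].
#' @export
qc_reads <- function(pairs, params = qc_params(),
                     mode = c("assembly", "gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pairs, "paired_reads"))
  fk <- vapply(pairs$fwd_qual, .trim_keep_length, integer(1),
               trim_q = params$trim_q)
  rk <- vapply(pairs$rev_qual, .trim_keep_length, integer(1),
               trim_q = params$trim_q)
  trimmed <- structure(list(
    id = pairs$id,
    fwd_seq = substr(pairs$fwd_seq, 1L, fk),
    fwd_qual = Map(function(q, k) q[seq_len(k)], pairs$fwd_qual, fk),
    rev_seq = substr(pairs$rev_seq, 1L, rk),
    rev_qual = Map(function(q, k) q[seq_len(k)], pairs$rev_qual, rk)),
    class = "paired_reads")
  filter_and_truncate(trimmed, params, mode)
}
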