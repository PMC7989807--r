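# Identity-based assignment of processed sequences to reference
# phylogenetic clusters at multiple identity thresholds, producing
# per-sample abundance matrices.

.pkg_cache <- new.env(parent = emptyenv())
.nuc_mat <- function() {
  if (is.null(.pkg_cache$nuc_mat))
    .pkg_cache$nuc_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  .pkg_cache$nuc_mat
}

# Vectorised global alignment of queries against one reference.
# type "global": end gaps penalised, identity = matches / alignment
# columns.  type "global-local": query global, reference end gaps free;
# identity denominator excludes the free end-gap columns (the reference
# overhang is simply not part of the alignment).
.align_identity <- function(queries, ref, type = "global") {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries), subject = ref,
    type = type, substitutionMatrix = .nuc_mat(),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::pattern(pa)))
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap
#' opening -2 and gap extension -1 (a gap of length L costs 2 + L).
#' Identity is the number of matching columns divided by the number of
#' alignment columns.  For gap-mode queries (`gap_junction` given) the
#' two sequenced segments are aligned independently against the
#' full-length reference with reference end gaps free, and the identity
#' is pooled over both segments; end-gap columns are excluded from the
#' denominator.
#'
#' @param query query sequence.
#' @param ref reference sequence.
#' @param gap_junction `NULL` for contiguous (assembly) queries, else
#'   the 0-based junction coordinate of the gapped query.
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(query, ref, gap_junction = NULL) {
  stopifnot(nzchar(query), nzchar(ref))
  if (is.null(gap_junction) || is.na(gap_junction))
    return(.align_identity(query, ref, "global"))
  .gapped_identity(query, ref, gap_junction)
}

.gapped_identity <- function(queries, ref, gj) {
  fwd <- substr(queries, 1L, gj)
  rev <- substr(queries, gj + 1L, nchar(queries))
  pa_f <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(fwd), subject = ref,
    type = "global-local", substitutionMatrix = .nuc_mat(),
    gapOpening = 2, gapExtension = 1)
  pa_r <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rev), subject = ref,
    type = "global-local", substitutionMatrix = .nuc_mat(),
    gapOpening = 2, gapExtension = 1)
  m <- Biostrings::nmatch(pa_f) + Biostrings::nmatch(pa_r)
  cols <- nchar(as.character(Biostrings::pattern(pa_f))) +
          nchar(as.character(Biostrings::pattern(pa_r)))
  m / cols
}

# identity matrix: uniques x references
.identity_matrix <- function(seqs, refdb, gap_junction = NA_integer_) {
  out <- matrix(0, nrow = length(seqs), ncol = nrow(refdb))
  for (j in seq_len(nrow(refdb))) {
    out[, j] <- if (is.na(gap_junction))
      .align_identity(seqs, refdb$seq[j], "global")
    else
      .gapped_identity(seqs, refdb$seq[j], gap_junction)
  }
  out
}

#' Assign unique sequences to reference clusters
#'
#' Exhaustive best-hit search over all references by global alignment
#' identity; the best hit's cluster is assigned iff its identity reaches
#' `threshold`, otherwise the sequence is `"unassigned"`.  Identity ties
#' resolve to the first reference in database order.  Gap-mode queries
#' use the junction-aware end-gap-free comparison (see
#' [global_identity()]).
#'
#' @param uniques a [unique_set] (or character vector of sequences).
#' @param refdb a [reference_db].
#' @param threshold identity cut-off in `(0, 1]`.
#' @return Character vector of cluster labels (or `"unassigned"`), one
#'   per unique.
#' @export
assign_clusters <- function(uniques, refdb, threshold = 0.97) {
  stopifnot(inherits(refdb, "reference_db"))
  if (!nrow(refdb)) stop("reference database is empty")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  gj <- if (inherits(uniques, "unique_set") &&
            identical(attr(uniques, "mode"), "gap"))
    attr(uniques, "gap_junction") else NA_integer_
  seqs <- if (is.data.frame(uniques)) uniques$seq else as.character(uniques)
  if (!length(seqs)) return(character(0))
  idm <- .identity_matrix(seqs, refdb, gj)
  best <- max.col(idm, ties.method = "first")
  best_id <- idm[cbind(seq_along(seqs), best)]
  ifelse(best_id >= threshold - 1e-12, refdb$cluster[best], "unassigned")
}

#' Build per-sample cluster abundance matrices at several thresholds
#'
#' Runs the best-hit search once per sample and applies every identity
#' threshold to the cached best hits, accumulating unique abundances
#' (`size`) into samples x clusters count matrices.  Cluster columns
#' follow database order, with a reserved final `"unassigned"` column;
#' all matrices share sample and cluster ordering.
#'
#' @param sample_uniques named list of [unique_set] objects, one per
#'   sample.
#' @param refdb a [reference_db].
#' @param thresholds identity cut-offs (default `c(0.9, 0.95, 0.97, 1)`).
#' @return A named list of `abundance_matrix` objects (integer matrices
#'   with a `threshold` attribute), one per threshold.
#' @export
build_matrices <- function(sample_uniques, refdb,
                           thresholds = c(0.9, 0.95, 0.97, 1.0)) {
  stopifnot(inherits(refdb, "reference_db"), length(sample_uniques) > 0)
  if (is.null(names(sample_uniques)))
    names(sample_uniques) <- paste0("S", seq_along(sample_uniques))
  clusters <- unique(refdb$cluster)
  cols <- c(clusters, "unassigned")
  hits <- lapply(sample_uniques, function(u) {
    gj <- if (identical(attr(u, "mode"), "gap"))
      attr(u, "gap_junction") else NA_integer_
    if (!nrow(u))
      return(data.frame(cluster = character(0), identity = numeric(0),
                        size = integer(0)))
    idm <- .identity_matrix(u$seq, refdb, gj)
    best <- max.col(idm, ties.method = "first")
    data.frame(cluster = refdb$cluster[best],
               identity = idm[cbind(seq_len(nrow(u)), best)],
               size = u$size, stringsAsFactors = FALSE)
  })
  out <- lapply(thresholds, function(th) {
    m <- matrix(0L, nrow = length(sample_uniques), ncol = length(cols),
                dimnames = list(names(sample_uniques), cols))
    for (s in names(sample_uniques)) {
      h <- hits[[s]]
      lab <- ifelse(h$identity >= th - 1e-12, h$cluster, "unassigned")
      agg <- tapply(h$size, factor(lab, levels = cols), sum)
      agg[is.na(agg)] <- 0L
      m[s, ] <- as.integer(agg)
    }
    attr(m, "threshold") <- th
    class(m) <- c("abundance_matrix", class(m))
    m
  })
  names(out) <- paste0("id", thresholds)
  out
}

#' Relative-abundance view of an abundance matrix
#'
#' @param mat an `abundance_matrix` (samples x clusters counts).
#' @param drop_unassigned exclude the `"unassigned"` column before
#'   normalising (the default for the ecology layer).
#' @return Matrix of row-normalised relative abundances; all-zero rows
#'   stay zero.
#' @export
relative_abundance <- function(mat, drop_unassigned = TRUE) {
  m <- unclass(mat)
  if (drop_unassigned && "unassigned" %in% colnames(m))
    m <- m[, colnames(m) != "unassigned", drop = FALSE]
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1L, rs, "/")
}

#' Bin relative abundances for heatmap export
#'
#' Bins a relative-abundance matrix at fixed intervals (default 12.5%),
#' returning integer bin indices (0 = zero abundance, k = abundance in
#' `((k-1)w, kw]`).
#'
#' @param rel relative-abundance matrix from [relative_abundance()].
#' @param width bin width (default 0.125).
#' @return Integer matrix of bin indices with the same dimnames.
#' @export
abundance_bins <- function(rel, width = 0.125) {
  b <- ceiling(pmax(rel, 0) / width - 1e-9)
  b[rel <= 0] <- 0L
  storage.mode(b) <- "integer"
  b
}
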