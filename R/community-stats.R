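# Method-comparison layer: per-sample Bray-Curtis and Pearson against a
# designated reference method, and analytic rarefied richness.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' Both vectors are first normalised to relative abundances; the
#' statistic is \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, which is
#' 0 for identical compositions and 1 for disjoint supports.  Note this
#' is a \emph{dissimilarity} (0 = identical), the convention of
#' `vegan::vegdist`.
#'
#' @param x,y equal-length non-negative vectors.
#' @return Dissimilarity in `[0, 1]`, or `NA` (with a warning) when
#'   both vectors are all-zero.
#' @examples
#' bray_curtis(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0) {
    warning("both vectors are all-zero; Bray-Curtis undefined")
    return(NA_real_)
  }
  if (sum(x) == 0 || sum(y) == 0) return(1)
  x <- x / sum(x); y <- y / sum(y)
  sum(abs(x - y)) / sum(x + y)
}

#' Pearson correlation of two relative-abundance vectors
#'
#' Standard product-moment correlation after normalising both vectors
#' to relative abundances.
#'
#' @param x,y equal-length vectors (length >= 2).
#' @param relative normalise to relative abundances first (default).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
pearson_cor <- function(x, y, relative = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (relative) {
    if (sum(x) > 0) x <- x / sum(x)
    if (sum(y) > 0) y <- y / sum(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; Pearson correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Analytic rarefied richness (Hurlbert's expectation)
#'
#' Expected number of distinct types in a random subsample of `n` reads
#' drawn without replacement:
#' \eqn{E[S_n] = \sum_i [1 - C(N - N_i, n) / C(N, n)]} with
#' \eqn{N = \sum_i N_i}.  Binomial coefficients are evaluated in log
#' space.
#'
#' @param counts non-negative integer abundance vector.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return Expected richness (equals observed richness at `n = N`).
#' @examples
#' rarefied_richness(c(5, 5), 2)  # 2 * (1 - choose(5,2)/choose(10,2))
#' @export
rarefied_richness <- function(counts, n) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n > N) stop(sprintf("subsample size %d exceeds total count %d", n, N))
  if (n < 1) stop("subsample size must be >= 1")
  miss <- ifelse(N - counts < n, 0,
                 exp(lchoose(N - counts, n) - lchoose(N, n)))
  sum(1 - miss)
}

#' Compare two community matrices per sample
#'
#' For every sample shared between two abundance matrices (e.g. the
#' assembly- and gap-route assignments of the same soils), computes the
#' Pearson correlation and Bray-Curtis dissimilarity of the two
#' relative-abundance rows over the union of their cluster labels
#' (absent clusters count as zero).  The first matrix is the designated
#' reference method.
#'
#' @param ref,alt `abundance_matrix` objects (samples x clusters).
#' @param reference_method,comparand_method labels for reporting.
#' @param drop_unassigned exclude the `"unassigned"` column (default).
#' @param relative compare relative abundances (default) rather than
#'   raw counts.
#' @return A data frame of class `comparison_report` with one row per
#'   shared sample (`sample_id`, `pearson_r`, `bray_curtis`); samples
#'   present in only one matrix are listed in the
#'   `missing_samples` attribute.
#' @export
compare_methods <- function(ref, alt, reference_method = "reference",
                            comparand_method = "comparand",
                            drop_unassigned = TRUE, relative = TRUE) {
  shared <- intersect(rownames(ref), rownames(alt))
  if (!length(shared)) stop("no shared samples between the two matrices")
  strip <- function(m) {
    m <- unclass(m)
    if (drop_unassigned && "unassigned" %in% colnames(m))
      m <- m[, colnames(m) != "unassigned", drop = FALSE]
    m
  }
  a <- strip(ref); b <- strip(alt)
  cols <- union(colnames(a), colnames(b))
  expand <- function(m) {
    out <- matrix(0, nrow(m), length(cols),
                  dimnames = list(rownames(m), cols))
    out[, colnames(m)] <- m
    out
  }
  a <- expand(a); b <- expand(b)
  rows <- lapply(shared, function(s) {
    x <- a[s, ]; y <- b[s, ]
    if (relative) {
      if (sum(x) > 0) x <- x / sum(x)
      if (sum(y) > 0) y <- y / sum(y)
    }
    data.frame(sample_id = s,
               pearson_r = suppressWarnings(pearson_cor(x, y, relative = FALSE)),
               bray_curtis = suppressWarnings(bray_curtis(x, y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_method") <- reference_method
  attr(out, "comparand_method") <- comparand_method
  attr(out, "missing_samples") <-
    c(setdiff(rownames(ref), shared), setdiff(rownames(alt), shared))
  class(out) <- c("comparison_report", "data.frame")
  out
}
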