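# Front-end chaining the modules into the two named pipelines, with
# per-stage read accounting.

#' Pipeline parameters
#'
#' All tunables of [run_pipeline()] in one object.
#'
#' @param qc a [qc_params()] object.
#' @param min_overlap,min_identity overlap-merge gates (assembly route;
#'   see [merge_overlap()]).
#' @param trunclen post-merge amplicon truncation length (assembly
#'   route; default 448).
#' @param frame_offset,rev_frame_offset codon phases for the
#'   translation filter (see [translation_filter()]); overridden by the
#'   reference database's offsets when a `refdb` is supplied to
#'   [run_pipeline()].
#' @param skew,max_diffs chimera-flagging parameters (see
#'   [flag_chimeras()]).
#' @param remove_chimeras set `FALSE` for ablation runs.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(qc = qc_params(), min_overlap = 10L,
                            min_identity = 0.9, trunclen = 448L,
                            frame_offset = 0L, rev_frame_offset = 0L,
                            skew = 2.0, max_diffs = 0L,
                            remove_chimeras = TRUE) {
  structure(list(qc = qc, min_overlap = as.integer(min_overlap),
                 min_identity = min_identity, trunclen = as.integer(trunclen),
                 frame_offset = as.integer(frame_offset),
                 rev_frame_offset = as.integer(rev_frame_offset),
                 skew = skew, max_diffs = as.integer(max_diffs),
                 remove_chimeras = isTRUE(remove_chimeras)),
            class = "pipeline_params")
}

#' Run the assembly or gap pipeline on a set of samples
#'
#' Executes, per sample and in fixed order: 3' quality trimming;
#' expected-error/N filtering with truncation; read joining (scored
#' overlap merge plus amplicon truncation in `"assembly"` mode,
#' reverse-complement concatenation in `"gap"` mode); dereplication at
#' 100% identity; stop-codon translation filtering; chimera flagging;
#' and singleton removal.  The run is deterministic given its inputs.
#'
#' @param samples a manifest path, a `sample_manifest` data frame, or a
#'   named list of [paired_reads] objects.
#' @param mode `"assembly"` or `"gap"`.
#' @param params a [pipeline_params()] object.
#' @param refdb optional [reference_db]; when given, its frame offsets
#'   override those in `params`.
#' @return A list of class `pipeline_run`: `uniques` (named list of
#'   final [unique_set] objects), `record` (long data frame of
#'   per-sample, per-stage input/kept counts whose stages telescope),
#'   `mode` and `params`.
#' @examples
#' cfg <- sim_config(n_clusters = 2, refs_per_cluster = 1, n_samples = 1,
#'                   depth = 50, errors = FALSE, seed = 7)
#' sim <- simulate_dataset(cfg)
#' run <- run_pipeline(sim$samples, mode = "assembly", refdb = sim$refdb)
#' run$record
#' @export
run_pipeline <- function(samples, mode = c("assembly", "gap"),
                         params = pipeline_params(), refdb = NULL) {
  mode <- match.arg(mode)
  if (is.character(samples) && length(samples) == 1L)
    samples <- read_manifest(samples)
  if (inherits(samples, "sample_manifest")) {
    man <- samples
    samples <- lapply(seq_len(nrow(man)), function(i)
      read_fastq_pairs(man$fastq_fwd[i], man$fastq_rev[i]))
    names(samples) <- man$sample_id
  }
  if (!length(samples)) stop("no samples to process")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be named")
  fo <- params$frame_offset
  ro <- params$rev_frame_offset
  if (!is.null(refdb)) {
    fo <- attr(refdb, "frame_offset")
    ro <- attr(refdb, "rev_frame_offset")
  }

  uniques <- list(); records <- list()
  for (s in names(samples)) {
    rec <- function(stage, n_in, n_out)
      data.frame(sample_id = s, stage = stage, n_in = n_in, n_out = n_out,
                 stringsAsFactors = FALSE)
    rd <- samples[[s]]
    if (!inherits(rd, "paired_reads"))
      stop(sprintf("sample '%s' is not a paired_reads object", s))
    r <- tryCatch({
      qcr <- qc_reads(rd, params$qc, mode)
      steps <- rec("qc", length(rd), length(qcr$kept))
      if (mode == "assembly") {
        mg <- merge_pairs(qcr$kept, params$min_overlap, params$min_identity)
        steps <- rbind(steps, rec("merge", length(qcr$kept),
                                  nrow(mg$amplicons)))
        tr <- truncate_amplicon(mg$amplicons, params$trunclen)
        steps <- rbind(steps, rec("truncate", nrow(mg$amplicons),
                                  nrow(tr$kept)))
        amp <- tr$kept
      } else {
        amp <- concat_gapped(qcr$kept)
        steps <- rbind(steps, rec("concat", length(qcr$kept), nrow(amp)))
      }
      uq <- dereplicate(amp)
      dn <- denoise(uq, frame_offset = fo, rev_frame_offset = ro,
                    skew = params$skew, max_diffs = params$max_diffs,
                    remove_chimeras = params$remove_chimeras)
      for (i in seq_len(nrow(dn$log)))
        steps <- rbind(steps, rec(dn$log$stage[i], dn$log$abundance_in[i],
                                  dn$log$abundance_kept[i]))
      list(uniques = dn$kept, steps = steps)
    }, error = function(e)
      stop(sprintf("pipeline failed at sample '%s': %s", s,
                   conditionMessage(e)), call. = FALSE))
    uniques[[s]] <- r$uniques
    records[[s]] <- r$steps
  }
  structure(list(uniques = uniques, record = do.call(rbind, records),
                 mode = mode, params = params),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run (%s mode): %d sample(s)\n", x$mode,
              length(x$uniques)))
  tot <- vapply(x$uniques, function(u) sum(u$size), numeric(1))
  for (s in names(x$uniques))
    cat(sprintf("  %s: %d uniques, %d reads retained\n", s,
                nrow(x$uniques[[s]]), tot[s]))
  invisible(x)
}
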