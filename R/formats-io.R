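# Readers and writers for the formats the pipeline consumes and emits:
# paired FASTQ (Phred+33), FASTA with ";size=" abundance annotations,
# reference FASTA with cluster labels, TSV manifests/metadata and the
# strain-lineage table.

PHRED_OFFSET <- 33L

# ---- paired_reads container -------------------------------------------------

#' Construct a set of paired-end reads
#'
#' A `paired_reads` object holds parallel vectors for a set of read pairs:
#' identifiers, forward/reverse sequences and per-base integer Phred
#' scores (lists of integer vectors).
#'
#' @param id character vector of read identifiers.
#' @param fwd_seq,rev_seq character vectors of DNA sequences over
#'   `{A,C,G,T,N}`.
#' @param fwd_qual,rev_qual lists of integer Phred score vectors, one per
#'   read, each the same length as the corresponding sequence.
#' @return An object of class `paired_reads`.
#' @export
paired_reads <- function(id, fwd_seq, fwd_qual, rev_seq, rev_qual) {
  n <- length(id)
  stopifnot(length(fwd_seq) == n, length(rev_seq) == n,
            length(fwd_qual) == n, length(rev_qual) == n)
  if (anyDuplicated(id)) stop("read identifiers must be unique")
  chk_len <- function(seqs, quals, mate) {
    bad <- which(nchar(seqs) != lengths(quals))
    if (length(bad))
      stop(sprintf("%s sequence/quality length mismatch for read '%s'",
                   mate, id[bad[1]]))
  }
  chk_len(fwd_seq, fwd_qual, "forward")
  chk_len(rev_seq, rev_qual, "reverse")
  rng <- range(c(0L, unlist(fwd_qual, use.names = FALSE),
                 unlist(rev_qual, use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > 60)
    stop("Phred scores must lie in [0, 60]")
  structure(list(id = as.character(id),
                 fwd_seq = as.character(fwd_seq), fwd_qual = fwd_qual,
                 rev_seq = as.character(rev_seq), rev_qual = rev_qual),
            class = "paired_reads")
}

#' @export
length.paired_reads <- function(x) length(x$id)

#' @export
`[.paired_reads` <- function(x, i) {
  structure(list(id = x$id[i],
                 fwd_seq = x$fwd_seq[i], fwd_qual = x$fwd_qual[i],
                 rev_seq = x$rev_seq[i], rev_qual = x$rev_qual[i]),
            class = "paired_reads")
}

#' @export
print.paired_reads <- function(x, ...) {
  cat(sprintf("paired_reads: %d read pairs\n", length(x)))
  if (length(x)) {
    cat(sprintf("  forward lengths: %s\n",
                paste(range(nchar(x$fwd_seq)), collapse = "-")))
    cat(sprintf("  reverse lengths: %s\n",
                paste(range(nchar(x$rev_seq)), collapse = "-")))
  }
  invisible(x)
}

# ---- FASTQ ------------------------------------------------------------------

.decode_phred <- function(qual_strings) {
  lapply(qual_strings, function(q) {
    if (!nzchar(q)) return(integer(0))
    utf8ToInt(q) - PHRED_OFFSET
  })
}

.encode_phred <- function(qual_ints) {
  vapply(qual_ints, function(q) {
    if (!length(q)) return("")
    intToUtf8(q + PHRED_OFFSET)
  }, character(1))
}

# Heuristic rejection of Phred+64 input: quality bytes never drop below
# '@' (ASCII 64) while bytes above 'J' (ASCII 74) occur. Genuine Phred+33
# data essentially always contains some character below '@' (Q < 31).
.check_phred33 <- function(qual_strings, path) {
  ints <- utf8ToInt(paste(qual_strings, collapse = ""))
  if (length(ints) && !any(ints < 64) && any(ints > 74))
    stop(sprintf(paste0("quality strings in '%s' look Phred+64 encoded ",
                        "(no character below '@', characters above 'J' ",
                        "present); re-encode as Phred+33"), path))
}

.read_fastq_one <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]            # tolerate trailing blank lines
  if (length(lines) %% 4 != 0)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record starts at line %d)",
                 path, length(lines), 4L * (length(lines) %/% 4L) + 1L))
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {      # benign notice about dropped mcols
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual_strings <- as.character(Biostrings::quality(x))
  .check_phred33(qual_strings, path)
  list(id = sub("[ \t].*$", "", names(x)),
       seq = as.character(x),
       qual = .decode_phred(qual_strings))
}

#' Read paired FASTQ files
#'
#' Reads two FASTQ files (4-line records, Phred+33) holding the forward
#' and reverse mates of the same read pairs, in the same order.  Records
#' are matched positionally and identifiers are checked (ignoring a
#' trailing `/1` or `/2` mate suffix).
#'
#' @param fwd_path,rev_path paths to the forward and reverse FASTQ files.
#' @return A [paired_reads] object.
#' @examples
#' cfg <- sim_config(n_clusters = 2, refs_per_cluster = 1, n_samples = 1,
#'                   depth = 20, seed = 1)
#' sim <- simulate_dataset(cfg, dir = tempfile("sim"))
#' rd <- read_fastq_pairs(sim$manifest$fastq_fwd[1], sim$manifest$fastq_rev[1])
#' length(rd)
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  if (!file.exists(fwd_path)) stop(sprintf("no such file: '%s'", fwd_path))
  if (!file.exists(rev_path)) stop(sprintf("no such file: '%s'", rev_path))
  fwd <- .read_fastq_one(fwd_path)
  rev <- .read_fastq_one(rev_path)
  if (length(fwd$id) != length(rev$id))
    stop(sprintf("record count mismatch: %d forward vs %d reverse records",
                 length(fwd$id), length(rev$id)))
  fid <- sub("/[12]$", "", fwd$id)
  rid <- sub("/[12]$", "", rev$id)
  bad <- which(fid != rid)
  if (length(bad))
    stop(sprintf("identifier mismatch at record %d: '%s' vs '%s'",
                 bad[1], fwd$id[bad[1]], rev$id[bad[1]]))
  paired_reads(fid, fwd$seq, fwd$qual, rev$seq, rev$qual)
}

#' Write paired FASTQ files
#'
#' Inverse of [read_fastq_pairs()]; emits 4-line Phred+33 records.
#'
#' @param reads a [paired_reads] object.
#' @param fwd_path,rev_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, fwd_path, rev_path) {
  stopifnot(inherits(reads, "paired_reads"))
  emit <- function(id, seq, qual, path) {
    writeLines(as.vector(rbind(paste0("@", id), seq, "+",
                               .encode_phred(qual))), path)
  }
  emit(reads$id, reads$fwd_seq, reads$fwd_qual, fwd_path)
  emit(reads$id, reads$rev_seq, reads$rev_qual, rev_path)
  invisible(c(fwd_path, rev_path))
}

# ---- FASTA with size annotations -------------------------------------------

#' Write unique sequences as FASTA with `;size=` abundance annotations
#'
#' Headers carry the dereplicated abundance in the `;size=N` dialect so
#' that abundance-aware downstream steps (chimera detection, assignment)
#' can consume the file.  Sequences are emitted unwrapped.
#'
#' @param uniques a [unique_set] (or data frame with columns `seq` and
#'   `size`).
#' @param path output path.
#' @param ids optional header identifiers; defaults to `Uniq1..UniqN`.
#' @return Invisibly, `path`.
#' @export
write_fasta_sized <- function(uniques, path, ids = NULL) {
  if (!all(c("seq", "size") %in% names(uniques)))
    stop("'uniques' must have columns 'seq' and 'size'")
  if (nrow(uniques) && any(uniques$size < 1))
    stop("abundances must be >= 1")
  if (is.null(ids)) ids <- paste0("Uniq", seq_len(nrow(uniques)))
  x <- Biostrings::DNAStringSet(uniques$seq)
  names(x) <- sprintf("%s;size=%d", ids, as.integer(uniques$size))
  Biostrings::writeXStringSet(x, path, width = 100000L)
  invisible(path)
}

#' Read FASTA with `;size=` abundance annotations
#'
#' @param path input FASTA path.
#' @return A [unique_set] with columns `seq` and `size` (and the header
#'   ids in `id`), in file order.
#' @export
read_fasta_sized <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(x), regexec(";size=([0-9]+)", names(x)))
  size <- vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else NA_integer_,
                 integer(1))
  if (anyNA(size))
    stop("FASTA headers lack ';size=N' annotations")
  out <- data.frame(seq = as.character(x), size = size,
                    id = sub(";size=[0-9]+.*$", "", names(x)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("unique_set", "data.frame")
  out
}

# ---- reference database -----------------------------------------------------

#' Construct a reference cluster database
#'
#' Labelled reference sequences grouped into named phylogenetic clusters,
#' plus the codon phase information needed by the translation filter:
#' `frame_offset` is the codon phase of position 1 of the amplicon and
#' `rev_frame_offset` the number of bases to skip after the gap junction
#' so that translation of the reverse segment starts on a codon boundary.
#'
#' @param ref_id,cluster,seq parallel vectors describing the references.
#' @param frame_offset integer in `{0,1,2}`.
#' @param rev_frame_offset integer in `{0,1,2}`.
#' @return An object of class `reference_db` (a data frame with
#'   attributes).
#' @export
reference_db <- function(ref_id, cluster, seq, frame_offset = 0L,
                         rev_frame_offset = 0L) {
  if (anyDuplicated(ref_id)) stop("reference ids must be unique")
  if (any(!nzchar(cluster))) stop("every reference needs a cluster label")
  if (any(!nzchar(seq))) stop("reference sequences must be non-empty")
  stopifnot(frame_offset %in% 0:2, rev_frame_offset %in% 0:2)
  db <- data.frame(ref_id = as.character(ref_id),
                   cluster = as.character(cluster),
                   seq = toupper(as.character(seq)),
                   stringsAsFactors = FALSE)
  attr(db, "frame_offset") <- as.integer(frame_offset)
  attr(db, "rev_frame_offset") <- as.integer(rev_frame_offset)
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Read a reference database FASTA
#'
#' Headers follow the dialect `>refID cluster=LABEL`.
#'
#' @param path FASTA path.
#' @param frame_offset,rev_frame_offset codon phases, see [reference_db()].
#' @return A [reference_db].
#' @export
read_reference_db <- function(path, frame_offset = 0L, rev_frame_offset = 0L) {
  x <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(x), regexec("cluster=([^ ;]+)", names(x)))
  cl <- vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_,
               character(1))
  if (anyNA(cl))
    stop("reference FASTA headers must carry 'cluster=LABEL'")
  reference_db(sub("[ \t].*$", "", names(x)), cl, as.character(x),
               frame_offset, rev_frame_offset)
}

#' Write a reference database FASTA
#'
#' @param db a [reference_db].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_reference_db <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- sprintf("%s cluster=%s", db$ref_id, db$cluster)
  Biostrings::writeXStringSet(x, path, width = 100000L)
  invisible(path)
}

# ---- strain table -----------------------------------------------------------

#' Load a strain lineage table
#'
#' Reads a TSV with columns `organism`, `amoa_lineage` and `rrna_lineage`
#' mapping cultivated strains to their functional-gene and 16S rRNA gene
#' phylogenetic lineages.  The curated Nitrosospira table shipped with
#' the package is at
#' `system.file("extdata", "nitrosospira_strains.tsv", package = "gapkit")`.
#'
#' @param path TSV path with a header row.
#' @return A data frame of class `strain_table`.
#' @examples
#' tab <- load_strain_table(system.file("extdata",
#'   "nitrosospira_strains.tsv", package = "gapkit"))
#' lineage_counts(tab)
#' @export
load_strain_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(first)) {
    warning(sprintf("strain table '%s' is empty", path))
    out <- data.frame(organism = character(0), amoa_lineage = character(0),
                      rrna_lineage = character(0), stringsAsFactors = FALSE)
    class(out) <- c("strain_table", "data.frame")
    return(out)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("organism", "amoa_lineage", "rrna_lineage")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop(sprintf("strain table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  tab <- tab[req]
  if (anyDuplicated(tab$organism))
    stop(sprintf("duplicate organism name: '%s'",
                 tab$organism[duplicated(tab$organism)][1]))
  if (any(!nzchar(tab$amoa_lineage)) || any(!nzchar(tab$rrna_lineage)))
    stop("lineage labels must be non-empty")
  class(tab) <- c("strain_table", "data.frame")
  tab
}

# ---- sample manifest --------------------------------------------------------

#' Read a sample manifest
#'
#' A manifest is a TSV with a header row and columns `sample_id`,
#' `fastq_fwd` and `fastq_rev`; any further columns are carried along as
#' per-sample environmental metadata (e.g. `pH`, `C`, `N`, `C:N`,
#' `moisture`, `LOI`, `vegetation`).
#'
#' @param path manifest TSV path.
#' @param check_files if `TRUE` (default) verify that the FASTQ files
#'   exist.
#' @return A data frame of class `sample_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_manifest(man, check_files = check_files, base_dir = dirname(path))
}

#' Validate a sample manifest
#'
#' @param man a data frame with at least `sample_id`, `fastq_fwd`,
#'   `fastq_rev`.
#' @param check_files verify FASTQ paths exist.
#' @param base_dir directory against which relative FASTQ paths are
#'   resolved.
#' @return The validated manifest (paths resolved), class
#'   `sample_manifest`.
#' @export
validate_manifest <- function(man, check_files = TRUE, base_dir = ".") {
  req <- c("sample_id", "fastq_fwd", "fastq_rev")
  miss <- setdiff(req, names(man))
  if (length(miss))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!nrow(man)) stop("manifest contains no samples")
  if (anyDuplicated(man$sample_id))
    stop(sprintf("duplicate sample_id: '%s'",
                 man$sample_id[duplicated(man$sample_id)][1]))
  for (col in c("fastq_fwd", "fastq_rev")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base_dir, man[[col]][rel])
    if (check_files) {
      bad <- !file.exists(man[[col]])
      if (any(bad))
        stop(sprintf("manifest file not found: '%s' (sample '%s')",
                     man[[col]][bad][1], man$sample_id[bad][1]))
    }
  }
  env_cols <- setdiff(names(man), req)
  for (col in env_cols) {
    if (anyNA(man[[col]]))
      stop(sprintf("environmental factor '%s' is missing for sample '%s'",
                   col, man$sample_id[which(is.na(man[[col]]))[1]]))
  }
  class(man) <- c("sample_manifest", "data.frame")
  man
}
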