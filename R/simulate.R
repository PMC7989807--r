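# Seeded synthetic-data generator providing ground truth for every
# pipeline stage: reference gene families, environmental gradients
# driving community composition, and paired-end reads with positional
# quality decay, substitution errors and chimeras.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic study.  Defaults emulate the
#' MiSeq V3 study conditions: 2 x 300-bp reads, 7 soils spanning a pH
#' gradient, 5,000 read pairs per sample, and a 448-nt amplicon (the
#' truncated bacterial target; use `amplicon_len = 629` for the
#' archaeal-style target whose mates cannot overlap).
#'
#' @param n_clusters number of phylogenetic clusters (default 5).
#' @param refs_per_cluster reference sequences per cluster (default 3).
#' @param amplicon_len amplicon length in nt (>= 3; default 448).
#' @param within_cluster_div,between_cluster_div substitutions per site
#'   separating leaves from their cluster ancestor and cluster
#'   ancestors from the root (defaults 0.01 and 0.08; both in
#'   `[0, 0.5)`).
#' @param read_len sequencing read length (default 300).
#' @param n_samples number of samples (default 7).
#' @param depth read pairs per sample (default 5000).
#' @param q_start,q_end per-position mean Phred quality, decaying
#'   linearly from the 5' to the 3' end of each read (defaults 38 and
#'   28; scores must stay within `[0, 60]`).
#' @param errors when `TRUE` (default), substitution errors are drawn
#'   per base at rate `10^(-Q/10)`; `FALSE` yields error-free reads
#'   (qualities are still emitted).
#' @param chimera_rate probability that a read derives from a spliced
#'   two-template chimera (default 0).
#' @param gradient_strength Gaussian niche width parameter linking the
#'   simulated pH to cluster abundances (0 = no structure; default 1).
#' @param noise_sd standard deviation of lognormal abundance noise
#'   (default 0.3).
#' @param gap_seg_len per-mate segment length retained by the gap route
#'   (default 200), used to compute the reverse-frame offset.
#' @param diagnostic_positions optional integer vector restricting
#'   where between-cluster (cluster-diagnostic) substitutions may fall;
#'   `NULL` (default) allows the whole amplicon.
#' @param indel_rate per-read probability of a 1-nt deletion (default
#'   0; exercise the frameshift sensitivity of the translation filter).
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 5L, refs_per_cluster = 3L,
                       amplicon_len = 448L,
                       within_cluster_div = 0.01,
                       between_cluster_div = 0.08,
                       read_len = 300L, n_samples = 7L, depth = 5000L,
                       q_start = 38L, q_end = 28L, errors = TRUE,
                       chimera_rate = 0, gradient_strength = 1,
                       noise_sd = 0.3, gap_seg_len = 200L,
                       diagnostic_positions = NULL, indel_rate = 0,
                       seed = 1L) {
  stopifnot(amplicon_len >= 3, n_clusters >= 1, refs_per_cluster >= 1,
            within_cluster_div >= 0, within_cluster_div < 0.5,
            between_cluster_div >= 0, between_cluster_div < 0.5,
            chimera_rate >= 0, chimera_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            q_start >= 0, q_start <= 60, q_end >= 0, q_end <= 60,
            depth >= 1, n_samples >= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 refs_per_cluster = as.integer(refs_per_cluster),
                 amplicon_len = as.integer(amplicon_len),
                 within_cluster_div = within_cluster_div,
                 between_cluster_div = between_cluster_div,
                 read_len = as.integer(read_len),
                 n_samples = as.integer(n_samples),
                 depth = as.integer(depth),
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 errors = isTRUE(errors),
                 chimera_rate = chimera_rate,
                 gradient_strength = gradient_strength,
                 noise_sd = noise_sd,
                 gap_seg_len = as.integer(gap_seg_len),
                 diagnostic_positions = diagnostic_positions,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"bacterial448"` is the short-amplicon target whose 2 x 300-bp mates
#' overlap after truncation (assembly route); `"archaeal629"` is the
#' long-amplicon target whose mates cannot overlap (gap route).
#'
#' @param preset `"bacterial448"` or `"archaeal629"`.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("bacterial448", "archaeal629"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 bacterial448 = list(amplicon_len = 448L),
                 archaeal629 = list(amplicon_len = 629L))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# substitute one base at 1-based position pos avoiding an in-frame
# (frame 0) stop codon; chars is a character vector of single bases
.substitute_safe <- function(chars, pos, L) {
  cod_start <- pos - (pos - 1L) %% 3L
  in_full_codon <- cod_start + 2L <= L
  for (try in 1:100) {
    nb <- sample(setdiff(BASES, chars[pos]), 1L)
    if (!in_full_codon) { chars[pos] <- nb; return(chars) }
    old <- chars[pos]
    chars[pos] <- nb
    codon <- paste(chars[cod_start:(cod_start + 2L)], collapse = "")
    if (!codon %in% STOP_CODONS) return(chars)
    chars[pos] <- old
  }
  stop("could not place a stop-free substitution after 100 retries")
}

.diverge <- function(chars, n_subs, allowed, L) {
  if (n_subs < 1) return(chars)
  if (length(allowed) < n_subs)
    stop("not enough allowed positions for the requested divergence")
  pos <- sample(allowed, n_subs)
  for (p in pos) chars <- .substitute_safe(chars, p, L)
  chars
}

#' Simulate a reference cluster database
#'
#' Generates a stop-free root coding sequence (random non-stop codons
#' in frame 0), derives one ancestor per cluster by
#' `between_cluster_div` substitutions (restricted to
#' `diagnostic_positions` when given) and leaves by
#' `within_cluster_div` substitutions; every substitution is resampled
#' if it would create an in-frame stop.  The forward frame offset is 0
#' by construction and the reverse-frame offset is derived from the
#' amplicon length and the gap-route segment length.
#'
#' @param config a [sim_config()].
#' @return A [reference_db()] with true cluster labels and frame
#'   offsets, plus a `templates` attribute (identical to the sequence
#'   column) for truth bookkeeping.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$amplicon_len
  n_cod <- L %/% 3L
  codons <- apply(matrix(sample(BASES, 3L * n_cod, replace = TRUE),
                         nrow = 3L), 2L, paste, collapse = "")
  while (any(codons %in% STOP_CODONS)) {
    i <- which(codons %in% STOP_CODONS)
    codons[i] <- apply(matrix(sample(BASES, 3L * length(i), replace = TRUE),
                              nrow = 3L), 2L, paste, collapse = "")
  }
  root <- c(unlist(strsplit(codons, "")),
            sample(BASES, L - 3L * n_cod, replace = TRUE))
  allowed_between <- if (is.null(config$diagnostic_positions))
    seq_len(L) else as.integer(config$diagnostic_positions)

  n_between <- round(config$between_cluster_div * L)
  n_within <- round(config$within_cluster_div * L)
  ref_id <- character(0); cluster <- character(0); seqs <- character(0)
  for (k in seq_len(config$n_clusters)) {
    anc <- .diverge(root, n_between, allowed_between, L)
    for (j in seq_len(config$refs_per_cluster)) {
      leaf <- .diverge(anc, n_within, seq_len(L), L)
      ref_id <- c(ref_id, sprintf("C%d_ref%d", k, j))
      cluster <- c(cluster, sprintf("C%d", k))
      seqs <- c(seqs, paste(leaf, collapse = ""))
    }
  }
  rev_start0 <- L - config$gap_seg_len       # 0-based index of reverse segment start
  rev_off <- (3L - rev_start0 %% 3L) %% 3L
  reference_db(ref_id, cluster, seqs, frame_offset = 0L,
               rev_frame_offset = rev_off)
}

#' Simulate a gradient-structured community
#'
#' Samples sit on a pH gradient (3.5-8.5); each cluster has a pH
#' optimum and its log abundance in a sample follows a Gaussian niche
#' model, `-gradient_strength * (pH_s - opt_k)^2`, plus lognormal
#' noise.  `gradient_strength = 0` gives exchangeable abundances across
#' samples (a null community).  The returned expected abundances are
#' the noise-free niche-model values.
#'
#' @param refdb a [reference_db] from [simulate_references()].
#' @param config a [sim_config()].
#' @return A list with `abund` (samples x clusters realised relative
#'   abundances), `expected` (noise-free), `env` (per-sample
#'   environment table with pH and auxiliary factors) and `optima`.
#' @export
simulate_community <- function(refdb, config) {
  stopifnot(inherits(refdb, "reference_db"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ns <- config$n_samples
  clusters <- unique(refdb$cluster)
  nk <- length(clusters)
  ph <- if (ns == 1) 6.0 else seq(3.5, 8.5, length.out = ns)
  optima <- if (nk == 1) 6.0 else seq(3.8, 8.2, length.out = nk)
  loglam <- -config$gradient_strength * outer(ph, optima, `-`)^2
  expected <- exp(loglam)
  expected <- expected / rowSums(expected)
  noise <- matrix(rnorm(ns * nk, sd = config$noise_sd), ns, nk)
  abund <- exp(loglam + noise)
  abund <- abund / rowSums(abund)
  dimnames(abund) <- dimnames(expected) <-
    list(sprintf("sample%02d", seq_len(ns)), clusters)
  env <- data.frame(
    sample_id = rownames(abund),
    pH = ph,
    C = round(exp(rnorm(ns, log(3), 0.4)), 3),
    N = round(exp(rnorm(ns, log(0.25), 0.4)), 3),
    moisture = round(runif(ns, 14.2, 75.1), 1),
    LOI = round(runif(ns, 2, 60), 1),
    vegetation = sample(c("grassland", "forest", "agricultural", "moorland"),
                        ns, replace = TRUE),
    stringsAsFactors = FALSE)
  env$`C:N` <- round(env$C / env$N, 2)
  list(abund = abund, expected = expected, env = env,
       optima = setNames(optima, clusters))
}

.qprofile <- function(config, len) {
  q <- round(seq(config$q_start, config$q_end, length.out = config$read_len))
  as.integer(q[seq_len(len)])
}

# apply per-position substitution errors to a vector of equal-length
# reads; p[j] is the error rate at position j
.apply_errors <- function(seqs, p) {
  if (!length(seqs)) return(seqs)
  n <- length(seqs); L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = n, byrow = TRUE)
  for (j in seq_len(L)) {
    hit <- which(runif(n) < p[j])
    if (length(hit)) {
      cur <- mat[hit, j]
      mat[hit, j] <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                            character(1))
    }
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Simulate paired-end reads from a community
#'
#' Draws templates per sample by cluster abundance (uniformly among a
#' cluster's references), optionally splices two drawn templates at a
#' uniform breakpoint with probability `chimera_rate` (PCR chimeras),
#' then reads both ends: the forward read is the template prefix and
#' the reverse read the reverse-complement suffix, each `read_len`
#' bases (or the whole template if shorter), with Phred scores from the
#' positional decay profile and substitution errors at rate
#' `10^(-Q/10)` when `errors = TRUE`.
#'
#' @param community output of [simulate_community()].
#' @param refdb the [reference_db] the community was built on.
#' @param config a [sim_config()].
#' @param dir optional directory; when given, per-sample FASTQ pairs, a
#'   manifest TSV (with the environment columns), the reference FASTA
#'   and a truth TSV are written there.
#' @return A list with `samples` (named list of [paired_reads]),
#'   `truth` (data frame: read id, sample, source ref and cluster,
#'   chimera status and parents) and, when `dir` was given, `manifest`
#'   (the manifest data frame with file paths).
#' @export
simulate_reads <- function(community, refdb, config, dir = NULL) {
  stopifnot(inherits(refdb, "reference_db"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  L <- config$amplicon_len
  rl <- min(config$read_len, L)
  qprof <- .qprofile(config, rl)
  perr <- 10^(-qprof / 10)
  clusters <- colnames(community$abund)
  ref_by_cluster <- split(seq_len(nrow(refdb)), refdb$cluster)[clusters]

  samples <- list(); truth <- list()
  for (s in rownames(community$abund)) {
    depth <- config$depth
    ck <- sample(seq_along(clusters), depth, replace = TRUE,
                 prob = community$abund[s, ])
    ridx <- vapply(ck, function(k) {
      pool <- ref_by_cluster[[k]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, integer(1))
    tmpl <- refdb$seq[ridx]
    src_ref <- refdb$ref_id[ridx]
    src_cluster <- refdb$cluster[ridx]
    parent2 <- rep(NA_character_, depth)
    is_chim <- runif(depth) < config$chimera_rate
    if (any(is_chim)) {
      for (i in which(is_chim)) {
        k2 <- sample(seq_along(clusters), 1L, prob = community$abund[s, ])
        pool <- ref_by_cluster[[k2]]
        j <- if (length(pool) == 1L) pool else sample(pool, 1L)
        b <- sample(L - 1L, 1L)
        tmpl[i] <- paste0(substr(tmpl[i], 1L, b),
                          substr(refdb$seq[j], b + 1L, L))
        parent2[i] <- refdb$ref_id[j]
      }
    }
    if (config$indel_rate > 0) {
      del <- which(runif(depth) < config$indel_rate)
      for (i in del) {
        p <- sample(nchar(tmpl[i]), 1L)
        tmpl[i] <- paste0(substr(tmpl[i], 1L, p - 1L),
                          substr(tmpl[i], p + 1L, nchar(tmpl[i])))
      }
    }
    fwd <- substr(tmpl, 1L, rl)
    rev <- substr(.revcomp(tmpl), 1L, rl)
    if (config$errors) {
      fwd <- .apply_errors(fwd, perr[seq_len(nchar(fwd[1]))])
      rev <- .apply_errors(rev, perr[seq_len(nchar(rev[1]))])
    }
    ids <- sprintf("%s_read%05d", s, seq_len(depth))
    quals <- rep(list(qprof), depth)
    rq <- if (all(nchar(rev) == rl)) quals else
      lapply(nchar(rev), function(k) qprof[seq_len(k)])
    fq <- if (all(nchar(fwd) == rl)) quals else
      lapply(nchar(fwd), function(k) qprof[seq_len(k)])
    samples[[s]] <- paired_reads(ids, fwd, fq, rev, rq)
    truth[[s]] <- data.frame(read_id = ids, sample_id = s,
                             ref_id = src_ref, cluster = src_cluster,
                             is_chimera = is_chim, parent2 = parent2,
                             stringsAsFactors = FALSE)
  }
  out <- list(samples = samples, truth = do.call(rbind, truth))
  rownames(out$truth) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- data.frame(sample_id = names(samples),
                      fastq_fwd = file.path(dir, paste0(names(samples), "_R1.fastq")),
                      fastq_rev = file.path(dir, paste0(names(samples), "_R2.fastq")),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(man)))
      write_fastq_pairs(samples[[man$sample_id[i]]],
                        man$fastq_fwd[i], man$fastq_rev[i])
    man <- merge(man, community$env, by = "sample_id", sort = FALSE)
    write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_reference_db(refdb, file.path(dir, "refs.fasta"))
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$manifest <- man
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_references()],
#' [simulate_community()] and [simulate_reads()].
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (see [simulate_reads()]).
#' @return A list with `refdb`, `community`, `samples`, `truth` and
#'   (when `dir` was given) `manifest`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  refdb <- simulate_references(config)
  community <- simulate_community(refdb, config)
  reads <- simulate_reads(community, refdb, config, dir = dir)
  c(list(refdb = refdb, community = community), reads)
}
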