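# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately share no code with the package.

# ---- affine-gap global alignment (Gotoh), with traceback ------------------
# Scoring: match +1, mismatch -1, a gap of length L costs open + ext * L.
# type "global": end gaps penalised; returns score, matches and alignment
# columns of one optimal alignment (diagonal preferred on ties).
oracle_global_align <- function(q, r, match = 1, mismatch = -1,
                                open = 2, ext = 1) {
  a <- strsplit(q, "")[[1]]
  b <- strsplit(r, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in (mis)match
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming query (gap in ref row)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap consuming ref
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  sc <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  best <- max(sc)
  # traceback, preferring diagonal, then query-gap, then ref-gap
  state <- which.max(sc)
  i <- n; j <- m
  matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == 1) {
      s <- if (a[i] == b[j]) match else mismatch
      if (a[i] == b[j]) matches <- matches + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2) {
      cur <- X[i + 1, j + 1]
      prev <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      state <- which.max(abs(prev - cur) < 1e-9)
      i <- i - 1L
    } else {
      cur <- Y[i + 1, j + 1]
      prev <- c(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                X[i + 1, j] - open - ext)
      state <- c(1L, 3L, 2L)[which.max(abs(prev - cur) < 1e-9)]
      j <- j - 1L
    }
    if (i == 0 && j > 0) state <- 3L
    if (j == 0 && i > 0) state <- 2L
  }
  list(score = best, matches = matches, columns = cols,
       identity = matches / cols)
}

# ---- exhaustive two-parent chimera search ---------------------------------
# Same decision rule as the implementation, via plain triple loops.
oracle_chimera_flags <- function(uniques, skew = 2, max_diffs = 0) {
  n <- nrow(uniques)
  out <- rep("clean", n)
  seqs <- strsplit(uniques$seq, "")
  for (i in seq_len(n)) {
    L <- length(seqs[[i]])
    parents <- which(uniques$size >= skew * uniques$size[i] &
                     seq_len(n) < i &
                     vapply(seqs, length, integer(1)) == L)
    if (length(parents) < 2) next
    single <- vapply(parents, function(p) sum(seqs[[p]] != seqs[[i]]),
                     numeric(1))
    if (any(single <= max_diffs)) next
    found <- FALSE
    for (pa in parents) for (pb in parents) {
      if (pa == pb || found) next
      for (b in 1:(L - 1)) {
        d <- sum(seqs[[pa]][1:b] != seqs[[i]][1:b]) +
             sum(seqs[[pb]][(b + 1):L] != seqs[[i]][(b + 1):L])
        if (d <= max_diffs) { found <- TRUE; break }
      }
    }
    if (found) out[i] <- "chimeric"
  }
  out
}

# ---- bipartition-table branch-score distance ------------------------------
# Enumerates leaf bipartitions of each unrooted tree by traversing the
# edge matrix directly (no phangorn).
oracle_split_table <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  keys <- character(0); lens <- numeric(0)
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(below(tree$edge[e, 2]))
    if (length(side) == 0 || length(side) == ntip) next
    if (!(tips[1] %in% side)) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% keys) {
      lens[keys == key] <- lens[keys == key] + tree$edge.length[e]
    } else {
      keys <- c(keys, key); lens <- c(lens, tree$edge.length[e])
    }
  }
  stats::setNames(lens, keys)
}

oracle_branch_score <- function(t1, t2) {
  s1 <- oracle_split_table(t1)
  s2 <- oracle_split_table(t2)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sqrt(sum((l1 - l2)^2))
}

# ---- misc helpers ----------------------------------------------------------
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutate_seq <- function(seq, n_subs) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_subs)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

strain_fixture_path <- function() {
  system.file("extdata", "nitrosospira_strains.tsv", package = "gapkit")
}
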