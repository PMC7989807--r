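# Tree and cluster-congruence metrics: branch-score distance between two
# trees and lineage counting/congruence tabulation over a strain table.

#' Branch-score (Kuhner-Felsenstein) distance between two trees
#'
#' The Euclidean distance between the two trees' branch-length vectors
#' indexed by leaf bipartitions: over the union of bipartitions of both
#' (unrooted) trees, the square root of the sum of squared differences
#' of branch lengths, with length 0 for a bipartition absent from a
#' tree.  Trees are compared unrooted, so rooting differences do not
#' affect the distance.  Leaf sets differing between the trees are
#' pruned to their intersection with a warning.
#'
#' @param treeA,treeB `phylo` objects (e.g. from [ape::read.tree()])
#'   with branch lengths on all edges.
#' @return A single non-negative number.
#' @export
branch_score_distance <- function(treeA, treeB) {
  stopifnot(inherits(treeA, "phylo"), inherits(treeB, "phylo"))
  if (is.null(treeA$edge.length) || is.null(treeB$edge.length))
    stop("both trees need branch lengths")
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(shared) < 4)
    stop("fewer than 4 shared leaves; branch-score distance undefined")
  if (length(shared) < length(treeA$tip.label) ||
      length(shared) < length(treeB$tip.label)) {
    warning(sprintf("pruning trees to %d shared leaves", length(shared)))
    treeA <- ape::keep.tip(treeA, shared)
    treeB <- ape::keep.tip(treeB, shared)
  }
  phangorn::KF.dist(ape::unroot(treeA), ape::unroot(treeB))
}

#' Count strains and distinct lineages in a strain table
#'
#' @param strain_table a `strain_table` from [load_strain_table()].
#' @return Named integer vector: `n_strains`, `n_amoa_lineages`,
#'   `n_rrna_lineages`.
#' @examples
#' tab <- load_strain_table(system.file("extdata",
#'   "nitrosospira_strains.tsv", package = "gapkit"))
#' lineage_counts(tab)  # 56 strains, 17 amoA and 19 16S lineages
#' @export
lineage_counts <- function(strain_table) {
  stopifnot(inherits(strain_table, "strain_table"))
  c(n_strains = nrow(strain_table),
    n_amoa_lineages = length(unique(strain_table$amoa_lineage)),
    n_rrna_lineages = length(unique(strain_table$rrna_lineage)))
}

#' Congruence between functional-gene and 16S lineages
#'
#' For every functional-gene (amoA) lineage, tabulates the 16S rRNA
#' lineages of its member strains and scores the lineage's purity — the
#' fraction of strains falling in the modal 16S cluster.  The overall
#' congruence summary is the strain-weighted mean purity (1 when every
#' amoA lineage maps to a single 16S lineage).
#'
#' @param strain_table a `strain_table`.
#' @return A list with `table` (data frame: `amoa_lineage`,
#'   `n_strains`, `rrna_lineages` as a comma-separated multiset,
#'   `modal_rrna`, `purity`) and `weighted_purity` (overall summary).
#' @export
congruence_table <- function(strain_table) {
  stopifnot(inherits(strain_table, "strain_table"))
  if (!nrow(strain_table))
    return(list(table = data.frame(), weighted_purity = NA_real_))
  sp <- split(strain_table$rrna_lineage, strain_table$amoa_lineage)
  sp <- sp[order(names(sp))]
  rows <- lapply(names(sp), function(lin) {
    tab <- sort(table(sp[[lin]]), decreasing = TRUE)
    data.frame(amoa_lineage = lin,
               n_strains = length(sp[[lin]]),
               rrna_lineages = paste(sort(sp[[lin]]), collapse = ","),
               modal_rrna = names(tab)[1],
               purity = as.numeric(tab[1]) / length(sp[[lin]]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       weighted_purity = weighted.mean(tab$purity, tab$n_strains))
}
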