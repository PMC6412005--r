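#' Small parsimony of an allele assignment on a lineage tree
#'
#' Minimal number of allele-change events needed to explain the alleles
#' assigned to the leaves of a rooted reference tree, under unordered states
#' (any allele-to-allele change costs 1; Sankoff dynamic programming on the
#' rooted topology, which reduces to the Fitch count on binary trees). The
#' tree is first restricted to the assigned leaves (unassigned leaves are
#' pruned and resulting degree-2 internal nodes suppressed). An optional
#' `"stepwise"` cost uses `|allele difference|` per event instead, for
#' sensitivity analysis; alleles must then be numeric.
#'
#' @param tree a rooted `phylo` tree (e.g. [ape::read.tree()]) with unique
#'   leaf labels.
#' @param assignment named vector mapping leaf labels to alleles; may cover
#'   only part of the leaves.
#' @param cost `"unordered"` (default) or `"stepwise"`.
#' @return Minimal total mutation cost (integer for unordered cost).
#' @examples
#' tr <- ape::read.tree(text = "((L1,L2),(L3,L4));")
#' parsimony_score(tr, c(L1 = 10, L2 = 10, L3 = 12, L4 = 12))  # 1
#' @export
parsimony_score <- function(tree, assignment, cost = c("unordered", "stepwise")) {
  cost <- match.arg(cost)
  stopifnot(inherits(tree, "phylo"))
  assignment <- .check_assignment(tree, assignment)
  if (length(assignment) == 1L) return(0)
  sub <- .restrict_tree(tree, names(assignment))
  states <- sort(unique(unname(assignment)))
  ns <- length(states)
  if (ns == 1L) return(0)
  cmat <- if (cost == "unordered") {
    1 - diag(ns)
  } else {
    vals <- as.numeric(states)
    if (anyNA(vals)) stop("stepwise cost needs numeric alleles", call. = FALSE)
    abs(outer(vals, vals, `-`))
  }
  ntip <- length(sub$tip.label)
  nnode <- sub$Nnode
  C <- matrix(Inf, ntip + nnode, ns)
  tipstate <- match(assignment[sub$tip.label], states)
  C[cbind(seq_len(ntip), tipstate)] <- 0
  edges <- ape::reorder.phylo(sub, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    ## min over child state of (child cost + change cost) for each parent state
    contrib <- apply(C[child, ] + cmat, 2, min)  # cmat symmetric
    if (!all(is.finite(C[parent, ]))) C[parent, ] <- 0
    C[parent, ] <- C[parent, ] + contrib
  }
  root <- ntip + 1L
  min(C[root, ])
}

.check_assignment <- function(tree, assignment) {
  if (is.null(names(assignment)) || !length(assignment))
    stop("`assignment` must be a nonempty named vector (names = leaves)",
         call. = FALSE)
  assignment <- assignment[!is.na(assignment)]
  if (!length(assignment))
    stop("no assigned leaves", call. = FALSE)
  unknown <- setdiff(names(assignment), tree$tip.label)
  if (length(unknown))
    stop(sprintf("assigned cells not in tree: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  assignment
}

.restrict_tree <- function(tree, leaves) {
  if (length(leaves) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, leaves)
}

#' Allele diversity of an assignment
#'
#' `D(A) = sqrt(sum_a (count_a - 1)^2)` over the distinct alleles of the
#' assignment: 0 when every allele occurs once, `m - 1` when all `m`
#' assignments share one allele. Compensates parsimony for inherently
#' diverse loci in [tree_fitness()].
#'
#' @param assignment named vector of alleles (NAs dropped).
#' @return Nonnegative numeric.
#' @export
allele_diversity <- function(assignment) {
  assignment <- assignment[!is.na(assignment)]
  if (!length(assignment)) stop("no assigned leaves", call. = FALSE)
  counts <- table(unname(assignment))
  sqrt(sum((as.numeric(counts) - 1)^2))
}

#' Reference-tree fitness of a genotyped locus
#'
#' `F(T, A) = |A| - 1 - P(T, A) - D(A)`, where `|A|` is the number of
#' genotyped cells, `P` the minimal number of mutations explaining the
#' alleles on the reference topology ([parsimony_score()]) and `D` the
#' allele diversity ([allele_diversity()]). Loci whose alleles support the
#' reference topology score positive, contradicting loci negative, and
#' uninformative loci — a single allele across all cells, or all alleles
#' distinct — score exactly zero.
#'
#' @inheritParams parsimony_score
#' @return Numeric fitness.
#' @examples
#' tr <- ape::read.tree(text = "((L1,L2),(L3,L4));")
#' tree_fitness(tr, c(L1 = "a", L2 = "a", L3 = "b", L4 = "b"))  # ~0.586
#' tree_fitness(tr, c(L1 = "a", L2 = "b", L3 = "a", L4 = "b"))  # ~-0.414
#' @export
tree_fitness <- function(tree, assignment, cost = "unordered") {
  assignment <- .check_assignment(tree, assignment)
  m <- length(assignment)
  P <- parsimony_score(tree, assignment, cost = cost)
  D <- allele_diversity(assignment)
  m - 1 - P - D
}

#' Score a batch of genotype calls against a reference tree
#'
#' For each locus in a calls table, restricts to calls passing the
#' confidence-percentile threshold and computes the reference-tree fitness
#' of the resulting leaf-to-allele assignment. Only monoallelic calls are
#' used by default (the metric is designed for haploid/hemizygous loci);
#' loci with fewer than 2 assigned cells are reported but not scored.
#'
#' @param tree a rooted `phylo` reference tree.
#' @param calls a data frame with columns `locus_id`, `cell`, `allele1`,
#'   `status`, `percentile` (e.g. [genotype_histograms()] output joined with
#'   a cell column and ranked by [rank_confidence()]).
#' @param max_percentile keep calls with `percentile <= max_percentile`
#'   (lower percentile = higher confidence; default 100 keeps everything).
#' @param cost parsimony cost model, see [parsimony_score()].
#' @return A list with `table` (per-locus data frame: `locus_id`, `n_cells`,
#'   `parsimony`, `diversity`, `fitness`, `status`) and `summary`
#'   (`n_scored`, `mean_fitness`, `total_fitness`).
#' @export
batch_tree_fitness <- function(tree, calls, max_percentile = 100,
                               cost = "unordered") {
  stopifnot(is.data.frame(calls),
            all(c("locus_id", "cell", "allele1", "status") %in% names(calls)))
  pct <- if ("percentile" %in% names(calls)) calls$percentile else 0
  keep <- calls$status == "called" & !is.na(calls$allele1) &
    (!is.na(pct) & pct <= max_percentile)
  calls <- calls[keep, , drop = FALSE]
  loci <- unique(calls$locus_id)
  rows <- lapply(loci, function(lc) {
    g <- calls[calls$locus_id == lc, , drop = FALSE]
    a <- setNames(g$allele1, g$cell)
    a <- a[names(a) %in% tree$tip.label]
    if (length(a) < 2)
      return(data.frame(locus_id = lc, n_cells = length(a),
                        parsimony = NA_real_, diversity = NA_real_,
                        fitness = NA_real_, status = "too_few_cells",
                        stringsAsFactors = FALSE))
    P <- parsimony_score(tree, a, cost = cost)
    D <- allele_diversity(a)
    data.frame(locus_id = lc, n_cells = length(a), parsimony = P,
               diversity = D, fitness = length(a) - 1 - P - D,
               status = "scored", stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), n_cells = integer(0),
               parsimony = numeric(0), diversity = numeric(0),
               fitness = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
  scored <- tab$status == "scored"
  list(table = tab,
       summary = list(n_scored = sum(scored),
                      mean_fitness = if (any(scored)) mean(tab$fitness[scored])
                                     else NA_real_,
                      total_fitness = if (any(scored)) sum(tab$fitness[scored])
                                      else 0))
}
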