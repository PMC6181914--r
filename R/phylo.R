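# Desk-scale tree building and tree utilities: maximum-likelihood pairwise
# distances, neighbor joining (via ape), bootstrap bipartition supports,
# and greedy phylogenetic-diversity subset selection.

DIST_CAP <- 3.0   # saturation cap on pairwise distances, subst/site

#' Maximum-likelihood pairwise distances
#'
#' Estimates the evolutionary distance between every pair of aligned rows
#' by one-dimensional likelihood optimization under the given substitution
#' model. Sites where either row has a gap or `X` are excluded pairwise.
#' Distances are capped at 3 substitutions/site (saturation).
#'
#' @param msa Named character vector of aligned rows (or `cpa_seqs`).
#' @param model A [cpa_model()] (default LG).
#' @return Symmetric labeled matrix with zero diagonal.
#' @export
pairwise_distances <- function(msa, model = cpa_model("LG")) {
  aln <- as_aligned_matrix(msa)
  n <- nrow(aln)
  labels <- rownames(aln)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  st <- matrix(match(aln, AA_ORDER), n)           # NA for gaps/X
  e <- model$eigen
  lfreq <- log(model$freq)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    if (!any(ok))
      stop("no comparable (ungapped) sites between '", labels[i],
           "' and '", labels[j], "'")
    a <- st[i, ok]; b <- st[j, ok]
    N <- matrix(0, 20, 20)
    tab <- table((a - 1L) * 20L + b)
    N[as.integer(names(tab))] <- as.numeric(tab)
    if (all(a == b)) { D[i, j] <- D[j, i] <- 0; next }
    nll <- function(t) {
      P <- e$U %*% (exp(e$values * t) * e$Uinv)
      P[P < 1e-300] <- 1e-300
      -sum(N * (log(P) + lfreq))
    }
    opt <- stats::optimize(nll, c(1e-8, DIST_CAP), tol = 1e-6)
    d <- opt$minimum
    # boundary handling: saturated pairs report the cap
    if (nll(DIST_CAP) <= opt$objective) d <- DIST_CAP
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining (delegated to [ape::nj()]).
#' Negative branch lengths are clamped to zero with a message.
#'
#' @param dm Symmetric distance matrix with labels (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm)) dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 labels")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamped ", sum(neg), " negative branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bipartitions (splits) of a tree
#'
#' One split per internal edge of the unrooted tree, canonicalized: each
#' split is reported as the sorted label vector of its smaller side (ties
#' between equal-sized sides resolved lexicographically). Trivial splits
#' (single leaves) are excluded. The split set is invariant to rooting.
#'
#' @param tree An `ape::phylo` tree.
#' @return Named list of sorted character vectors; names are `|`-joined
#'   labels usable as set keys.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  all_labels <- sort(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  internal_children <- tree$edge[, 2][tree$edge[, 2] > ntip]
  out <- list()
  for (node in internal_children) {
    side <- sort(tips_under(node))
    other <- setdiff(all_labels, side)
    if (length(side) < 2L || length(other) < 2L) next   # trivial
    canon <- if (length(side) < length(other)) side
             else if (length(other) < length(side)) other
             else if (paste(side, collapse = "|") <=
                      paste(other, collapse = "|")) side else other
    out[[paste(canon, collapse = "|")]] <- canon
  }
  out
}

#' Bootstrap bipartition supports
#'
#' Resamples alignment columns with replacement, rebuilds an NJ tree per
#' replicate (ML pairwise distances under `model`), and annotates each
#' internal edge of the base tree with the fraction of replicates whose
#' tree contains the same split. Supports are stored as internal node
#' labels of the returned tree.
#'
#' @param msa Named character vector of aligned rows (or `cpa_seqs`).
#' @param n_replicates Number of bootstrap replicates (default 100, as in
#'   standard practice).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param model A [cpa_model()].
#' @return List: `tree` (base NJ tree with node labels = supports in
#'   [0, 1]), `supports` (named numeric vector keyed by split).
#' @export
bootstrap_supports <- function(msa, n_replicates = 100L, seed = 1L,
                               model = cpa_model("LG")) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  aln <- as_aligned_matrix(msa)
  L <- ncol(aln)
  base_tree <- nj_tree(pairwise_distances(aln, model))
  base_splits <- bipartitions(base_tree)
  counts <- stats::setNames(numeric(length(base_splits)), names(base_splits))
  set.seed(as.integer(seed))
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- aln[, cols, drop = FALSE]
    rep_tree <- try(nj_tree(pairwise_distances(rep_aln, model)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rep_splits <- names(bipartitions(rep_tree))
    hit <- names(counts) %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  supports <- counts / n_replicates
  # annotate internal nodes of the base tree
  ntip <- length(base_tree$tip.label)
  ub <- ape::unroot(base_tree)
  kids <- split(ub$edge[, 2], ub$edge[, 1])
  all_labels <- sort(ub$tip.label)
  tips_under <- function(node) {
    if (node <= ntip) return(ub$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  node_label <- character(ub$Nnode)
  for (node in unique(ub$edge[, 2][ub$edge[, 2] > ntip])) {
    side <- sort(tips_under(node))
    other <- setdiff(all_labels, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (length(side) < length(other)) side
             else if (length(other) < length(side)) other
             else if (paste(side, collapse = "|") <=
                      paste(other, collapse = "|")) side else other
    key <- paste(canon, collapse = "|")
    if (key %in% names(supports))
      node_label[node - ntip] <- format(supports[[key]], digits = 3)
  }
  ub$node.label <- node_label
  list(tree = ub, supports = supports)
}

#' Phylogenetic diversity of a leaf subset
#'
#' Total branch length of the minimal spanning subtree connecting the
#' subset: an edge contributes iff both of its sides contain at least one
#' subset leaf.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param leaf_subset Character vector of leaf labels (>= 2, subset of the
#'   tree's leaves).
#' @return Total branch length (numeric scalar).
#' @export
phylogenetic_diversity <- function(tree, leaf_subset) {
  unknown <- setdiff(leaf_subset, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  if (length(leaf_subset) < 2L) stop("subset must contain at least 2 leaves")
  ntip <- length(tree$tip.label)
  in_set <- tree$tip.label %in% leaf_subset
  k <- sum(in_set)
  # postorder count of subset leaves below each node
  below <- c(as.integer(in_set), integer(tree$Nnode))
  eord <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- tree$edge.length[match(paste(eord[, 1], eord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (r in seq_len(nrow(eord)))
    below[eord[r, 1]] <- below[eord[r, 1]] + below[eord[r, 2]]
  cnt <- below[eord[, 2]]
  sum(elen[cnt >= 1L & cnt < k])
}

#' Greedy phylogenetic-diversity subset selection
#'
#' Greedy PD maximization: start from the two leaves at maximal path
#' distance (the tree diameter pair), then repeatedly add the leaf with
#' the largest PD gain. Ties are broken lexicographically by leaf label.
#' For phylogenetic diversity the greedy algorithm attains the exhaustive
#' maximum at every k.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param k Number of leaves to select (2..n).
#' @return Character vector of `k` leaf labels in selection order.
#' @export
select_diverse_subset <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 2L || k > n) stop("k must lie in 2..", n)
  cd <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(cd))
  cd <- cd[labs, labs]
  # diameter pair, lexicographic tie-break via sorted label order
  best <- which(cd == max(cd), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- c(labs[min(best[1, ])], labs[max(best[1, ])])
  while (length(sel) < k) {
    cand <- setdiff(labs, sel)
    base_pd <- phylogenetic_diversity(tree, sel)
    gains <- vapply(cand, function(x)
      phylogenetic_diversity(tree, c(sel, x)) - base_pd, numeric(1))
    sel <- c(sel, cand[which.max(gains)])   # which.max: first (lexicographic)
  }
  sel
}

#' Per-leaf placement instability diagnostic
#'
#' For each leaf, the fraction of base-tree splits containing that leaf on
#' their canonical (smaller) side that were not recovered across bootstrap
#' replicates, averaged over those splits. High values flag rogue-like
#' taxa whose placement varies between replicates. Diagnostic only.
#'
#' @param boot Result of [bootstrap_supports()].
#' @return Named numeric vector in [0, 1] (NA for leaves on no canonical
#'   side).
#' @export
leaf_instability <- function(boot) {
  splits <- bipartitions(boot$tree)
  sup <- boot$supports[names(splits)]
  leaves <- boot$tree$tip.label
  out <- vapply(leaves, function(lf) {
    inn <- vapply(splits, function(s) lf %in% s, logical(1))
    if (!any(inn)) return(NA_real_)
    mean(1 - sup[inn])
  }, numeric(1))
  out
}
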