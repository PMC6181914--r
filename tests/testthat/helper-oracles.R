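# Shared fixtures and independent oracles used across the suite.

AA <- cpamotif:::AA_ORDER

# Clade motif tables -------------------------------------------------------

# Fully clade-informative polar/charged planted table used by the
# discovery suite: a distinct state per clade in every motif column, all
# states polar or charged so every planted column passes the candidate
# residue-class filter.
discovery_motif_table <- list(
  clade1 = c("S", "T", "D", "S", "E", "N", "D", "R", "P"),
  clade2 = c("T", "S", "E", "T", "Q", "Q", "E", "K", "P"),
  clade3 = c("N", "Q", "N", "D", "S", "D", "T", "H", "P"),
  clade4 = c("Q", "N", "Q", "E", "T", "E", "S", "Q", "P"))

# Brute-force glocal Viterbi ------------------------------------------------

# Exhaustive enumeration of all legal state paths through a profile with
# free flanking query residues; independent of the DP implementation.
brute_viterbi_score <- function(hmm, query) {
  xs <- strsplit(toupper(query), "")[[1]]
  L <- length(xs)
  M <- hmm$M
  xi <- match(xs, AA)
  l2 <- function(p) if (p > 0) log2(p) else -Inf
  emit <- function(j, i) {
    if (is.na(xi[i])) 0
    else unname(log2(hmm$match_em[j, xi[i]] / hmm$bg[xi[i]]))
  }
  best <- -Inf
  # state in {M, I, D} at node j, having consumed residues up to p; the
  # consumed region must end exactly at e (flanks outside are free)
  rec <- function(state, j, p, sc, e) {
    if (sc == -Inf) return()
    if (j == M) {
      exit <- switch(state,
                     M = sc + l2(hmm$tMM[M + 1L]),
                     I = sc + l2(hmm$tIM[M + 1L]),
                     D = sc)
      if (p == e && exit > best) best <<- exit
      if (state == "M" && p < e)
        rec("I", j, p + 1L, sc + l2(hmm$tMI[j + 1L]), e)
      if (state == "I" && p < e)
        rec("I", j, p + 1L, sc + l2(hmm$tII[j + 1L]), e)
      return()
    }
    if (state == "M") {
      if (p < e)
        rec("M", j + 1L, p + 1L,
            sc + l2(hmm$tMM[j + 1L]) + emit(j + 1L, p + 1L), e)
      if (p < e) rec("I", j, p + 1L, sc + l2(hmm$tMI[j + 1L]), e)
      rec("D", j + 1L, p, sc + l2(hmm$tMD[j + 1L]), e)
    } else if (state == "I") {
      if (p < e)
        rec("M", j + 1L, p + 1L,
            sc + l2(hmm$tIM[j + 1L]) + emit(j + 1L, p + 1L), e)
      if (p < e) rec("I", j, p + 1L, sc + l2(hmm$tII[j + 1L]), e)
    } else {
      if (p < e)
        rec("M", j + 1L, p + 1L,
            sc + l2(hmm$tDM[j + 1L]) + emit(j + 1L, p + 1L), e)
      rec("D", j + 1L, p, sc + l2(hmm$tDD[j + 1L]), e)
    }
  }
  for (s in seq_len(L + 1L)) {        # first consumed residue index
    for (e in seq(s - 1L, L)) {       # last consumed residue index
      rec("M", 0L, s - 1L, 0, e)
    }
  }
  best
}

# Exhaustive pruning oracle -------------------------------------------------

# Likelihood of one column by explicit summation over all internal-node
# state assignments (trees up to a handful of nodes).
brute_site_likelihood <- function(tree, column, rate, model) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    prob_matrix(model, tree$edge.length[k] * rate))
  leaf_state <- match(toupper(column[tree$tip.label]), AA)
  root <- ntip + 1L
  internal <- seq(ntip + 1L, ntip + nnode)
  grid <- do.call(expand.grid, rep(list(1:20), nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= ntip) leaf_state[node]
      else as.integer(grid[g, node - ntip])
    }
    term <- model$freq[assign_state(root)]
    for (k in seq_len(nrow(tree$edge))) {
      a <- assign_state(tree$edge[k, 1])
      b <- assign_state(tree$edge[k, 2])
      if (is.na(b)) next                       # missing leaf: marginalized
      term <- term * P[[k]][a, b]
    }
    tot <- tot + term
  }
  unname(tot)
}

# Brute-force PD ------------------------------------------------------------

# PD as the sum over edges separating the subset (direct re-derivation,
# structured differently from the package: union of leaf-to-leaf paths).
brute_pd <- function(tree, subset) {
  ntip <- length(tree$tip.label)
  # edge set of the path between two tips, via node paths to the root
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path_to_root <- function(node) {
    out <- integer(0)
    while (parent[node] != 0L) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  idx <- match(subset, tree$tip.label)
  edges <- integer(0)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    pa <- path_to_root(idx[i]); pb <- path_to_root(idx[j])
    edges <- union(edges, c(setdiff(pa, pb), setdiff(pb, pa)))
  }
  sum(tree$edge.length[match(edges, tree$edge[, 2])])
}

# Random additive trees -----------------------------------------------------

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Random small profile ------------------------------------------------------

random_small_profile <- function(M, n_rows = 5L, seed = 1L) {
  set.seed(seed)
  rows <- replicate(n_rows, paste(sample(AA, M, replace = TRUE), collapse = ""))
  # introduce some shared structure so transitions are non-trivial
  rows[1:2] <- rows[1]
  msa <- stats::setNames(rows, paste0("r", seq_len(n_rows)))
  build_profile(msa)
}

# Phenotype call accuracy of the rule classifier against a family's truth
# table, from the true planted motif states (call-wise).
phenotype_call_accuracy <- function(fam) {
  calls <- t(vapply(seq_len(nrow(fam$truth)), function(i) {
    st <- strsplit(fam$truth$motif_states[i], "")[[1]]
    m <- motif_assignment(st, aux = fam$truth$aux_state[i])
    f <- classify_family(m)$family
    c(f, classify_electrogenicity(m, f)$electrogenicity,
      classify_selectivity(m, f)$selectivity)
  }, character(3)))
  truth <- as.matrix(fam$truth[, c("family", "electrogenicity", "selectivity")])
  mean(calls == truth)
}

# Synthetic structure builders ----------------------------------------------

# A minimal PDB text for a set of atoms given as a data frame with
# columns resno, resname, chain, atom, x, y, z.
synthetic_pdb_text <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
            i, atoms$atom[i], atoms$resname[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i],
            substr(atoms$atom[i], 1, 1))
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}
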