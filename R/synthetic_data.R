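# Synthetic clade-structured CPA-like families with planted motif states.
#
# The generator emulates the statistical structure of a transporter
# superfamily: monophyletic clades, each carrying a distinct state
# combination at the 8 motif columns (plus the auxiliary TM-3 column),
# superimposed on gamma-distributed site-rate heterogeneity, with deletions
# confined to non-motif columns so that column-level truth is preserved.

#' Parameters for the synthetic family generator
#'
#' @param n_leaves Number of sequences (tree leaves). Default 120.
#' @param seq_length Alignment length in residues. Default 400.
#' @param gamma_alpha Shape of the gamma distribution of relative site
#'   rates (mean fixed at 1). Default 1.
#' @param n_clades Number of monophyletic clades. Default 4.
#' @param clade_motif_table Named list mapping clade label to a character
#'   vector of 9 amino-acid states: motif positions 1..8 followed by the
#'   auxiliary TM-3 state. Default: consensus motifs of the first
#'   `n_clades` reference clades with complete text-derived motifs
#'   (see [default_clade_motifs()]).
#' @param motif_noise_eps Probability that a planted motif residue is
#'   replaced by a uniformly random amino acid, independently per leaf and
#'   per motif cell. Default 0.
#' @param indel_rate Per-site probability that a deletion event starts at a
#'   non-motif column of a leaf. Default 0.01.
#' @param indel_mean_len Mean deletion length in residues (geometric).
#'   Default 3.
#' @param motif_columns Integer vector of 8 distinct alignment columns
#'   carrying motif positions 1..8. Defaults to the EcNhaA residue numbers
#'   131, 132, 133, 134, 159, 163, 164, 300 so that synthetic coordinates
#'   read like the reference transporter.
#' @param aux_column Alignment column of the auxiliary TM-3 position
#'   (default 108, EcNhaA P108).
#' @param branch_mean Mean branch length in expected substitutions per
#'   site for [simulate_tree()]. Default 0.1.
#' @param seed Integer seed controlling every stochastic step.
#' @return A validated list of class `cpa_sim_params`.
#' @export
simulation_params <- function(n_leaves = 120, seq_length = 400,
                              gamma_alpha = 1, n_clades = 4,
                              clade_motif_table = NULL,
                              motif_noise_eps = 0,
                              indel_rate = 0.01, indel_mean_len = 3,
                              motif_columns = NULL,
                              aux_column = NULL,
                              branch_mean = 0.1,
                              seed = 1L) {
  if (n_clades < 1) stop("n_clades must be >= 1")
  if (n_leaves < 2) stop("n_leaves must be >= 2")
  if (motif_noise_eps < 0 || motif_noise_eps > 1)
    stop("motif_noise_eps must lie in [0, 1]")
  if (is.null(motif_columns)) {
    ec <- c(131L, 132L, 133L, 134L, 159L, 163L, 164L, 300L)
    if (seq_length >= 320L) motif_columns <- ec
    else {
      # rescale the EcNhaA layout into a short alignment, keeping order
      motif_columns <- as.integer(round(ec / 320 * (seq_length - 10L)) + 5L)
      for (i in 2:8)
        if (motif_columns[i] <= motif_columns[i - 1L])
          motif_columns[i] <- motif_columns[i - 1L] + 1L
    }
  }
  if (is.null(aux_column)) {
    if (seq_length >= 320L) aux_column <- 108L
    else {
      # nearest free column below the motif, else the first free column
      free <- setdiff(seq_len(seq_length), motif_columns)
      below <- free[free < min(motif_columns)]
      aux_column <- if (length(below)) max(below) else free[1L]
    }
  }
  motif_columns <- as.integer(motif_columns)
  cols <- c(motif_columns, as.integer(aux_column))
  if (length(motif_columns) != 8L)
    stop("motif_columns must contain exactly 8 columns")
  if (anyDuplicated(cols))
    stop("motif/aux columns must be pairwise distinct")
  if (any(cols < 1L) || any(cols > seq_length))
    stop("motif/aux columns must lie within seq_length")
  if (is.null(clade_motif_table)) {
    clade_motif_table <- default_clade_motifs(n_clades)
    # generated clades are labeled clade1..cladeN; remember the reference
    # clade each motif came from
    attr(clade_motif_table, "reference_clades") <- names(clade_motif_table)
    names(clade_motif_table) <- paste0("clade", seq_len(n_clades))
  }
  if (length(clade_motif_table) != n_clades)
    stop("clade_motif_table must have one entry per clade")
  for (nm in names(clade_motif_table)) {
    st <- clade_motif_table[[nm]]
    if (length(st) != 9L || !all(st %in% AA_ORDER))
      stop("clade '", nm, "': motif states must be 9 valid amino-acid letters ",
           "(positions 1..8 plus the auxiliary state)")
  }
  structure(list(
    n_leaves = as.integer(n_leaves), seq_length = as.integer(seq_length),
    gamma_alpha = gamma_alpha, n_clades = as.integer(n_clades),
    clade_motif_table = clade_motif_table,
    motif_noise_eps = motif_noise_eps,
    indel_rate = indel_rate, indel_mean_len = indel_mean_len,
    motif_columns = motif_columns, aux_column = as.integer(aux_column),
    branch_mean = branch_mean, seed = as.integer(seed)
  ), class = "cpa_sim_params")
}

#' Default clade motif tables for simulation
#'
#' Returns the consensus motif states (positions 1..8 plus auxiliary TM-3
#' state) of the first `n` reference clades, ordered so that the clades
#' with fully text-supported consensus motifs come first: NhaP-I/NHE,
#' NhaP-II K+-specific, NhaA, Kef-like, then the remaining reference
#' clades.
#'
#' @param n Number of clades requested (1..15).
#' @return Named list of character vectors of length 9.
#' @export
default_clade_motifs <- function(n = 4) {
  ref <- load_clade_reference()
  pref <- c("NhaP-I/NHE", "NhaP-II K+-specific", "NhaA", "Kef-like")
  ord <- c(pref, setdiff(ref$clade, pref))
  if (n > nrow(ref)) stop("at most ", nrow(ref), " reference clades available")
  ref <- ref[match(ord[seq_len(n)], ref$clade), ]
  out <- lapply(seq_len(nrow(ref)), function(i)
    c(strsplit(ref$motif[i], "")[[1]], ref$aux[i]))
  names(out) <- ref$clade
  out
}

#' Simulate a Yule tree with exponential branch lengths
#'
#' Pure-birth topology: starting from a two-leaf cherry, a uniformly chosen
#' extant leaf is split until `n_leaves` is reached. Branch lengths are
#' drawn i.i.d. exponential with mean `branch_mean`. Leaves are labeled
#' `t1..tn` left to right.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed; the same seed reproduces the tree exactly.
#' @param branch_mean Mean branch length (expected substitutions/site).
#' @return A rooted binary `ape::phylo` tree.
#' @export
simulate_tree <- function(n_leaves, seed = 1L, branch_mean = 0.1) {
  if (!is.numeric(n_leaves) || n_leaves < 2)
    stop("n_leaves must be >= 2")
  n_leaves <- as.integer(n_leaves)
  set.seed(as.integer(seed))
  # children[[k]] = integer(2) for internal nodes, NULL for leaves
  children <- vector("list", 2L * n_leaves - 1L)
  children[[1L]] <- c(2L, 3L)
  leaves <- c(2L, 3L)
  nxt <- 4L
  while (length(leaves) < n_leaves) {
    pick <- leaves[sample.int(length(leaves), 1L)]
    children[[pick]] <- c(nxt, nxt + 1L)
    leaves <- c(setdiff(leaves, pick), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  # deterministic left-to-right traversal emitting newick with branch lengths
  leaf_counter <- 0L
  build <- function(node) {
    len <- format(stats::rexp(1L, rate = 1 / branch_mean), digits = 6)
    if (is.null(children[[node]])) {
      leaf_counter <<- leaf_counter + 1L
      paste0("t", leaf_counter, ":", len)
    } else {
      kids <- vapply(children[[node]], build, character(1))
      paste0("(", paste(kids, collapse = ","), "):", len)
    }
  }
  kids <- vapply(children[[1L]], build, character(1))
  nwk <- paste0("(", paste(kids, collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Partition tree leaves into monophyletic clades
#'
#' Starting from the whole tree as one part, the partition is refined by
#' repeatedly splitting a randomly chosen (leaf-count-weighted) splittable
#' part into the two subtrees of its root node, until `n_clades` parts
#' exist. Every part is therefore the full leaf set under a single node
#' (equivalently, a single internal edge), i.e. monophyletic.
#'
#' @param tree A rooted binary `ape::phylo`.
#' @param n_clades Number of clades (1..number of leaves).
#' @param seed Integer seed.
#' @return Named character vector: leaf label -> clade label (`"clade1"`,
#'   `"clade2"`, ...; clade numbering follows the order in which parts were
#'   created).
#' @export
assign_clades <- function(tree, n_clades, seed = 1L) {
  n <- length(tree$tip.label)
  if (n_clades > n) stop("n_clades must not exceed the number of leaves")
  if (n_clades < 1) stop("n_clades must be >= 1")
  set.seed(as.integer(seed))
  ntip <- n
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under), use.names = FALSE)
  }
  parts <- list(root)
  while (length(parts) < n_clades) {
    sizes <- vapply(parts, function(nd) length(tips_under(nd)), numeric(1))
    splittable <- which(vapply(parts, function(nd) nd > ntip, logical(1)))
    w <- sizes[splittable]
    pick <- splittable[sample.int(length(splittable), 1L, prob = w)]
    node <- parts[[pick]]
    parts <- c(parts[-pick], as.list(kids[[as.character(node)]]))
  }
  out <- character(ntip)
  for (i in seq_along(parts)) {
    tl <- tree$tip.label[tips_under(parts[[i]])]
    out[match(tl, tree$tip.label)] <- paste0("clade", i)
  }
  names(out) <- tree$tip.label
  out
}

# Sample per-site relative rates from a discretized gamma (16 categories of
# equal prior mass, category means; mean rate 1).
sample_site_rates <- function(L, alpha, k = 16L) {
  rates <- discrete_gamma_rates(alpha, k)
  rates[sample.int(k, L, replace = TRUE)]
}

#' Simulate a clade-structured protein family with planted motif states
#'
#' Sequences evolve along `tree` under the LG model with per-site gamma
#' rates; motif columns are then overwritten with each leaf's clade states
#' (independently randomized per cell with probability
#' `params$motif_noise_eps`); deletions of geometric length are finally
#' introduced outside the motif/auxiliary columns. Indels are modeled as
#' deletions relative to the ancestral sequence, so the true alignment has
#' exactly `seq_length` columns and column-level truth is preserved.
#'
#' @param tree A rooted binary `ape::phylo`; if `NULL`, one is simulated
#'   from `params`.
#' @param clades Named leaf -> clade map as from [assign_clades()]; if
#'   `NULL`, computed from `params`.
#' @param params A [simulation_params()] object.
#' @return A list of class `cpa_family`:
#' \describe{
#'   \item{msa}{named character vector, the true alignment (rows with `-`).}
#'   \item{sequences}{named character vector, degapped leaf sequences.}
#'   \item{tree}{the tree used.}
#'   \item{clades}{the leaf -> clade map.}
#'   \item{truth}{data frame: leaf_id, clade, motif_states (8 letters),
#'     aux_state, family, electrogenicity, selectivity.}
#'   \item{motif_columns, aux_column}{true alignment columns of the motif.}
#'   \item{params}{the parameter object.}
#' }
#' @export
simulate_family <- function(tree = NULL, clades = NULL, params = simulation_params()) {
  stopifnot(inherits(params, "cpa_sim_params"))
  if (is.null(tree))
    tree <- simulate_tree(params$n_leaves, seed = params$seed,
                          branch_mean = params$branch_mean)
  if (is.null(clades))
    clades <- assign_clades(tree, params$n_clades, seed = params$seed + 1L)
  missing_clades <- setdiff(unique(clades), names(params$clade_motif_table))
  if (length(missing_clades))
    stop("clade_motif_table lacks entries for: ",
         paste(missing_clades, collapse = ", "))
  model <- cpa_model("LG")
  L <- params$seq_length
  ntip <- length(tree$tip.label)

  set.seed(params$seed + 2L)
  rates <- sample_site_rates(L, params$gamma_alpha)
  rate_groups <- split(seq_len(L), rates)

  # evolve states (integer 1..20) down the tree, preorder over edges
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = L)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, L, replace = TRUE, prob = model$freq)
  eord <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- tree$edge.length[match(paste(eord[, 1], eord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (k in seq_len(nrow(eord))) {
    par <- eord[k, 1]; chd <- eord[k, 2]; bl <- elen[k]
    for (g in seq_along(rate_groups)) {
      idx <- rate_groups[[g]]
      r <- as.numeric(names(rate_groups)[g])
      P <- prob_matrix(model, bl * r)
      ps <- states[par, idx]
      for (a in unique(ps)) {
        sel <- idx[ps == a]
        states[chd, sel] <- sample.int(20L, length(sel), replace = TRUE,
                                       prob = P[a, ])
      }
    }
  }

  leaf_states <- states[seq_len(ntip), , drop = FALSE]
  rownames(leaf_states) <- tree$tip.label

  # plant clade motif states (with per-cell noise) at motif + aux columns
  plant_cols <- c(params$motif_columns, params$aux_column)
  truth_states <- matrix("", nrow = ntip, ncol = 9L,
                         dimnames = list(tree$tip.label, NULL))
  for (leaf in tree$tip.label) {
    st <- params$clade_motif_table[[clades[[leaf]]]]
    noise <- stats::runif(9L) < params$motif_noise_eps
    st[noise] <- AA_ORDER[sample.int(20L, sum(noise), replace = TRUE)]
    truth_states[leaf, ] <- st
    leaf_states[leaf, plant_cols] <- match(st, AA_ORDER)
  }

  # deletions (geometric length) outside motif/aux columns
  chars <- matrix(AA_ORDER[leaf_states], nrow = ntip,
                  dimnames = list(tree$tip.label, NULL))
  deletable <- setdiff(seq_len(L), plant_cols)
  for (i in seq_len(ntip)) {
    j <- 1L
    while (j <= length(deletable)) {
      if (stats::runif(1L) < params$indel_rate) {
        len <- stats::rgeom(1L, 1 / params$indel_mean_len) + 1L
        stop_at <- min(j + len - 1L, length(deletable))
        chars[i, deletable[j:stop_at]] <- "-"
        j <- stop_at + 1L
      } else j <- j + 1L
    }
  }

  msa <- apply(chars, 1L, paste, collapse = "")
  sequences <- gsub("-", "", msa, fixed = TRUE)

  # phenotypes implied by each clade's (noise-free) planted states
  pheno <- lapply(params$clade_motif_table, function(st) {
    m <- motif_assignment(st[1:8], aux = st[9])
    fam <- classify_family(m)
    el <- classify_electrogenicity(m, fam$family)
    sel <- classify_selectivity(m, fam$family)
    c(fam$family, el$electrogenicity, sel$selectivity)
  })
  ph <- do.call(rbind, pheno[clades])
  truth <- data.frame(
    leaf_id = tree$tip.label,
    clade = unname(clades),
    motif_states = apply(truth_states[, 1:8, drop = FALSE], 1L, paste,
                         collapse = ""),
    aux_state = truth_states[, 9L],
    family = ph[, 1L], electrogenicity = ph[, 2L], selectivity = ph[, 3L],
    stringsAsFactors = FALSE, row.names = NULL
  )

  structure(list(msa = msa, sequences = sequences, tree = tree,
                 clades = clades, truth = truth,
                 motif_columns = params$motif_columns,
                 aux_column = params$aux_column, params = params),
            class = "cpa_family")
}

#' Write a simulated family to disk
#'
#' Writes the true alignment (`msa.fasta`), the unaligned sequences
#' (`sequences.fasta`), the tree (`tree.nwk`), the truth table
#' (`truth.tsv`) and a JSON manifest echoing the simulation parameters
#' (`manifest.json`). Byte-identical outputs for identical parameters and
#' seed.
#'
#' @param family A `cpa_family` from [simulate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "cpa_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sequence_set(names(family$msa), family$msa),
              file.path(dir, "msa.fasta"))
  write_fasta(sequence_set(names(family$sequences), family$sequences),
              file.path(dir, "sequences.fasta"))
  ape::write.tree(family$tree, file.path(dir, "tree.nwk"))
  utils::write.table(family$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- family$params
  manifest <- p[setdiff(names(p), "clade_motif_table")]
  manifest$clade_motif_table <- lapply(p$clade_motif_table, paste, collapse = "")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cpa_family <- function(x, ...) {
  cat("Synthetic CPA-like family:", length(x$msa), "leaves,",
      nchar(x$msa[[1]]), "alignment columns,",
      length(unique(x$clades)), "clades\n")
  cat("  motif columns:", paste(x$motif_columns, collapse = ", "),
      " aux:", x$aux_column, "\n")
  invisible(x)
}
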