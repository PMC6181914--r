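# Tree-aware per-column conservation scoring (empirical-Bayes posterior
# mean rate over a discrete gamma), 9-grade binning, polar/charged
# candidate filtering, clade-association scoring and greedy discovery of a
# minimal discriminating column set.

#' Discrete gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a gamma distribution
#' with shape `alpha` and mean 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of length `k` with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 8L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  edges <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p_up <- stats::pgamma(c(edges, Inf), shape = alpha + 1, rate = alpha)
  p_lo <- stats::pgamma(c(0, edges), shape = alpha + 1, rate = alpha)
  k * (p_up - p_lo)
}

# Vectorized Felsenstein pruning over all sites of a leaf-state matrix.
# states: integer matrix (leaves x sites), NA = missing (gap/X).
# Returns per-site log-likelihood (natural log) under `model` with branch
# lengths scaled by `rate`.
prune_loglik <- function(tree, states, rate, model) {
  ntip <- length(tree$tip.label)
  S <- ncol(states)
  if (is.null(rownames(states)) ||
      length(setdiff(tree$tip.label, rownames(states))))
    stop("leaf labels missing from the state matrix: ",
         paste(setdiff(tree$tip.label, rownames(states)), collapse = ", "))
  states <- states[tree$tip.label, , drop = FALSE]
  eord <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- tree$edge.length[match(paste(eord[, 1], eord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  partial <- vector("list", ntip + tree$Nnode)
  logscale <- numeric(S)
  leaf_partial <- function(i) {
    m <- matrix(0, 20, S)
    obs <- states[i, ]
    m[cbind(obs[!is.na(obs)], which(!is.na(obs)))] <- 1
    m[, is.na(obs)] <- 1                 # missing data: uniform partial
    m
  }
  for (r in seq_len(nrow(eord))) {
    par <- eord[r, 1]; chd <- eord[r, 2]
    Pc <- prob_matrix(model, elen[r] * rate)
    child <- if (chd <= ntip) leaf_partial(chd) else partial[[chd]]
    contrib <- Pc %*% child
    if (is.null(partial[[par]])) partial[[par]] <- contrib
    else partial[[par]] <- partial[[par]] * contrib
    if (chd > ntip) partial[chd] <- list(NULL)   # free memory, keep slot
    # rescale the parent to avoid underflow (column-wise max)
    p <- partial[[par]]
    mx <- p[1L, ]
    for (kk in 2:20) mx <- pmax(mx, p[kk, ])
    mx[mx == 0] <- 1
    partial[[par]] <- p / rep(mx, each = 20L)
    logscale <- logscale + log(mx)
  }
  root <- eord[nrow(eord), 1]
  ll <- log(as.numeric(model$freq %*% partial[[root]])) + logscale
  ll
}

#' Single-site likelihood by Felsenstein pruning
#'
#' Exact likelihood of one alignment column on a tree under the model,
#' with all branch lengths multiplied by `rate_multiplier`. Gaps and `X`
#' are treated as missing data (uniform partial likelihood). For a
#' single-leaf tree the likelihood reduces to the equilibrium frequency of
#' the observed residue.
#'
#' @param tree An `ape::phylo`.
#' @param column Named character vector: leaf label -> residue (or `-`/`X`).
#' @param rate_multiplier Non-negative rate scaler.
#' @param model A [cpa_model()].
#' @return Likelihood (numeric scalar).
#' @export
site_likelihood <- function(tree, column, rate_multiplier = 1,
                            model = cpa_model("LG")) {
  miss <- setdiff(tree$tip.label, names(column))
  if (length(miss))
    stop("leaf labels missing from the column: ", paste(miss, collapse = ", "))
  st <- matrix(match(toupper(column), AA_ORDER), ncol = 1L,
               dimnames = list(names(column), NULL))
  unname(exp(prune_loglik(tree, st, rate_multiplier, model)))
}

#' Per-column evolutionary rates (empirical-Bayes posterior means)
#'
#' The gamma shape `alpha` is chosen from `alpha_grid` by maximizing the
#' summed log-likelihood over columns with equal-prior discrete-gamma
#' categories; each column's rate is then the posterior mean category rate.
#' Rates are renormalized to mean 1 over non-degenerate (not all-gap)
#' columns. All-gap columns get `NA` rate and a flag.
#'
#' @param tree An `ape::phylo` whose leaves match the MSA rows.
#' @param msa Named character vector of aligned rows (or `cpa_seqs`).
#' @param model A [cpa_model()].
#' @param n_gamma_categories Number of discrete gamma categories
#'   (default 8).
#' @param alpha_grid Candidate shape values (default 25 points on
#'   0.2..5).
#' @return A data frame of class `cpa_conservation` with columns `column`,
#'   `rate`, `gap_fraction`, `modal_residue`, `degenerate`, plus
#'   attributes `alpha` (chosen shape) and `log_likelihood`.
#' @export
site_rates <- function(tree, msa, model = cpa_model("LG"),
                       n_gamma_categories = 8L,
                       alpha_grid = seq(0.2, 5, length.out = 25)) {
  aln <- as_aligned_matrix(msa)
  if (length(setdiff(tree$tip.label, rownames(aln))))
    stop("tree leaves absent from MSA: ",
         paste(setdiff(tree$tip.label, rownames(aln)), collapse = ", "))
  states <- matrix(match(aln, AA_ORDER), nrow(aln),
                   dimnames = dimnames(aln))
  S <- ncol(states)
  degenerate <- colSums(!is.na(states)) == 0L
  live <- which(!degenerate)

  best <- NULL
  for (alpha in alpha_grid) {
    rc <- discrete_gamma_rates(alpha, n_gamma_categories)
    ll <- vapply(rc, function(r)
      prune_loglik(tree, states[, live, drop = FALSE], r, model),
      numeric(length(live)))               # sites x categories
    if (length(live) == 1L) ll <- matrix(ll, nrow = 1L)
    m <- apply(ll, 1L, max)
    site_ll <- m + log(rowMeans(exp(ll - m)))
    total <- sum(site_ll)
    if (is.null(best) || total > best$total)
      best <- list(alpha = alpha, rc = rc, ll = ll, total = total)
  }
  w <- exp(best$ll - apply(best$ll, 1L, max))
  post_mean <- as.numeric((w %*% best$rc) / rowSums(w))
  rates <- rep(NA_real_, S)
  rates[live] <- post_mean / mean(post_mean)

  modal <- apply(aln, 2L, function(col) {
    col <- col[col %in% AA_ORDER]
    if (!length(col)) return(NA_character_)
    tb <- table(factor(col, levels = AA_ORDER))
    AA_ORDER[which.max(tb)]
  })
  out <- data.frame(column = seq_len(S), rate = rates,
                    gap_fraction = colMeans(aln == "-"),
                    modal_residue = modal, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("cpa_conservation", "data.frame")
  attr(out, "alpha") <- best$alpha
  attr(out, "log_likelihood") <- best$total
  out
}

#' Conservation grades 1..9
#'
#' Ranks finite rates and partitions them into 9 equal-frequency bins:
#' the lowest-rate (most conserved) bin is grade 9, the highest-rate (most
#' variable) bin grade 1. Ties are resolved by column index, so grading is
#' deterministic.
#'
#' @param rates Numeric vector of per-column rates (NA allowed).
#' @return Integer vector of grades (NA where rate is NA).
#' @export
conservation_grades <- function(rates) {
  fin <- which(is.finite(rates))
  if (length(fin) < 9L) stop("need at least 9 finite rates to grade")
  ord <- order(rates[fin], fin)             # ascending rate, ties by index
  n <- length(fin)
  grade_by_rank <- 9L - as.integer(floor((seq_len(n) - 1L) * 9L / n))
  out <- rep(NA_integer_, length(rates))
  out[fin[ord]] <- grade_by_rank
  out
}

#' Conservation profile (rates + grades)
#'
#' Convenience wrapper: [site_rates()] followed by
#' [conservation_grades()].
#'
#' @inheritParams site_rates
#' @return The `cpa_conservation` data frame with an added `grade` column.
#' @export
conservation_profile <- function(tree, msa, model = cpa_model("LG"),
                                 n_gamma_categories = 8L,
                                 alpha_grid = seq(0.2, 5, length.out = 25)) {
  prof <- site_rates(tree, msa, model, n_gamma_categories, alpha_grid)
  prof$grade <- conservation_grades(prof$rate)
  prof
}

# residue classes used for candidate filtering; the charged/polar split
# follows standard biochemistry and is overridable by the caller
CHARGED_RESIDUES <- c("D", "E", "K", "R", "H")
POLAR_RESIDUES <- c("S", "T", "N", "Q", "Y", "C", "W")
NONPOLAR_RESIDUES <- c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C")

#' Candidate specificity-determining positions
#'
#' Filters profile columns to the candidates considered for the motif:
#' grade at least `min_grade` (default 8, i.e. the two most conserved
#' grades), modal residue polar or charged, and gap fraction at most
#' `max_gap_fraction`.
#'
#' @param profile A graded `cpa_conservation` data frame (from
#'   [conservation_profile()]).
#' @param min_grade Minimum conservation grade (default 8).
#' @param residue_classes Character vector of admissible modal residues
#'   (default polar union charged).
#' @param max_gap_fraction Maximum per-column gap fraction (default 0.5).
#' @return Data frame of candidate columns with grade, modal residue and
#'   residue class.
#' @export
candidate_sdp <- function(profile, min_grade = 8L,
                          residue_classes = c(CHARGED_RESIDUES, POLAR_RESIDUES),
                          max_gap_fraction = 0.5) {
  stopifnot(inherits(profile, "data.frame"), !is.null(profile$grade))
  keep <- !is.na(profile$grade) & profile$grade >= min_grade &
    profile$modal_residue %in% residue_classes &
    profile$gap_fraction <= max_gap_fraction
  out <- profile[keep, c("column", "grade", "gap_fraction", "modal_residue")]
  out$residue_class <- ifelse(out$modal_residue %in% CHARGED_RESIDUES,
                              "charged", "polar")
  rownames(out) <- NULL
  out
}

# plug-in mutual information (bits) between two discrete vectors
plugin_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Clade association of alignment columns
#'
#' Normalized mutual information `I(residue; label) / H(label)` of each
#' column with the clade labels (plug-in estimates). Rows with a gap at
#' the column are excluded for that column. Returns 0 when the labels are
#' constant (with a warning).
#'
#' @param msa Named character vector of aligned rows (or `cpa_seqs`).
#' @param columns Integer vector of column indices.
#' @param labels Named character vector: row label -> clade label.
#' @return Named numeric vector in [0, 1] (names = column indices).
#' @export
clade_association <- function(msa, columns, labels) {
  aln <- as_aligned_matrix(msa)
  miss <- setdiff(rownames(aln), names(labels))
  if (length(miss)) stop("unlabeled rows: ", paste(miss, collapse = ", "))
  lab <- labels[rownames(aln)]
  if (length(unique(lab)) < 2L) {
    warning("labels are constant; association defined as 0")
    return(stats::setNames(rep(0, length(columns)), columns))
  }
  hl <- entropy_bits(lab)
  out <- vapply(columns, function(cc) {
    res <- aln[, cc]
    ok <- res != "-"
    if (!any(ok)) return(0)
    plugin_mi(res[ok], lab[ok]) / hl
  }, numeric(1))
  stats::setNames(out, columns)
}

#' Greedy discovery of a discriminating column set
#'
#' Greedy forward selection over candidate columns maximizing the
#' normalized mutual information between the joint residue state of the
#' selected columns and the labels. Selection stops after `k_max` columns
#' or when the best gain drops below `min_gain`. Ties in gain are broken
#' first by the per-column association score (descending), then by column
#' index; this keeps the selection well defined once the labels are fully
#' explained by the columns already chosen. Gaps count as a distinct state
#' in the joint computation.
#'
#' @param candidates Candidate table from [candidate_sdp()] (or an integer
#'   vector of columns).
#' @param msa Named character vector of aligned rows (or `cpa_seqs`).
#' @param labels Named character vector: row label -> clade label.
#' @param k_max Maximum number of columns to select (default 8).
#' @param min_gain Minimum NMI gain to continue (default 0: run to
#'   `k_max`).
#' @return Integer vector of selected columns in selection order, with
#'   attribute `nmi` (the NMI trajectory).
#' @export
discover_motif <- function(candidates, msa, labels, k_max = 8L, min_gain = 0) {
  cols <- if (is.data.frame(candidates)) candidates$column else as.integer(candidates)
  if (!length(cols)) stop("no candidate columns supplied")
  aln <- as_aligned_matrix(msa)
  lab <- labels[rownames(aln)]
  if (anyNA(lab)) stop("unlabeled rows present")
  hl <- entropy_bits(lab)
  if (hl == 0) {
    warning("labels are constant; returning empty selection")
    return(integer(0))
  }
  assoc <- clade_association(aln, cols, labels)
  sel <- integer(0)
  joint <- rep("", nrow(aln))
  cur <- 0
  traj <- numeric(0)
  remaining <- cols
  while (length(sel) < k_max && length(remaining)) {
    gains <- vapply(remaining, function(cc)
      plugin_mi(paste(joint, aln[, cc]), lab) / hl - cur, numeric(1))
    gq <- round(gains, 10)   # quantize so float noise cannot mask exact ties
    # order: gain desc, per-column association desc, column index asc
    ord <- order(-gq, -assoc[as.character(remaining)], remaining)
    bi <- ord[1L]
    if (gq[bi] < min_gain) break
    cc <- remaining[bi]
    sel <- c(sel, cc)
    joint <- paste(joint, aln[, cc])
    cur <- cur + gains[bi]
    traj <- c(traj, cur)
    remaining <- remaining[-bi]
  }
  attr(sel, "nmi") <- traj
  sel
}
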