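# Profile hidden Markov model over the 20 amino acids: construction from a
# seed alignment and glocal (global-in-profile, local-in-query) Viterbi
# alignment of queries, yielding the query <-> match-column map used for
# motif extraction.
#
# Architecture per node j = 0..M: match M_j (M_0 = begin), insert I_j,
# delete D_j (j >= 1). Transitions: M->M/I/D, I->M/I, D->M/D, plus
# begin/end; I->D and D->I are not modeled (observed seed pairs of that
# form are not counted). Insert states emit at background frequencies, so
# their emission log-odds are zero.

as_aligned_matrix <- function(msa) {
  if (inherits(msa, "cpa_seqs")) msa <- stats::setNames(msa$seq, msa$id)
  if (is.matrix(msa)) return(msa)
  if (!length(msa)) stop("seed MSA is empty")
  n <- nchar(msa)
  if (length(unique(n)) != 1L) stop("aligned rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Build a profile HMM from a seed alignment
#'
#' Columns whose gap fraction is at most `match_gap_threshold` become match
#' states; the rest are insert columns. Match emissions are residue counts
#' plus `pseudocount_weight` times the background frequencies, normalized;
#' transitions are counted from the observed per-row state paths with
#' Laplace (add-one) smoothing over the legal targets of each state.
#'
#' @param seed_msa Aligned seed sequences: named character vector,
#'   character matrix, or `cpa_seqs` with aligned rows.
#' @param match_gap_threshold Maximum gap fraction for a match column
#'   (default 0.5).
#' @param pseudocount_weight Weight of the background pseudocount added to
#'   each match emission (default 1).
#' @param model Background model supplying equilibrium frequencies
#'   (default LG).
#' @return An object of class `cpa_profile_hmm` with elements `M`,
#'   `match_em` (M x 20), `log_odds` (M x 20, bits), transition vectors,
#'   `column_map` (match state -> seed column) and `bg`.
#' @export
build_profile <- function(seed_msa, match_gap_threshold = 0.5,
                          pseudocount_weight = 1,
                          model = cpa_model("LG")) {
  aln <- as_aligned_matrix(seed_msa)
  gapfrac <- colMeans(aln == "-")
  match_cols <- which(gapfrac <= match_gap_threshold)
  M <- length(match_cols)
  if (M == 0L) stop("all columns are gap-rich; profile would be empty")
  bg <- model$freq

  match_em <- matrix(0, M, 20, dimnames = list(NULL, AA_ORDER))
  for (j in seq_len(M)) {
    res <- aln[, match_cols[j]]
    res <- res[res %in% AA_ORDER]
    cnt <- table(factor(res, levels = AA_ORDER))
    em <- as.numeric(cnt) + pseudocount_weight * bg
    match_em[j, ] <- em / sum(em)
  }

  # per-row state paths -> transition counts (nodes 0..M)
  is_match <- logical(ncol(aln)); is_match[match_cols] <- TRUE
  node_of_col <- cumsum(is_match)          # node index after passing column
  cnt <- list(MM = numeric(M + 1), MI = numeric(M + 1), MD = numeric(M + 1),
              II = numeric(M + 1), IM = numeric(M + 1),
              DM = numeric(M + 1), DD = numeric(M + 1))
  for (r in seq_len(nrow(aln))) {
    state <- "M"; node <- 0L                 # begin = M_0
    for (cc in seq_len(ncol(aln))) {
      ch <- aln[r, cc]
      if (is_match[cc]) {
        new_state <- if (ch == "-") "D" else "M"
        key <- paste0(state, new_state)
        if (!is.null(cnt[[key]])) cnt[[key]][node + 1L] <- cnt[[key]][node + 1L] + 1
        state <- new_state; node <- node_of_col[cc]
      } else if (ch != "-") {
        key <- paste0(state, "I")
        if (!is.null(cnt[[key]])) cnt[[key]][node + 1L] <- cnt[[key]][node + 1L] + 1
        state <- "I"                         # insert at current node
      }
    }
    key <- paste0(state, "M")                # exit to end state
    cnt[[key]][node + 1L] <- cnt[[key]][node + 1L] + 1
  }

  # Laplace smoothing and normalization over the legal targets of each state
  tMM <- tMI <- tMD <- tII <- tIM <- tDM <- tDD <- numeric(M + 1)
  for (j in 0:M) {
    i <- j + 1L
    md_legal <- j < M                        # M_M cannot delete
    m_tot <- (cnt$MM[i] + 1) + (cnt$MI[i] + 1) + if (md_legal) cnt$MD[i] + 1 else 0
    tMM[i] <- (cnt$MM[i] + 1) / m_tot
    tMI[i] <- (cnt$MI[i] + 1) / m_tot
    tMD[i] <- if (md_legal) (cnt$MD[i] + 1) / m_tot else 0
    i_tot <- (cnt$II[i] + 1) + (cnt$IM[i] + 1)
    tII[i] <- (cnt$II[i] + 1) / i_tot
    tIM[i] <- (cnt$IM[i] + 1) / i_tot
    if (j >= 1) {
      dd_legal <- j < M                      # D_M exits to end
      d_tot <- (cnt$DM[i] + 1) + if (dd_legal) cnt$DD[i] + 1 else 0
      tDM[i] <- (cnt$DM[i] + 1) / d_tot
      tDD[i] <- if (dd_legal) (cnt$DD[i] + 1) / d_tot else 0
    }
  }

  structure(list(
    M = M, match_em = match_em,
    log_odds = log2(match_em / matrix(bg, M, 20, byrow = TRUE)),
    tMM = tMM, tMI = tMI, tMD = tMD, tII = tII, tIM = tIM,
    tDM = tDM, tDD = tDD,
    column_map = match_cols, bg = bg,
    match_gap_threshold = match_gap_threshold,
    pseudocount_weight = pseudocount_weight
  ), class = "cpa_profile_hmm")
}

#' @export
print.cpa_profile_hmm <- function(x, ...) {
  cat("Profile HMM:", x$M, "match states\n")
  cat("  consensus:", paste(profile_consensus(x), collapse = ""), "\n")
  invisible(x)
}

#' Profile consensus sequence
#'
#' The highest-emission residue of each match state.
#'
#' @param hmm A `cpa_profile_hmm`.
#' @return Character vector of length `M`.
#' @export
profile_consensus <- function(hmm) {
  AA_ORDER[apply(hmm$match_em, 1L, which.max)]
}

#' Glocal Viterbi alignment of a query to a profile
#'
#' Finds the maximum log-odds state path through the full profile
#' (begin-to-end; deletions allowed at either end) with free flanking query
#' residues on both sides. Log-odds are emissions over background in bits;
#' insert and flank residues score zero.
#'
#' @param hmm A `cpa_profile_hmm`.
#' @param query Residue string (amino acids, `X` allowed and scored
#'   neutrally).
#' @return An object of class `cpa_alignment_map`: list with `score`
#'   (bits), `match_to_query` (integer, length `M`; `NA` where the match
#'   column is deleted), `query_to_match` (integer, length `nchar(query)`;
#'   `NA` for flank/insert residues), `insert_after` (node index for insert
#'   residues, `NA` otherwise) and `flank` (logical).
#' @export
viterbi_align <- function(hmm, query) {
  stopifnot(inherits(hmm, "cpa_profile_hmm"))
  query <- toupper(query)
  if (!nzchar(query)) stop("query sequence is empty")
  xs <- strsplit(query, "")[[1]]
  if (any(!xs %in% VALID_RESIDUES))
    stop("query contains non-amino-acid characters: ",
         paste(unique(xs[!xs %in% VALID_RESIDUES]), collapse = ""))
  L <- length(xs); M <- hmm$M
  xi <- match(xs, AA_ORDER)                       # NA for X
  l2 <- function(p) ifelse(p > 0, log2(p), -Inf)
  lMM <- l2(hmm$tMM); lMI <- l2(hmm$tMI); lMD <- l2(hmm$tMD)
  lII <- l2(hmm$tII); lIM <- l2(hmm$tIM)
  lDM <- l2(hmm$tDM); lDD <- l2(hmm$tDD)

  # VM columns 1..M+1 are nodes 0..M (node 0 = begin, score 0 = free flank)
  VM <- matrix(-Inf, L + 1L, M + 1L); VM[, 1L] <- 0
  VI <- matrix(-Inf, L + 1L, M + 1L)
  VD <- matrix(-Inf, L + 1L, M + 1L)              # column j+1 = D_j (D_0 unused)
  PM <- matrix(0L, L + 1L, M + 1L)                # 1 = from M, 2 = I, 3 = D
  PI <- matrix(0L, L + 1L, M + 1L)                # 1 = from M, 2 = I

  # delete chain: VD[j] = S[j] + max_{k<j}(VM[k] + lMD[k] - S[k+1]) with
  # S[j] = sum of D->D log-transitions up to D_j (S[1] = 0)
  Sdd <- c(0, if (M > 1L) cumsum(lDD[seq(2L, M)]) else NULL)[seq_len(M)]
  dchain <- function(vm_row) {
    base <- vm_row[seq_len(M)] + lMD[seq_len(M)]  # entry M_k -> D_{k+1}, k=0..M-1
    Sdd + cummax(base - Sdd)
  }
  VD[1L, 2:(M + 1L)] <- dchain(VM[1L, ])

  jj <- seq_len(M)                                # target nodes 1..M
  for (i in seq_len(L)) {
    em <- if (is.na(xi[i])) rep(0, M) else hmm$log_odds[, xi[i]]
    pm <- VM[i, jj] + lMM[jj]                     # from M_{j-1}
    pi_ <- VI[i, jj] + lIM[jj]                    # from I_{j-1}
    pd <- VD[i, jj] + lDM[jj]                     # from D_{j-1}
    best <- pmax(pm, pi_, pd)
    VM[i + 1L, jj + 1L] <- em + best
    PM[i + 1L, jj + 1L] <- ifelse(pm >= best, 1L, ifelse(pi_ >= best, 2L, 3L))
    im <- VM[i, ] + lMI                           # I_j from M_j (all nodes 0..M)
    ii <- VI[i, ] + lII
    VI[i + 1L, ] <- pmax(im, ii)
    PI[i + 1L, ] <- ifelse(im >= ii, 1L, 2L)
    VD[i + 1L, 2:(M + 1L)] <- dchain(VM[i + 1L, ])
  }

  endM <- VM[, M + 1L] + lMM[M + 1L]
  endI <- VI[, M + 1L] + lIM[M + 1L]
  endD <- VD[, M + 1L]                            # D_M -> E has probability 1
  endbest <- pmax(endM, endI, endD)
  i_end <- which.max(endbest)                     # rows are i = 0..L (+1)
  score <- endbest[i_end]

  # ---- traceback ----
  match_to_query <- rep(NA_integer_, M)
  query_to_match <- rep(NA_integer_, L)
  insert_after <- rep(NA_integer_, L)
  i <- i_end - 1L                                 # residues consumed
  state <- if (endM[i_end] >= score - 1e-9) "M"
           else if (endI[i_end] >= score - 1e-9) "I" else "D"
  j <- M
  tol <- 1e-9
  while (!(state == "M" && j == 0L)) {
    if (state == "M") {
      match_to_query[j] <- i
      query_to_match[i] <- j
      v <- VM[i + 1L, j + 1L]
      p <- PM[i + 1L, j + 1L]
      i <- i - 1L
      state <- c("M", "I", "D")[p]
      j <- j - 1L
    } else if (state == "I") {
      insert_after[i] <- j
      p <- PI[i + 1L, j + 1L]
      i <- i - 1L
      state <- c("M", "I")[p]
      # node unchanged for I self-loop; entry from M_j also at node j
    } else {                                      # D_j
      if (j >= 2L && abs(VD[i + 1L, j + 1L] -
                         (VD[i + 1L, j] + lDD[j])) < tol) {
        j <- j - 1L                               # from D_{j-1}
      } else {
        state <- "M"; j <- j - 1L                 # from M_{j-1}
      }
    }
  }
  structure(list(score = score,
                 match_to_query = match_to_query,
                 query_to_match = query_to_match,
                 insert_after = insert_after,
                 flank = is.na(query_to_match) & is.na(insert_after)),
            class = "cpa_alignment_map")
}

#' Viterbi log-odds score of a query
#'
#' @param hmm A `cpa_profile_hmm`.
#' @param query Residue string.
#' @return Score in bits (numeric scalar); identical queries always score
#'   identically.
#' @export
score_query <- function(hmm, query) {
  viterbi_align(hmm, query)$score
}

#' @export
print.cpa_alignment_map <- function(x, ...) {
  cat("Alignment map: score", format(x$score, digits = 5), "bits;",
      sum(!is.na(x$match_to_query)), "match columns aligned,",
      sum(is.na(x$match_to_query)), "deleted,",
      sum(!is.na(x$insert_after)), "inserted residues\n")
  invisible(x)
}

#' Serialize a profile HMM to JSON
#'
#' @param hmm A `cpa_profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(hmm, path) {
  stopifnot(inherits(hmm, "cpa_profile_hmm"))
  obj <- list(schema = "cpa_profile_hmm/1", M = hmm$M,
              alphabet = paste(AA_ORDER, collapse = ""),
              match_em = unname(apply(hmm$match_em, 1L, as.numeric,
                                      simplify = FALSE)),
              tMM = hmm$tMM, tMI = hmm$tMI, tMD = hmm$tMD,
              tII = hmm$tII, tIM = hmm$tIM, tDM = hmm$tDM, tDD = hmm$tDD,
              column_map = hmm$column_map, bg = as.numeric(hmm$bg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from JSON
#'
#' @param path Path written by [write_profile_json()].
#' @return A `cpa_profile_hmm`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "cpa_profile_hmm/1")
    stop("not a cpa profile JSON file (schema mismatch)")
  em <- if (is.matrix(obj$match_em)) obj$match_em
        else do.call(rbind, obj$match_em)
  colnames(em) <- AA_ORDER
  bg <- obj$bg; names(bg) <- AA_ORDER
  structure(list(M = obj$M, match_em = em,
                 log_odds = log2(em / matrix(bg, obj$M, 20, byrow = TRUE)),
                 tMM = obj$tMM, tMI = obj$tMI, tMD = obj$tMD,
                 tII = obj$tII, tIM = obj$tIM, tDM = obj$tDM, tDD = obj$tDD,
                 column_map = obj$column_map, bg = bg),
            class = "cpa_profile_hmm")
}
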