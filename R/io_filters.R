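# Sequence I/O and the pre-processing filters applied before profile
# alignment: length screen, greedy identity clustering (CD-HIT surrogate)
# and the essential-region coverage screen.

VALID_RESIDUES <- c(AA_ORDER, "X")

#' Construct a sequence set
#'
#' A lightweight container for protein sequence records: a data frame with
#' columns `id`, `desc` and `seq` (uppercase residues over the 20 amino
#' acids plus `X`).
#'
#' @param ids Character vector of unique, non-empty identifiers.
#' @param seqs Character vector of residue strings.
#' @param descs Optional character vector of free-text descriptions.
#' @return A data frame of class `cpa_seqs`.
#' @export
sequence_set <- function(ids, seqs, descs = "") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- vapply(strsplit(gsub("-", "", seqs), ""), function(ch)
    any(!ch %in% VALID_RESIDUES), logical(1))
  if (any(bad))
    stop("illegal residue characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(!nzchar(gsub("-", "", seqs))))
    stop("empty sequence in record(s): ",
         paste(ids[!nzchar(gsub("-", "", seqs))], collapse = ", "))
  structure(data.frame(id = ids, desc = rep_len(as.character(descs), length(ids)),
                       seq = seqs, stringsAsFactors = FALSE),
            class = c("cpa_seqs", "data.frame"))
}

#' Read a FASTA file
#'
#' Reads protein FASTA into a [sequence_set()]. Residues are uppercased
#' (with a message when lowercase input was folded); duplicate ids, empty
#' files and illegal residue characters raise parse errors naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return A `cpa_seqs` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(raw)
  if (any(grepl("[a-z]", seqs)))
    message("read_fasta: lowercase residues uppercased in ",
            sum(grepl("[a-z]", seqs)), " record(s)")
  sequence_set(ids, seqs, descs)
}

#' Write a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces
#' `x` for canonical records.
#'
#' @param x A `cpa_seqs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "cpa_seqs"))
  header <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  out <- Biostrings::BStringSet(x$seq)
  names(out) <- header
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}

#' Length filter
#'
#' Partitions a sequence set into records with at least `min_length`
#' residues (gaps excluded) and shorter ones. The reference screen drops
#' sequences shorter than 300 residues, too short to span the full
#' NhaA-fold.
#'
#' @param x A `cpa_seqs` data frame.
#' @param min_length Minimum residue count to keep (default 300; the drop
#'   is strict-less).
#' @return List with `kept` and `dropped` sequence sets (input order
#'   preserved).
#' @export
length_filter <- function(x, min_length = 300L) {
  stopifnot(inherits(x, "cpa_seqs"))
  if (min_length < 1) stop("min_length must be >= 1")
  len <- nchar(gsub("-", "", x$seq))
  keep <- len >= min_length
  list(kept = x[keep, , drop = FALSE], dropped = x[!keep, , drop = FALSE])
}

# Fraction of identical aligned positions over the full global alignment
# length (internal and terminal gap columns included in the denominator).
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Greedy identity clustering
#'
#' CD-HIT-style greedy clustering: records are sorted by decreasing length
#' (ties keep input order) and each record joins the first existing cluster
#' whose representative it matches at pairwise identity >= `threshold`
#' (identity = matches / global alignment length, Needleman-Wunsch with
#' BLOSUM62, gap open 10 / extend 1), otherwise it founds a new cluster.
#'
#' @param x A non-empty `cpa_seqs` data frame.
#' @param threshold Identity threshold in (0, 1]; the reference workflow
#'   uses 0.90 for the seed stage and 0.70 for the pool stage.
#' @return A data frame (`record_id`, `cluster_id`, `representative`);
#'   every record appears exactly once.
#' @export
greedy_identity_cluster <- function(x, threshold) {
  stopifnot(inherits(x, "cpa_seqs"))
  if (nrow(x) == 0L) stop("sequence set is empty")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  ord <- order(-nchar(gsub("-", "", x$seq)), seq_len(nrow(x)))
  reps <- integer(0)      # row indices of representatives, in founding order
  assignment <- integer(nrow(x))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(x$seq[i], x$seq[reps[k]]) >= threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  data.frame(record_id = x$id,
             cluster_id = paste0("cluster", assignment),
             representative = seq_len(nrow(x)) %in% reps,
             stringsAsFactors = FALSE)
}

#' Essential-region coverage filter
#'
#' Screens profile-aligned queries for coverage of functionally essential
#' match columns (e.g. the TM helices indispensable for antiport). A query
#' is kept iff (i) the fraction of `essential_columns` aligned to query
#' residues is at least `min_coverage` (inclusive) and (ii) the match
#' column anchoring motif position 7 -- the ion-binding aspartate on TM-5
#' -- is not deleted.
#'
#' @param maps Named list of alignment maps from [viterbi_align()].
#' @param hmm The profile the maps refer to.
#' @param essential_columns Integer vector of essential match columns.
#' @param min_coverage Minimum fraction covered (default 0.7).
#' @param anchor_column Match column anchoring motif position 7; must be
#'   non-deleted regardless of coverage. `NULL` disables the anchor clause.
#' @return List with `kept` and `dropped` character vectors of query ids
#'   (input order preserved) and `coverage`, the per-query fraction.
#' @export
essential_coverage_filter <- function(maps, hmm, essential_columns,
                                      min_coverage = 0.7,
                                      anchor_column = NULL) {
  stopifnot(inherits(hmm, "cpa_profile_hmm"))
  cols <- as.integer(essential_columns)
  if (any(cols < 1L) || any(cols > hmm$M))
    stop("essential_columns outside profile range 1..", hmm$M)
  if (!is.null(anchor_column) &&
      (anchor_column < 1L || anchor_column > hmm$M))
    stop("anchor_column outside profile range 1..", hmm$M)
  cov <- vapply(maps, function(m) {
    mean(!is.na(m$match_to_query[cols]))
  }, numeric(1))
  anchored <- vapply(maps, function(m) {
    is.null(anchor_column) || !is.na(m$match_to_query[anchor_column])
  }, logical(1))
  keep <- cov >= min_coverage & anchored
  list(kept = names(maps)[keep], dropped = names(maps)[!keep],
       coverage = cov)
}
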