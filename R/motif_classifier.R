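# The 8-position CPA motif and its decision rules.
#
# The motif X1 X2 X3 X4 ... [E/-]5 - - - X6 D7 ... [R/K]8 anchors, in
# EcNhaA numbering: A131 T132 D133 I134 (unwound TM-4), L159/E5 (TM-5, one
# helix turn below the binding site), D163 D164 (the ND/DD pair on TM-5),
# K300 (TM-10), plus the auxiliary TM-3 position (P108 in EcNhaA; the
# conserved glutamate unique to mammalian-NHA-like CPA2s).
#
# Decision rules:
#   family:         CPA1 iff s5 = E and s8 = R; CPA2 iff s5 != E and s8 is
#                   a non-gap residue other than R; partial signatures and
#                   gapped s5/s8 are "ambiguous" (conservative by design).
#   electrogenicity: CPA1 -> electroneutral. The mammalian-NHA-like
#                   pattern (acidic s6, s7 = D, s8 = R, aux = E) ->
#                   electroneutral with flag. CPA2 -> electrogenic iff
#                   s8 = K and s6 acidic (D/E), else electroneutral.
#   selectivity:    K iff s1 or s4 is S/T; Na iff s1 and s4 are both
#                   nonpolar; otherwise unknown.

ECNHAA_MOTIF_RESIDUES <- c(131L, 132L, 133L, 134L, 159L, 163L, 164L, 300L)
ECNHAA_AUX_RESIDUE <- 108L

#' Motif specification
#'
#' The eight anchored motif positions plus the auxiliary TM-3 anchor,
#' expressed as match columns of a reference profile. Default columns are
#' the EcNhaA residue numbers themselves (appropriate when the profile's
#' match columns correspond to EcNhaA coordinates, as in the synthetic
#' families).
#'
#' @param columns Integer vector of 8 strictly increasing match columns.
#' @param aux_column Match column of the auxiliary TM-3 anchor.
#' @return Object of class `cpa_motif_spec`; carries the EcNhaA residue
#'   numbering of each anchor and the expected mean segment lengths
#'   (23 residues between the position-5 segment and position 6, 156
#'   between the position-7 segment and position 8).
#' @export
motif_spec <- function(columns = ECNHAA_MOTIF_RESIDUES,
                       aux_column = ECNHAA_AUX_RESIDUE) {
  columns <- as.integer(columns)
  if (length(columns) != 8L) stop("a motif spec has exactly 8 positions")
  if (any(diff(columns) <= 0L))
    stop("motif columns must be strictly increasing")
  structure(list(columns = columns, aux_column = as.integer(aux_column),
                 ecnhaa_residues = ECNHAA_MOTIF_RESIDUES,
                 ecnhaa_aux = ECNHAA_AUX_RESIDUE,
                 segment_means = c(23L, 156L)),
            class = "cpa_motif_spec")
}

#' Motif assignment
#'
#' States of the 8 motif positions (amino-acid letter, `-` for a deleted
#' anchor column, `X` for unknown) plus the auxiliary state, with optional
#' 1-based query coordinates.
#'
#' @param states Character vector of 8 states.
#' @param aux Auxiliary TM-3 state (default `X`).
#' @param query_pos Optional integer vector of 8 query residue numbers
#'   (NA where gapped).
#' @param aux_pos Optional query residue number of the auxiliary state.
#' @return Object of class `cpa_motif_assignment`.
#' @export
motif_assignment <- function(states, aux = "X", query_pos = NULL,
                             aux_pos = NA_integer_) {
  states <- toupper(as.character(states))
  if (length(states) != 8L) stop("a motif assignment has exactly 8 states")
  ok <- states %in% c(AA_ORDER, "-", "X")
  if (any(!ok)) stop("invalid motif state(s): ", paste(states[!ok], collapse = ","))
  if (!is.null(query_pos)) {
    stopifnot(length(query_pos) == 8L)
    if (any(states != "-" & states != "X" & is.na(query_pos)))
      stop("non-gap states must carry query coordinates when positions are given")
  }
  structure(list(states = states, aux = toupper(aux),
                 query_pos = query_pos, aux_pos = aux_pos),
            class = "cpa_motif_assignment")
}

#' @export
print.cpa_motif_assignment <- function(x, ...) {
  cat("CPA motif: ", paste0(x$states, seq_len(8), collapse = " "),
      "  aux(TM-3): ", x$aux, "\n", sep = "")
  invisible(x)
}

#' Extract the motif from an aligned query
#'
#' Reads the residue aligned to each anchor match column from a Viterbi
#' alignment map; deleted anchors become `-`.
#'
#' @param map A `cpa_alignment_map` from [viterbi_align()].
#' @param query The query residue string the map was computed for.
#' @param spec A [motif_spec()] whose columns lie within the profile.
#' @return A `cpa_motif_assignment` with 1-based query coordinates.
#' @export
extract_motif <- function(map, query, spec = motif_spec()) {
  stopifnot(inherits(map, "cpa_alignment_map"), inherits(spec, "cpa_motif_spec"))
  M <- length(map$match_to_query)
  if (any(spec$columns > M) || spec$aux_column > M)
    stop("motif spec columns exceed profile length ", M)
  xs <- strsplit(toupper(query), "")[[1]]
  pos <- map$match_to_query[spec$columns]
  states <- ifelse(is.na(pos), "-", xs[ifelse(is.na(pos), 1L, pos)])
  apos <- map$match_to_query[spec$aux_column]
  aux <- if (is.na(apos)) "-" else xs[apos]
  motif_assignment(states, aux = aux, query_pos = pos, aux_pos = apos)
}

#' Classify CPA family from a motif assignment
#'
#' CPA1 requires the full CPA1 fingerprint: glutamate at position 5 with
#' arginine at position 8. A non-E position 5 with any non-gap, non-R
#' position 8 is CPA2. Partial signatures (exactly one of s5 = E, s8 = R)
#' and gapped s5..s8 yield "ambiguous" with an explanatory flag.
#'
#' @param m A `cpa_motif_assignment`.
#' @return List with `family` ("CPA1", "CPA2" or "ambiguous") and
#'   `flags` (character vector).
#' @export
classify_family <- function(m) {
  stopifnot(inherits(m, "cpa_motif_assignment"))
  s <- m$states
  flags <- character(0)
  if (any(s[5:8] == "-")) {
    flags <- c(flags, "GAPPED_MOTIF")
    return(list(family = "ambiguous", flags = flags))
  }
  e5 <- s[5] == "E"; r8 <- s[8] == "R"
  if (e5 && r8) return(list(family = "CPA1", flags = flags))
  if (!e5 && !r8) return(list(family = "CPA2", flags = flags))
  flags <- c(flags, if (e5) "E5_WITHOUT_R8" else "R8_WITHOUT_E5")
  list(family = "ambiguous", flags = flags)
}

#' Classify electrogenicity from a motif assignment
#'
#' All CPA1s are electroneutral. Among CPA2s, transport is electrogenic
#' iff position 8 is lysine and position 6 is acidic (D or E), reflecting
#' the two binding-site carboxylates plus the TM-10 lysine required to
#' move a second proton; otherwise electroneutral. The mammalian-NHA-like
#' pattern -- acidic position 6, aspartate at 7, arginine at 8 and the
#' uniquely conserved TM-3 glutamate -- is called electroneutral with the
#' `NHA_LIKE_E_TM3` flag regardless of the family call. A non-acidic
#' position 7 raises `POS7_NOT_ACIDIC` (likely transport-deficient).
#'
#' @param m A `cpa_motif_assignment`.
#' @param family Family string as returned by [classify_family()].
#' @return List with `electrogenicity` ("electrogenic", "electroneutral"
#'   or "unknown") and `flags`.
#' @export
classify_electrogenicity <- function(m, family) {
  stopifnot(inherits(m, "cpa_motif_assignment"))
  s <- m$states
  flags <- character(0)
  if (!s[7] %in% c("D", "E")) flags <- c(flags, "POS7_NOT_ACIDIC")
  if (family == "CPA1")
    return(list(electrogenicity = "electroneutral", flags = flags))
  if (s[6] == "-" || s[8] == "-") {
    flags <- c(flags, "GAPPED_MOTIF")
    return(list(electrogenicity = "unknown", flags = flags))
  }
  if (s[6] %in% c("D", "E") && s[7] == "D" && s[8] == "R" && m$aux == "E") {
    flags <- c(flags, "NHA_LIKE_E_TM3")
    return(list(electrogenicity = "electroneutral", flags = flags))
  }
  if (family == "CPA2") {
    el <- if (s[8] == "K" && s[6] %in% c("D", "E")) "electrogenic"
          else "electroneutral"
    return(list(electrogenicity = el, flags = flags))
  }
  list(electrogenicity = "unknown", flags = flags)
}

#' Classify ion selectivity from a motif assignment
#'
#' K+-selective transporters carry serine or threonine at motif position 1
#' or 4 (the extra hydroxyl provides the additional coordination potassium
#' needs); Na+-selective ones have nonpolar residues at both. Anything
#' else -- including both anchors gapped -- is unknown.
#'
#' @param m A `cpa_motif_assignment`.
#' @param family Family string (not used by the rule; kept for interface
#'   symmetry).
#' @return List with `selectivity` ("Na", "K" or "unknown") and `flags`.
#' @export
classify_selectivity <- function(m, family = NULL) {
  stopifnot(inherits(m, "cpa_motif_assignment"))
  s <- m$states
  flags <- character(0)
  if (s[1] == "-" && s[4] == "-") {
    flags <- c(flags, "GAPPED_MOTIF")
    return(list(selectivity = "unknown", flags = flags))
  }
  st <- c("S", "T")
  if (s[1] %in% st || s[4] %in% st)
    return(list(selectivity = "K", flags = flags))
  if (s[1] %in% NONPOLAR_RESIDUES && s[4] %in% NONPOLAR_RESIDUES)
    return(list(selectivity = "Na", flags = flags))
  list(selectivity = "unknown", flags = flags)
}

#' Assign the nearest reference clade
#'
#' Hamming distance between the query's 8 motif states and each reference
#' clade's consensus states (`X` in a consensus matches anything). The
#' best clade wins; the margin is the distance difference to the runner-up.
#' Exact ties raise `AMBIGUOUS_CLADE` and resolve lexicographically.
#'
#' @param m A `cpa_motif_assignment`.
#' @param reference Clade reference table from [load_clade_reference()].
#' @return List with `clade`, `margin` and `flags`.
#' @export
assign_clade <- function(m, reference = load_clade_reference()) {
  stopifnot(inherits(m, "cpa_motif_assignment"))
  if (is.null(reference) || nrow(reference) == 0L)
    stop("no reference clades loaded")
  dist <- vapply(seq_len(nrow(reference)), function(i) {
    cons <- strsplit(reference$motif[i], "")[[1]]
    sum(cons != "X" & cons != m$states)
  }, numeric(1))
  ord <- order(dist, reference$clade)
  flags <- character(0)
  margin <- if (length(dist) > 1L) dist[ord[2L]] - dist[ord[1L]] else NA_real_
  if (!is.na(margin) && margin == 0) flags <- c(flags, "AMBIGUOUS_CLADE")
  list(clade = reference$clade[ord[1L]], margin = margin, flags = flags)
}

#' Full classification of a query sequence
#'
#' Composition of the pipeline stages for one query: glocal Viterbi
#' alignment to the reference profile, essential-coverage screen, motif
#' extraction, family / electrogenicity / selectivity rules, and nearest
#' reference clade. A query failing the coverage screen is reported with
#' family "ambiguous" and the `COVERAGE_FAIL` flag.
#'
#' @param query Residue string (unaligned).
#' @param hmm Reference `cpa_profile_hmm`.
#' @param spec A [motif_spec()] in the profile's match coordinates.
#' @param clade_ref Clade reference table (default packaged reference).
#' @param essential_columns Match columns that must be covered (default:
#'   all match columns).
#' @param min_coverage Minimum covered fraction (default 0.7).
#' @return Object of class `cpa_classification`: list with `motif`
#'   (`cpa_motif_assignment`), `family`, `electrogenicity`, `selectivity`,
#'   `clade`, `margin`, `score` (alignment bits), `coverage` and `flags`.
#' @export
classify <- function(query, hmm, spec = motif_spec(),
                     clade_ref = load_clade_reference(),
                     essential_columns = NULL, min_coverage = 0.7) {
  stopifnot(inherits(hmm, "cpa_profile_hmm"))
  if (is.null(essential_columns)) essential_columns <- seq_len(hmm$M)
  map <- viterbi_align(hmm, query)
  cov <- essential_coverage_filter(list(q = map), hmm, essential_columns,
                                   min_coverage,
                                   anchor_column = spec$columns[7])
  m <- extract_motif(map, query, spec)
  if (!"q" %in% cov$kept) {
    res <- list(motif = m, family = "ambiguous",
                electrogenicity = "unknown", selectivity = "unknown",
                clade = NA_character_, margin = NA_real_,
                score = map$score, coverage = unname(cov$coverage),
                flags = "COVERAGE_FAIL")
    class(res) <- "cpa_classification"
    return(res)
  }
  fam <- classify_family(m)
  el <- classify_electrogenicity(m, fam$family)
  sel <- classify_selectivity(m, fam$family)
  cl <- assign_clade(m, clade_ref)
  res <- list(motif = m, family = fam$family,
              electrogenicity = el$electrogenicity,
              selectivity = sel$selectivity,
              clade = cl$clade, margin = cl$margin,
              score = map$score, coverage = unname(cov$coverage),
              flags = unique(c(fam$flags, el$flags, sel$flags, cl$flags)))
  class(res) <- "cpa_classification"
  res
}

#' @export
print.cpa_classification <- function(x, ...) {
  cat("CPA classification\n")
  cat("  motif:  ", paste0(x$motif$states, collapse = ""),
      " aux ", x$motif$aux, "\n", sep = "")
  cat("  family:", x$family, "| electrogenicity:", x$electrogenicity,
      "| selectivity:", x$selectivity, "\n")
  if (!is.na(x$clade))
    cat("  nearest clade:", x$clade, "(margin", x$margin, ")\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classification results as a data frame
#'
#' @param results Named list of `cpa_classification` objects.
#' @return Data frame with one row per query (id, s1..s8, aux, family,
#'   electrogenicity, selectivity, clade, margin, flags).
#' @export
classification_table <- function(results) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    st <- as.list(stats::setNames(r$motif$states, paste0("s", 1:8)))
    c(list(query_id = id), st,
      list(aux = r$motif$aux, family = r$family,
           electrogenicity = r$electrogenicity, selectivity = r$selectivity,
           clade = ifelse(is.na(r$clade), "", r$clade),
           margin = ifelse(is.na(r$margin), NA_real_, r$margin),
           flags = paste(r$flags, collapse = ";")))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}
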