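# Mapping motif positions onto 3D structures: residue-residue distances,
# salt-bridge detection by the 4 A criterion, and the spatial extent of a
# residue set. Legacy PDB is the contract format (parsed via bio3d).

BASIC_N_ATOMS <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")
ACIDIC_O_ATOMS <- c("OD1", "OD2", "OE1", "OE2")
ACIDIC_RESNAMES <- c("ASP", "GLU")

#' Parse a PDB structure
#'
#' Accepts a file path or raw PDB text. Only the first MODEL is retained;
#' alternate locations other than blank/`A` are dropped. Malformed
#' ATOM/HETATM records raise a parse error carrying the line number.
#'
#' @param x Path to a PDB file, or a character scalar/vector of PDB text.
#' @return Object of class `cpa_structure`: list with `atoms`, a data
#'   frame (record, chain, resno, inscode, resname, atom, x, y, z,
#'   element).
#' @export
parse_pdb <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE))
  # keep first model only
  if (any(grepl("^ENDMDL", lines))) {
    first_end <- which(grepl("^ENDMDL", lines))[1L]
    lines <- lines[seq_len(first_end)]
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record at line ", i, " (too short)")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords) || any(!is.finite(coords)))
      stop("malformed ATOM record at line ", i, " (bad coordinates)")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(record = a$type, chain = a$chain,
                      resno = a$resno,
                      inscode = ifelse(is.na(a$insert), "", a$insert),
                      resname = a$resid, atom = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      element = ifelse(is.na(a$elesy), "", a$elesy),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("non-finite coordinates after parsing")
  structure(list(atoms = atoms), class = "cpa_structure")
}

#' @export
print.cpa_structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$inscode))),
      "residues,", length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Write a structure as legacy PDB
#'
#' Minimal writer (coordinates to 3 decimals) sufficient to round-trip
#' models produced by [parse_pdb()] or built synthetically in code.
#'
#' @param model A `cpa_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "cpa_structure"))
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("%-6s%5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$record[i], i, a$atom[i], a$resname[i], a$chain[i], a$resno[i],
            ifelse(nzchar(a$inscode[i]), a$inscode[i], " "),
            a$x[i], a$y[i], a$z[i], a$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# resolve "chain:resno" to the atom rows of that residue
residue_atoms <- function(model, key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("residue must be given as 'chain:resno': ", key)
  sel <- model$atoms$chain == parts[1] &
    model$atoms$resno == as.integer(parts[2])
  if (!any(sel)) stop("residue not found in structure: ", key)
  model$atoms[sel, , drop = FALSE]
}

#' Distance between two residues
#'
#' Euclidean distance in Angstrom between two residues under the chosen
#' atom selection: `"CA"` (alpha carbons), `"side-chain-charged"`
#' (minimum over the charged side-chain atom sets: basic nitrogens NZ,
#' NH1, NH2, NE, ND1, NE2 and acidic oxygens OD1, OD2, OE1, OE2) or
#' `"all-atom-min"` (minimum over all atom pairs).
#'
#' @param model A `cpa_structure`.
#' @param resA,resB Residues as `"chain:resno"` (author numbering).
#' @param atom_selection One of `"all-atom-min"`, `"CA"`,
#'   `"side-chain-charged"`.
#' @return Distance in Angstrom (numeric scalar).
#' @export
residue_distance <- function(model, resA, resB,
                             atom_selection = c("all-atom-min", "CA",
                                                "side-chain-charged")) {
  atom_selection <- match.arg(atom_selection)
  a <- residue_atoms(model, resA)
  b <- residue_atoms(model, resB)
  pick <- function(df, which_res) {
    out <- switch(atom_selection,
      "CA" = df[df$atom == "CA", , drop = FALSE],
      "side-chain-charged" =
        df[df$atom %in% c(BASIC_N_ATOMS, ACIDIC_O_ATOMS), , drop = FALSE],
      "all-atom-min" = df)
    if (nrow(out) == 0L)
      stop("no atoms matching selection '", atom_selection,
           "' in residue ", which_res)
    out
  }
  a <- pick(a, resA); b <- pick(b, resB)
  d2 <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    (a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
  sqrt(min(d2))
}

#' Detect salt bridges
#'
#' For each (acidic, basic) residue pair, computes the minimum distance
#' between acidic carboxylate oxygens (OD1/OD2/OE1/OE2) and basic
#' nitrogens (NZ/NH1/NH2/NE/ND1/NE2) and flags a salt bridge iff that
#' distance is strictly below `cutoff` (default 4 Angstrom).
#'
#' @param model A `cpa_structure`.
#' @param pairs List of 2-element character vectors
#'   `c("chain:resno_acidic", "chain:resno_basic")`.
#' @param cutoff Bridge cutoff in Angstrom (strict inequality).
#' @param histidine_basic Count histidine as basic (default TRUE).
#' @return Data frame: resA, resB, atomA, atomB, distance, bridge.
#' @export
detect_salt_bridges <- function(model, pairs, cutoff = 4.0,
                                histidine_basic = TRUE) {
  basic_resnames <- c("LYS", "ARG", if (histidine_basic) "HIS")
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    a <- residue_atoms(model, pr[1]); b <- residue_atoms(model, pr[2])
    if (!a$resname[1] %in% ACIDIC_RESNAMES)
      stop("residue ", pr[1], " (", a$resname[1], ") is not acidic")
    if (!b$resname[1] %in% basic_resnames)
      stop("residue ", pr[2], " (", b$resname[1], ") is not basic")
    ao <- a[a$atom %in% ACIDIC_O_ATOMS, , drop = FALSE]
    bn <- b[b$atom %in% BASIC_N_ATOMS, , drop = FALSE]
    if (nrow(ao) == 0L) stop("no carboxylate oxygens in ", pr[1])
    if (nrow(bn) == 0L) stop("no basic nitrogens in ", pr[2])
    d2 <- outer(seq_len(nrow(ao)), seq_len(nrow(bn)), function(i, j)
      (ao$x[i] - bn$x[j])^2 + (ao$y[i] - bn$y[j])^2 + (ao$z[i] - bn$z[j])^2)
    mi <- arrayInd(which.min(d2), dim(d2))
    data.frame(resA = pr[1], resB = pr[2],
               atomA = ao$atom[mi[1]], atomB = bn$atom[mi[2]],
               distance = sqrt(min(d2)),
               bridge = sqrt(min(d2)) < cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spatial extent of a residue set
#'
#' Maximum pairwise alpha-carbon distance over the given residues;
#' residues without a resolved CA are skipped with a warning. A single
#' resolved residue has extent 0.
#'
#' @param model A `cpa_structure`.
#' @param residues Character vector of `"chain:resno"` keys.
#' @return Maximum CA-CA distance in Angstrom.
#' @export
motif_spatial_extent <- function(model, residues) {
  cas <- lapply(residues, function(key) {
    at <- tryCatch(residue_atoms(model, key), error = function(e) NULL)
    if (is.null(at)) return(NULL)
    ca <- at[at$atom == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) return(NULL)
    c(ca$x[1], ca$y[1], ca$z[1])
  })
  bad <- vapply(cas, is.null, logical(1))
  if (any(bad))
    warning("unresolved residue(s) skipped: ",
            paste(residues[bad], collapse = ", "))
  cas <- cas[!bad]
  if (length(cas) == 0L) stop("no resolved residues")
  if (length(cas) == 1L) return(0)
  xyz <- do.call(rbind, cas)
  max(stats::dist(xyz))
}
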