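# Per-residue structure profiles: predicted solvent accessibility (percent
# ASA per residue) and 3-state secondary structure, aligned to fragments.

#' Construct a per-residue structure profile
#'
#' @param protein_id Protein identifier.
#' @param asa Numeric vector of per-residue ASA percentages in `[0, 100]`.
#' @param ss Character vector of per-residue secondary-structure states over
#'   `H` (helix), `E` (sheet), `C` (coil).
#' @param sequence Optional protein sequence used to validate lengths.
#' @return A `residue_profile` object.
#' @export
residue_profile <- function(protein_id, asa, ss, sequence = NULL) {
  asa <- as.numeric(asa)
  ss <- as.character(ss)
  if (length(asa) != length(ss)) {
    stop("profile for ", protein_id, ": ASA and SS lengths differ (",
         length(asa), " vs ", length(ss), ")")
  }
  if (anyNA(asa) || any(asa < 0 | asa > 100)) {
    stop("profile for ", protein_id, ": ASA values must lie in [0, 100]")
  }
  bad <- setdiff(unique(ss), SS_STATES)
  if (length(bad) > 0L) {
    stop("profile for ", protein_id, ": unknown secondary-structure state(s) ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(sequence) && nchar(sequence) != length(asa)) {
    stop("profile for ", protein_id, ": length ", length(asa),
         " does not match sequence length ", nchar(sequence))
  }
  structure(list(protein_id = protein_id, asa = asa, ss = ss),
            class = "residue_profile")
}

#' Read per-residue ASA percentages from a TSV table
#'
#' Expects headerless rows of `(protein_id, position, asa_percent)` with
#' 1-based positions.  Each protein must be covered densely from position 1
#' to its last row (and to its sequence length when `records` is given).
#'
#' @param path Path to the ASA table.
#' @param records Optional named record list used to check completeness
#'   against sequence lengths.
#' @return Named list of numeric ASA vectors, one per protein.
#' @export
read_asa_table <- function(path, records = NULL) {
  if (!file.exists(path)) stop("ASA table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("ASA table must have 3 columns (id, position, asa)")
  ids <- as.character(tab[[1]])
  pos <- as.integer(tab[[2]])
  asa <- as.numeric(tab[[3]])
  if (anyNA(asa) || any(asa < 0 | asa > 100)) {
    stop("ASA values outside [0, 100] in ", path)
  }
  out <- lapply(split(seq_along(ids), ids), function(idx) {
    p <- pos[idx]
    if (anyDuplicated(p)) stop("duplicate ASA position for ", ids[idx[1]])
    full <- seq_len(max(p))
    if (!setequal(p, full)) {
      stop("ASA table incomplete for ", ids[idx[1]], ": missing position(s) ",
           paste(utils::head(setdiff(full, p), 5L), collapse = ", "))
    }
    asa[idx][order(p)]
  })
  if (!is.null(records)) {
    for (id in names(out)) {
      len <- nchar(records[[id]]$sequence)
      if (length(out[[id]]) != len) {
        stop("ASA table for ", id, " covers ", length(out[[id]]),
             " residues but the sequence has ", len)
      }
    }
  }
  out
}

#' Read a PSIPRED .ss2 secondary-structure file
#'
#' Parses PSIPRED VFORMAT: comment/header lines are skipped and each data row
#' is `index residue state conf_C conf_H conf_E`.  Only the state letter is
#' retained.
#'
#' @param path Path to the `.ss2` file.
#' @param sequence Optional protein sequence; the residue column is checked
#'   against it (positions where either side is `'X'` are not compared).
#' @return Character vector of states over `H`, `E`, `C`.
#' @export
read_psipred_ss2 <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("ss2 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("ss2 file has no data rows: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L)) stop("malformed ss2 row in ", path)
  idx <- as.integer(vapply(fields, `[`, character(1), 1L))
  res <- toupper(vapply(fields, `[`, character(1), 2L))
  ss <- toupper(vapply(fields, `[`, character(1), 3L))
  if (!identical(idx, seq_along(idx))) {
    stop("ss2 residue indices are not 1..n in ", path)
  }
  bad <- setdiff(unique(ss), SS_STATES)
  if (length(bad) > 0L) {
    stop("unknown secondary-structure state(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(sequence)) {
    sq <- chars(toupper(sequence))
    if (length(sq) != length(ss)) {
      stop("ss2 file ", path, " has ", length(ss),
           " rows but the sequence has ", length(sq), " residues")
    }
    cmp <- sq != "X" & res != "X" & sq != res
    if (any(cmp)) {
      i <- which(cmp)[1]
      stop("ss2 residue mismatch in ", path, " at position ", i,
           ": file has ", res[i], ", sequence has ", sq[i])
    }
  }
  ss
}

#' Read a directory of per-protein .ss2 files
#'
#' @param dir Directory containing one `<protein_id>.ss2` per record.
#' @param records Named record list; every record must have a file.
#' @return Named list of state vectors.
#' @export
read_ss2_dir <- function(dir, records) {
  out <- lapply(records, function(rec) {
    path <- file.path(dir, paste0(rec$id, ".ss2"))
    read_psipred_ss2(path, rec$sequence)
  })
  names(out) <- names(records)
  out
}

#' Assemble residue profiles from ASA and secondary-structure tables
#'
#' @param records Named record list.
#' @param asa Named list of ASA vectors (see [read_asa_table()]).
#' @param ss Named list of state vectors (see [read_ss2_dir()]).
#' @return Named list of [residue_profile()] objects.
#' @export
build_profiles <- function(records, asa, ss) {
  missing_asa <- setdiff(names(records), names(asa))
  missing_ss <- setdiff(names(records), names(ss))
  if (length(missing_asa) > 0L || length(missing_ss) > 0L) {
    stop("missing structure data for protein(s): ",
         paste(union(missing_asa, missing_ss), collapse = ", "))
  }
  out <- lapply(records, function(rec) {
    residue_profile(rec$id, asa[[rec$id]], ss[[rec$id]], rec$sequence)
  })
  names(out) <- names(records)
  out
}

#' Cut a structure window around a position
#'
#' ASA percentages are rescaled to `[0, 1]` (divided by 100); positions
#' beyond the protein termini contribute ASA 0 and secondary-structure state
#' `"pad"`.
#'
#' @param profile A [residue_profile()].
#' @param center 1-based centre position.
#' @param cfg A [window_config()].
#' @return List with `asa` (numeric, length `2n + 1`, in `[0, 1]`) and `ss`
#'   (character over `H`, `E`, `C`, `pad`).
#' @export
profile_window <- function(profile, center, cfg = window_config()) {
  stopifnot(inherits(profile, "residue_profile"))
  len <- length(profile$asa)
  if (center < 1L || center > len) {
    stop("center ", center, " outside 1..", len, " for ", profile$protein_id)
  }
  idx <- center + seq.int(-cfg$n, cfg$n)
  inside <- idx >= 1L & idx <= len
  asa <- numeric(cfg$window_length)
  asa[inside] <- profile$asa[idx[inside]] / 100
  ss <- rep("pad", cfg$window_length)
  ss[inside] <- profile$ss[idx[inside]]
  list(asa = asa, ss = ss)
}
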