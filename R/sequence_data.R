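#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 standard
#' amino-acid letters is mapped to `'X'` (unknown residue).  The record id is
#' the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return A named list of protein records; each record is a list with
#'   elements `id`, `sequence` and `sites` (1-based positions of annotated
#'   carboxylated glutamates, initially empty).
#' @seealso [read_site_annotations()] to attach site annotations,
#'   [extract_fragments()] to cut Glu-centred windows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(ids == "")) stop("FASTA header without an id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- unname(toupper(as.character(set)))
  seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", seqs)
  records <- lapply(seq_along(ids), function(i) {
    protein_record(ids[i], seqs[i])
  })
  names(records) <- ids
  records
}

#' Construct a single protein record
#'
#' @param id Protein identifier.
#' @param sequence Residue string over the 20 amino-acid letters plus `'X'`.
#' @param sites Integer vector of 1-based positions of carboxylated
#'   glutamates; every position must fall on an `'E'`.
#' @return A `protein_record` object (a list with `id`, `sequence`, `sites`).
#' @export
protein_record <- function(id, sequence, sites = integer(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("sequence of ", id, " contains symbols outside the amino-acid alphabet")
  }
  rec <- structure(list(id = id, sequence = sequence, sites = integer(0)),
                   class = "protein_record")
  if (length(sites) > 0L) rec <- set_sites(rec, sites)
  rec
}

# Attach validated, sorted, unique carboxylation positions to a record.
set_sites <- function(record, sites) {
  sites <- sort(unique(as.integer(sites)))
  len <- nchar(record$sequence)
  bad_range <- sites[sites < 1L | sites > len]
  if (length(bad_range) > 0L) {
    stop("annotation for ", record$id, ": position(s) ",
         paste(bad_range, collapse = ", "), " outside 1..", len)
  }
  res <- substring(record$sequence, sites, sites)
  not_glu <- sites[res != "E"]
  if (length(not_glu) > 0L) {
    stop("annotation for ", record$id, ": position(s) ",
         paste(not_glu, collapse = ", "),
         " are not glutamate (found ",
         paste(res[res != "E"], collapse = ", "), ")")
  }
  record$sites <- sites
  record
}

#' Attach carboxylation-site annotations to protein records
#'
#' Reads a headerless two-column TSV of `(protein_id, position)` rows, where
#' positions are 1-based, and attaches them to the matching records.  Every
#' annotated position must fall on a glutamate (`'E'`) within the sequence.
#'
#' @param path Path to the annotation TSV.
#' @param records Named list of records as returned by [read_fasta()].
#' @return The records with their `sites` fields filled (sorted, unique).
#' @export
read_site_annotations <- function(path, records) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(records)
  if (ncol(tab) < 2L) stop("annotation file must have 2 columns (id, position)")
  ids <- as.character(tab[[1]])
  pos <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(pos)) stop("non-integer position in annotation file: ", path)
  unknown <- setdiff(unique(ids), names(records))
  if (length(unknown) > 0L) {
    stop("annotation refers to unknown protein(s): ",
         paste(unknown, collapse = ", "))
  }
  for (id in unique(ids)) {
    records[[id]] <- set_sites(records[[id]], pos[ids == id])
  }
  records
}

#' Window configuration for Glu-centred fragments
#'
#' A fragment spans `n` residues on each side of the central glutamate, a
#' window of `2n + 1` residues.  The default `n = 7` gives the 15-mer window
#' used throughout the down-stream analyses.
#'
#' @param n Integer half-width, between 4 and 10.
#' @return A `window_config` object with elements `n` and `window_length`.
#' @export
window_config <- function(n = 7L) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n))
  if (n < 4L || n > 10L) stop("window half-width n must be in 4..10, got ", n)
  structure(list(n = n, window_length = 2L * n + 1L), class = "window_config")
}

#' Extract labelled Glu-centred fragments
#'
#' Cuts a `2n + 1` window around every glutamate of every record.  A fragment
#' is labelled `"positive"` when its centre is an annotated carboxylation
#' site, `"negative"` otherwise (the non-annotated glutamates of carboxylated
#' proteins form the negative set).  Windows truncated at the protein termini
#' are padded with `'-'`.
#'
#' @param records A single `protein_record` or a list of them.
#' @param cfg A [window_config()].
#' @return A data frame with columns `protein_id`, `center` (1-based),
#'   `window` (string of length `2n + 1`) and `label`.
#' @export
extract_fragments <- function(records, cfg = window_config()) {
  stopifnot(inherits(cfg, "window_config"))
  if (inherits(records, "protein_record")) records <- list(records)
  n <- cfg$n
  pad <- strrep(PAD_SYMBOL, n)
  out <- lapply(records, function(rec) {
    hits <- gregexpr("E", rec$sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      return(data.frame(protein_id = character(0), center = integer(0),
                        window = character(0), label = character(0),
                        stringsAsFactors = FALSE))
    }
    centers <- as.integer(hits)
    padded <- paste0(pad, rec$sequence, pad)
    windows <- substring(padded, centers, centers + 2L * n)
    data.frame(protein_id = rec$id,
               center = centers,
               window = windows,
               label = ifelse(centers %in% rec$sites, "positive", "negative"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Write fragments to a TSV file
#'
#' @param fragments Fragment data frame from [extract_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Infer the window half-width from a set of fragment windows.
fragment_half_width <- function(windows) {
  len <- unique(nchar(windows))
  if (length(len) != 1L) {
    stop("fragments have mixed window lengths: ", paste(len, collapse = ", "))
  }
  if (len %% 2L == 0L) stop("window length must be odd, got ", len)
  as.integer((len - 1L) / 2L)
}

# Accept either a fragment data frame or a character vector of windows.
as_windows <- function(fragments) {
  if (is.data.frame(fragments)) {
    if (!"window" %in% names(fragments)) stop("fragment data frame lacks a 'window' column")
    fragments$window
  } else {
    as.character(fragments)
  }
}
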