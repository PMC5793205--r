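#' Read a FASTA file into a named sequence vector
#'
#' Sequences are returned as an uppercase named character vector (names are
#' the first whitespace-delimited token of each header); the remainder of
#' each header is kept in the `"description"` attribute. Amino-acid files
#' are validated against the 20 standard residues plus `X`; other letters
#' are rejected or masked to `X` per `on_nonstandard`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"aa"` (validate as protein) or `"any"` (no validation).
#' @param on_nonstandard for `alphabet = "aa"`: `"error"` (default) or
#'   `"mask"` (replace nonstandard letters with `X`).
#' @return named character vector of residues with a `description` attribute.
#' @export
read_fasta <- function(path, alphabet = c("aa", "any"),
                       on_nonstandard = c("error", "mask")) {
  alphabet <- match.arg(alphabet)
  on_nonstandard <- match.arg(on_nonstandard)
  if (!file.exists(path)) fs_stop("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) fs_stop("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) fs_stop("FASTA record with empty id in %s", path)
  if (anyDuplicated(ids)) {
    fs_stop("duplicate FASTA id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    fs_stop("FASTA record with empty sequence: %s",
            paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (alphabet == "aa") {
    ok <- paste0(c(AA20, "X"), collapse = "")
    bad <- grepl(sprintf("[^%s]", ok), seqs)
    if (any(bad)) {
      if (on_nonstandard == "error") {
        fs_stop("nonstandard amino-acid letters in record(s): %s",
                paste(ids[bad], collapse = ", "))
      }
      seqs[bad] <- gsub(sprintf("[^%s]", ok), "X", seqs[bad])
    }
  }
  names(seqs) <- ids
  attr(seqs, "description") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    fs_stop("all sequences must be named to write FASTA")
  }
  set <- Biostrings::BStringSet(seqs)
  desc <- attr(seqs, "description")
  if (!is.null(desc)) {
    full <- ifelse(desc[names(seqs)] == "" | is.na(desc[names(seqs)]),
                   names(seqs), paste(names(seqs), desc[names(seqs)]))
    names(set) <- full
  }
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
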