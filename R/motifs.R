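#' Parse a bracket-consensus motif pattern
#'
#' Patterns are written left-to-right with single residue letters,
#' bracketed sets (`[PK]` = P or K at that position) and `X` (any of the
#' 20 standard residues).
#'
#' @param text the pattern string.
#' @param motif_id optional integer id carried through to the result.
#' @return a `motif_pattern`: list with `motif_id`, `positions` (list of
#'   allowed-residue character vectors) and `width`.
#' @export
parse_bracket_pattern <- function(text, motif_id = NA_integer_) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[[j]] != "]") {
        if (!(chars[[j]] %in% AA20)) {
          fs_stop("invalid residue '%s' at offset %d in pattern '%s'",
                  chars[[j]], j, text)
        }
        set <- c(set, chars[[j]])
        j <- j + 1L
      }
      if (j > length(chars)) {
        fs_stop("unbalanced bracket at offset %d in pattern '%s'",
                length(chars), text)
      }
      if (length(set) == 0L) {
        fs_stop("empty bracket set at offset %d in pattern '%s'", i, text)
      }
      positions[[length(positions) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "X") {
      positions[[length(positions) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "]") {
      fs_stop("unbalanced bracket at offset %d in pattern '%s'", i, text)
    } else {
      fs_stop("invalid character '%s' at offset %d in pattern '%s'",
              ch, i, text)
    }
  }
  structure(list(motif_id = motif_id, positions = positions,
                 width = length(positions)),
            class = "motif_pattern")
}

#' Read bracket-consensus patterns from a text file
#'
#' One pattern per line; `#` starts a comment.
#'
#' @param path file of patterns.
#' @return list of `motif_pattern` objects, ids numbered by line order.
#' @export
read_motif_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    parse_bracket_pattern(lines[[i]], motif_id = i)
  })
}

#' The 20 conserved motifs of the potato bHLH family
#'
#' Bracket-consensus patterns of the 20 conserved motifs predicted for
#' potato bHLH proteins, shipped with the package; motif widths range
#' from 10 to 138 residues.
#'
#' @return list of 20 `motif_pattern` objects.
#' @export
stbhlh_motifs <- function() {
  read_motif_patterns(system.file("extdata", "stbhlh_motifs.txt",
                                  package = "famscan", mustWork = TRUE))
}

#' Scan a protein for motif occurrences
#'
#' Exact set-membership matching: for each motif, the leftmost window in
#' which every residue is in the corresponding allowed set is recorded;
#' at most one occurrence per motif is kept (leftmost wins).
#'
#' @param protein amino-acid string.
#' @param patterns list of `motif_pattern` objects.
#' @param protein_id optional id recorded in the result.
#' @return a `motif_architecture`: data.frame with columns `motif_id` and
#'   `start` (1-based), sorted by `start`.
#' @export
scan_motifs <- function(protein, patterns, protein_id = NA_character_) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  occ <- list()
  for (p in patterns) {
    w <- p$width
    if (w > L) next
    for (s in seq_len(L - w + 1L)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        if (!(chars[[s + k - 1L]] %in% p$positions[[k]])) { ok <- FALSE; break }
      }
      if (ok) {
        occ[[length(occ) + 1L]] <- data.frame(motif_id = p$motif_id,
                                              start = s)
        break  # leftmost occurrence only
      }
    }
  }
  out <- if (length(occ)) do.call(rbind, occ) else
    data.frame(motif_id = integer(), start = integer())
  out <- out[order(out$start, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "protein_id") <- protein_id
  class(out) <- c("motif_architecture", class(out))
  out
}
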