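#' Read a labelled numeric TSV matrix
#'
#' Expects a header row of condition names and a first column of gene ids;
#' the body must be fully numeric. Ragged rows, empty cells and
#' non-numeric cells are hard errors (with the offending row/column
#' address) rather than silent `NA`s.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene ids as rownames and condition names as
#'   colnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) fs_stop("matrix file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) fs_stop("matrix file %s has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  cond <- header[-1L]
  if (length(cond) == 0L) fs_stop("matrix file %s has no data columns", path)
  body <- cells[-1L]
  ncell <- lengths(body)
  if (any(ncell != length(header))) {
    fs_stop("ragged row %d: %d cells, expected %d",
            which(ncell != length(header))[1L] + 1L,
            ncell[ncell != length(header)][1L], length(header))
  }
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    fs_stop("duplicate row id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = length(body), ncol = length(cond),
              dimnames = list(ids, cond))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(is.na(vals) | body[[i]][-1L] == "")
    if (length(bad)) {
      fs_stop("non-numeric or missing cell at row '%s', column '%s'",
              ids[[i]], cond[[bad[1L]]])
    }
    m[i, ] <- vals
  }
  m
}

#' Write a labelled numeric matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (row-id) column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
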