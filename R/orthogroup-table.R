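#' Construct an orthogroup membership table
#'
#' An orthogroup table maps each orthogroup ID to the member protein IDs it
#' holds in each proteome, in the order they appear in the source file. The
#' in-file order matters downstream: annotation transfer uses the *first*
#' protein listed for a species in an orthogroup.
#'
#' @param orthogroups Named list. One element per orthogroup (names are the
#'   orthogroup IDs); each element is a named list mapping proteome ID to a
#'   character vector of member protein IDs (possibly empty).
#' @param proteomes Character vector of proteome IDs, in column order.
#' @return An object of class `orthogroup_table`: the `orthogroups` list with
#'   a `proteomes` attribute. Every cell is normalised so that all proteomes
#'   are present (missing ones as empty vectors) in `proteomes` order.
#' @export
orthogroup_table <- function(orthogroups, proteomes) {
  if (!is.character(proteomes) || anyDuplicated(proteomes))
    stop("'proteomes' must be a character vector without duplicates")
  if (!is.list(orthogroups))
    stop("'orthogroups' must be a list")
  if (length(orthogroups) && is.null(names(orthogroups)))
    stop("'orthogroups' must be named by orthogroup ID")
  if (anyDuplicated(names(orthogroups)))
    stop("duplicate orthogroup IDs: ",
         paste(unique(names(orthogroups)[duplicated(names(orthogroups))]),
               collapse = ", "))
  empty <- stats::setNames(rep(list(character(0)), length(proteomes)), proteomes)
  orthogroups <- lapply(orthogroups, function(cells) {
    extra <- setdiff(names(cells), proteomes)
    if (length(extra))
      stop("cell proteome(s) not in header set: ", paste(extra, collapse = ", "))
    out <- empty
    for (p in names(cells)) {
      v <- as.character(cells[[p]])
      if (anyDuplicated(v))
        stop("duplicated protein ID within one orthogroup/proteome cell: ",
             paste(unique(v[duplicated(v)]), collapse = ", "))
      out[[p]] <- v
    }
    out
  })
  structure(orthogroups, proteomes = proteomes, class = "orthogroup_table")
}

#' Proteome IDs of a table
#' @param x An `orthogroup_table` or `gene_level_table`.
#' @return Character vector of proteome IDs in column order.
#' @export
proteomes <- function(x) attr(x, "proteomes")

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("<%s> %d orthogroups x %d proteomes\n",
              class(x)[1], length(x), length(proteomes(x))))
  invisible(x)
}

.split_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  v <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  v[nzchar(v)]
}

#' Read an OrthoFinder-style orthogroup TSV
#'
#' Expects a tab-separated file whose first line is a header: an orthogroup-ID
#' column followed by one column per proteome. Cells hold comma-separated
#' protein IDs (the `", "` join OrthoFinder emits; bare commas are tolerated).
#' Row order, column order and within-cell protein order are preserved.
#'
#' @param path Path to the TSV file.
#' @return An [orthogroup_table()].
#' @export
read_orthogroup_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("orthogroup table format error: empty file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || !nzchar(header[[1]]))
    stop("orthogroup table format error: malformed header line")
  ncol <- length(header)
  prot <- header[-1]
  ogs <- vector("list", max(length(lines) - 1L, 0L))
  ids <- character(length(ogs))
  for (i in seq_along(lines)[-1]) {
    line <- lines[[i]]
    ntab <- lengths(gregexpr("\t", line, fixed = TRUE))
    if (!grepl("\t", line, fixed = TRUE)) ntab <- 0L
    if (ntab != ncol - 1L)
      stop(sprintf(
        "orthogroup table format error: ragged row at line %d (expected %d fields, found %d)",
        i, ncol, ntab + 1L))
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    length(fields) <- ncol
    fields[is.na(fields)] <- ""
    ids[[i - 1L]] <- fields[[1]]
    cells <- lapply(fields[-1], .split_cell)
    names(cells) <- prot
    ogs[[i - 1L]] <- cells
  }
  if (anyDuplicated(ids))
    stop("orthogroup table format error: duplicate orthogroup ID ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(ogs) <- ids
  orthogroup_table(ogs, prot)
}

#' Write an orthogroup table
#'
#' Emits the same dialect [read_orthogroup_table()] consumes; protein lists
#' are joined with `", "`. Reading the result back reproduces the table, and
#' a canonically formatted file round-trips byte-identically.
#'
#' @param table An `orthogroup_table`.
#' @param path Output path.
#' @param id_column Name of the first header column.
#' @return Invisibly, `path`.
#' @export
write_orthogroup_table <- function(table, path, id_column = "Orthogroup") {
  stopifnot(inherits(table, "orthogroup_table"))
  prot <- proteomes(table)
  header <- paste(c(id_column, prot), collapse = "\t")
  rows <- vapply(seq_along(table), function(i) {
    cells <- vapply(table[[i]][prot], paste, "", collapse = ", ")
    paste(c(names(table)[i], cells), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
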