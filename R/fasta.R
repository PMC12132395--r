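#' Read a FASTA file into a record table
#'
#' Parses protein or transcript FASTA. The record ID is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' kept as the description (the "header information" that annotation transfer
#' appends to genomic intervals). Sequence lines are concatenated with all
#' whitespace stripped.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `protein_id`, `description`, `sequence`
#'   (one row per record; zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(protein_id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && !startsWith(first[[1]], ">"))
    stop("FASTA format error: sequence line before any header in ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), trimws(sub("^\\S+\\s+", "", headers)), "")
  if (any(!nzchar(ids))) stop("FASTA format error: empty record ID in ", path)
  data.frame(protein_id = ids, description = desc,
             sequence = gsub("\\s", "", as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a record table as FASTA
#'
#' @param records Data frame with columns `protein_id`, `description`
#'   (optional), `sequence`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- trimws(paste(records$protein_id, desc))
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
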