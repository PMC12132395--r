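#' GFF3 interval features
#'
#' Genomic interval features are held in an ordinary data frame with one row
#' per feature and an `attributes` list-column of named character vectors, so
#' that per-feature attribute *order* is preserved exactly. Coordinates are
#' 1-based and inclusive throughout (a feature of length 1 has
#' `start == end`); no 0-based conversion happens anywhere.
#'
#' This bespoke reader/writer exists because the annotation-transfer contract
#' requires lossless round-trips of attribute order and percent-encoded
#' values, which column-oriented GFF3 importers do not guarantee.
#'
#' @param seqid,source,type Character vectors (recycled to a common length).
#' @param start,end Integer vectors, 1-based inclusive, `end >= start`.
#' @param score,strand,phase Character vectors; `"."` for absent.
#' @param attributes List of named character vectors, one per feature.
#' @return A data frame of class `gff3_features`.
#' @export
gff3_features <- function(seqid, source = ".", type, start, end,
                          score = ".", strand = ".", phase = ".",
                          attributes = NULL) {
  n <- max(length(seqid), length(type), length(start), length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("GFF3 format error: non-integer coordinates")
  if (any(start < 1L)) stop("GFF3 format error: start < 1")
  if (any(end < start)) stop("GFF3 format error: end < start")
  if (is.null(attributes)) attributes <- rep(list(character(0)), n)
  df <- data.frame(seqid = rep_len(as.character(seqid), n),
                   source = rep_len(as.character(source), n),
                   type = rep_len(as.character(type), n),
                   start = rep_len(start, n), end = rep_len(end, n),
                   score = rep_len(as.character(score), n),
                   strand = rep_len(as.character(strand), n),
                   phase = rep_len(as.character(phase), n),
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("GFF3 format error: strand must be one of '+', '-', '.'")
  df$attributes <- attributes
  class(df) <- c("gff3_features", "data.frame")
  df
}

# Percent-encode the characters GFF3 reserves inside attribute values.
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

gff3_unescape <- function(x) {
  vapply(x, function(v) utils::URLdecode(v), "", USE.NAMES = FALSE)
}

.parse_gff3_attributes <- function(field, line_no) {
  if (field == "." || !nzchar(field)) return(character(0))
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  keys <- sub("=.*$", "", parts)
  if (any(keys == parts))
    stop(sprintf("GFF3 format error: attribute without '=' at line %d", line_no))
  vals <- gff3_unescape(sub("^[^=]*=", "", parts))
  stats::setNames(vals, trimws(keys))
}

#' Read a GFF3 file
#'
#' @param path Path to a GFF3 file. Comment/directive lines are skipped.
#' @return A [gff3_features()] data frame; attribute values are
#'   percent-decoded and per-feature attribute order is preserved.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[[j]]
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    ntab <- lengths(gregexpr("\t", lines[[i]], fixed = TRUE))
    if (ntab != 8L)
      stop(sprintf("GFF3 format error: expected 9 tab-separated columns at line %d", i))
    length(fields) <- 9L
    fields[is.na(fields)] <- ""
    if (!grepl("^[0-9]+$", fields[[4]]) || !grepl("^[0-9]+$", fields[[5]]))
      stop(sprintf("GFF3 format error: non-integer coordinates at line %d", i))
    start <- as.integer(fields[[4]]); end <- as.integer(fields[[5]])
    if (end < start)
      stop(sprintf("GFF3 format error: end < start at line %d", i))
    rows[[j]] <- list(seqid = fields[[1]], source = fields[[2]],
                      type = fields[[3]], start = start, end = end,
                      score = fields[[6]], strand = fields[[7]],
                      phase = fields[[8]],
                      attributes = .parse_gff3_attributes(fields[[9]], i))
  }
  gff3_features(
    seqid = vapply(rows, `[[`, "", "seqid"),
    source = vapply(rows, `[[`, "", "source"),
    type = vapply(rows, `[[`, "", "type"),
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    score = vapply(rows, `[[`, "", "score"),
    strand = vapply(rows, `[[`, "", "strand"),
    phase = vapply(rows, `[[`, "", "phase"),
    attributes = lapply(rows, `[[`, "attributes"))
}

#' Write features as GFF3
#'
#' Attribute values are percent-encoded for the characters GFF3 reserves
#' (`;`, `=`, `&`, `,`, tab, newline, `%`), so a write/read cycle preserves
#' decoded values exactly.
#'
#' @param features A [gff3_features()] data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(inherits(features, "gff3_features"))
  attr_field <- vapply(features$attributes, function(a) {
    if (!length(a)) return(".")
    paste(paste0(names(a), "=", gff3_escape(unname(a))), collapse = ";")
  }, "")
  lines <- paste(features$seqid, features$source, features$type,
                 features$start, features$end, features$score,
                 features$strand, features$phase, attr_field, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3", lines), con)
  invisible(path)
}
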