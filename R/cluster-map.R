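#' Protein-to-gene-cluster map
#'
#' Maps each predicted protein (one per transcript isoform) to the gene
#' cluster — the locus — it belongs to in a given assembly. Collapsing an
#' orthogroup table through this map turns protein-level membership into
#' gene-level membership, so that a locus with many isoforms counts once.
#'
#' @param protein_id,assembly_id,cluster_id Character vectors of equal length.
#' @return A data frame of class `gene_cluster_map` with those three columns.
#'   Each protein must map to exactly one cluster.
#' @export
gene_cluster_map <- function(protein_id, assembly_id, cluster_id) {
  df <- data.frame(protein_id = as.character(protein_id),
                   assembly_id = as.character(assembly_id),
                   cluster_id = as.character(cluster_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$protein_id))
    stop("gene cluster map error: protein mapped more than once: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  class(df) <- c("gene_cluster_map", "data.frame")
  df
}

#' Look up the clusters of a set of proteins
#'
#' The map is total by contract: looking up an unmapped protein is an error,
#' never a silent miss.
#'
#' @param map A [gene_cluster_map()].
#' @param protein_ids Character vector of protein IDs.
#' @return Character vector of cluster IDs, named by protein ID.
#' @export
lookup_cluster <- function(map, protein_ids) {
  idx <- match(protein_ids, map$protein_id)
  if (anyNA(idx))
    stop("gene cluster map error: unmapped protein ID(s): ",
         paste(utils::head(protein_ids[is.na(idx)], 10L), collapse = ", "))
  stats::setNames(map$cluster_id[idx], protein_ids)
}

#' Read / write a cluster map as 3-column TSV
#'
#' Columns: `protein_id`, `assembly_id`, `cluster_id`, with a header line.
#'
#' @param path File path.
#' @return [read_cluster_map()]: a [gene_cluster_map()].
#' @export
read_cluster_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("protein_id", "assembly_id", "cluster_id")
  if (!all(need %in% names(df)))
    stop("cluster map format error: need columns ", paste(need, collapse = ", "))
  gene_cluster_map(df$protein_id, df$assembly_id, df$cluster_id)
}

#' @rdname read_cluster_map
#' @param map A [gene_cluster_map()].
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(inherits(map, "gene_cluster_map"))
  utils::write.table(as.data.frame(map)[, c("protein_id", "assembly_id", "cluster_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
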