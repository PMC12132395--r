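#' Build an orthogroup-by-species annotation map
#'
#' For every (orthogroup, species) pair, records the annotation string to
#' transfer: `"protein_id description"` of the *first* protein listed for
#' that species in that orthogroup row (file order, never alphabetical), or
#' the literal token `"none"` when the species has no member there. The map
#' is total over orthogroups x species.
#'
#' @param table An [orthogroup_table()].
#' @param proteins Named list, one element per species, each a
#'   [read_fasta()] data frame supplying descriptions.
#' @param species Character vector of species (proteome) IDs to annotate
#'   with; defaults to `names(proteins)`.
#' @return A data frame of class `annotation_map` with columns `orthogroup`,
#'   `species`, `annotation`.
#' @export
build_annotation_map <- function(table, proteins, species = names(proteins)) {
  stopifnot(inherits(table, "orthogroup_table"), is.list(proteins))
  miss <- setdiff(species, names(proteins))
  if (length(miss))
    stop("no protein records supplied for species: ", paste(miss, collapse = ", "))
  bad <- setdiff(species, proteomes(table))
  if (length(bad))
    stop("species not in the orthogroup table header: ", paste(bad, collapse = ", "))
  lookups <- lapply(proteins[species], function(df)
    stats::setNames(df$description, df$protein_id))
  rows <- vector("list", length(table) * length(species))
  unresolved <- character(0)
  k <- 0L
  for (og in names(table)) {
    cells <- table[[og]]
    for (sp in species) {
      k <- k + 1L
      members <- cells[[sp]]
      ann <- if (!length(members)) "none" else {
        first <- members[[1L]]
        if (!first %in% names(lookups[[sp]])) {
          unresolved <- c(unresolved, first)
          "none"
        } else trimws(paste(first, lookups[[sp]][[first]]))
      }
      rows[[k]] <- list(orthogroup = og, species = sp, annotation = ann)
    }
  }
  if (length(unresolved))
    stop("consistency error: orthogroup protein(s) absent from the protein FASTA: ",
         paste(utils::head(unique(unresolved), 10L), collapse = ", "))
  out <- data.frame(orthogroup = vapply(rows, `[[`, "", "orthogroup"),
                    species = vapply(rows, `[[`, "", "species"),
                    annotation = vapply(rows, `[[`, "", "annotation"),
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_map", "data.frame")
  out
}

#' Transfer ortholog annotations onto transcript interval features
#'
#' Appends, to every transcript-level feature, one attribute per configured
#' species with key `"<species>_ortholog"` and value the mapped annotation
#' (or `"none"` for species absent from the orthogroup, and for clusters
#' assigned to no orthogroup). Feature count, order, coordinates, strand,
#' and all pre-existing attributes are preserved exactly; features of other
#' types (exons, CDS, ...) are left untouched. Values are percent-encoded
#' only at [write_gff3()] time.
#'
#' @param features A [gff3_features()] data frame whose transcript features
#'   carry a cluster-ID attribute.
#' @param cluster_to_og Named character vector mapping cluster ID to
#'   orthogroup ID (see [cluster_orthogroup_map()]); clusters absent from it
#'   get `"none"` for every species.
#' @param amap An `annotation_map` from [build_annotation_map()].
#' @param species Species to transfer, in output attribute order; defaults
#'   to the species present in `amap`.
#' @param cluster_attr Name of the attribute holding the cluster ID.
#' @param transcript_types Feature types treated as transcript-level.
#' @return The features with ortholog attributes appended.
#' @export
transfer_annotations <- function(features, cluster_to_og, amap,
                                 species = unique(amap$species),
                                 cluster_attr = "cluster",
                                 transcript_types = c("mRNA", "transcript")) {
  stopifnot(inherits(features, "gff3_features"), inherits(amap, "annotation_map"))
  ann <- stats::setNames(amap$annotation, paste(amap$orthogroup, amap$species, sep = "\r"))
  is_tx <- features$type %in% transcript_types
  attrs <- features$attributes
  for (i in which(is_tx)) {
    a <- attrs[[i]]
    if (!cluster_attr %in% names(a)) {
      fid <- if ("ID" %in% names(a)) a[["ID"]] else sprintf("feature #%d", i)
      stop("consistency error: transcript feature lacks a '", cluster_attr,
           "' attribute: ", fid)
    }
    og <- cluster_to_og[a[[cluster_attr]]]
    for (sp in species) {
      val <- if (is.na(og)) "none" else {
        hit <- ann[paste(og, sp, sep = "\r")]
        if (is.na(hit)) "none" else unname(hit)
      }
      a[[paste0(sp, "_ortholog")]] <- val
    }
    attrs[[i]] <- a
  }
  features$attributes <- attrs
  features
}
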