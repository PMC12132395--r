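#' Collapse protein-level orthogroup membership to gene-cluster level
#'
#' For each focal assembly, replaces the proteins in every orthogroup cell
#' (often several isoforms per locus) with a single entry per gene cluster,
#' deduplicated in first-occurrence order. Cells of all other proteomes are
#' copied verbatim. A cluster whose proteins span more than one orthogroup
#' is retained in each and reported via the `multi_orthogroup_clusters`
#' attribute (and a message).
#'
#' @param table An [orthogroup_table()] (protein level).
#' @param map A [gene_cluster_map()] covering every focal protein in the
#'   table; an unmapped focal protein is an error.
#' @param config A [species_group_config()]; its `focal_assemblies` decide
#'   which columns are collapsed.
#' @return A `gene_level_table` (same shape as the input table; focal cells
#'   hold cluster IDs) with attributes `proteomes`, `focal`, and
#'   `multi_orthogroup_clusters`.
#' @export
collapse_to_gene_table <- function(table, map, config) {
  stopifnot(inherits(table, "orthogroup_table"),
            inherits(map, "gene_cluster_map"),
            inherits(config, "species_group_config"))
  focal <- intersect(proteomes(table), config$focal_assemblies)
  cl <- stats::setNames(map$cluster_id, map$protein_id)
  unmapped <- character(0)
  out <- lapply(table, function(cells) {
    for (a in focal) {
      prots <- cells[[a]]
      if (!length(prots)) next
      miss <- prots[!prots %in% names(cl)]
      if (length(miss)) unmapped <<- c(unmapped, miss)
      cells[[a]] <- unique(unname(cl[prots[prots %in% names(cl)]]))
    }
    cells
  })
  if (length(unmapped))
    stop("consistency error: focal protein(s) missing from the cluster map: ",
         paste(utils::head(unique(unmapped), 10L), collapse = ", "))
  gt <- structure(out, proteomes = proteomes(table), focal = focal,
                  class = c("gene_level_table", "orthogroup_table"))
  multi <- .multi_orthogroup_clusters(gt, focal)
  if (nrow(multi)) {
    message(sprintf("%d gene cluster(s) span more than one orthogroup; retained in each",
                    nrow(multi)))
  }
  attr(gt, "multi_orthogroup_clusters") <- multi
  gt
}

.multi_orthogroup_clusters <- function(gt, focal) {
  rows <- list()
  for (a in focal) {
    occ <- unlist(lapply(gt, `[[`, a), use.names = FALSE)
    tab <- table(occ)
    dup <- names(tab)[tab > 1L]
    if (length(dup))
      rows[[a]] <- data.frame(assembly = a, cluster = dup,
                              n_orthogroups = as.integer(tab[dup]),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(assembly = character(0), cluster = character(0),
                      n_orthogroups = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count orthogroup members per comparison group
#'
#' Evaluates one orthogroup's membership against the three comparison
#' groups the census criteria quantify over: *conspecific-others* (the
#' conspecific proteomes other than the censused assembly itself),
#' *non-conspecific*, and *non-ingroup*. Under `counting_unit = "species"` a
#' group's count is the number of distinct proteomes in the group with at
#' least one member; under `"proteins"` it is the total number of member
#' entries.
#'
#' @param membership One orthogroup's cells: a named list mapping proteome
#'   ID to its member entries.
#' @param config A [species_group_config()].
#' @param focal_assembly The assembly (or reference proteome) relative to
#'   which "conspecific-others" is evaluated.
#' @return Named integer vector with elements `conspecific-others`,
#'   `non-conspecific`, `non-ingroup`.
#' @export
orthogroup_group_counts <- function(membership, config, focal_assembly) {
  stopifnot(inherits(config, "species_group_config"))
  if (!focal_assembly %in% config$conspecific)
    stop("focal_assembly must be a conspecific proteome: ", focal_assembly)
  grp <- list(
    `conspecific-others` = setdiff(config$conspecific, focal_assembly),
    `non-conspecific` = setdiff(config$proteomes, config$conspecific),
    `non-ingroup` = setdiff(config$proteomes, config$ingroup))
  vapply(grp, function(g) {
    sizes <- lengths(membership[intersect(g, names(membership))])
    if (config$counting_unit == "species") sum(sizes > 0L) else sum(sizes)
  }, 0L)
}

#' The five gene-census criteria
#'
#' An assembly's gene cluster is counted under a criterion when it sits in
#' at least one orthogroup whose comparison-group count reaches the
#' threshold: at least one other conspecific member, at least 1 or at least
#' 10 non-conspecific members, and at least 1 or at least 10 non-ingroup
#' members.
#'
#' @return Data frame with columns `group`, `min_members`, `label`.
#' @export
census_criteria <- function() {
  grp <- c("conspecific-others", "non-conspecific", "non-ingroup",
           "non-conspecific", "non-ingroup")
  thr <- c(1L, 1L, 1L, 10L, 10L)
  data.frame(group = grp, min_members = thr,
             label = sprintf("%s_ge%d", gsub("-", "_", grp, fixed = TRUE), thr),
             stringsAsFactors = FALSE)
}

#' Census gene clusters by orthogroup composition
#'
#' For every censused proteome (the focal assemblies, plus the conspecific
#' reference proteome(s), whose gene units are their protein entries) and
#' every criterion, counts the distinct gene clusters appearing in at least
#' one orthogroup satisfying that criterion. A cluster found in several
#' qualifying orthogroups counts once.
#'
#' @param gene_table A `gene_level_table` from [collapse_to_gene_table()].
#' @param config A [species_group_config()].
#' @param criteria Data frame of `(group, min_members)` pairs; defaults to
#'   [census_criteria()].
#' @return A data frame of class `census_result`: one row per
#'   (assembly, criterion) with columns `assembly`, `group`, `min_members`,
#'   `label`, `n_genes`.
#' @export
census_counts <- function(gene_table, config, criteria = census_criteria()) {
  stopifnot(inherits(gene_table, "orthogroup_table"),
            inherits(config, "species_group_config"))
  if (!"label" %in% names(criteria))
    criteria$label <- sprintf("%s_ge%d",
                              gsub("-", "_", criteria$group, fixed = TRUE),
                              criteria$min_members)
  subjects <- intersect(c(config$focal_assemblies, reference_proteomes(config)),
                        proteomes(gene_table))
  res <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    sets <- rep(list(character(0)), nrow(criteria))
    for (cells in gene_table) {
      entries <- cells[[s]]
      if (is.null(entries) || !length(entries)) next
      gcount <- orthogroup_group_counts(cells, config, focal_assembly = s)
      sat <- gcount[criteria$group] >= criteria$min_members
      for (k in which(sat)) sets[[k]] <- c(sets[[k]], entries)
    }
    res[[si]] <- data.frame(
      assembly = s, group = criteria$group, min_members = criteria$min_members,
      label = criteria$label,
      n_genes = vapply(sets, function(e) length(unique(e)), 0L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("census_result", "data.frame")
  out
}

#' Extract candidate novel genes
#'
#' Returns the orthogroups that hold at least one gene cluster in *every*
#' focal assembly, no member at all in any reference proteome, at least
#' `min_outgroup` non-ingroup members (under the configured counting unit),
#' and at least one member from the configured required species. These are
#' candidate genes conserved across distant species yet absent from the
#' reference annotation.
#'
#' @param gene_table A `gene_level_table` from [collapse_to_gene_table()].
#' @param config A [species_group_config()]; must define at least one
#'   reference proteome.
#' @param min_outgroup Minimum non-ingroup member count (default 10).
#' @return A data frame of class `novel_gene_report`, sorted by orthogroup
#'   ID: `orthogroup`, one comma-joined cluster-ID column per focal
#'   assembly, `n_outgroup`, `required_members`.
#' @export
extract_novel <- function(gene_table, config, min_outgroup = 10L) {
  stopifnot(inherits(gene_table, "orthogroup_table"),
            inherits(config, "species_group_config"))
  refs <- reference_proteomes(config)
  if (!length(refs))
    stop("group config error: no reference proteome (conspecific minus focal is empty); the novel-gene filter is undefined")
  focal <- config$focal_assemblies
  req <- config$required_species
  rows <- list()
  for (og in names(gene_table)) {
    cells <- gene_table[[og]]
    if (!all(lengths(cells[focal]) > 0L)) next
    if (sum(lengths(cells[refs])) > 0L) next
    gcount <- orthogroup_group_counts(cells, config, focal_assembly = focal[[1L]])
    if (gcount[["non-ingroup"]] < min_outgroup) next
    if (!length(cells[[req]])) next
    row <- c(list(orthogroup = og),
             stats::setNames(lapply(focal, function(a) paste(cells[[a]], collapse = ",")),
                             focal),
             list(n_outgroup = unname(gcount[["non-ingroup"]]),
                  required_members = paste(cells[[req]], collapse = ",")))
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE,
                                               check.names = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(c(list(orthogroup = character(0)),
                    stats::setNames(rep(list(character(0)), length(focal)), focal),
                    list(n_outgroup = integer(0), required_members = character(0))),
                  check.names = FALSE)
  out <- out[order(out$orthogroup), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("novel_gene_report", "data.frame")
  out
}

#' Map gene clusters to the orthogroup(s) holding them
#'
#' @param gene_table A `gene_level_table`.
#' @return Named character vector cluster ID -> orthogroup ID (the first
#'   orthogroup, for clusters spanning several).
#' @export
cluster_orthogroup_map <- function(gene_table) {
  stopifnot(inherits(gene_table, "orthogroup_table"))
  focal <- attr(gene_table, "focal")
  if (is.null(focal)) focal <- proteomes(gene_table)
  out <- character(0)
  for (og in names(gene_table)) {
    cl <- unlist(gene_table[[og]][focal], use.names = FALSE)
    cl <- setdiff(cl, names(out))
    if (length(cl)) out[cl] <- og
  }
  out
}
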