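#' Species-group configuration
#'
#' The census criteria quantify over nested proteome groups: the focal
#' assemblies being censused, the conspecific set (focal assemblies plus the
#' same-species reference annotation), the ingroup (conspecific plus close
#' relatives — here, other aphids), and everything else (the outgroup).
#' Group membership is always declared by the user, never inferred from
#' taxonomy.
#'
#' @param proteomes All proteome IDs in the analysis.
#' @param focal_assemblies Assemblies being annotated and censused.
#' @param conspecific Focal assemblies plus same-species reference
#'   proteome(s); must contain `focal_assemblies`.
#' @param ingroup Conspecific plus congeneric/family relatives; must contain
#'   `conspecific`.
#' @param required_species A single proteome ID outside the ingroup whose
#'   presence the novel-gene filter requires (the conserved anchor species,
#'   e.g. *Drosophila melanogaster*).
#' @param counting_unit `"species"` (distinct proteomes with at least one
#'   member; the default) or `"proteins"` (total member entries) for group
#'   size evaluation.
#' @return An object of class `species_group_config`.
#' @export
species_group_config <- function(proteomes, focal_assemblies, conspecific,
                                 ingroup, required_species,
                                 counting_unit = c("species", "proteins")) {
  counting_unit <- match.arg(counting_unit)
  proteomes <- as.character(proteomes)
  check_subset <- function(small, big, a, b) {
    bad <- setdiff(small, big)
    if (length(bad))
      stop(sprintf("group config error: %s not nested in %s; offending proteome(s): %s",
                   a, b, paste(bad, collapse = ", ")))
  }
  check_subset(focal_assemblies, conspecific, "focal_assemblies", "conspecific")
  check_subset(conspecific, ingroup, "conspecific", "ingroup")
  check_subset(ingroup, proteomes, "ingroup", "proteomes")
  if (length(required_species) != 1L || !required_species %in% proteomes)
    stop("group config error: required_species must be one proteome ID")
  if (required_species %in% ingroup)
    stop("group config error: required_species must lie outside the ingroup: ",
         required_species)
  structure(list(proteomes = proteomes,
                 focal_assemblies = as.character(focal_assemblies),
                 conspecific = as.character(conspecific),
                 ingroup = as.character(ingroup),
                 required_species = as.character(required_species),
                 counting_unit = counting_unit),
            class = "species_group_config")
}

#' Reference proteomes of a configuration
#'
#' The reference set is conspecific-but-not-focal by definition: the
#' pre-existing same-species annotation(s) that the novel-gene filter
#' excludes against.
#'
#' @param config A [species_group_config()].
#' @return Character vector of reference proteome IDs.
#' @export
reference_proteomes <- function(config) {
  setdiff(config$conspecific, config$focal_assemblies)
}

#' Load / write a species-group configuration
#'
#' Flat `key = value` text file; list-valued keys are comma-separated. Keys:
#' `proteomes`, `focal_assemblies`, `conspecific`, `ingroup`,
#' `required_species`, and optionally `counting_unit` (default `species`).
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return [load_group_config()]: a validated [species_group_config()].
#' @export
load_group_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- list()
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE))
      stop("group config format error: expected 'key = value' in line: ", line)
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(strsplit(sub("^[^=]*=", "", line), ",", fixed = TRUE)[[1]])
    kv[[key]] <- val[nzchar(val)]
  }
  need <- c("proteomes", "focal_assemblies", "conspecific", "ingroup",
            "required_species")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("group config format error: missing key(s): ", paste(miss, collapse = ", "))
  species_group_config(kv$proteomes, kv$focal_assemblies, kv$conspecific,
                       kv$ingroup, kv$required_species,
                       counting_unit = if (is.null(kv$counting_unit)) "species"
                                       else kv$counting_unit)
}

#' @rdname load_group_config
#' @param config A [species_group_config()].
#' @export
write_group_config <- function(config, path) {
  stopifnot(inherits(config, "species_group_config"))
  fmt <- function(key) paste0(key, " = ", paste(config[[key]], collapse = ", "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(c("proteomes", "focal_assemblies", "conspecific",
                      "ingroup", "required_species", "counting_unit"),
                    fmt, ""), con)
  invisible(path)
}
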