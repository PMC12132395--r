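#' Parameters for a synthetic multi-assembly gene-family scenario
#'
#' Defines a simulated study: several newly annotated assemblies of one
#' species, one same-species reference proteome, a set of ingroup relatives,
#' and a set of outgroup species (the first of which is the conserved anchor
#' species the novel-gene filter requires). Families are planted with the
#' events that complicate real multi-assembly annotation: focal-lineage
#' duplications, families missing from the reference annotation, duplicated
#' paralogs collapsed into a single reference locus, and pseudogenes whose
#' longest intact ORF differs between assemblies.
#'
#' @param n_families Number of gene families (one orthogroup each).
#' @param n_outgroup_species Number of outgroup proteomes (>= 1; >= 10 is
#'   needed for the novel-gene filter to be satisfiable).
#' @param n_ingroup_species Number of ingroup relatives beyond the
#'   conspecific set.
#' @param n_focal_assemblies Number of focal assemblies (default 3).
#' @param p_focal_duplication Probability that a family carries a
#'   focal-lineage duplication (two paralogous loci in every focal assembly).
#' @param p_missing_in_reference Probability that a family has no member in
#'   the reference proteome.
#' @param p_collapse_in_reference Probability, for a duplicated family, that
#'   the reference mis-assembles the paralogs into one locus (one entry).
#'   Requires `p_focal_duplication > 0`.
#' @param p_pseudogene Probability that a family's youngest copy is a
#'   pseudogene: premature stops are planted at assembly-specific positions,
#'   so the longest intact ORF length (sampled in 50-149 aa, distinct per
#'   assembly) straddles the 100-aa coding threshold differently per
#'   assembly.
#' @param p_species_presence Per-species presence probability of a family in
#'   each ingroup-relative and outgroup proteome (default 1: present
#'   everywhere, so that with all event probabilities 0 every criterion
#'   counts every family).
#' @param orf_length_aa Mean coding length (amino acids) of intact genes.
#' @param seed Integer seed driving all randomness.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(n_families = 500L, n_outgroup_species = 15L,
                            n_ingroup_species = 5L, n_focal_assemblies = 3L,
                            p_focal_duplication = 0.2,
                            p_missing_in_reference = 0.05,
                            p_collapse_in_reference = 0.5,
                            p_pseudogene = 0.05,
                            p_species_presence = 1,
                            orf_length_aa = 200L, seed = 1L) {
  counts <- c(n_families = n_families, n_outgroup_species = n_outgroup_species,
              n_ingroup_species = n_ingroup_species,
              n_focal_assemblies = n_focal_assemblies)
  if (any(counts < 1L)) stop("parameter error: counts must be >= 1")
  probs <- c(p_focal_duplication = p_focal_duplication,
             p_missing_in_reference = p_missing_in_reference,
             p_collapse_in_reference = p_collapse_in_reference,
             p_pseudogene = p_pseudogene,
             p_species_presence = p_species_presence)
  if (any(probs < 0 | probs > 1))
    stop("parameter error: probabilities must lie in [0, 1]")
  if (p_collapse_in_reference > 0 && p_focal_duplication == 0)
    stop("parameter error: paralog collapse requires duplication (p_focal_duplication = 0 but p_collapse_in_reference > 0)")
  if (orf_length_aa < 110L)
    stop("parameter error: orf_length_aa must be >= 110 so intact genes clear the 100-aa coding threshold")
  structure(c(as.list(counts), as.list(probs),
              list(orf_length_aa = as.integer(orf_length_aa),
                   seed = as.integer(seed))),
            class = "scenario_params")
}

# Codon alphabets chosen so that planted ORFs are provably the only complete
# ORFs in a transcript: interior codons contain no adenine, hence no ATG and
# no stop codon can arise outside the planted start/stop positions, in any
# frame; spurious out-of-frame ATGs near planted stops never reach an
# in-frame stop and so never form a complete ORF.
.AFREE_CODONS <- apply(expand.grid(c("C", "G", "T"), c("C", "G", "T"),
                                   c("C", "G", "T")), 1L, paste, collapse = "")
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.rand_cds <- function(len_aa) {
  paste0("ATG", paste(sample(.AFREE_CODONS, len_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

.rand_utr <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("C", "T"), len, replace = TRUE), collapse = "")
}

.rand_protein <- function(len_aa) {
  paste(sample(.AA_ALPHABET, len_aa, replace = TRUE), collapse = "")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic multi-assembly scenario
#'
#' Deterministically (seeded) emits a complete file set under `outdir` —
#' ground-truth orthogroup table, per-proteome protein FASTA, per-assembly
#' transcript FASTA and GFF3 intervals, cluster map, group configuration,
#' and a truth table — together with a `synthetic_truth` object from which
#' every downstream expectation (census counts, novel-gene set, planted
#' longest-ORF lengths) can be recomputed exactly without touching the
#' files.
#'
#' Coding sequences are built as ATG + adenine-free random codons + stop, so
#' the planted ORF is provably the longest complete ORF of its transcript;
#' pseudogene copies carry a premature stop splitting the ancestral frame
#' into two ORFs whose longest piece differs per assembly. Families hit by
#' the missing-in-reference event have an empty reference cell; collapsed
#' families keep both focal paralog clusters but a single reference entry.
#'
#' @param params A [scenario_params()] object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with elements `dir`, `files` (named paths),
#'   `config` (the [species_group_config()]), `truth` (a `synthetic_truth`),
#'   and `params`.
#' @export
generate_scenario <- function(params, outdir = tempfile("scenario")) {
  stopifnot(inherits(params, "scenario_params"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("proteins", "transcripts", "intervals"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)

  assemblies <- sprintf("asm%d", seq_len(params$n_focal_assemblies))
  ref <- "refseq"
  relatives <- sprintf("aphid%d", seq_len(params$n_ingroup_species))
  outgroups <- c("dmel",
                 if (params$n_outgroup_species > 1L)
                   sprintf("outsp%d", 2:params$n_outgroup_species))
  all_prot <- c(assemblies, ref, relatives, outgroups)
  config <- species_group_config(
    proteomes = all_prot, focal_assemblies = assemblies,
    conspecific = c(assemblies, ref), ingroup = c(assemblies, ref, relatives),
    required_species = "dmel", counting_unit = "species")

  min_aa <- 100L  # coding threshold the planted memberships respect

  truth <- .with_seed(params$seed, {
    fam_rows <- vector("list", params$n_families)
    orf_rows <- list()
    detail <- vector("list", params$n_families)
    ogs <- vector("list", params$n_families)
    map_rows <- list()
    tx <- stats::setNames(rep(list(list()), length(assemblies)), assemblies)
    focal_prot <- stats::setNames(rep(list(list()), length(assemblies)), assemblies)
    other_prot <- stats::setNames(rep(list(list()), length(c(ref, relatives, outgroups))),
                                  c(ref, relatives, outgroups))

    for (f in seq_len(params$n_families)) {
      fid <- sprintf("F%04d", f)
      ogid <- sprintf("OG%07d", f)
      duplicated <- stats::runif(1) < params$p_focal_duplication
      n_par <- if (duplicated) 2L else 1L
      missing <- stats::runif(1) < params$p_missing_in_reference
      collapsed <- duplicated && !missing &&
        stats::runif(1) < params$p_collapse_in_reference
      pseudo <- stats::runif(1) < params$p_pseudogene
      L <- max(110L, as.integer(round(stats::rnorm(1, params$orf_length_aa,
                                                   params$orf_length_aa / 8))))
      pl <- if (pseudo) sample(50:149, length(assemblies)) else
        rep(L, length(assemblies))

      cells <- stats::setNames(rep(list(character(0)), length(all_prot)), all_prot)
      fam_clusters <- stats::setNames(rep(list(character(0)), length(assemblies)),
                                      assemblies)
      for (ai in seq_along(assemblies)) {
        a <- assemblies[[ai]]
        for (j in seq_len(n_par)) {
          cid <- sprintf("%s_%s_g%d", a, fid, j)
          is_pseudo_copy <- pseudo && j == n_par
          longest <- if (is_pseudo_copy) pl[[ai]] else L
          cds <- if (is_pseudo_copy) {
            second <- max(5L, longest %/% 2L)
            segs <- c(.rand_cds(longest), .rand_cds(second))
            paste(segs[sample(2L)], collapse = "")
          } else .rand_cds(longest)
          n_iso <- if (is_pseudo_copy) 1L else sample(1:3, 1L)
          coding <- longest >= min_aa
          for (i in seq_len(n_iso)) {
            tid <- sprintf("%s_t%d", cid, i)
            seq <- paste0(.rand_utr(sample(0:30, 1L)), cds,
                          .rand_utr(sample(0:30, 1L)))
            tx[[a]][[tid]] <- seq
            if (coding) {
              cells[[a]] <- c(cells[[a]], tid)
              map_rows[[length(map_rows) + 1L]] <- c(tid, a, cid)
            }
          }
          if (coding) {
            fam_clusters[[a]] <- c(fam_clusters[[a]], cid)
            # proteins of all isoforms are identical: translate the planted CDS
            call <- find_longest_orf(cds, orf_params(min_protein_length = 1L))
            for (i in seq_len(n_iso)) {
              tid <- sprintf("%s_t%d", cid, i)
              focal_prot[[a]][[tid]] <- call$protein
            }
          }
          orf_rows[[length(orf_rows) + 1L]] <- data.frame(
            family = fid, orthogroup = ogid, assembly = a, cluster = cid,
            paralog = j, planted_longest_orf_aa = longest, coding = coding,
            pseudogene_copy = is_pseudo_copy, stringsAsFactors = FALSE)
        }
      }

      ref_ids <- character(0)
      if (!missing) {
        ref_ids <- if (collapsed) sprintf("%s_%s_g1", ref, fid) else
          sprintf("%s_%s_g%d", ref, fid, seq_len(n_par))
        cells[[ref]] <- ref_ids
        for (id in ref_ids)
          other_prot[[ref]][[id]] <- .rand_protein(L)
      }

      present_species <- character(0)
      for (sp in c(relatives, outgroups)) {
        if (stats::runif(1) < params$p_species_presence) {
          id <- sprintf("%s_%s", sp, fid)
          cells[[sp]] <- id
          other_prot[[sp]][[id]] <- .rand_protein(L)
          present_species <- c(present_species, sp)
        }
      }

      n_out_species <- length(intersect(present_species, outgroups))
      novel <- missing && all(lengths(fam_clusters) > 0L) &&
        n_out_species >= 10L && "dmel" %in% present_species

      ogs[[f]] <- cells
      fam_rows[[f]] <- data.frame(
        family = fid, orthogroup = ogid, n_paralogs = n_par,
        duplicated = duplicated, missing_in_reference = missing,
        collapsed_in_reference = collapsed, pseudogene = pseudo,
        base_orf_aa = L, novel = novel, stringsAsFactors = FALSE)
      detail[[f]] <- list(family = fid, orthogroup = ogid,
                          assembly_clusters = fam_clusters,
                          reference_n = length(ref_ids),
                          species_present = present_species)
    }
    names(ogs) <- vapply(fam_rows, `[[`, "", "orthogroup")
    names(detail) <- names(ogs)
    list(families = do.call(rbind, fam_rows),
         orf_lengths = do.call(rbind, orf_rows),
         detail = detail, ogs = ogs, map_rows = map_rows,
         tx = tx, focal_prot = focal_prot, other_prot = other_prot)
  })

  table <- orthogroup_table(truth$ogs, all_prot)
  map <- gene_cluster_map(
    vapply(truth$map_rows, `[[`, "", 1L),
    vapply(truth$map_rows, `[[`, "", 2L),
    vapply(truth$map_rows, `[[`, "", 3L))

  files <- list(orthogroups = file.path(outdir, "orthogroups.tsv"),
                cluster_map = file.path(outdir, "cluster_map.tsv"),
                groups = file.path(outdir, "groups.cfg"),
                truth = file.path(outdir, "truth.tsv"),
                orf_lengths = file.path(outdir, "truth_orf_lengths.tsv"))
  write_orthogroup_table(table, files$orthogroups)
  write_cluster_map(map, files$cluster_map)
  write_group_config(config, files$groups)
  utils::write.table(truth$families, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$orf_lengths, files$orf_lengths, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  for (a in assemblies) {
    seqs <- truth$tx[[a]]
    write_fasta(data.frame(protein_id = names(seqs),
                           description = "",
                           sequence = unlist(seqs, use.names = FALSE),
                           stringsAsFactors = FALSE),
                file.path(outdir, "transcripts", paste0(a, ".fa")))
    files[[paste0("transcripts_", a)]] <- file.path(outdir, "transcripts",
                                                    paste0(a, ".fa"))
    prots <- truth$focal_prot[[a]]
    pids <- if (is.null(names(prots))) character(0) else names(prots)
    cl <- stats::setNames(map$cluster_id, map$protein_id)
    write_fasta(data.frame(protein_id = pids,
                           description = sprintf("predicted protein, cluster %s",
                                                 unname(cl[pids])),
                           sequence = as.character(unlist(prots, use.names = FALSE)),
                           stringsAsFactors = FALSE),
                file.path(outdir, "proteins", paste0(a, ".faa")))
    files[[paste0("proteins_", a)]] <- file.path(outdir, "proteins",
                                                 paste0(a, ".faa"))
    # genomic intervals: transcripts laid end to end on one scaffold
    tids <- names(seqs)
    lens <- nchar(unlist(seqs, use.names = FALSE))
    starts <- cumsum(c(1L, utils::head(lens + 100L, -1L)))
    clusters <- sub("_t[0-9]+$", "", tids)
    feat <- gff3_features(
      seqid = "scaffold_1", source = "simulator",
      type = rep(c("mRNA", "exon"), length(tids))[seq_len(2L * length(tids))],
      start = rep(starts, each = 2L), end = rep(starts + lens - 1L, each = 2L),
      strand = "+",
      attributes = unlist(lapply(seq_along(tids), function(i) {
        list(c(ID = tids[[i]], cluster = clusters[[i]]),
             c(ID = paste0(tids[[i]], ".exon1"), Parent = tids[[i]]))
      }), recursive = FALSE))
    write_gff3(feat, file.path(outdir, "intervals", paste0(a, ".gff3")))
    files[[paste0("intervals_", a)]] <- file.path(outdir, "intervals",
                                                  paste0(a, ".gff3"))
  }
  for (sp in c(ref, relatives, outgroups)) {
    prots <- truth$other_prot[[sp]]
    pids <- if (is.null(names(prots))) character(0) else names(prots)
    write_fasta(data.frame(protein_id = pids,
                           description = sprintf("hypothetical protein %s [%s]",
                                                 sub("^.*_(F[0-9]+).*$", "\\1", pids),
                                                 sp),
                           sequence = as.character(unlist(prots, use.names = FALSE)),
                           stringsAsFactors = FALSE),
                file.path(outdir, "proteins", paste0(sp, ".faa")))
    files[[paste0("proteins_", sp)]] <- file.path(outdir, "proteins",
                                                  paste0(sp, ".faa"))
  }

  truth_obj <- structure(list(params = params, config = config,
                              families = truth$families,
                              orf_lengths = truth$orf_lengths,
                              detail = truth$detail),
                         class = "synthetic_truth")
  invisible(list(dir = outdir, files = files, config = config,
                 truth = truth_obj, params = params))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d families, %d assemblies; %d duplicated, %d missing-in-reference, %d collapsed, %d pseudogene, %d novel\n",
              nrow(x$families), x$params$n_focal_assemblies,
              sum(x$families$duplicated), sum(x$families$missing_in_reference),
              sum(x$families$collapsed_in_reference), sum(x$families$pseudogene),
              sum(x$families$novel)))
  invisible(x)
}

#' Expected census counts from planted truth
#'
#' Recomputes the gene census directly from the planted event structure —
#' per-family cluster counts, reference entries, and species presence —
#' without touching any emitted file or the gene-level table machinery. It
#' is the recovery target the file-based pipeline must match exactly.
#'
#' @param truth A `synthetic_truth` from [generate_scenario()].
#' @param config A [species_group_config()] (defaults to the scenario's).
#' @param criteria Criterion table, as for [census_counts()].
#' @return A `census_result` data frame, same shape as [census_counts()].
#' @export
expected_census <- function(truth, config = truth$config,
                            criteria = census_criteria()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!"label" %in% names(criteria))
    criteria$label <- sprintf("%s_ge%d",
                              gsub("-", "_", criteria$group, fixed = TRUE),
                              criteria$min_members)
  refs <- reference_proteomes(config)
  subjects <- c(config$focal_assemblies, refs)
  counts <- matrix(0L, nrow = length(subjects), ncol = nrow(criteria),
                   dimnames = list(subjects, NULL))
  for (fd in truth$detail) {
    # gene-entry count per proteome for this family
    n_entries <- integer(0)
    for (a in config$focal_assemblies)
      n_entries[[a]] <- length(fd$assembly_clusters[[a]])
    for (r in refs) n_entries[[r]] <- fd$reference_n
    for (sp in fd$species_present) n_entries[[sp]] <- 1L
    for (s in subjects) {
      self_n <- n_entries[[s]]
      if (self_n == 0L) next
      for (k in seq_len(nrow(criteria))) {
        grp_members <- switch(criteria$group[[k]],
          "conspecific-others" = setdiff(config$conspecific, s),
          "non-conspecific" = setdiff(config$proteomes, config$conspecific),
          "non-ingroup" = setdiff(config$proteomes, config$ingroup),
          stop("unknown group: ", criteria$group[[k]]))
        tally <- 0L
        for (p in grp_members) {
          np <- unname(n_entries[p])
          if (is.na(np)) np <- 0L
          if (config$counting_unit == "species") {
            if (np > 0L) tally <- tally + 1L
          } else tally <- tally + np
        }
        if (tally >= criteria$min_members[[k]])
          counts[s, k] <- counts[s, k] + self_n
      }
    }
  }
  out <- do.call(rbind, lapply(subjects, function(s)
    data.frame(assembly = s, group = criteria$group,
               min_members = criteria$min_members, label = criteria$label,
               n_genes = unname(counts[s, ]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("census_result", "data.frame")
  out
}

#' Truth-flagged novel families
#'
#' The families the novel-gene filter must recover: planted as missing from
#' the reference, with at least one coding cluster in every focal assembly,
#' at least 10 outgroup species present, and the required anchor species
#' among them.
#'
#' @param truth A `synthetic_truth`.
#' @return Data frame with columns `family`, `orthogroup`.
#' @export
expected_novel <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- truth$families[truth$families$novel, c("family", "orthogroup")]
  rownames(out) <- NULL
  out
}

#' Perturb orthogroup clustering for pseudogene-bearing families
#'
#' Emulates the clustering disruption caused by differential ORF
#' fragmentation of a pseudogene: with probability `p_split` per
#' pseudogene-bearing family, the most divergent assembly's members (the
#' non-empty focal cell whose planted pseudogene ORF is shortest) are moved
#' to a new singleton orthogroup named `<orthogroup>_split`. Moved members
#' are never duplicated: the source cell is emptied.
#'
#' @param table A protein-level [orthogroup_table()] (e.g. the scenario's).
#' @param truth The `synthetic_truth` identifying pseudogene families and
#'   their planted ORF lengths.
#' @param p_split Split probability per pseudogene-bearing family.
#' @param seed Integer seed.
#' @return A perturbed [orthogroup_table()].
#' @export
perturb_clustering <- function(table, truth, p_split = 1, seed = 1L) {
  stopifnot(inherits(table, "orthogroup_table"),
            inherits(truth, "synthetic_truth"))
  if (p_split < 0 || p_split > 1) stop("p_split must lie in [0, 1]")
  fams <- truth$families[truth$families$pseudogene, , drop = FALSE]
  ogs <- unclass(table)
  attrs <- attributes(table)
  new_ogs <- list()
  .with_seed(seed, {
    for (i in seq_len(nrow(fams))) {
      if (stats::runif(1) >= p_split) next
      og <- fams$orthogroup[[i]]
      if (!og %in% names(ogs)) next
      ol <- truth$orf_lengths
      ol <- ol[ol$orthogroup == og & ol$pseudogene_copy, , drop = FALSE]
      cand <- ol$assembly[order(ol$planted_longest_orf_aa)]
      cand <- cand[vapply(cand, function(a) length(ogs[[og]][[a]]) > 0L, TRUE)]
      if (!length(cand)) next
      div <- cand[[1L]]
      cells <- stats::setNames(rep(list(character(0)), length(attrs$proteomes)),
                               attrs$proteomes)
      cells[[div]] <- ogs[[og]][[div]]
      ogs[[og]][[div]] <- character(0)
      new_ogs[[paste0(og, "_split")]] <- cells
    }
  })
  orthogroup_table(c(ogs, new_ogs), attrs$proteomes)
}
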