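toy_config <- function(counting = "species") {
  species_group_config(
    proteomes = c("A1", "A2", "REF", "ING1", paste0("OUT", 1:12)),
    focal_assemblies = c("A1", "A2"),
    conspecific = c("A1", "A2", "REF"),
    ingroup = c("A1", "A2", "REF", "ING1"),
    required_species = "OUT1", counting_unit = counting)
}

test_that("collapsing replaces isoform proteins with one entry per cluster", {
  cfg <- toy_config()
  tab <- orthogroup_table(
    list(OG1 = list(A1 = c("p1", "p2", "p3"), REF = c("r1", "r2")),
         OG2 = list(A1 = "p4")),
    cfg$proteomes)
  map <- gene_cluster_map(c("p1", "p2", "p3", "p4"), "A1",
                          c("c1", "c1", "c2", "c3"))
  gt <- collapse_to_gene_table(tab, map, cfg)
  expect_identical(gt[["OG1"]][["A1"]], c("c1", "c2"))
  expect_identical(gt[["OG2"]][["A1"]], "c3")
  # non-focal cells are copied verbatim
  expect_identical(gt[["OG1"]][["REF"]], c("r1", "r2"))
  expect_identical(nrow(attr(gt, "multi_orthogroup_clusters")), 0L)

  # one protein per cluster: isomorphic to the input under renaming
  map1 <- gene_cluster_map(c("p1", "p2", "p3", "p4"), "A1",
                           paste0("g_", c("p1", "p2", "p3", "p4")))
  gt1 <- collapse_to_gene_table(tab, map1, cfg)
  expect_identical(gt1[["OG1"]][["A1"]], paste0("g_", c("p1", "p2", "p3")))

  # unmapped focal protein is a consistency error naming the ID
  expect_error(collapse_to_gene_table(tab, gene_cluster_map("p1", "A1", "c1"), cfg),
               "p2")
})

test_that("a cluster spanning orthogroups is retained in each and reported", {
  cfg <- toy_config()
  tab <- orthogroup_table(list(OG1 = list(A1 = "p1"), OG2 = list(A1 = "p2")),
                          cfg$proteomes)
  map <- gene_cluster_map(c("p1", "p2"), "A1", c("cX", "cX"))
  expect_message(gt <- collapse_to_gene_table(tab, map, cfg),
                 "span more than one orthogroup")
  multi <- attr(gt, "multi_orthogroup_clusters")
  expect_identical(multi$cluster, "cX")
  expect_identical(multi$n_orthogroups, 2L)
  # counted once per criterion across both orthogroups
  cc <- census_counts(gt, cfg)
  expect_true(all(cc$n_genes[cc$assembly == "A1"] %in% c(0L, 1L)))
})

test_that("group counts distinguish species and protein counting units", {
  cfg <- toy_config()
  cells <- stats::setNames(rep(list(character(0)), length(cfg$proteomes)),
                           cfg$proteomes)
  for (sp in paste0("OUT", 1:12)) cells[[sp]] <- paste0(sp, c("_x", "_y"))
  counts <- orthogroup_group_counts(cells, cfg, focal_assembly = "A1")
  expect_identical(unname(counts["non-ingroup"]), 12L)
  countsP <- orthogroup_group_counts(cells, toy_config("proteins"),
                                     focal_assembly = "A1")
  expect_identical(unname(countsP["non-ingroup"]), 24L)

  # members only from the focal assembly itself: all groups count zero
  cells0 <- cells
  for (sp in paste0("OUT", 1:12)) cells0[[sp]] <- character(0)
  cells0[["A1"]] <- "c1"
  expect_true(all(orthogroup_group_counts(cells0, cfg, "A1") == 0L))
})

test_that("census counts hand-checked tables", {
  cfg <- toy_config()
  # singleton orthogroup: nothing else present, all five criteria zero
  gt <- orthogroup_table(list(OG1 = list(A1 = "c1")), cfg$proteomes)
  class(gt) <- c("gene_level_table", "orthogroup_table")
  cc <- census_counts(gt, cfg)
  expect_true(all(cc$n_genes == 0L))

  # two conspecific assemblies see each other under conspecific-others >= 1
  gt2 <- orthogroup_table(list(OG1 = list(A1 = "c1", A2 = "g2")), cfg$proteomes)
  class(gt2) <- c("gene_level_table", "orthogroup_table")
  cc2 <- census_counts(gt2, cfg)
  get <- function(df, a, lab) df$n_genes[df$assembly == a & df$label == lab]
  expect_identical(get(cc2, "A1", "conspecific_others_ge1"), 1L)
  expect_identical(get(cc2, "A2", "conspecific_others_ge1"), 1L)
  expect_true(all(cc2$n_genes[grepl("non_", cc2$label)] == 0L))
})

test_that("census equals the brute-force recount on random tables", {
  set.seed(202)
  for (i in 1:40) {
    sc <- random_scenario_table()
    expect_true(compare_census(census_counts(sc$table, sc$config),
                               brute_census(sc$table, sc$config)))
  }
})

test_that("criterion nesting is monotone on random tables", {
  set.seed(303)
  for (i in 1:30) {
    sc <- random_scenario_table()
    cc <- census_counts(sc$table, sc$config)
    for (a in unique(cc$assembly)) {
      g <- function(lab) cc$n_genes[cc$assembly == a & cc$label == lab]
      expect_lte(g("non_ingroup_ge10"), g("non_ingroup_ge1"))
      expect_lte(g("non_ingroup_ge1"), g("non_conspecific_ge1"))
      expect_lte(g("non_ingroup_ge10"), g("non_conspecific_ge10"))
    }
  }
})

test_that("collapsing clusters onto themselves is idempotent for the census", {
  set.seed(404)
  sc <- random_scenario_table()
  clusters <- unique(unlist(lapply(sc$table, function(cells)
    unlist(cells[sc$config$focal_assemblies], use.names = FALSE))))
  if (length(clusters)) {
    idmap <- gene_cluster_map(clusters, "X", clusters)
    reread <- orthogroup_table(lapply(sc$table, identity), proteomes(sc$table))
    gt2 <- suppressMessages(collapse_to_gene_table(reread, idmap, sc$config))
    expect_true(compare_census(census_counts(gt2, sc$config),
                               census_counts(sc$table, sc$config)))
  }
})

test_that("novel-gene extraction applies all four filters", {
  cfg <- toy_config()
  outs <- function(n) stats::setNames(lapply(paste0("OUT", seq_len(n)),
                                             function(s) paste0(s, "_p")),
                                      paste0("OUT", seq_len(n)))
  # qualifying: all focal assemblies, no REF, 12 outgroups incl. required
  og_novel <- c(list(A1 = "c1", A2 = "g1"), outs(12))
  # excluded: has a reference member
  og_ref <- c(list(A1 = "c2", A2 = "g2", REF = "r1"), outs(12))
  # excluded: required species absent
  og_noreq <- c(list(A1 = "c3", A2 = "g3"), outs(12)[-1])
  # excluded: too few outgroup species
  og_few <- c(list(A1 = "c4", A2 = "g4"), outs(9))
  gt <- orthogroup_table(list(OG1 = og_novel, OG2 = og_ref,
                              OG3 = og_noreq, OG4 = og_few),
                         cfg$proteomes)
  class(gt) <- c("gene_level_table", "orthogroup_table")
  attr(gt, "focal") <- cfg$focal_assemblies
  nv <- extract_novel(gt, cfg, min_outgroup = 10)
  expect_identical(nv$orthogroup, "OG1")
  expect_identical(nv$A1, "c1")
  expect_identical(nv$n_outgroup, 12L)

  # every orthogroup containing a reference member -> empty report
  allref <- lapply(gt, function(cells) { cells$REF <- "r"; cells })
  gt2 <- orthogroup_table(allref, cfg$proteomes)
  class(gt2) <- c("gene_level_table", "orthogroup_table")
  expect_identical(nrow(extract_novel(gt2, cfg)), 0L)

  # no reference proteome configured -> the filter is undefined
  cfg2 <- species_group_config(cfg$proteomes, c("A1", "A2", "REF"),
                               c("A1", "A2", "REF"), cfg$ingroup, "OUT1")
  expect_error(extract_novel(gt, cfg2), "reference proteome")
})

test_that("novel clusters are a subset of the non-ingroup >= 10 census", {
  set.seed(505)
  for (i in 1:20) {
    sc <- random_scenario_table()
    nv <- extract_novel(sc$table, sc$config, min_outgroup = 10)
    cc <- census_counts(sc$table, sc$config,
                        data.frame(group = "non-ingroup", min_members = 10L))
    for (a in sc$config$focal_assemblies) {
      novel_clusters <- unique(unlist(strsplit(nv[[a]], ",", fixed = TRUE)))
      expect_lte(length(novel_clusters), cc$n_genes[cc$assembly == a])
      # and each novel cluster is itself census-qualified
      qual <- unique(unlist(lapply(sc$table, function(cells) {
        gc <- orthogroup_group_counts(cells, sc$config, a)
        if (gc[["non-ingroup"]] >= 10L) cells[[a]] else character(0)
      })))
      expect_true(all(novel_clusters %in% qual))
    }
  }
})
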