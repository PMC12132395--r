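test_that("orthogroup TSV parsing preserves order and handles empty cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tA\tB", "OG1\tp1, p2\t"), f)
  tab <- read_orthogroup_table(f)
  expect_identical(proteomes(tab), c("A", "B"))
  expect_identical(tab[["OG1"]][["A"]], c("p1", "p2"))
  expect_identical(tab[["OG1"]][["B"]], character(0))

  # header-only file: proteomes but no orthogroups
  writeLines("Orthogroup\tA\tB", f)
  empty <- read_orthogroup_table(f)
  expect_length(empty, 0L)
  expect_identical(proteomes(empty), c("A", "B"))

  # bare commas tolerated on read
  writeLines(c("Orthogroup\tA", "OG1\tx,y,z"), f)
  expect_identical(read_orthogroup_table(f)[["OG1"]][["A"]], c("x", "y", "z"))
})

test_that("orthogroup TSV format errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tA\tB", "OG1\tp1"), f)
  expect_error(read_orthogroup_table(f), "line 2")
  writeLines(c("Orthogroup\tA", "OG1\tp1", "OG1\tp2"), f)
  expect_error(read_orthogroup_table(f), "duplicate orthogroup ID")
  expect_error(orthogroup_table(list(OG1 = list(A = c("p1", "p1"))), "A"),
               "duplicated protein ID")
})

test_that("orthogroup tables round-trip byte-identically", {
  set.seed(11)
  for (rep in 1:10) {
    prot <- paste0("P", seq_len(sample(2:6, 1)))
    ogs <- lapply(stats::setNames(seq_len(sample(1:15, 1)), NULL), function(i) {
      cells <- lapply(stats::setNames(prot, prot), function(p)
        if (runif(1) < 0.5) paste0(p, "_", sample(100, sample(0:4, 1))) else character(0))
      cells
    })
    names(ogs) <- sprintf("OG%04d", seq_along(ogs))
    tab <- orthogroup_table(ogs, prot)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_orthogroup_table(tab, f1)
    back <- read_orthogroup_table(f1)
    # within-cell protein order is exactly the generated order
    expect_identical(unclass(back)[], unclass(tab)[])
    write_orthogroup_table(back, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  # a single-protein cell carries no separator characters
  f <- withr::local_tempfile()
  write_orthogroup_table(orthogroup_table(list(OG1 = list(A = "p9")), "A"), f)
  expect_false(grepl(",", readLines(f)[2], fixed = TRUE))
})

test_that("FASTA records parse into id / description / sequence", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 desc here", "MKV", ">p2", "MK", "VA"), f)
  rec <- read_fasta(f)
  expect_identical(rec$protein_id, c("p1", "p2"))
  expect_identical(rec$description, c("desc here", ""))
  expect_identical(rec$sequence, c("MKV", "MKVA"))

  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_identical(nrow(read_fasta(f2)), 0L)

  writeLines(c("MKV", ">p1"), f)
  expect_error(read_fasta(f), "sequence line before any header")

  # write/read round-trip
  write_fasta(rec, f)
  expect_identical(read_fasta(f), rec)
})

test_that("GFF3 read/write round-trips coordinates, attribute order and escaping", {
  feat <- gff3_features(
    seqid = "chr1", source = "test", type = c("mRNA", "exon"),
    start = c(10L, 10L), end = c(99L, 50L), strand = "+",
    attributes = list(c(ID = "t1", cluster = "c1", note = "a;b=c,d %50"),
                      c(ID = "t1.e1", Parent = "t1")))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feat, f)
  expect_identical(readLines(f)[1], "##gff-version 3")
  back <- read_gff3(f)
  expect_identical(back$start, feat$start)
  expect_identical(back$end, feat$end)
  expect_identical(back$attributes, feat$attributes)
  expect_identical(names(back$attributes[[1]]), c("ID", "cluster", "note"))

  # zero features: header line only
  write_gff3(feat[0, ], f)
  expect_identical(readLines(f), "##gff-version 3")
  expect_identical(nrow(read_gff3(f)), 0L)
})

test_that("GFF3 format errors are raised for bad coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\ts\tmRNA\t50\t10\t.\t+\t.\tID=x"), f)
  expect_error(read_gff3(f), "end < start")
  writeLines(c("chr1\ts\tmRNA\tten\t20\t.\t+\t.\tID=x"), f)
  expect_error(read_gff3(f), "non-integer")
  expect_error(gff3_features("c", type = "mRNA", start = 5, end = 3),
               "end < start")
  # a feature of length 1 has start == end
  expect_silent(gff3_features("c", type = "mRNA", start = 3, end = 3))
})

test_that("cluster maps are total and reject double mappings", {
  map <- gene_cluster_map(c("p1", "p2", "p3"), "A1", c("c1", "c1", "c2"))
  expect_identical(unname(lookup_cluster(map, c("p3", "p1"))), c("c2", "c1"))
  expect_error(lookup_cluster(map, "p4"), "unmapped protein")
  expect_error(gene_cluster_map(c("p1", "p1"), "A1", c("c1", "c2")),
               "mapped more than once")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_map(map, f)
  expect_identical(read_cluster_map(f), map)
})

test_that("group configuration enforces nesting and required-species placement", {
  cfg <- species_group_config(c("A1", "R", "M", "D"), "A1", c("A1", "R"),
                              c("A1", "R", "M"), "D")
  expect_identical(reference_proteomes(cfg), "R")
  expect_identical(cfg$counting_unit, "species")
  expect_error(
    species_group_config(c("A1", "R", "D"), "A1", "R", c("A1", "R"), "D"),
    "A1")
  expect_error(
    species_group_config(c("A1", "R", "M", "D"), "A1", c("A1", "R"),
                         c("A1", "R", "M"), "M"),
    "outside the ingroup")

  f <- withr::local_tempfile(fileext = ".cfg")
  write_group_config(cfg, f)
  expect_identical(load_group_config(f), cfg)
  writeLines(c("proteomes = A1, R, D", "focal_assemblies = A1",
               "conspecific = R", "ingroup = A1, R",
               "required_species = D"), f)
  expect_error(load_group_config(f), "not nested")
})
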