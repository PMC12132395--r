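# Independent brute-force oracles and random-instance generators.
# These deliberately avoid the package's own set/vector machinery: the ORF
# oracle walks codon by codon, the census oracle loops over
# (assembly, criterion, orthogroup, cluster) with explicit membership tests.

brute_longest_orf <- function(seq, min_aa = 100L, stranded = TRUE,
                              allow_partial = FALSE) {
  seq <- toupper(seq)
  stop_codons <- c("TAA", "TAG", "TGA")
  cands <- list()
  scan <- function(s, strand) {
    n <- nchar(s)
    p <- 1L
    while (p + 2L <= n) {
      if (substr(s, p, p + 2L) == "ATG") {
        q <- p + 3L
        while (q + 2L <= n) {
          if (substr(s, q, q + 2L) %in% stop_codons) {
            cands[[length(cands) + 1L]] <<- list(
              len = (q - p) / 3, nt_start = p, frame = (p - 1L) %% 3L,
              strand = strand, complete = TRUE)
            break
          }
          q <- q + 3L
        }
      }
      p <- p + 1L
    }
    if (allow_partial) {
      for (f in 0:2) {
        q <- f + 1L
        len <- 0L
        while (q + 2L <= n) {
          if (substr(s, q, q + 2L) %in% stop_codons) break
          len <- len + 1L
          q <- q + 3L
        }
        if (len >= 1L)
          cands[[length(cands) + 1L]] <<- list(
            len = len, nt_start = f + 1L, frame = f, strand = strand,
            complete = FALSE)
      }
    }
  }
  scan(seq, "+")
  if (!stranded)
    scan(as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))), "-")
  cands <- Filter(function(cc) cc$len >= min_aa, cands)
  if (!length(cands)) return(NULL)
  best <- cands[[1L]]
  for (cc in cands[-1L]) {
    better <- cc$len > best$len ||
      (cc$len == best$len && cc$nt_start < best$nt_start) ||
      (cc$len == best$len && cc$nt_start == best$nt_start && cc$frame < best$frame) ||
      (cc$len == best$len && cc$nt_start == best$nt_start &&
         cc$frame == best$frame && cc$strand == "+" && best$strand == "-")
    if (better) best <- cc
  }
  best
}

random_dna <- function(len, p_n = 0.01) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Loop-only census recount: no unique(), no set union.
brute_census <- function(gt, config, criteria = census_criteria()) {
  subjects <- c(config$focal_assemblies,
                setdiff(config$conspecific, config$focal_assemblies))
  subjects <- subjects[subjects %in% proteomes(gt)]
  rows <- list()
  for (s in subjects) {
    for (k in seq_len(nrow(criteria))) {
      counted <- character(0)
      for (og in names(gt)) {
        cells <- gt[[og]]
        grp <- switch(criteria$group[[k]],
          "conspecific-others" = setdiff(config$conspecific, s),
          "non-conspecific" = setdiff(config$proteomes, config$conspecific),
          "non-ingroup" = setdiff(config$proteomes, config$ingroup))
        m <- 0L
        for (p in grp) {
          nn <- length(cells[[p]])
          if (config$counting_unit == "species") {
            if (nn > 0L) m <- m + 1L
          } else m <- m + nn
        }
        if (m >= criteria$min_members[[k]]) {
          for (cl in cells[[s]]) {
            already <- FALSE
            for (seen in counted) if (seen == cl) already <- TRUE
            if (!already) counted <- c(counted, cl)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        assembly = s, label = criteria$label[[k]], n_genes = length(counted),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random gene-level table plus a matching group configuration. Cluster IDs
# are drawn from a shared per-assembly pool so some clusters recur across
# orthogroups (exercising the count-once rule).
random_scenario_table <- function() {
  n_focal <- sample(2:3, 1L)
  focal <- paste0("A", seq_len(n_focal))
  ref <- "REF"
  rel <- paste0("ING", seq_len(sample(1:3, 1L)))
  outg <- paste0("OUT", seq_len(sample(11:18, 1L)))
  prot <- c(focal, ref, rel, outg)
  config <- species_group_config(
    prot, focal, c(focal, ref), c(focal, ref, rel),
    required_species = "OUT1",
    counting_unit = sample(c("species", "proteins"), 1L))
  m <- sample(1:50, 1L)
  pool <- lapply(stats::setNames(focal, focal),
                 function(a) paste0(a, "_c", seq_len(max(3L, m %/% 2L))))
  ogs <- list()
  for (i in seq_len(m)) {
    cells <- list()
    for (a in focal)
      if (stats::runif(1) < 0.6)
        cells[[a]] <- sample(pool[[a]], sample(1:3, 1L))
    if (stats::runif(1) < 0.6)
      cells[[ref]] <- paste0("REF_p", i, "_", seq_len(sample(1:3, 1L)))
    for (sp in c(rel, outg))
      if (stats::runif(1) < 0.4)
        cells[[sp]] <- paste0(sp, "_p", i, "_", seq_len(sample(1:2, 1L)))
    ogs[[sprintf("OG%03d", i)]] <- cells
  }
  gt <- orthogroup_table(ogs, prot)
  class(gt) <- c("gene_level_table", "orthogroup_table")
  attr(gt, "focal") <- focal
  list(table = gt, config = config)
}

compare_census <- function(a, b) {
  key <- function(df) {
    df <- as.data.frame(df)[, c("assembly", "label", "n_genes")]
    df <- df[order(df$assembly, df$label), ]
    rownames(df) <- NULL
    class(df) <- "data.frame"
    df
  }
  identical(key(a), key(b))
}
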