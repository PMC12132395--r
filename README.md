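# orthocensus

Comparative gene censusing and annotation transfer for species with
several genome assemblies.

## The problem

Species with heavy recent gene duplication — pea aphids are the motivating
case — are poorly served by a single annotation of a single assembly:
short-read assemblies merge duplicated loci into one, reference
annotations miss genes, and pseudogenes carry different intact ORFs in
different assemblies, disrupting ortholog clustering unpredictably. Raw
transcript-cluster counts from RNA-seq-based annotation are inflated by
pseudogenes and contamination and are not gene-number estimates.

`orthocensus` implements the comparative remedy. Given an
OrthoFinder-style orthogroup table over the proteomes of several focal
assemblies, a same-species reference annotation, and a panel of other
species, it:

* **collapses** protein-level orthogroup membership to gene-cluster
  (locus) level through a protein→cluster map (`collapse_to_gene_table()`);
* **censuses** each assembly's gene clusters by the evolutionary breadth
  of their orthogroups (`census_counts()`): for censused proteome *s* and
  criterion *(G, k)*, the count is
  `C_s(G,k) = |⋃ { M(o,s) : n_G(o;s) ≥ k }|` — the distinct clusters of
  *s* in orthogroups with at least *k* members from group *G*, where *G*
  ranges over conspecific-others / non-conspecific / non-ingroup and *k*
  over {1, 10};
* **extracts novel genes** (`extract_novel()`): orthogroups with clusters
  in every focal assembly, no reference member, ≥10 outgroup members, and
  a required anchor species (e.g. *Drosophila melanogaster*);
* **transfers annotations** (`build_annotation_map()`,
  `transfer_annotations()`): appends the first-listed ortholog's FASTA
  header per species, or `"none"`, as `<species>_ortholog` attributes on
  GFF3 transcript features, losslessly;
* **classifies coding transcripts** (`find_longest_orf()`,
  `classify_coding()`): longest ATG-initiated, stop-terminated ORF in
  stranded mode under the universal code, minimum 100 aa;
* **simulates** multi-assembly gene-family datasets with planted
  duplication, missing-annotation, paralog-collapse and pseudogene events
  (`generate_scenario()`), plus truth-side oracles (`expected_census()`,
  `expected_novel()`, `perturb_clustering()`) for exact end-to-end
  validation.

## Worked example

```r
library(orthocensus)

params <- scenario_params(n_families = 120, p_pseudogene = 0.3, seed = 42)
sc  <- generate_scenario(params, file.path(tempdir(), "demo"))

tab <- read_orthogroup_table(sc$files$orthogroups)
map <- read_cluster_map(sc$files$cluster_map)
cfg <- load_group_config(sc$files$groups)
gt  <- collapse_to_gene_table(tab, map, cfg)

census_counts(gt, cfg)
#>    assembly              group min_members                  label n_genes
#> 1      asm1 conspecific-others           1 conspecific_others_ge1     122
#> 2      asm1    non-conspecific           1    non_conspecific_ge1     122
#> 3      asm1        non-ingroup           1        non_ingroup_ge1     122
#> 4      asm1    non-conspecific          10   non_conspecific_ge10     122
#> 5      asm1        non-ingroup          10       non_ingroup_ge10     122
#> ...
#> 16   refseq conspecific-others           1 conspecific_others_ge1     122
#> 17   refseq    non-conspecific           1    non_conspecific_ge1     124
```

Assembly `asm1` counts 122 gene clusters with conspecific support: the 120
families plus extra paralogous loci from planted duplications, minus
pseudogene copies whose intact ORF fell below 100 aa in that assembly.
The reference proteome reaches 124 under the outgroup criteria (its cells
are never pseudogene-fragmented in this scenario) but only 122 with
conspecific-other support.

```r
nrow(extract_novel(gt, cfg))
#> [1] 9
```

Nine orthogroups have clusters in all three assemblies, ≥10 outgroup
species including the anchor species, and no reference member — the
planted missing-from-reference families, recovered exactly.

```r
tx <- read_fasta(sc$files$transcripts_asm1)
summarize_method(tx, classify_coding(tx), tab, "asm1", method_id = "asm1")
#>   method_id n_transcripts n_coding n_coding_in_orthogroups n_unassigned_proteins
#> 1      asm1           234      215                     215                     0
```

Of 234 transcript isoforms, 215 carry an ORF of ≥100 aa; all of their
proteins are in orthogroups here, so none are unassigned.

The methods vignette (`vignettes/gene-censusing.Rmd`) describes the census
model, the ORF scan's tie-breaking and `N` handling, the generator's event
model, and its limitations.

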