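---
title: "Orthogroup-based gene censusing across genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogroup-based gene censusing across genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocensus)
```

## The problem

When a species has several genome assemblies — say two long-read assemblies
and an older short-read reference — their independent annotations disagree
for exactly the genes that matter most to gene-family evolution: recent
duplicates (mis-assembled into a single locus in short-read assemblies),
genes missing from the reference annotation, and pseudogenes whose
premature stop codons fragment the ancestral reading frame differently in
each assembly. Raw transcript-cluster counts are inflated by pseudogenes
and contamination, so a raw count is not a gene-number estimate.

The remedy implemented here is a *comparative census*: cluster predicted
proteins from all assemblies plus many reference species into orthogroups,
collapse each assembly's proteins to gene clusters (loci), and count, per
assembly, the clusters whose orthogroup has independent support — members
from other conspecific annotations, from other species, or from at least
ten distant species. Stricter criteria give more conservative estimates;
comparing criteria separates lineage-specific annotation from deeply
conserved genes.

## The census model

Let an orthogroup table assign to each orthogroup $o$ and proteome $p$ a
list of members $M_{o,p}$. For a focal assembly, members are first
collapsed through a protein-to-cluster map so that $M_{o,a}$ holds distinct
gene clusters (`collapse_to_gene_table()`). Proteomes are partitioned by a
user-declared configuration into nested groups
$\mathrm{focal} \subseteq \mathrm{conspecific} \subseteq \mathrm{ingroup}
\subseteq \mathrm{all}$.

For a censused proteome $s$ and a criterion $(G, k)$, define the group
count $n_G(o; s)$ as the number of distinct proteomes of group $G$ with at
least one member in $o$ (or the total member count, under
`counting_unit = "proteins"`), where $G$ is one of *conspecific-others*
(conspecific $\setminus \{s\}$), *non-conspecific*, or *non-ingroup*. The
census statistic is

$$ C_s(G, k) \;=\; \Bigl|\, \bigcup_{o\,:\, n_G(o;s) \ge k} M_{o,s} \Bigr| $$

i.e. the number of distinct gene clusters of $s$ appearing in at least one
qualifying orthogroup; a cluster in several qualifying orthogroups counts
once. The five standard criteria (`census_criteria()`) are
(conspecific-others, ≥1), (non-conspecific, ≥1), (non-ingroup, ≥1),
(non-conspecific, ≥10), (non-ingroup, ≥10). Counts are non-strictly
monotone along criterion nesting, and the package tests enforce this on
every random and synthetic input.

Two design points were genuinely open:

* **Censused proteomes.** The census runs over the focal assemblies *and*
  the conspecific reference proteome(s); for a reference, the gene units
  are its protein entries. This lets the reference annotation be compared
  on the same axes as the new annotations.
* **Counting unit.** Whether "≥10 members" counts species or proteins is
  ambiguous in common usage; the default is distinct species (the reading
  "orthologs in at least ten non-aphid species"), with
  `counting_unit = "proteins"` as a switch. The "at least one other
  conspecific member" criterion is evaluated against conspecific sources
  *other than* the censused assembly, since the assembly's own cluster is
  trivially a member.

### Novel-gene extraction

`extract_novel()` returns orthogroups with (i) at least one cluster in
*every* focal assembly, (ii) no member in any reference proteome, (iii) at
least `min_outgroup` (default 10) non-ingroup members, and (iv) at least
one member from a configured required anchor species. These are candidate
deeply conserved genes absent from the reference annotation. The filter is
undefined without a reference proteome and errors in that case. Every
reported cluster necessarily also satisfies the (non-ingroup, ≥10) census
criterion — a subset relation the tests check.

### Annotation transfer

`build_annotation_map()` records, per (orthogroup, species), the
`"protein_id description"` of the *first* protein listed for that species
in the table (file order — order preservation is therefore part of the
table parser's contract), or the literal `"none"` when absent.
`transfer_annotations()` appends one `<species>_ortholog` attribute per
configured species to every transcript-level GFF3 feature, leaving
coordinates, feature order and pre-existing attributes byte-identical;
reserved characters are percent-encoded only at write time, so a
write/read cycle restores values verbatim. Child features (exons, CDS) are
not annotated.

## Coding classification

`find_longest_orf()` emulates a longest-ORF transcript scan: ATG-initiated,
stop-terminated reading frames on the sense strand (all six frames with
`stranded = FALSE`), universal nuclear code, minimum protein length 100
amino acids by default. Numerical/tie-break choices:

* Equal-length ORFs resolve by smaller start coordinate, then lower frame
  index, then plus strand — determinism rather than biology; any fixed
  order would do.
* Codons containing `N` translate to `X` and never terminate an ORF
  (permissive, matching common practice); characters outside `ACGTN` are
  an input error.
* 5′-partial ORFs (a frame-initial stop-free prefix, no ATG required)
  compete only behind `allow_5prime_partial = TRUE`, default off; their
  reported interval excludes any stop codon, so
  `length(protein) = (nt_end - nt_start + 1)/3` holds for partials and
  `... - 1` for complete ORFs.
* Degenerate inputs: sequences shorter than one codon, or with no ATG,
  yield `NULL`, not an error; the empty transcript set yields an empty
  call table.

`summarize_method()` reports, per annotation method, total transcripts,
coding transcripts, coding transcripts whose protein is in ≥1 orthogroup,
and unassigned coding transcripts. Counts are per transcript (one
predicted protein each); `assigned + unassigned = coding` is an enforced
identity.

## What the synthetic generator emulates

`generate_scenario()` plants gene families across focal assemblies, a
same-species reference proteome, ingroup relatives and outgroup species,
and emits the complete file set (orthogroup TSV, per-proteome FASTA,
per-assembly transcript FASTA and GFF3, cluster map, group config) plus a
truth object. Events per family, with scenario defaults:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 500 | families; one orthogroup each |
| `n_focal_assemblies` | 3 | newly annotated assemblies |
| `n_ingroup_species` / `n_outgroup_species` | 5 / 15 | relatives / distant species |
| `p_focal_duplication` | 0.2 | two paralogous loci in every focal assembly |
| `p_missing_in_reference` | 0.05 | empty reference cell |
| `p_collapse_in_reference` | 0.5 | duplicated paralogs merged to one reference locus |
| `p_pseudogene` | 0.05 | assembly-specific premature stops in the youngest copy |
| `p_species_presence` | 1 | per-species family presence (relatives/outgroups) |
| `orf_length_aa` | 200 | mean intact coding length (aa) |

The defaults define the package's reference study conditions: three
assemblies of a duplication-rich insect genome compared against one
reference annotation, five close relatives and fifteen distant species.
Rates for duplication, reference collapse and pseudogenisation have no
published point estimates; the defaults are fixed illustrative values
chosen once to make every event type common enough to exercise.

Construction details that make expectations *exact* rather than
approximate:

* Coding sequences are `ATG` + adenine-free random codons + `TAA`, with
  5′/3′ UTRs over `{C,T}`. Since every stop codon and every `ATG` contains
  an adenine, no complete ORF can arise outside the planted ones, in any
  frame; the planted ORF is provably the unique longest complete ORF. The
  coding scan therefore recovers planted lengths by integer equality.
* A pseudogene copy is one premature stop splitting the ancestral frame
  into two ORFs; the longest-piece length is drawn in 50–149 aa,
  *distinct per assembly*, so it straddles the 100-aa coding threshold
  differently across assemblies — the mechanism by which a pseudogene
  disrupts clustering in some assemblies but not others. The reference
  proteome keeps a clusterable protein for pseudogene families (only the
  missing-in-reference event empties the reference cell), so the
  novel-gene filter identifies exactly the planted missing families.
* Duplicated families place both paralogs in every focal assembly; the
  collapse event gives the reference a single entry instead of two. Per
  collapsed family the reference census contribution is exactly 1 while
  each focal assembly contributes the paralog count — the mechanism that
  drives focal and reference gene-count estimates apart.
* Clusters carry 1–3 isoform transcripts (identical CDS, varying UTRs), so
  protein-to-cluster collapse does real work.

`expected_census()` and `expected_novel()` recompute every expectation
directly from event labels, by plain loops, without touching the emitted
files or the census machinery — an independent truth-side oracle.
`perturb_clustering()` additionally emulates clustering disruption by
moving the most divergent assembly's members of a pseudogene family into a
new singleton orthogroup.

What the generator does **not** emulate: sequence similarity and real
orthology inference (the emitted table is ground truth, perturbed only by
`perturb_clustering()`); substitution processes or phylogenetic structure;
splice isoform structure beyond UTR length variation; read-level noise,
assembly errors, or contamination. Passing tests therefore show the
*bookkeeping* — collapse, censusing, filtering, transfer, ORF scanning — is
exact under known family structure; they do not validate orthology
clustering itself, which the analysis treats as an upstream oracle.

## A worked example

```{r example, message = FALSE}
params <- scenario_params(n_families = 120, p_pseudogene = 0.3, seed = 42)
sc <- generate_scenario(params, file.path(tempdir(), "demo"))

tab <- read_orthogroup_table(sc$files$orthogroups)
map <- read_cluster_map(sc$files$cluster_map)
cfg <- load_group_config(sc$files$groups)
gt  <- collapse_to_gene_table(tab, map, cfg)

census_counts(gt, cfg)[1:5, ]
nrow(extract_novel(gt, cfg))
all.equal(census_counts(gt, cfg)$n_genes,
          expected_census(sc$truth)$n_genes)
```

## Problem sizes and limitations

The validation suite works at 200 random tables (≤50 orthogroups, ≤25
proteomes) for census/brute-force equivalence, 1,000 random sequences
(≤2,000 nt) for ORF/oracle equivalence, and the 500-family reference
scenario for end-to-end parameter recovery — sizes at which exact
(integer) recovery is the pass condition, chosen as the package's working
scale for its study design.

Known limitations: one ORF is reported per transcript (no multi-ORF
output); no coding-potential scoring beyond ORF length; orthology
clustering, transcript assembly and alignment are out of scope; group
membership is configuration, never taxonomy-derived; gene clusters
spanning several orthogroups (possible after collapse) are counted once
per criterion and reported via the `multi_orthogroup_clusters` attribute
rather than resolved.
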