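# lociview

Comparative visualization of annotated genomic loci — phage and plasmid
genomes, or regions of longer prokaryotic genomes — as publication-quality
vector PDF figures, with the pangenome-style analysis steps needed to make
such figures informative: protein homology grouping, proteome-composition
clustering, and conserved / intermediate / variable gene classification.
A single-genome browser mode stacks the gene map with GC content, GC skew
and sequencing-coverage tracks.

The package is aimed at microbial comparative genomics: anyone who needs to
line up a handful (or dozens) of related phage genomes, see at a glance
which genes are core and which are cargo, and drop the figure straight into
a manuscript.

## What it computes

Given loci parsed from GenBank or *extended GFF* files (GFF3 with the
nucleotide sequence appended after `##FASTA`, as written by prokka and
pharokka):

1. **Homology groups.** Every protein is assigned to a group by a greedy
   clusterer: proteins are visited by decreasing length and join the first
   group whose representative aligns globally with identity ≥ 0.35 (exact
   matches over alignment columns) and bidirectional coverage ≥ 0.7.
   Predefined group tables and an external-clusterer adapter (e.g. MMseqs2)
   are drop-in alternatives.
2. **Proteome similarity.** For loci *i*, *j* with group sets *G<sub>i</sub>*,
   *G<sub>j</sub>*:

   *S(i,j) = ½ (|G<sub>i</sub>∩G<sub>j</sub>|/|G<sub>i</sub>| +
   |G<sub>i</sub>∩G<sub>j</sub>|/|G<sub>j</sub>|)*,  *D = 1 − S*.

   The symmetric mean (rather than Jaccard) keeps a deletion variant close
   to its parent genome; `similarity = "jaccard"` is available.
3. **Order and clusters.** UPGMA (average linkage) on *D* fixes the row
   order; flat sequence clusters are cut at cophenetic distance 0.75.
4. **Gene classes.** Within each cluster, a group present in fraction *f*
   of the member loci is *conserved* (f ≥ 0.75), *variable* (f ≤ 0.25) or
   *intermediate* — the core / cloud / shell of pangenomics.
5. **Figure.** One row per locus against a single bp scale: strand-aware
   gene arrows, grey homology ribbons between adjacent rows, automatic
   non-overlapping label placement (labels of conserved groups appear only
   at their first occurrence; hypothetical proteins are unlabelled), PHROG
   functional-category strips, per-row axes or a compact global scale bar —
   rendered to a deterministic single-page vector PDF.

## Worked example

The built-in fixture generator writes a fully annotated phage-like locus
set with known core/cargo structure, so the example is self-contained:

```r
library(lociview)

set <- make_locus_set("fixture", n_loci = 4, n_core = 8,
                      n_cargo_pool = 10, cargo_per_locus = 2, seed = 42,
                      with_categories = TRUE, hypothetical_fraction = 0.25)
res <- run_comparative("fixture/loci.gbk", "out")
#> [lociview] parsed 4 loci, 40 protein-coding features
#> [lociview] clustered 40 proteins into 14 groups
#> [lociview] 1 sequence clusters; row order L01, L02, L03, L04
#> [lociview] layout: 4 rows, 25 connectors, 0 dropped labels
#> [lociview] wrote out/lociview.pdf

round(res$proteome$S, 3)
#>     L01 L02 L03 L04
#> L01 1.0 0.8 0.8 0.8
#> L02 0.8 1.0 0.9 0.9
#> L03 0.8 0.9 1.0 0.8
#> L04 0.8 0.9 0.8 1.0

head(res$classes)
#>   cluster group_id presence_fraction     class
#> 1      C1    G0001              1.00 conserved
#> 2      C1    G0002              0.25  variable
#> 3      C1    G0003              1.00 conserved
#> 4      C1    G0004              1.00 conserved
#> 5      C1    G0005              0.25  variable
#> 6      C1    G0006              1.00 conserved
```

The four loci share their 8 core families (presence fraction 1 →
conserved, drawn grey) while each carries 2 cargo genes from a pool of 10;
cargo landing in a single locus has presence fraction 0.25 → variable, and
each variable group gets its own colour in the figure. `out/` also holds
the similarity matrix TSV, the Newick dendrogram, the group-class table and
the feature/locus annotation tables — re-feeding those tables (with
`no_cluster = TRUE`) reproduces the identical PDF, and editing them is the
supported way to override any automatic decision.

Browser mode for a single genome with a coverage track:

```r
make_signal("cov.bedgraph", "L01", set$loci[["L01"]]$length_bp,
            peaks = list(c(2000, 300, 25)), noise_sd = 2, seed = 1)
run_browser("fixture/L01.gff", "browser.pdf", bedgraphs = "cov.bedgraph")
```

A thin command-line wrapper with the same two modes is installed at
`inst/scripts/lociview`:

```sh
Rscript inst/scripts/lociview comparative --gb fixture/loci.gbk --out out --compact
Rscript inst/scripts/lociview browser --gff fixture/L01.gff --out browser.pdf \
        --bedgraph cov.bedgraph --window 1:20000
```

## Documentation

The methods vignette (`vignettes/locus-visualization.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic fixtures do and do not emulate, and the
package's numerical and design choices.
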