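# genovis

Server-side infrastructure for genomic visual analysis: the data
machinery that genome-browser-style applications (linear track views,
Circos-style genome-wide views, tool parameter-sweep explorers,
phylogenetic tree viewers, scatter plots) need behind their rendering
layer. The package is aimed at developers of such applications and at
analysts who want browser-grade region queries, coverage summaries,
filtering, layout and region-restricted tool execution as composable R
functions or a small CLI — without a web stack.

What it provides:

- **Format I/O** — BED 3–12, GFF3, GTF, a configurable tab-separated
  interval dialect, minimal text SAM, Wiggle (`fixedStep`/
  `variableStep`), BedGraph, site-level VCF and delimited tables, all
  normalized to 0-based half-open coordinates at parse time (display
  strings stay 1-based inclusive: `chr17:7569899-7591385`).
- **Indexing** — binned interval indices with multi-bin registration,
  persisted as JSON sidecars with checksum-based staleness detection,
  exactly equivalent to a linear scan.
- **Data providers** — the multi-resolution contract at the heart of a
  scalable browser: a region query returns individual records when at
  most `max_detail` (default 5000) overlap, and per-bin coverage
  otherwise, with `total_in_region` always exact. Coverage counts a
  record in every bin it overlaps; signal summaries (`mean`, `max`,
  `min`) are base-weighted. Plus genome-wide per-chromosome summaries,
  aligned multi-track ("rainbow") matrices, dynamic attribute filters,
  column statistics for tabular data, and a transparent LRU payload
  cache with sub-region reuse.
- **Layout + SVG** — greedy first-fit feature packing (provably minimal
  row counts), proportional circular chromosome layouts with chords for
  interaction data, and deterministic static SVG rendering (one path
  per track per chromosome for summary data).
- **Sweeps** — tool command templates with evenly-sampled numeric and
  categorical parameters arranged in a parameter-space tree; selecting
  a node runs one job per leaf under it on a cached region subset and
  slices outputs per region; bundled toy tools make the engine testable
  anywhere.
- **Phylogenetics** — Newick/PhyloXML/Nexus parsing, lossless Newick
  writing, dendrogram layout with collapse support, search by name,
  annotation or root distance, and local edits; comfortable at the
  ~10,000-node scale.
- **Fixtures** — seeded, stream-independent synthetic genomes,
  features, signal and trees, so everything above is testable offline.

## Worked example

```r
library(genovis)

genome <- generate_genome(42, n_chrom = 2,
                          path = file.path(tempdir(), "toy.chrom.sizes"))
genome
#> <gv_genome 'synthetic': 2 chromosomes, 279,115 bases>

bed <- file.path(tempdir(), "toy.bed")
generate_features(42, genome, n = 800, path = bed)
ds  <- open_dataset(bed, "bed")
idx <- index_dataset(ds)

view <- parse_region_string("chr1:20001-60000", genome)
get_data(ds, idx, view)
#> <gv_payload detail: 120 in region>
```

120 features overlap the 40 kb window — under the 5000-record detail
budget, so the payload carries the individual records. The same window
as 8 coverage bins, then filtered to high-scoring features:

```r
get_summary(ds, idx, view, nbins = 8, stat = "count")$values
#> [1] 21 15 20 17 18 14 15 18

flt <- apply_filters(get_data(ds, idx, view),
                     list(filter_spec("score", 800, 1000)))
flt
#> <gv_payload detail: 24 in region>
head(flt$records[, c("chrom", "start", "end", "name", "score", "strand")], 3)
#>     chrom start   end  name score strand
#> 464  chr1 20861 22197 f0464 985.0      +
#> 24   chr1 21594 22142 f0024 934.7      +
#> 290  chr1 22238 23070 f0290 800.4      -
```

Each bin holds the number of features overlapping it (a feature spanning
a bin boundary counts in both bins), and the filter keeps the 24 records
with score in [800, 1000]. Zooming out triggers the detail→summary
switch once the count exceeds the detail budget:

```r
wide <- navigate(view, "zoom", 4, genome)
format_region_string(wide)
#> [1] "chr1:1-120000"
get_data(ds, idx, wide, max_detail = 100, nbins = 8)
#> <gv_payload summary: 355 in region; 355 records exceed max_detail = 100; showing 8-bin coverage>
```

The same pipeline is available from the shell (`inst/cli/genovis`):

```sh
genovis fixtures --seed 42 --out-dir demo
genovis query --format bed demo/features.bed chr1:1-30000        # payload JSON
genovis render --mode circular --genome demo/genome.chrom.sizes \
        --format bed demo/features.bed --out genome.svg
```

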