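---
title: "genovis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genovis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genovis)
```

`genovis` re-creates, as a self-contained R library plus command-line
tool, the server-side machinery that genome-visualization applications
need: format readers that normalize everything to one coordinate
convention, interval indices, multi-resolution data providers, layout
engines for linear and circular views, a tool parameter-sweep engine,
and a phylogenetic-tree component. This vignette explains the models and
conventions the package commits to, the parameters that matter, and the
choices made where the design was genuinely open.

## Coordinates

All internal coordinates are 0-based half-open `[start, end)`. Display
strings (`chr17:7569899-7591385`) are 1-based inclusive, the convention
genome browsers print, and `parse_region_string()` /
`format_region_string()` convert between the two. The half-open internal
convention matches BED natively, so BED passes through untouched, and
every other format is converted exactly once at parse time: GFF3/GTF and
VCF subtract one from their 1-based starts, Wiggle declarations subtract
one from `start=` and emit one point of length `span` per value. A
consequence worth internalizing: two records abut, and do *not* overlap,
when one's `end` equals the other's `start`.

Navigation (`navigate()`) is total: zooming scales the width about the
view center and truncates at chromosome ends; panning shifts by a
fraction of the width and slides back inside the chromosome, preserving
the window width where possible. Clamping rather than erroring mirrors
how a browser viewport behaves. Coordinates are kept integral by
rounding, which means zoom-in/zoom-out pairs invert each other exactly
only when no rounding or clamping occurs; the test suite exercises the
exact case.

## Detail versus summary: the provider contract

A region query cannot always return individual records — a chromosome of
mapped reads is millions of rows — so `get_data()` switches
representation on record count: at most `max_detail` overlapping records
yields detail mode (every record), anything more yields a per-bin count
summary with an explanatory message. The boundary is inclusive: exactly
`max_detail` records still returns detail, so the flip happens at
`max_detail + 1`. Defaults are `max_detail = 5000` and `nbins = 1000`;
both are plain arguments, chosen as round numbers at the scale where a
client-side renderer stops benefiting from individual records. Nothing
in the algorithms depends on their values.

Summary bins divide the region into `nbins` integer-width bins (the last
bin absorbs the remainder; `nbins` is clamped to the region width so a
bin is never narrower than one base). Under `stat = "count"` a record
contributes to *every* bin it overlaps — coverage semantics, not
start-position binning. For signal data, `mean` is base-weighted: each
overlapped base contributes its value once, so the answer is invariant
to how the signal happens to be segmented into intervals. `max`/`min`
take extremes over overlapping segments. Empty bins are 0 under `count`
and `NA` otherwise — an empty bin has no mean, and fabricating a 0 would
be indistinguishable from real signal at zero. Strand is ignored
throughout summarization.

Every provider path is checked against a brute-force linear scan in the
tests: counts and detail records must agree exactly, floating-point
statistics to 1e-9.

## The binned index

The index is a single level of fixed-width bins (default 4096 bases)
with multi-bin registration: a record is listed in each bin its span
overlaps, so a query touches only `ceiling(width / bin_size) + 1` bins
and then filters candidates with the exact overlap test. This is
deliberately simpler than hierarchical binning schemes: at the scale
this package targets it is fast enough, and its behavior is easy to
verify against the linear-scan oracle, which the tests do on thousands
of randomized queries. Bin size is configurable per index.

Indices persist to a JSON sidecar (`<dataset>.gvx`) holding the record
table; bins are rebuilt deterministically on load. The sidecar stores a
source fingerprint — file size plus whole-file MD5 — and loading fails
with a stale-index error if the source has changed. The fingerprint
deliberately excludes modification time so that regenerating a
byte-identical dataset does not invalidate its index.

## Filters

A `filter_spec()` is an inclusive numeric band on one attribute: the BED
score, a SAM read's `mapq`, or any named GFF/GTF attribute. Filters
combine by conjunction and act on detail payloads only (a summary has no
records to hide). Records missing the attribute pass by default
(`missing_passes = TRUE`): a filter is an opt-in restriction, and hiding
a record because it lacks an optional annotation would silently bias the
display. The algebra — conjunction, idempotence, monotonicity under
tightening — is property-tested against a per-record predicate oracle.

## Layout engines

**Packing.** The linear "pack" display assigns features to rows by
greedy first-fit over features sorted by `(start, end, name)`: each
feature takes the lowest row whose previous occupant ends at or before
the feature's start, with `label_pad` bases reserved after each feature
for its label. First-fit by sorted start is optimal on intervals, so the
row count equals the maximum overlap depth; the tests assert exactly
that against an event-sweep oracle. Label padding is expressed in bases
(label length × bases-per-character supplied by the caller) so the
geometry core needs no pixel knowledge. The sort's name tiebreak makes
output deterministic.

**Circular layout.** Chromosomes become arcs of a circle, in genome
order (file order of the chrom.sizes input — never sorted, so layout
order stays user-controllable), clockwise from 12 o'clock, the usual
Circos orientation. With `n` chromosomes and gap `g` radians between
adjacent arcs, chromosome `c` spans `(2π − n·g) · length(c) / Σ lengths`,
so arcs plus gaps tile the circle exactly (asserted to 1e-9).
`position_to_angle()` is affine within a chromosome, hence strictly
monotone. The default gap of 0.01 rad is purely cosmetic, as are the
default annulus radii; all are exposed in the style configuration.
Interaction chords anchor at the angle of each region's midpoint on a
radius below the innermost data annulus, with the curve's control point
at the circle center.

**SVG rendering.** `render_svg()` is a pure function: the same payloads
produce byte-identical documents (coordinates are emitted at fixed
3-decimal precision). Summary data is drawn as a single path per track
per chromosome — one step-outline histogram — rather than one element
per bin, which is what keeps documents small at a thousand bins. Data
values map linearly from `[0, max]` to the annulus radial extent per
track. Rendering is static by design; interactivity belongs to a client,
not to this library.

## Parameter sweeps

A tool is a shell command template (`{input}`, `{output}`,
`{param:name}`) plus parameter declarations. Numeric parameters are
sampled evenly with both endpoints included,
`value_i = min + i·(max−min)/(n−1)`; a single sample yields `[min]`
(the range's low end is the only value the user actually stated);
categorical parameters contribute all their values in declared order.
The in-tree parameters form a tree whose level *d* is the *d*-th
parameter and whose leaves are complete in-tree assignments, so the leaf
count is the product of the per-parameter sample counts. Selecting any
node enumerates the leaves under it — ancestors contribute their fixed
values — so for a two-parameter tree, a depth-1 node yields exactly one
run per value of the second parameter. Out-of-tree parameters ride along
at their fixed value.

Region-restricted execution subsets the dataset first: the records
overlapping any selected region are written, as the original source
lines byte-for-byte with header lines kept, to a cache keyed by (dataset
checksum, canonicalized region set), so repeated sweeps over the same
view reuse the file without rewriting. The sweep runs the tool once per
assignment on the union subset and slices the parsed output per region;
for tools that act record-by-record this is exactly equal to restricting
a full-dataset run, a property the bundled toy tools (identity, a
per-record counter, a score scaler) let the tests verify. A
`per_region = TRUE` flag switches to one invocation per
(assignment, region) for tools where the union would differ. Failing
runs are recorded with their exit code and output and do not abort the
sweep; `run_full()` promotes a chosen assignment to the complete
dataset.

## Phylogenetic trees

The tree component parses Newick (quoted labels, `''` escapes, and the
underscore-for-space convention), a PhyloXML subset (clade nesting,
names, branch lengths; other elements are skipped with a warning naming
them), and Nexus TREES blocks (honoring `translate` tables; other
blocks ignored with a warning). `write_newick()` quotes labels that
need protection and prints branch lengths at 17 significant digits, so
parse→write→parse is an isomorphism, a property tested on hundreds of
random trees and cross-checked against an independent Newick reader.

The rectangular layout places visible leaves on rows 0, 1, 2, … in
traversal order and each internal node at the arithmetic mean of its
children's rows — mean rather than median is the standard dendrogram
choice and keeps the rule exactly testable. Horizontal position is
cumulative root distance, rendering a missing branch length as a unit
length while preserving it as `NULL` in the data: display and data are
separate concerns. Collapsed nodes are treated as leaves when the layout
honors collapse state. Distance search measures cumulative distance from
the root, with missing lengths contributing zero there (no length
means no measured distance, whereas layout needs *some* extent to draw
an edge); name and annotation search are case-insensitive substring
matches, and an empty query errors rather than matching everything.

The recursive-descent parser and recursive layout handle the ~10,000
node trees the design targets comfortably (the acceptance checks parse
and lay out a 9,999-node generated tree in well under five seconds);
extremely deep caterpillar topologies beyond that scale would be limited
by R's recursion depth.

## Synthetic data

The generators exist so every module is testable without downloads.
Each draws from its own random stream derived from `(seed, generator
name)`, so outputs are byte-reproducible and adding one generator to a
pipeline never perturbs another's output. Defaults — a few chromosomes
of 50–200 kb, features of 50–2000 bases with scores in [0, 1000],
piecewise-constant signal segments of 100–5000 bases, trees grown by
random leaf splitting — are sized like a small annotation track rather
than a sequencing run: large enough to exercise binning, overlap and
packing logic, small enough that brute-force oracles stay instant. An
`overlap_factor` of 0 packs features disjointly (for tests that need a
known depth); the default places them freely. What the generators do
*not* emulate: read-error structure, coverage biases, linkage between
tracks, realistic score distributions, or coalescent tree shapes — so a
green suite demonstrates correctness of the data machinery, not
biological fidelity of any downstream interpretation.

## Problem sizes in the checks

The randomized suites use datasets of 100–2000 records (dozens of
datasets, ~100 regions each), 1000 packing instances, and a ~10,000-node
tree; these sizes give the oracles full coverage of the combinatorics
(multi-bin spans, empty bins, cross-chromosome queries, deep overlap
stacks) while keeping each property suite comfortably fast on one core.

## Interface notes and limitations

The command-line surface (`run_cli()`, thin wrapper in `inst/cli/`)
covers fixture generation, conversion, indexing, queries and summaries
(emitting the documented payload JSON), filtering, rendering, sweeps,
tree layout/search and table statistics. Queries against an unindexed
dataset build and persist the sidecar automatically rather than
erroring. An HTTP serve mode would be a natural addition on top of
`get_data()`/`payload_to_json()` but is intentionally not included; the
library surface is the contract.

Known limitations: binary formats (BAM, BigWig/BigBed) are out of scope
— the text SAM reader covers the mapped-read use cases here, and a
binary adapter would slot in behind `open_dataset()`; a linear view is
restricted to one chromosome; summaries are not strand-aware; the
Galaxy-style "Interval" dialect has no fixed column layout, so its
column indices are explicit configuration; and tree rerooting or
radial layouts are not provided.
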