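---
title: "Template-strand analysis with strandtools: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-strand analysis with strandtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

Strand-seq libraries contain only the parental template strands of a
single cell.  Each aligned read is directional: a plus-strand alignment
comes from the Crick template, a minus-strand alignment from the Watson
template.  Because a diploid cell carries two homologues per chromosome,
each inheriting its template independently, a chromosome presents one of
three *template states* with probabilities 1/4 : 1/2 : 1/4 —

* **WW** — both homologues passed a Watson template; all reads map minus;
* **WC** — one of each; reads split evenly between strands;
* **CC** — both Crick; all reads map plus.

Haploid chromosomes (the X in male cells, any monosome) carry a single
template, **W** or **C**, with probability 1/2 each.

Everything in `strandtools` is built on the per-bin normalized ratio

$$ r = \frac{W - C}{W + C} \in [-1, 1], $$

where $W$ and $C$ are the Watson and Crick read counts of a bin (200 kb by
default).  $r = 1$ on WW, $-1$ on CC, $0$ on WC; rounding $r$ to the
nearest of $\{-1, 0, 1\}$ (ties away from zero, so the rule is symmetric
under relabelling W $\leftrightarrow$ C) gives the template call.  A
sister chromatid exchange (SCE) is a changepoint in this track: one
homologue swaps template downstream of the breakpoint, so a homozygous
state becomes heterozygous or vice versa.  Two further signal classes ride
on the same track: a *misoriented reference segment* (sequence stored
reverse-complemented) flips WW to CC at the same position in every
homozygous library, and a copy-number change shifts total depth without
changing direction.

# Stage by stage

## Reads, bins, and the depth filter

`load_reads()` accepts BAM (through Rsamtools) or a six-column strand BED.
Duplicate-flagged reads, secondary alignments and reads under the
mapping-quality floor (default 10; the choice is exposed because no
canonical value exists) are dropped.  Coordinates are 0-based half-open
everywhere internally; a read contributes to bin $\lfloor p / B \rfloor$
by its start position.

`filter_bins()` masks bins whose total count deviates from the mean by
more than `sd_threshold` standard deviations (default 0.2, configurable).
Two deliberate choices:

* **Per-chromosome statistics.**  The mean and SD are computed per
  chromosome, not genome-wide.  A monosomic chromosome sits at half the
  library's average depth by construction; against a genome-wide baseline
  every one of its bins would be "deviant" and the chromosome would be
  unanalyzable.  Against its own baseline the filter does what it is for:
  removing collapsed repeats and dropped regions.
* **Strict comparison.**  A zero-variance track (e.g. perfectly uniform
  simulated coverage) masks nothing.

At the default 0.2 SD the filter is aggressive on Poisson-like coverage
(roughly five of six bins masked); segmentation still works because the
retained bins are spread uniformly, but first-pass changepoint intervals
are reported in true coordinates and therefore widen where masked bins
are spanned.  The read-level refinement below is mask-free, so final SCE
localization does not inherit this coarseness.

## Segmentation

`segment_track()` runs circular binary segmentation (CBS) on the raw
ratios of the unmasked bins: the arc $(i, j]$ maximizing the standardized
mean difference against the rest of the (circularized) segment is tested
by permutation (1000 permutations, $\alpha = 0.01$), and significant splits
recurse.  Three numerical choices matter:

* **Own RNG.**  Permutations use a dedicated xorshift generator seeded
  from the `seed` argument, so segmentation is bit-reproducible and
  independent of R's RNG state and call order.
* **Strict exceedances.**  The p-value counts permutations whose maximal
  statistic *strictly* exceeds the observed one.  On noise-free two-valued
  tracks (every simulation at background 0, and every refinement pass on a
  clean step) any permutation that re-forms a contiguous block ties the
  observed statistic exactly; counting ties would leave a 10-bin clean
  step non-significant at $\alpha = 0.01$.  Ties are measure-zero on noisy
  data, so the test is unaffected where it matters.
* **Three-level post-processing.**  Segment means are rounded to
  $\{-1, 0, 1\}$ and equal-level neighbours merged, enforcing that only
  the three template calls survive; single deviant bins that strict
  counting might split off are absorbed here.

Each changepoint is reported as the two-bin interval spanning the last bin
of one segment and the first bin of the next — 400 kb at the default
200 kb bin size when the flanking bins are adjacent.

## Iterative refinement and the walker

`refine_interval()` shrinks a gross interval by re-binning its reads: each
pass pads the current interval by half its length per side (events at bin
boundaries stay inside the window), re-bins at one fifth of the interval
width on the first pass (80 kb for a 400 kb gross interval) and one fifth
of the previous bin size thereafter, re-segments, and keeps the new
two-bin interval.  It stops when fewer than `min_reads` (default 50) reads
remain in the interval or when re-segmentation does not find exactly one
changepoint; the full per-iteration trace is returned.

`walker_refine()` then walks reads from the homozygous flank: the first
opposite-template read is accepted if its 10 predecessors all carry the
template strand and at least 4 of the 20 reads starting at it (the
candidate counts itself) are opposite — i.e. at least 20% of what follows
already behaves heterozygous.  Rejected candidates (isolated background
reads) are skipped.  The reported interval is the span between the last
template-strand read and the accepted read: at zero background this is
exactly the gap between the two reads straddling the breakpoint.  Near the
breakpoint the rule will accept a background read whose 20-read window
already reaches the heterozygous side, so localization error scales like
a dozen read spacings; at the ~1.2 reads/kb coverage typical of real
libraries that is on the order of 10 kb in the worst case and tens of
base pairs in the median.

`detect_events()` classifies each localized transition by its flanks and
the chromosome's copy number: homozygous–heterozygous is an SCE,
WW–CC is a misorientation candidate, and any switch on a copy-1 chromosome
is a haploid switch (never mistaken for a misorientation).  Events whose
gross interval touches a chromosome end are flagged `terminal` —
end-proximal events are the method's known blind spot.

## Library quality, ploidy, segregation

`background_metric()` pools homozygous chromosomes: the percentage of
Crick reads on WW/W chromosomes plus Watson reads on CC/C chromosomes over
all reads there.  Pooling (rather than averaging per-chromosome ratios)
keeps the estimate stable when short chromosomes carry few reads;
libraries with no homozygous chromosome get a flagged, undefined metric
rather than silent omission.  The metric is invariant under global
W/C relabelling.

`call_ploidy()` converts relative depth $d$ (chromosome mean per-bin depth
over library mean) to $n = \mathrm{round}(2d)$, halves away from zero:
$d = 0.5$ is a monosome, $1.5$ a triploid chromosome.

`segregation_summary()` tallies WW/WC/CC across libraries per chromosome
and tests against 1:2:1 (the null under independent segregation; the
expected ratio is an argument for designs where it should differ) with
`chisq.test`, Holm-adjusting across chromosomes.

## Misorientations, recurrence, CNV

Misorientation candidates are paired per library into flipped regions
(consecutive WW→CC / CC→WW boundaries toggle the orientation; an unpaired
boundary extends to the chromosome end), merged across libraries by
overlap, and scored by concordance: the percentage of *informative*
libraries showing the flip.  Informative means homozygous over the region
— in a WC library both homologues flip and the mixture is unchanged, so WC
libraries cannot see a misorientation and do not enter the denominator.
A flip seen in a single library is suppressed as a probable segmentation
artifact.  On haploid chromosomes every switch looks like an SCE, so a
misoriented segment is called only where paired boundaries recur in every
informative library.  `amalgamate_events()` applies single-linkage
grouping (≥ 1 bp overlap, configurable) to all events and reports groups
spanning two or more libraries with their intersected interval — recurrent
SCE regions and structural rearrangements are reported alike, the
interpretation being left to the user.  `detect_cnv_segments()` reuses the
CBS backend on relative depth, with copy estimates rounded as in
`call_ploidy()`.

## Scaffold placement

Chromosomes are split at every library's event midpoints; the union of
breakpoints across libraries defines a common region grid (the finest
partition on which concordance is well defined), and each library's state
over a grid region is called from its binned counts.  A scaffold's
per-library states are then matched against every region: WC matches WC
(no orientation information), WW matches WW in the same orientation and CC
in reverse (CC symmetric), and homozygous never matches WC.  Concordance
is the match percentage over mutually informative libraries, the best
region wins, orientation follows the majority of same-versus-reverse
votes, and a call is confident with more than 10 informative libraries and
more than 60% concordance (both strict; both configurable).  Scaffolds
that never show WC across informative libraries are scored against haploid
chromosomes when the genome has any, and fall back to diploid scoring
otherwise (a short diploid scaffold can miss WC by chance).
`crossref_gaps()` nominates assembly gaps in the best region — unbridged
gaps at any size, bridged gaps at least as long as the scaffold — largest
unbridged first.  `update_reference()` performs the edits: misoriented
intervals are reverse-complemented in place (an involution), placed
scaffolds are inserted into the centre of their primary gap preserving
flanking Ns, and an edit ledger records every change; coordinates
downstream of insertions shift, which the ledger, not the sequence,
documents.

## Early-build assembly

`build_state_matrix()` drops libraries that are WC on every contig (failed
libraries carry no directional signal) and contigs that are WC in every
library (degenerate sequence), plus contigs under 10 kb.  Clustering is
seeded greedy: contigs in descending informative-library count (names
break ties, making the procedure deterministic) join the best existing
group whose consensus (per-library majority state) they match at ≥ 0.85
all-states concordance, or found a new group.  Orientation uses
homozygous-only concordance — two groups from the same chromosome in
opposite orientation score near 0 there — and a greedy pass inverts
whichever group most increases the summed pairwise concordance until no
inversion helps (never the same group twice in a row, hard cap 100
iterations), after which concordant groups merge.  Contigs never observed
WC are routed to a separate haploid clustering on W/C states.

`order_contigs()` treats the fraction of mutually informative libraries
with differing (orientation-corrected) states as a genetic distance — SCEs
accumulate with physical separation like crossovers on a linkage map — and
finds the shortest Hamiltonian path.  Groups of up to 12 contigs are
solved *exactly* by Held–Karp dynamic programming; larger groups use
best-of-all-starts nearest-neighbour plus 2-opt.  The exact route exists
because plain 2-opt stalls in local optima on matrices as small as six
contigs, and small groups are precisely where users will scrutinize an
order.  Groups with identical states everywhere cannot be ordered (no SCE
ever separated them) and are returned flagged.

# The simulator: what it does and does not emulate

`simulate_library()` draws per-homologue templates, plants SCEs on one
homologue each (so diploid transitions are homozygous↔heterozygous;
WW↔CC transitions arise only from planted misorientations), places
fixed-length (50 bp) single-end reads uniformly with chromosome weights
proportional to length × copy number, flips strand labels inside
misoriented segments (mirroring positions), relabels reads in extracted
intervals onto orphan-scaffold contigs (reverse-complement aware), and
finally flips each read with the configured background probability.
Fixing the seed fixes every output bit-exactly, per library.

Deliberately *not* modelled: coverage waviness and mappability bias,
variable read lengths and alignment artifacts, BrdU-incorporation
chemistry, and reciprocal SCEs shared by paired daughter cells.  Passing
tests on these simulations therefore demonstrate algorithmic correctness
under the stated model, not robustness to every artifact of real
libraries; the background-rate dial is the one knob that injects
real-data-like noise.

Where the literature reports conditions, the defaults follow it: 200 kb
bins, 0.2 SD filtering, 50-read refinement floor, the 10-predecessor /
4-of-20 walker rule, 1:2:1 segregation, >10 libraries and >60% concordance
for scaffold confidence.  The empirical SCE rate per library is left as a
parameter (`sce_rate`).

# Test problem sizes

The regression suite simulates at sizes chosen to exercise every code
path while keeping a full run under a minute: the SCE-recovery regression
uses 60 libraries on two 50 Mb chromosomes at 1.2 reads/kb (the coverage
scale of real 3M-read libraries), 3% background and 0.5 SCEs per
chromosome per library; scaffold placement runs 100 seeded trials of 30
libraries on three 10 Mb chromosomes with a 400 kb extracted scaffold of
alternating orientation; assembly recovery fragments two chromosomes into
ten contigs each, with clustering purity checked on SCE-free libraries and
contig ordering on libraries carrying three SCEs per chromosome.  All
seeds are fixed in the tests.

# Known limitations

* Detection quality degrades on chromosomes with more than two copies;
  events there are out of scope (the ratio levels are no longer three).
* SCEs within a few megabases of chromosome ends are under-detected
  (flagged `terminal`); SCE pairs closer than the gross-interval scale can
  merge into one call.
* Misorientation pairing assumes flipped regions do not start before the
  first detected boundary; a chromosome whose very start is misoriented is
  attributed from its first boundary onward.
* Recurrent events are counted, not classified into
  translocation/inversion/deletion; that interpretation needs orthogonal
  evidence.
* `update_reference()` does not lift annotations; coordinates downstream
  of insertions change.
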