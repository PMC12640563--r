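---
title: "Processing multiomic single-cell Hi-C alignments with pairwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing multiomic single-cell Hi-C alignments with pairwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairwalk)
```

## The model

A proximity-ligation molecule is a walk $L_1 \to L_2 \to \dots \to L_k$
through $k$ genomic loci. Sticky-end ligation joins restriction fragments
at enzyme cut sites, reconstituting a single copy of the recognition
motif at each junction. Sequencing reads the molecule from both ends
(R1 forward, R2 reverse-complemented), and a soft-clipping local aligner
reports one alignment record per locus visited by each mate. `pairwalk`
takes those records and produces contacts, SV annotations, breakpoints
and QC. Its processing chain is strictly ordered:

1. **Parse** name-grouped SAM/BAM into per-mate chains of alignment
   segments, each with a read-coordinate span derived from its CIGAR.
2. **Filter** segments with MAPQ below a threshold.
3. **Trim** multimapped read bases shared by adjacent soft-clipped
   alignments of one mate.
4. **Call** contacts (mask or all policy), canonicalize, annotate
   cut-site proximity, call breakpoints, and aggregate QC.

Trimming precedes calling because the duplicated junction motif would
otherwise shift every junction coordinate by up to the motif length.

### Read-coordinate arithmetic

All internal coordinates are 0-based half-open; conversion to 1-based
happens only at PAIRS/breakpoint serialization, so there is a single
off-by-one boundary. Read coordinates are always expressed in the
*original read orientation*: a minus-strand record's leading soft clip is
a trailing clip on the read, so its clips are flipped. Adjacency and
overlap between two alignments of one read are properties of the read,
not of the reference, and this convention makes them directly comparable
across segments regardless of strand. Hard-clipped bases are counted into
the read length so that coordinates agree between a primary record and
its supplementary (hard- or soft-clipped) siblings.

### Multimapping trimming

For consecutive segments $u, d$ of one mate chain (sorted by read start),
the overlap is $\max(0,\, u_{\mathrm{read\_end}} -
d_{\mathrm{read\_start}})$. Those read bases are removed from **both**
segments — $u$ loses them at its 3'-in-read end, $d$ at its 5'-in-read
end. There is no principled rule for assigning the shared motif to one
side (it derives from exactly one locus, but which one is unobservable),
so symmetric removal is the conservative choice: no junction coordinate
is ever supported by bases that might belong to the other locus. In the
CIGAR, removed query-consuming operations become soft clip, the reference
span shrinks by the reference-consuming length removed on the
strand-correct side, and deletions stranded at the new alignment edge are
dropped. A segment consumed entirely is removed from the chain and
counted. Trimming operates on read-coordinate overlap generically rather
than on exact motif matches, since chimeric-alignment redundancy also
arises from mechanisms other than the junction motif.

Two consequences are worth noting. First, trimming is idempotent: after
one pass the former overlap has become a gap of the same length, so a
second pass changes nothing. Second, a trimmed sticky-end junction is no
longer base-adjacent (both flanks gave up the motif bases), which is
exactly why such junctions cannot and should not produce 1 bp breakpoint
calls.

### Contact calling

Under **mask**, only unambiguous two-locus products are reported: 1+1
(`UU`), or 2+1 where the chimeric mate's 3'-in-read segment matches the
other mate's segment — same chromosome, opposite strand, 5' positions
within the rescue window — in which case the contact joins the two
5'-in-read segments (`RU`/`UR`). Everything else is masked with an
`M`/`N` code recorded for QC. Under **all**, the walk is R1's chain in
read order followed by R2's chain in reverse read order; the two mates'
terminal segments are merged into one walk element when they satisfy the
same matching rule, because they are the two reads' views of the same
fragment end. A walk of $k$ merged elements yields $k-1$ contacts with
ascending `contact_index`.

One asymmetry follows directly from these definitions: a 1+1 pair whose
two segments merge (a self-ligation read) is a `UU` contact under mask
but a single-element walk — hence zero contacts — under all. The two
policies agree on every non-merging pair, and the package's tests pin
both behaviours.

Each reported side is the segment's 5'-in-read reference coordinate
(`ref_start + 1` on `+`, `ref_end` on `-`), the pairs convention. Sides
are canonicalized into upper-triangle order under the reference
chromosome order; facing-end annotations swap together with their sides.
No duplicate removal is performed — the PAIRS output is coordinate-sorted
so standard downstream dedup tools can run on it.

### Cut-site proximity and breakpoints

The facing ends of a within-read junction are the upstream segment's
3'-in-read terminus and the downstream segment's 5'-in-read terminus; for
a mate-paired contact the junction itself is unsequenced and both 3' ends
face it. Distances to the nearest cut site are computed from an in-silico
digest of the reference (`Biostrings` motif matching; palindromic motifs
scanned once, non-palindromic on both strands, N never matches; multiple
enzymes merge into one index; a precomputed single-position BED can
substitute for enzymes whose sites are not expressible as one exact
motif).

A contact is SV-flagged when *either* facing-end distance exceeds the
tolerance: a single distal end already violates the digestion model, and
both distances are always recorded so users can impose a stricter AND
rule. The default tolerance is $|\mathrm{motif}| + 1$ bp because
sticky-end ligation and fill-in leave the observed junction within the
overhang length of the cut: on simulated GATC junctions the post-trim
facing distances are exactly 0 or 4 bp depending on orientation.

Breakpoints are emitted for flagged within-mate junctions whose segments
abut in read coordinates (gap at most `max_junction_gap`, default 0 —
any unread base forfeits the 1 bp claim). The reported coordinates are
the junction-adjacent aligned bases, 1-based, on trimmed alignments. Both
intra- and inter-chromosomal junctions are reported. The core caller does
no cross-read clustering; a QC tabulation counts supporting reads per
unique junction, and the BEDPE output carries that count as its score.

Mate-paired contacts routinely show distal facing ends simply because the
read stops before reaching the fragment end; they are annotated but can
never become breakpoints, and SV interpretation should rest on the
adjacent soft-clipped class.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_mapq` | 30 | phred-like | standard BWA-MEM confident-placement cut |
| `rescue_window` | 500 | bp | max 5'-end distance for mask rescue / walk merge; generous vs. typical fragment lengths, small vs. genomic distance between distinct loci |
| `sv_tolerance` | motif + 1 | bp | overhang fill-in shifts the junction by up to the overhang |
| `max_junction_gap` | 0 | bp | strict adjacency is what makes the 1 bp resolution claim true |
| `policy` | mask | — | the conservative two-locus caller; all for walk-level analyses |

The enzyme is required user input: assays differ, and the package makes
no attempt to guess it from the data.

## The simulator

`simulate_hic()` is the package's test bed. It generates a uniform-random
genome (default 3 × 100 kb, so a 4-cutter lands every ~256 bp), digests
it with an independent character-by-character scan, and builds molecules
whose geometry makes the ground truth exact: every junction falls inside
R1, the final fragment is at least one read long so R2 lies wholly within
it, interior fragments are ≥ 25 bp, and a fragment carrying both a
cut-anchored end and an SV end is long enough
(≥ `sv_distal_min` + 1) that its own anchor cannot violate the distal
condition. Junction types are Bernoulli draws; for large walks whose
type combination cannot fit the read-length budget the types are redrawn,
so high-$k$ molecules are slightly enriched for proper junctions —
two-fragment molecules, which all calibration experiments use, are
unbiased. Proper junctions duplicate the motif into both flanking
alignments (the artifact under test); SV junction ends are rejection-
sampled at least `sv_distal_min` (default 50) bp from every cut site.
Orientation is random per fragment, and consecutive fragments are
inter-chromosomal with probability `fraction_trans` (default 0.2, giving
the ~4:1 cis/trans ratio typical of good single-cell Hi-C).

What it does **not** emulate: sequencing errors, bisulfite conversion,
PCR duplicates, mappability structure, or aligner scoring — records are
synthesized directly, because the package's contract begins at aligned
BAM. Passing tests therefore demonstrate the correctness of the
coordinate arithmetic, trimming, calling and annotation logic under the
stated read geometry, not robustness to alignment noise; low-MAPQ
robustness is exercised only through the `fraction_low_mapq` whole-read
injection.

Validation problem sizes were chosen to give tight binomial bounds while
keeping the default suite fast: 10,000 junctions for trimming, 5,000
walks of 1–5 fragments for contact recovery, 2,000 junctions at a 50/50
proper/SV mix for breakpoint recall, and 10,000 contacts for the
cis/trans calibration, with 100–400-molecule runs for everything
property-based.

## Numerical and degenerate-input choices

* Cut positions are 0-based offsets *between* bases; a cut at $k$
  separates $k-1$ and $k$. `nearest_cut_distance` returns `Inf` for a
  chromosome with no sites rather than erroring.
* A cis/trans ratio with zero trans contacts is `NA`, not an error or
  `Inf`; JSON serializes it as `null`.
* Empty inputs produce valid header-only PAIRS/SAM files and empty BEDPE.
* Name-grouping is verified on read (non-adjacent same-name records are
  an error instructing collation), and coordinate-sorted headers are
  rejected outright rather than silently re-sorted.
* The trimmed-span statistics (mean ± SD of the fraction of a segment's
  original aligned span removed) are computed over soft-clipped segments
  that had multimapping, matching how such statistics are quoted for
  real cells.

## Limitations

* Files are read whole into memory as a segments tibble. At single-cell
  scale (10^5–10^7 records) this is comfortable; genome-scale multi-cell
  BAMs should be processed per cell.
* Degenerate (IUPAC) motifs are not supported; supply a cut-site BED for
  such enzymes. Methylation-sensitive digestion is not modelled.
* No PCR/optical duplicate removal; run a dedup tool on the sorted PAIRS
  output if required.
* Breakpoint support counting treats the two sides as ordered by read
  orientation; the same physical junction read in both directions
  tabulates as two entries.
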