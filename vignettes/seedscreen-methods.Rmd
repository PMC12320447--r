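---
title: "Methods: models, parameters and design choices in seedscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in seedscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic data generator does and does not
show about real experiments.

## The splicing model behind cassette validation

A SEED cassette integrates at an intronic Cas9 cut site. Its insert is, 5′
to 3′: a splice-acceptor block (branchpoint, polypyrimidine tract and the
acceptor AG), 0–2 filler nucleotides, a P2A coding sequence, the payload
ORF, and one of four 3′ ends:

* `P2A_SD` — a second P2A followed by a copy of the donor sequence of the
  interrupted intron, so the transcript resumes the endogenous downstream
  exons and reuses the target's own poly(A);
* `OPEN_READTHROUGH` — no second P2A: the payload reading frame runs
  directly into the downstream exons (used when the payload is completed by
  the target's constant region);
* `POLYA` — stop codon plus a poly(A) signal block, no donor;
* `EXOGENOUS_PROMOTER_STOP` — a stop codon straight after the acceptor
  truncates the target; the payload is expressed from its own promoter
  inside the insert.

The model is deliberately minimal. A locus is stored strand-normalized
(coding strand forward; minus-strand genes are flipped on ingest, and all
downstream logic is strand-agnostic). Exon content is treated as pure CDS —
UTRs sit outside the model — and the phase of an exon is the cumulative
length of the preceding exons mod 3. Splicing honours exactly one synthetic
acceptor/donor pair: no cryptic-splice prediction, no splice-strength
scoring. That is a stated non-goal; the simulator is a frame bookkeeper,
not a splicing predictor.

Frame maintenance reduces to two numbers. If the upstream exons carry
`leftover = (cumulative CDS) mod 3` nucleotides of an open codon into the
junction, the 5′ filler has length `(3 - leftover) mod 3`; the 3′ filler
must restore the phase of the first resumed exon, which in a contiguous CDS
equals `leftover`. `frame_fill()` is total on the 9 possible (leftover,
phase) pairs and is tested exhaustively against an enumeration oracle.
Filler *sequences* are chosen deterministically: candidates are enumerated
in alphabetical order and the first that creates no stop codon in the
junction codon is taken.

`simulate_splice()` is the validator: it rebuilds the edited locus, locates
the acceptor block by sequence, takes the *last* donor-motif occurrence
inside the insert (the designed donor is the insert's final element, which
makes the search robust to chance motif hits inside the payload), splices,
and then demands that the CDS length is a multiple of 3 and that the
payload translation appears verbatim in the protein. A single-nucleotide
deletion anywhere upstream of the donor shifts the synthetic exon length
and is caught; this is the purpose of the function, not an edge case.

Open design points resolved here: the acceptor block of the vector cited by
the original construct designs is not printed anywhere public, so the
package ships a synthetic default (`seed_elements()`), documents it as
such, and refuses to run in `strict` mode unless the user supplies their
own. The P2A default is the canonical GSG-linker form. Homology arms
default to 500 nt, typical for AAV repair templates. Coordinates are
0-based half-open throughout; residue numbering is 1-based with a
configurable window so positions can match a published numbering (the
default window is residues 101–150).

## Scanning and saturation library design

The scanning design follows two rules per residue: substitute alanine plus
the `n = 4` substitutions with the highest BLOSUM80 score against the
native residue (the least disruptive changes); at alanine residues take the
top `n = 5` non-alanine residues. Residues observed at that column of a
homolog alignment and not already chosen are added. Each substitution is
synthesised with up to two codons, ranked by human codon usage (only the
within-amino-acid ranking matters); single-codon amino acids get one.
Controls: one synonymous codon per position (the highest-usage codon that
is not the reference codon), a single-residue deletion at every position,
and a stop codon at five positions. With a 50-residue window this yields a
649-member library at the default configuration — the scale of the screen
the package emulates.

Choices the published rules leave open, fixed here once: BLOSUM score ties
break alphabetically by one-letter code, making the pick deterministic;
the codon-usage table is human and configurable; homolog columns come from
an ungapped mapping of the alignment to the native segment with gap
characters ignored; the saturation scheme defaults to `NNN` (64 codons, 61
sense, 19 distinct non-native substitutions) with `NNK` and any other
IUPAC triplet supported. Every designed oligo is re-translated and checked
against its declared annotation before the table is returned, and
`validate_library()` applies the same audit to externally supplied tables.

## Quantification

Reads are scanned for the two fixed anchor sequences with **no mismatches
permitted**; the region strictly between them is kept, everything else is
discarded. Trimmed regions map to members by exact string equality only.
This mirrors the exact-match analysis the package reimplements and is a
deliberate trade: with a 150-nt region and a typical per-base error rate of
10⁻³, roughly 14% of fragments carry an error and go unmapped — counted
and reported, never silently dropped. Base qualities are ignored (no
quality filter is part of the workflow); an orientation fallback tries the
reverse complement of each read, and in paired-end mode the mate is
consulted only when the first read yields no anchors, so a fragment is
counted at most once. Whether the original workflow merged pairs or used
read 1 alone is not stated anywhere we could verify; read 1 with mate
fallback is the package default and the 150-nt region fits comfortably in
one 250-nt read either way.

Abundance is reads mapped to a member over total mapped reads, after
excluding stop-codon and deletion controls from the totals; synonymous
controls are ordinary members for this purpose (only stop and deletion
classes are excluded). Read accounting is conserved by construction:
`reads_in = no_anchor + unmapped + mapped`, asserted on every simulated
run.

## Enrichment and epitope calls

Fold enrichment is `(a_sel + eps) / (a_in + eps)` on the abundance scale.
The default pseudocount is `1 / min(non-control mapped reads)` across the
samples involved — one read in the shallowest sample — which keeps
zero-count members finite without distorting well-covered ones; linear and
log2 values are both reported because either convention appears in
practice. The conservation score is the ratio of bound-bin to unbound-bin
enrichment; members are ranked least to most conservative with ties broken
by bound-bin fold enrichment, then member id. Codon scores are averaged
(unweighted) per amino acid. A position is called part of the epitope when
at least 50% of its non-native substitutions have a mean bin ratio at or
below 0.5 (log2 ≤ −1). The published analysis states no numeric rule for
this step, so these two thresholds are the package's own operating point,
chosen as a round two-fold cutoff and a majority criterion; both are
arguments and appear in the epitope-call output.

## ddPCR

The naive mode is the stated calculation: 100 × FAM⁺/HEX⁺ droplets. The
Poisson mode converts each channel to a per-droplet rate
`-ln(1 - k/total)` first, as droplet readers conventionally do. One
mathematical note: because the rate transform is convex, the *busier*
channel is inflated more, and in the translocation regime (FAM occupancy
far below HEX occupancy) the naive ratio is slightly **larger** than the
Poisson ratio — the two agree in the limit of low occupancy in both
channels (within 0.1% relative when both are below ~0.25%). The tests
assert this direction.

## What the synthetic screen emulates — and what it does not

The generator reproduces the *structure* of the experiment: a 50-residue
window scanned by a 649-member library (the synthetic reference segment
and homolog set are constructed so the default design lands exactly on
that size, with planted homolog-derived substitutions standing in for the
real alignment's contribution); a mildly skewed library composition
(log-normal, sd 0.3); 50,000 cells allocated multinomially; each cell
routed to the antibody-negative bin with probability equal to its
variant's binding loss; 100,000 reads per bin resampled from bin cell
counts; 250-nt reads with anchors and backbone context; and substitution
sequencing error at 10⁻³ per base.

Ground-truth effects live at the amino-acid level (codons of one
substitution share one effect). Escape positions — by default 102, 112 and
116, mirroring the three epitope residues the emulated screen found — draw
binding loss from Beta(6, 2): strong escape, as in the real screen where
most substitutions at those positions escaped. Background substitutions
draw from 0.4 × Beta(2, 8): small but continuous, so that rank-based
recovery can be scored over the whole library rather than only at the
planted positions. Synonymous members are pinned to exactly zero (the
native residue is the most conservative variant at its position, a
property the screen reproduced and the tests assert), and deletion/stop
controls to one (no surface expression). These distributions were fixed by
a power analysis of the sampling model before the acceptance suite was
written: at the default depths they give a planned Spearman correlation
between true binding loss and −log2 bin ratio of ~0.82–0.89 and exact
recovery of the three planted positions, with background positions staying
safely below the escape threshold.

What is *not* modelled: PCR amplification bias, chimeras, index hopping,
quality-score structure, expression differences between variants,
cell-sorting impurity, and any correlation between binding loss and
surface expression. Passing the recovery tests therefore shows that the
analysis code inverts the sampling model it is given — not that the
thresholds would be optimal on a real screen, where those unmodelled
effects add noise and bias.

## Problem sizes and determinism

Default problem sizes are desk-scale by design: 649 members, 50,000 cells,
3 × 100,000 reads, one end-to-end run in well under a minute; unit tests
use smaller instances of the same generators. Every stochastic function
takes an explicit integer seed (package default 42) and threads it through
a local RNG scope, so identical inputs give byte-identical outputs — FASTQ
files included — and the pipeline stamps a config hash into its outputs so
a run is reproducible from its config alone.

## Known limitations

* The splicing model assumes exon content is pure CDS; genes with long
  UTR-containing terminal exons need their intervals trimmed to the CDS
  before use.
* Exact-match counting discards all error-bearing reads; at very low input
  depth this can starve rare members. The read accounting makes the loss
  visible but the package deliberately offers no error-tolerant mapping.
* The GenBank writer emits the small feature subset the package itself
  uses (`misc_feature` + label); it is not a general GenBank library.
* Saturation libraries share the scanning reference window; positions
  outside it are rejected rather than re-anchored.
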