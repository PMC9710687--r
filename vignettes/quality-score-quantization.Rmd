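---
title: "Quality-score quantization for nanopore FASTQ data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-score quantization for nanopore FASTQ data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsquant)
```

## The problem

Nanopore basecallers attach a Phred quality score to every base, drawn from
94 possible values: FASTQ stores score $q \in \{0, \dots, 93\}$ as the ASCII
character $q + 33$ (codes 33–126). Scores encode the per-base error
probability $10^{-q/10}$, but at this resolution they are nearly
incompressible and dominate the size of losslessly compressed FASTQ files —
more bytes than the bases themselves. Downstream tools that consume quality
scores (assembly polishers, variant callers) turn out to be remarkably
insensitive to their precision, which motivates *quantizing* scores — a
deterministic many-to-one map onto a small output alphabet — before
compression, trading resolution nobody uses for large storage savings.

This package implements the quantizers, the repeat-context variant, and the
bookkeeping needed to produce quantized datasets and measure the
consequences: FASTQ streaming, seeded coverage downsampling,
recall/precision/F1 arithmetic, compression ratios and an entropy
diagnostic, plus a synthetic read generator so everything is testable
without external data.

## Quantizers

An **interval quantizer** partitions $\{0,\dots,93\}$ into contiguous bins,
each mapped to one representative value. The builtins:

| name | bins |
|------|------|
| `Q2` | 0–7 → 5, 8–93 → 15 |
| `Q4` | 0–7 → 5, 8–13 → 12, 14–19 → 18, 20–93 → 24 |
| `Q8` | 0–6 → 5, 7–11 → 10, 12–16 → 15, 17–21 → 20, 22–26 → 25, 27–31 → 30, 32–36 → 35, 37–93 → 40 |

All collapse the large set of rarely used high scores into a single value
and bin the frequent low scores more finely. A **constant quantizer** $F_z$
maps every score to a fixed $z$; `F10` uses $z = 10$, a common read-quality
filtering threshold. Evidence from variant-calling benchmarks is that exact
thresholds matter little: shifting the two-level quantizer's boundary and
output values by a point or two changes F1 by roughly a tenth of a percent,
so the builtin definitions are taken as given rather than tuned.

Three structural properties are enforced by the `IntervalQuantizer` validity
method rather than merely tested:

* **totality** — bins tile $[0, 93]$ exactly; partial maps are rejected so a
  typo in a custom spec cannot silently pass scores through;
* **monotonicity** — representative values strictly increase across bins, so
  score ranks survive quantization;
* **idempotence** — each representative lies inside its own bin, hence
  re-quantizing an already-quantized file is a byte-level no-op; pipeline
  re-runs are safe.

Custom quantizers use a small grammar: `0-6:1,7-93:13` (bins), `F:20`
(constant), or a builtin name.

## The repeat-context quantizer

Repetitive sequence — homopolymers and tandem dinucleotide repeats — is
where nanopore base calls degrade most, and where downstream tools lean
hardest on quality scores. The two-regime quantizer
$\langle f, f' \rangle_\delta$ therefore applies a coarse quantizer $f$ to
scores *far* from repeats and a finer $f'$ to scores *within or near* them.
A position is "near" when its distance to the closest base of a repetitive
interval is at most $\delta$; for an interval $[s, e)$ the near region is
$s - \delta \dots e - 1 + \delta$, clamped to the read. Defaults follow the
experimental setting: minimum homopolymer length $h = 5$, minimum
dinucleotide copies $d = 4$, $\delta = 5$.

Conventions that the definitions leave open were fixed as follows:

* a homopolymer "of length $h$" means any maximal run of length $\ge h$
  (every longer run contains one of length $h$);
* dinucleotide units with equal letters (`AA`) are excluded — such regions
  are homopolymers and are governed by $h$, otherwise `d = 4` would silently
  lower the homopolymer threshold to 8;
* "more than $\delta$ bases away" is read inclusively as above; off-by-one
  conventions differ between tools, so the package states its choice;
* overlapping or touching intervals are merged before masking (the mask is
  a union of positions, so merged intervals are its canonical maximal
  representation);
* `N` and lowercase letters participate in runs like any letter — basecaller
  case varies, and excluding `N` would need a rule the definitions do not
  supply;
* all coordinates are 0-based, half-open.

Dinucleotide detection exploits the fact that every run of $\ge d$ copies
lies inside a maximal period-2 region (positions where
`seq[i] == seq[i+2]`): a region of length $L$ whose first two letters differ
qualifies exactly when $\lfloor L/2 \rfloor \ge d$, and then the union of
copy intervals over both phases covers the whole region. Tests compare this
against a quadratic brute-force oracle that extends every start position
literally, over thousands of random and planted sequences.

## FASTQ handling

Only strict 4-line records are accepted (nanopore basecallers emit nothing
else, and the restriction removes the `+`-line ambiguity of wrapped FASTQ).
Headers and separator lines are preserved verbatim: quantization must alter
quality characters and nothing else, and an untransformed parse-then-write
is byte-identical. gzip input is detected by its magic bytes, not the file
extension. Quality is stored encoded and rewritten through a single
integer-lookup pass; scores outside ASCII 33–126 abort with the record
ordinal rather than being clipped, since they indicate corrupt input.
`streamFastq()` processes bounded-size chunks so memory scales with chunk
size, not file size.

**Downsampling** emulates reduced coverage by keeping exactly
`round(fraction × N)` reads (half-up), selected uniformly without
replacement by a seeded generator and emitted in input order. Exact-count
selection, rather than per-read Bernoulli trials, makes the emitted coverage
reproducible. Multi-file datasets are pooled into one stream in argument
order before selection; whether the original experiments sampled per file or
per pool is unstated, and the pooled stream is the simplest reproducible
choice.

## Evaluation arithmetic

From confusion counts: $\mathrm{Rec} = TP/(TP+FN)$,
$\mathrm{Prec} = TP/(TP+FP)$,
$F_1 = 2 \cdot \mathrm{Prec} \cdot \mathrm{Rec} / (\mathrm{Prec} + \mathrm{Rec})$,
with the total-function convention that a metric with zero denominator is 0.
Values are kept at full precision; `roundHalfUp(x, 4)` matches the half-up
display rounding of published benchmark tables.

Two numerical caveats the tests encode explicitly. First, published hap.py
reports derive precision from *query-side* true-positive counts, which
differ slightly from the truth-side counts the tables print; recomputing
precision from printed counts therefore lands within one unit of the fourth
decimal but not always exactly on it. Recall, computed from truth-side
counts, reproduces exactly. Second, an F1 recomputed from
4-decimal-*printed* precision and recall inherits their rounding and is
determined only to within about $10^{-4}$; tests assert that band, not
exact equality.

Compression is measured as $\mathrm{CR} = $ compressed bytes / uncompressed
bytes (smaller is better) and percent space saving
$100 \times (b - v)/b$ against a baseline's compressed size $b$.
Compression uses R's zlib-based gzip codec at default level 6 (reported by
the CLI); byte counts are reproducible within a codec version, and only
ratios and orderings are compared across implementations. The zeroth-order
empirical entropy $-\sum_s p_s \log_2 p_s$ of a score sequence bounds what a
memoryless compressor can achieve; since quantization merges symbols it can
never increase this entropy, a property tested across builtins and random
quantizers.

## The synthetic generator

`simulateFastq()` exists so every detector and codec path is testable with
exhaustive ground truth and no downloads. Reads get negative-binomial
lengths (default mean 250, dispersion 6), i.i.d. background bases, and
quality scores drawn i.i.d. from a score law peaked near 10–14 with a thin
high tail (`defaultScoreLaw()`, a two-component negative-binomial mixture) —
the qualitative low-skew of nanopore basecallers. Planted repeats are
overwritten verbatim at recorded intervals, and each read is
rejection-sampled until the detectors recover *exactly* the planted
intervals: ground truth is exhaustive by construction, so tests can assert
interval equality instead of fuzzy overlap.

What the fixture does **not** emulate: real nanopore read lengths (tens of
kilobases — rejection of spontaneous repeats makes long repeat-free reads
exponentially unlikely, hence the short default), sequence composition,
basecalling error processes, or any instrument's actual score distribution.
Passing tests demonstrate the *algebra* of quantization, detection and
bookkeeping; they say nothing about biological consequences on real data,
which is what the published polishing/variant-calling experiments measured.

Problem sizes used by the test suite were chosen to exercise the contracts
at comfortable margins: detector/oracle equivalence on 1000 random sequences
of lengths 1–300 plus 100 planted fixtures; idempotence/monotonicity over
the builtins and 500 random interval quantizers; entropy monotonicity on 100
simulated reads; byte-identical round trip and seeded downsampling on a
100,000-read file (mean length 80); compressibility ordering on 400 reads of
mean length 200.

## Command-line interface

`inst/scripts/qsquant.R` wires the package into a shell tool with
subcommands `quantize`, `downsample`, `simulate`, `metrics` and
`compress-report`. Logs go to standard error, data to files or standard
output, so the tool composes with pipes; exit statuses are 0 (success), 1
(data error), 2 (usage error). The repeat-context scheme is selected with
`--far F:10 --near Q8 --delta 5 --homopolymer 5 --dinucleotide 4`.

## Known limitations

* Wrapped (multi-line) FASTQ and Phred+64 legacy encoding are rejected by
  design; SAM/BAM/CRAM and raw signal formats are out of scope.
* Repeat context is limited to homopolymers and dinucleotide repeats;
  trinucleotide and longer tandem units, and alignment/locus-based context,
  are not modelled.
* No rate–distortion optimization of bin placement is attempted; the
  builtins are fixed reference points, and per-application tuning is an open
  question upstream of this package.
* `downsampleReads()` holds the read set in memory (exact-count selection
  needs `N`); the streaming paths (`streamFastq`, CLI `quantize`) are the
  constant-memory ones.
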