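---
title: "Typing chlorotypes and ribotypes from marker alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing chlorotypes and ribotypes from marker alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistyper)
```

## The problem

Phylogeographic surveys of closely related plant taxa routinely type
individuals at a small number of sequence markers: chloroplast intergenic
spacers (here *trnL-trnF* and *rpl32-trnL*) and the nuclear ribosomal ITS
region. The analysis pipeline looks deceptively simple — find the variable
alignment columns, group identical state patterns into named haplotypes
("chlorotypes" for plastid markers, "ribotypes" for ITS), map them, and draw
a haplotype network — but each step hides judgement calls that are usually
made by hand in an alignment editor. `cistyper` turns those calls into
explicit, parameterised, logged rules so that the whole analysis is
reproducible and testable.

The package's second concern is specific to ITS. Ribosomal DNA occurs in
tandem arrays that concerted evolution normally homogenises; when
homogenisation fails, an individual carries two divergent paralogous
ribotypes. A direct Sanger read over both templates shows *additive
polymorphic sites* (two superimposed peaks, reported as IUPAC ambiguity
codes) where the templates differ by substitutions, and a sustained run of
ambiguous calls downstream of any length mutation, where the two templates
are read out of register. In the *Cistus creticus* complex that motivated
this package, the paralog pairs differ by one to five SNPs plus a 6 bp
insertion (`CGTCCT`) in the last third of the amplicon. `cistyper` models
such reads as the position-wise IUPAC union of the two templates and
recovers the second template by *base subtraction* against a clean reference
from a geographically neighbouring accession.

## Variable sites and indel coding

`extract_variable_columns()` reports every column with two or more observed
states. The consensus is the majority state; ties break to the state of the
first sequence and are logged. Ambiguity codes are **literal states** at this
stage: a published ribotype defined by an `S` at one column is a distinct
pattern, not "C or G". Interpreting ambiguities as superpositions is
deliberately deferred to the phasing module, because typing operates on
pattern identity while phasing operates on a physical model of the
chromatogram.

Gap-containing columns are grouped by `group_indel_events()` under simple
indel coding: a maximal run of adjacent gap columns whose gap pattern (the
set of gapped sequences) is identical forms one event, one evolutionary
character. A 4 bp deletion therefore counts once, not four times; adjacent
1 bp events with different carrier sets stay separate.

Single-base indels attached to mononucleotide runs — classically poly-T
stretches in chloroplast spacers — are replication-slippage hotspots and are
conventionally ignored when haplotypes are defined.
`flag_homopolymer_indels()` flags an event when all inserted/deleted
residues equal the homopolymer base and the adjacent ungapped context
carries a combined flanking run of at least `min_run` copies (default
`base = "T"`, `min_run = 4`; four is the shortest run plausibly called a
"stretch", and both are configurable). `condense()` then keeps one column
per substitution and per non-excluded event; excluded columns stay in the
matrix, marked, because mutation-event distances still report them
separately ("five mutations plus one poly-T indel").

## Types, mains, variants, intermediates

`define_types()` names one type per distinct state vector over the retained
columns (deterministically: descending count, then first occurrence, named
`A`, `B`, `C`, ...). Names are labels only — the *role* of a type is stored
separately, so a rare type structurally derived from a frequent one keeps
its own name.

`designate_mains()` designates a type as *main* when its sample count
reaches `min_main_count` (default 10, which separates the published main
ribotypes, n ≥ 13, from the largest local variant, n = 7) and it is not
expressible as an already designated main plus extra non-consensus states;
candidates are processed in descending count order. Two design points
deserve a note:

* The structural test runs on the **full** representative vectors, excluded
  homopolymer columns included. Two frequent types may differ only by one
  substitution plus a poly-T state; on retained columns alone the younger
  one would be demoted to a variant even though the printed tables treat
  both as mains.
* Processing order matters because one published main ribotype *is* the
  all-consensus vector: everything is "consensus plus extras", so the
  consensus type must not be designated before more frequent mains.

`classify_variant()` assigns the remaining types a role. A *variant* of main
`M` equals `M` plus private extra states (columns where all other mains are
consensus); additionally, a type carrying `M`'s full distinctive pattern may
hold an additive ambiguity overlapping `M`'s own state at another main's
discriminating column — that reads as a heterozygous position on an `M`
background. An *intermediate* between `M1` and `M2` holds, at every column
distinguishing the two, either main's state or an ambiguity covering both,
with a genuine mixture; when several pairs qualify the winner maximises the
fraction of ambiguity-covered distinguishing columns (the strongest
intermediacy signal), then the fraction of the type's own deviations the
pair explains, then the smallest distinguishing set. Everything else is
*unique*. These rules reproduce the published classification of the fixture
tables: nine local variants of ribotype A, the D/B intermediate, and the
C-variants as C/B intermediates.

`assign_clade()` combines one chlorotype with one or two ribotypes per
individual: chlorotype group A with only A-group ribotypes is the Eastern
Mediterranean (EM) pattern; chlorotype C/D/E, or a co-occurring non-A main
ribotype, the Western Mediterranean (WM) pattern; chlorotype A with only
rare non-A variants is called admixed (the contact-zone pattern). A missing
marker does not downgrade a call that the other marker decides.

## The superposition model and base subtraction

`superimpose()` is the forward model: for a balanced mixture (equivalent
copy numbers) the read is the IUPAC union of the two template bases at every
position, over the length of the shorter template. For a skewed mixture the
read shows the dominant template, with the minor base surfacing at a
detection rate of 0.1 by default — a free parameter of the model, not an
empirical value, since real data only show that one paralog can be
"underrepresented". The trace object carries the major-peak calls in skewed
mode, mirroring the information a real chromatogram provides.

`detect_heterozygote()` calls a read heterozygous when some window of 20
positions contains at least 4 ambiguity codes — the sustained
"noise/divergence" signature of out-of-register templates. Isolated additive
sites alone never trigger phasing: a read with one clean double peak defines
a typed variant (an `A2`-style pattern), not a phasing candidate. This is a
deliberate decision: with a conjunction ("isolated sites AND a dense
window") a mixture whose templates differ only by the length mutation would
be missed, although it is exactly the case the subtraction method exists
for. The breakpoint is the first ambiguous position opening a qualifying
window; with defaults it localises the insertion point to within the motif
length.

`subtract_reference()` recovers the second template. Upstream of the
breakpoint, each additive site contributes the member of the ambiguity set
that differs from the reference base. Downstream, candidate register offsets
up to ±10 are scored by the fraction of positions whose ambiguity set
contains the shifted reference base, and the **smallest-magnitude offset
reaching the support threshold** (default 0.9) is adopted. Parsimony of the
register shift matters: a reference one SNP away from a true template can
give a *perfect* score at a larger, wrong shift, yielding a chimeric allele
that still re-superimposes consistently; taking the minimal sufficient shift
instead restores exact recovery. For every balanced, noise-free trace built
by the forward model, subtraction with either true template as reference
returns the other template exactly over the resolvable window (the read
length) — a property the test suite checks over a thousand seeded pairs.

`phase_individual()` tries candidate references in ascending geographic
distance, preferring the longer reference among equidistant ones (an
insertion-bearing reference maximises the recovered window), then id order;
a reference is accepted only if re-superimposing it with the recovered
allele reproduces the read bit-exactly. In the pipeline, recovered alleles
re-enter the alignment with `extracted_from_heterozygote` provenance;
positions beyond the resolvable window (at most the motif length, always
downstream of every tabulated variable column in these markers) are filled
from the column majority and logged.

## Distances and networks

`provesti_distance()` is the proportion of compared characters at which two
state vectors differ — on haploid per-marker sequences the general
multi-allele form reduces to exactly this. Gaps are states, ambiguities
compare literally (an optional overlap mode exists, off by default, for
consistency with typing), and missing-data symbols drop out of the
denominator. The function is a metric on literal-state vectors; the suite
asserts the axioms and equality with an independent per-column comparer on
10^4 random triples.

`event_distance()` reports differing substitution columns and differing
indel events separately, with homopolymer-attached events in their own
count, matching the annotation style of published networks.

`build_msn()` grows a minimum spanning network Kruskal-style over edges in
ascending weight (ties by endpoint names). Edges joining distinct components
are primary; an edge whose weight exactly equals the threshold at which its
endpoints' components merged is kept as an *alternative* — an equally
minimal connection the tree could have used. Epsilon is 0: only exact ties
qualify, consistent with the sparse grey alternative links of published
figures. Primary edges provably form a minimum spanning tree; the tests
verify optimality against exhaustive enumeration of all spanning trees for
up to six nodes, and that alternatives are exactly the zero-epsilon ties.
The two chloroplast markers are never concatenated for network building:
their sequence sets differ, and combining them would manufacture haplotypes
no molecule carries.

## Fixtures and the synthetic generator

The package carries the three published variable-site tables as
code-generated fixtures: catalogs with the printed names, state vectors and
per-species counts, and full-length gapped alignments (427 / 899 / 699
columns; 158, 142 and 143 sequences following the printed n columns, which
slightly exceed the prose totals — the tables are taken as authoritative).
The invariant background is drawn from a fixed-seed stream so the alignments
are byte-stable; the poly-T context around the two 1 bp chloroplast indels
is embedded so the homopolymer rule fires, and the 1 bp deletion at column
366 is kept away from any homopolymer context. One documented oddity is
preserved: the *trnL-trnF* table shows four gap regions while the prose
counts three indels; the package groups strictly by contiguity and gap
pattern, so column 366 is its own event.

`generate_dataset()` emulates the study's structure with known truth: three
geographic regions of four populations with two sequenced individuals each
(the study's sampling unit); one ubiquitous insertion-free ribotype
co-occurring in every region with one regional, insertion-bearing ribotype
1–5 SNPs away; one regional chlorotype per plastid marker; a 0.27
heterozygote fraction; balanced mixtures by default. The skewed-mix fraction
defaults to 0 because no rate is published for underrepresented paralogs and
the balanced case is the one the subtraction method fully resolves; skewed
mixing is exercised through its parameter in dedicated tests. What the
generator does *not* emulate: sequencing noise, alignment error, more than
two paralogs per individual, within-type poly-T variation, and fungal
contamination dropout — so a passing noise-free recovery test demonstrates
the correctness of the inference logic, not robustness to dirty reads.

Problem sizes throughout the suite are desk-scale by design: tables of at
most 29 types, alignments of ≤ 700 columns and ≤ 160 sequences, 10^3 phasing
pairs, 10^4 distance triples, exhaustive tree enumeration at ≤ 6 nodes. All
randomness flows from explicit seeds; generation is a pure function of the
specification.

## Known limitations

* Phasing assumes exactly two templates; three-paralog mixtures are out of
  scope and will fail the consistency check rather than return a wrong pair.
* The dominant-template extraction for skewed mixtures relies on major-peak
  calls; from a bare IUPAC string (e.g. FASTA input) it falls back to
  resolving ambiguities toward the reference.
* Network alternatives are exact-tie only; statistical-parsimony or
  median-joining networks are not implemented.
* The clade rule encodes the published EM/WM convention; applying it to a
  catalog with differently named mains requires passing the corresponding
  names.
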