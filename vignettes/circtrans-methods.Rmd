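---
title: "circtrans: models, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circtrans: models, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtrans)
```

# The biology in one paragraph

Circular RNAs (circRNAs) arise from back-splicing and lack a 5' cap, so any
translation they support must initiate cap-independently, classically via an
internal ribosome entry site (IRES). Canonical IRESs are rare, yet reporter
screens show that a surprisingly large class of short AU-rich hexamers can
drive circRNA translation on their own ("IRES-like elements"). If ~2% of the
4096 hexamers behave this way, almost any circRNA longer than a few dozen
nucleotides contains one by chance, and circRNA translation becomes the rule
rather than the exception — including *rolling-circle* translation when a
reading frame never meets a stop codon on the circle. `circtrans` implements
the computational side of this programme: the screen statistic that finds the
elements, frequency statistics that compare them across transcript classes,
a circular ORF caller that recognises rolling-circle ORFs, and a
proteogenomics stage that builds a back-splice-junction peptide database and
filters peptide-spectrum matches (PSMs) down to credible circRNA-coded
peptides.

# Screen enrichment statistic

Reads from sorted reporter fractions carry a random 10-nt insert between
fixed vector arms. An insert is recovered only when the 24 nt immediately
upstream and the 30 nt immediately downstream match the reporter exactly
(`extract_inserts()`); no quality trimming or fuzzy matching is attempted,
mirroring the stringent recovery used in such screens. Each decamer is then
extended by 2 nt of vector sequence on each side — elements straddling the
insert boundary are real and would otherwise be invisible — and the
resulting 14-mer contributes its 9 overlapping hexamers to a count table
(`count_hexamers()`).

For each hexamer we compare its frequency among all counted windows in the
translating ("green", medium + high fluorescence) versus the non-translating
("dark", GFP-negative) population with the pooled two-proportion z statistic

$$ z = \frac{p_1 - p_2}
{\sqrt{\hat p (1 - \hat p)\left(\frac{1}{n_1} + \frac{1}{n_2}\right)}},
\qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2}, $$

classifying $z > 7$ as *enriched* (IRES-like) and $z < -7$ as *depleted*.
Design choices worth stating:

* **Form of the z test.** "A z test between two count-derived proportions"
  admits pooled and unpooled variants; we use the pooled form, the textbook
  statistic for $H_0: p_1 = p_2$. The two-sample layout and thresholds are
  arguments, not constants.
* **No pseudocounts.** A hexamer absent from both fractions scores 0 by
  convention. Smoothing would be an invention; absence is simply
  uninformative here.
* **Counting is per read**, so PCR duplicates count multiply. Whether the
  original analysis deduplicated inserts is unknowable from the outside;
  per-read counting is the more conservative default for a statistic whose
  denominators are window totals.
* **Vector extensions** default to the dinucleotides abutting the insert in
  the published library primer (`AA` upstream, `AT` downstream), but the
  post-cloning construct is not printed end-to-end anywhere, so both arms
  are configuration (`vector_context()`).

Motif clusters (`cluster_hexamers()`) use deterministic average-linkage
hierarchical clustering on a best-offset ungapped mismatch distance
(offsets −2..+2; unaligned overhang positions count as mismatches). The
original work clustered its 97 hits with an external multiple-alignment
tool; reproducing that tool's exact 11 memberships is a non-goal, and the
internal distance keeps the artifact dependency-free and deterministic.

# Hexamer-set frequencies and comparisons

`transcript_set_frequency()` computes, per transcript, the fraction of
overlapping 6-nt windows (step 1) whose hexamer belongs to a given set;
windows containing N are excluded from numerator and denominator. Two
averaging conventions exist in the wild: the per-window fraction (default)
and the mean of individual hexamer frequencies, which is the per-window
value divided by the set size (`mode = "per_hexamer_mean"`). Distribution
comparisons between transcript classes use the two-sample two-sided
Kolmogorov–Smirnov test, which is scale-free, so the choice of convention
does not affect p-values within a fixed set; both are exposed because
absolute frequencies plotted across sets of different sizes do depend on it.

Positional structure is examined with `positional_profile()` over
equal-length regions anchored at start or stop codons (±300 nt by default
via `anchored_regions()`); regions that would run past a transcript end are
dropped rather than padded, so every window offset averages over complete
observations. The 18S rRNA analysis ingests user-supplied heptamer lists and
splits each 7-mer into its two 6-mers for score lookup
(`heptamer_split_lookup()`); the active/inactive heptamer lists come from an
external published dataset and are deliberately not bundled.

# Circular ORF calling

`find_circorfs()` concatenates the circle four times and scans NTG start
codons (ATG/CTG/GTG/TTG — non-ATG initiation is common in cap-independent
translation) at offsets within the first copy, translating codon by codon on
the sense strand only. The key observation making rolling-circle calls exact
rather than heuristic: the frame path of a circular sequence is periodic
with period $3L$ nt (one circle when $L \equiv 0 \bmod 3$, three circles
otherwise), so *no stop within $3L$ nt past the start* is equivalent to *no
stop ever* — such starts are reported as rcORFs with infinite length.
Stop-terminated frames are cORFs when the peptide reaches `min_aa`
(default 20).

Choices the source left open:

* **One ORF per start.** The first stop governs; a start cannot yield both
  a cORF and an rcORF.
* **Per-circRNA reduction for surveys.** When one circle carries several
  qualifying ORFs, the survey (`survey_orfs()`) represents it by the
  "most coding" one: rcORF over cORF, then longest, then smallest offset.
  The original figures do not state their reduction rule; this one is
  documented and configurable in spirit (the full ORF table is always
  available).
* **Survey categories** follow a strict priority: host-overlap (a shared
  run of ≥7 consecutive residues with the host protein) beats homology
  (ungapped match to any known protein with ≤2 substitutions over the
  shorter sequence) beats non-homologous; circles without a ≥20-aa ORF are
  `no_orf`. The homology matcher is pluggable (`homology_fun`) so external
  aligner output can stand in for the internal Hamming scan.

Controls are plain sequence reversal (no complementation — the point is to
destroy codon structure while keeping composition) and seeded per-sequence
shuffling.

# Junction proteogenomics

`junction_translations()` translates each circle through its back-splice
junction in all three frames, extending in both directions until a stop or
one full circle per side. The one-circle cap is this package's choice: a
stop-free (rolling-circle) frame has no natural boundary, and one circle per
side is the smallest bound that still contains every junction-spanning
tryptic peptide the circle can encode. `digest_trypsin()` cleaves after K/R
with the standard proline suppression (configurable — the source names only
"lysine or arginine").

`build_junction_db()` keeps digestion products that span the junction with
at least 2 newly-encoded residues on each side, length ≥8 and ≤3 missed
cleavages, deduplicated with provenance, and writes FASTA with
`circ|<id>|f<frame>|j<offset>` headers.

`filter_psms()` is the sequential cascade applied to search-engine output:

1. **threshold** — spectrum-level q < 0.01 (q-values are consumed, never
   recomputed; this package does not score spectra), length ≥8, ≥2-aa
   junction flanks, ≤3 missed cleavages, and modifications restricted to
   carbamidomethyl-C, oxidation-M, N-terminal acetylation, pyro-Glu from Q
   and phospho-S/T/Y. Malformed modification or ion strings fail the
   record, not the run.
2. **reference_exact** — exact substring of any reference protein, with I/L
   treated as equivalent (they are isobaric and indistinguishable to the
   mass spectrometer).
3. **reference_homology** — ungapped alignment to the reference with ≤2
   substitutions; gapped matches are not considered.
4. **fragment_ions** — at least one matched b or y ion whose fragmentation
   site falls strictly upstream of the junction and one strictly
   downstream. "Any b or y ion on each side" is the implemented reading of
   the published criterion; the geometry is computed at nucleotide
   resolution, so for frame 0 the site exactly at the junction supports
   neither side, while a junction-spanning residue's flanking sites support
   both.

Every step logs in/out counts (`FilterReport`), which are monotone by
construction. `linear_control_peptides()` applies identical digestion and
flank rules to the linear splice junctions immediately adjacent to the
back-splice site, the natural abundance control for junction peptides, and
`junction_residue_stats()` quantifies the K/R bias at the −1 junction
position that depresses tryptic junction-peptide recovery.

# What the simulators emulate — and what they do not

All generators are pure functions of (config, seed) and regenerate
byte-identical files.

**Screen** (`simulate_screen()`): an insert is active iff its 14-mer
contains a planted hexamer; actives sort green with probability 0.8,
inactives with 0.02; reads are sampled multinomially within fractions and
wrapped in perfect vector arms (optional uniform substitution noise
exercises the exact-flank filter). Defaults: 200,000 inserts, 5 planted
AU-rich hexamers, 3000 reads per fraction. The read depth deserves a note:
real screens sequence millions of reads, but at high depth the hexamers
overlapping a planted occurrence by 4–5 nt become *genuinely* statistically
enriched (they ride along in adjacent windows) — a real feature of k-mer
screens, not a bug. 3000 reads per fraction gives each hexamer a stable
~6–7 expected background counts after window expansion while keeping those
correlated shift-neighbours mostly below the z = 7 threshold, so planted
recovery is cleanly testable. The Bernoulli sorter is deliberately minimal:
no FACS optics, no PCR bias, no per-cell expression noise. A green test
here establishes that the statistic recovers a planted signal at realistic
signal-to-background ratios — not that the biological screen had no
systematic artifacts.

**circRNAs** (`simulate_circrnas()`): planted cORFs (NTG start, 20–50
random codons, stop) and rcORFs (stop-free frame), plus no-ORF circles
drawn from a G-free alphabet. ORF bodies are built from codons that are
neither stops nor NTG starts, with a fixed "frame-killer" block
(`TTA-ATT-AGT`: Leu-Ile-Ser in frame, TAA/TAG in the shifted frames) every
5 codons. This guarantees — not just makes likely — that the planted ORF is
the only ORF the caller can find, so the survey ground truth is exact.
The price is mildly unnatural codon statistics, which none of the tested
statistics depend on. Toy host annotation (5 exons, circle over exons 2–3)
feeds the first-exon and linear-control machinery.

**PSMs** (`simulate_psms()`): true junction PSMs plus one planted violator
per filter rule, each constructed to fail *only* its intended rule (e.g.
the reference-exact violator carries a real reference substring but valid
q, flanks and ions). Peptides drawn from the junction database are
pre-screened to be ≥3 substitutions from the reference so chance collisions
cannot contaminate the truth table. No spectra, masses or retention times
are simulated; q-values are drawn, not computed.

# Numerical and interface choices

* Coordinates on circles are 0-based; the junction lies between positions
  L−1 and 0. Peptide and protein indices are 1-based, as is idiomatic in R.
* Hexamer tables are always indexed by the fixed lexicographic order of
  `all_hexamers()`; score antisymmetry holds exactly
  (`score(A,B) = -score(B,A)`).
* Clustering ties break lexicographically (members are sorted, the seed is
  the smallest member, offsets prefer small absolute shifts), making
  cluster output invariant to input order.
* KS tests delegate to `stats::ks.test`; the test suite cross-checks the D
  statistic against a direct ECDF implementation to 1e-12.
* The pipeline configuration file is JSON (via jsonlite), not YAML — R has
  no YAML parser in this package's dependency footprint, and JSON
  round-trips losslessly. Unknown keys fail validation by name. Per-stage
  seeds derive deterministically from the master seed and the stage's fixed
  position, so enabling or disabling one stage does not reshuffle another's
  randomness.

# Known limitations

* The published headline numbers (97 enriched / 122 depleted hexamers from
  the deposited screen reads; the 67% / 14% / 7% ORF-survey split on the
  full-length circRNA set; 2721 spectra / 990 junctions / 646 genes) require
  external downloads and an external search engine and are *validation
  goals* for the offline workflow, not results this package's test suite
  reproduces at desk scale.
* Antisense-strand ORFs are never scanned, by specification.
* The homology filters are ungapped by design; a peptide homologous to a
  reference protein only through a gapped alignment will survive filter 3.
* FDR estimation, spectral scoring and mzML handling are out of scope; the
  package builds the search database and consumes the engine's scored
  output.
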