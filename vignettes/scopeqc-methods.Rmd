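---
title: "Methods: screening SCOPe releases for structural heterogeneity, terminal artifacts, and variant context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening SCOPe releases for structural heterogeneity, terminal artifacts, and variant context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopeqc)
```

# Scope and data model

scopeqc operates on the machine-parseable artifacts of a SCOPe release:

* **dir.cla** — one line per classified domain: the 7-character sid, the
  PDB entry, a concise region string, the sccs (dot-separated
  class.fold.superfamily.family), the sunid, and the full lineage of sunids.
* **dir.inc** — annotations of structurally heterogeneous clades: sccs,
  a two-letter heterogeneity code, and the affected sids.
* **dir.rep** — the canonical tandem-repeat unit of repeat-defined
  families: sccs, the sid in which the unit is delineated, and its extent.
* **RAF maps** — per-chain fixed-width lines recording, in SEQRES order,
  the correspondence between the genetically encoded sequence (SEQRES) and
  the experimentally observed residues (ATOM records).

Two supporting inputs feed the artifact-detection and variant-mapping
chains: a JSON *chain dump* (SEQRES sequence, SEQADV difference notes, and
the DBREF cross-reference of each chain) and a minimal 4-column SIFTS-style
table of per-residue UniProt-to-SEQRES correspondences.

# The heterogeneity screen

## Model and assumption

The screen rests on a single working assumption: if all domains in a family
share the same structure, their lengths must be nearly equal. Two lengths
are computed per domain through its RAF record, summed over region
segments: the SEQRES length (what the construct encodes) and the ATOM
length (what the experiment resolved). Deviations are evidence of
heterogeneity — alternative domain divisions, extra subdomains, fragments —
and are routed to manual review; the screen never assigns one of the eleven
curation labels itself, because distinguishing, say, an additional
subdomain from an insertion requires looking at the structure.

## Two-track length test

* **Large families** (at least `large_family_min = 10` members) use kernel
  density estimation on the SEQRES lengths. The density is a Gaussian
  mixture evaluated *exactly* on a regular grid spanning
  `[min − 3·bw, max + 3·bw]` with step `bw/10`; more than one peak flags
  the family. FFT-binned density estimators were deliberately avoided so
  that the implementation agrees bit-for-bit in peak count with a
  brute-force dense-grid scan, which the test suite verifies on hundreds of
  random mixtures.
* **Small families** use the ratio of the longest to shortest SEQRES
  length; a ratio at or above `ratio_threshold = 1.5` flags the family.

The bandwidth defaults to 10% of the family's median SEQRES length, floored
at 3 residues. A relative bandwidth is the natural choice here because a
20-residue spread means something very different in a 60-residue zinc
finger family than in a 600-residue beta-propeller family. The family-size
boundary, bandwidth rule and ratio threshold are genuinely free parameters
of the method; they live in `flag_config()` and are exposed on the command
line, so a curator can tighten or relax the screen without touching code.

## Peak definition

A peak is a strict local maximum of the gridded density, with plateau runs
collapsed to a single candidate. To suppress numerical ripple, a candidate
must rise above the higher of its two flanking valleys by at least 1% of
the curve maximum; endpoints of the grid are never peaks. Because the grid
extends three bandwidths beyond the data, boundary densities are
effectively zero and genuine modes are never clipped.

## Additional flags

Independent of the length tests, a domain whose ATOM length falls below
2/3 of its SEQRES length (`atom_deficit_fraction = 1/3`) is reported — a
large unobserved fraction can hide a fragment or a mis-assigned region —
and any family whose free-text metadata contains one of
*duplication, repeat, swap, fragment, circular permut* (case-insensitive
substring) is flagged for review, since legacy curation often recorded
heterogeneity only in comments.

Fragment candidates are listed relative to the family **median** SEQRES
length: a domain missing at least 1/3 of the median, in sequence or in
structure, is a candidate. The median, not the mean, is the reference
because the very outliers being hunted would drag a mean toward
themselves.

`validate_new_entry()` applies the same ratio and fragment rules to a
single candidate domain against its family's report, guarding manual
classification against typos in region bounds.

# RAF format choices

The byte layout — a 5-character chain key (PDB id + chain), a 2-character
flag field, then 7-character cells of a right-justified residue identifier
plus the ATOM and SEQRES one-letter codes — is declared in a single layout
table (`.RAF_LAYOUT`), so it can be adjusted to match released raf files
without touching parsing or query logic. Version 0.02 marks SEQRES residues
absent from the ATOM records with the legacy letters B/M/E (gap at the
beginning, middle, or end); version 0.03 carries a PDB-assigned residue
identifier in every cell, and `convert_v2_to_v3()` performs the upgrade
given an identifier assignment, refusing to guess when an assignment is
missing. Sequences are treated as canonical one-letter codes throughout:
post-translationally modified residues are assumed to be already
back-translated upstream.

# Terminal tag detection

Two evidence paths run independently and are merged by interval overlap:

* **SEQADV metadata**: a note whose description contains one of
  *expression tag, cloning artifact, purification tag, linker* and which —
  after merging adjacent qualifying notes — touches position 1 or the last
  SEQRES position becomes a call. The initiator methionine is deliberately
  not in the vocabulary: it is a natural residue. Qualifying notes in the
  chain interior are warnings, never calls.
* **UniProt comparison**: for chains with a DBREF cross-reference, the
  DBREF offset is extended to every SEQRES position; positions falling
  before the start or past the end of the UniProt sequence automatically
  mismatch. The maximal terminal run of mismatching positions is a
  putative tag if it is 1–9 residues long (strictly less than 10). The
  call is made only when the interior (non-tag) SEQRES matches the implied
  UniProt subsequence *exactly*, which doubles as a consistency check of
  the DBREF record itself.

Two policies here deserve justification. First, a terminus that partially
matches (e.g. three matching then four mismatching residues) is resolved by
the *maximal mismatching run* rule: the run ends at the outermost matching
position. Second, the interior comparison tolerates no substitutions, so an
engineered point mutant produces a diagnostic and no automatic call — a
deliberate conservative choice: a silent wrong trim is worse than a skipped
one. Mismatching terminal runs of 10+ residues are likewise reported as
diagnostics only; they are more likely a fusion partner or a wrong DBREF
than a tag.

`trim_domain()` excises called intervals from a domain's region with exact
residue bookkeeping through RAF (SEQRES indices to residue identifiers) and
emits each excised piece as an artifact-class domain record (sccs prefix
`l.`). Residues are conserved exactly: the trimmed SEQRES length plus the
artifact lengths equals the original, a property the tests check across
random scenarios.

# Variant-to-structure mapping

`map_protein_position()` chains two table lookups: UniProt position →
SEQRES index via the SIFTS pairs (validated to be strictly increasing in
both coordinates, so alignments cannot cross), then SEQRES index → ATOM
residue identifier via RAF. A position outside the mapped span is an
"unmapped" result, not an error, because incomplete SIFTS coverage is the
normal state of affairs. For a position in a disordered region the nearest
resolved residues are reported — both flanks when equidistant — since the
structural context of a loop variant is carried by its neighbours.
Classified domains containing the position, and their family siblings,
supply evolutionary context. When several chains carry the position, all
are returned in lexicographic chain order; ranking structures by quality
score is out of scope.

Everything upstream of the protein position — HGVS parsing, genome
coordinates, consequence prediction — is delegated to external tools, and
nothing here queries a network service.

# The synthetic fixture generator

`generate_release()` produces a miniature release in which every anomaly is
planted and recorded in a manifest, so detection can be scored against
ground truth. The defaults define the study conditions used throughout the
tests and the acceptance script:

* 20 families: 14 homogeneous (unimodal lengths, one mean drawn from
  80–250 residues per family, sd 3), 3 bimodal (modes 100 and 200, sd 3 —
  a mode separation far above four bandwidths, i.e. unambiguously
  bimodal), 3 small families with one 2× length outlier. Length noise is
  truncated at ±3 sd so a homogeneous family cannot wander across the
  ratio threshold by a freak draw.
* per-residue disorder probability 0.05, the scale of short unmodelled
  loops; enough to exercise the SEQRES/ATOM machinery without triggering
  the 1/3 deficit rule.
* 12 chains with planted mismatching terminal tags of length 1–9 (forced
  to differ from the UniProt flank at every position), 2 chains whose
  planted tag equals the flank — undetectable by any sequence comparison,
  and recorded as such — and 5 tag-free chains.
* sequences are uniform over the 20-letter alphabet, and PDB-like ids
  start with 8 or 9 to avoid colliding with real entries. Realistic
  residue composition is irrelevant to length- and match-based
  algorithms, and is not emulated.

The generator is a pure function of its seed: identical specs give
byte-identical bundles. What passing tests on these fixtures show is that
the algorithms implement their stated rules exactly and recover anomalies
of the planted kinds; what they cannot show is performance on real
releases, where heterogeneity can hide at equal lengths (a fold change
with the same residue count), SEQADV vocabularies are noisier, and DBREF
records can be subtly wrong. Those limits are inherent to the method, not
the fixtures: a length-based screen cannot see length-preserving
heterogeneity, and the authors of the screen plan structural comparison as
the remedy.

# Numerical and degenerate-input choices

* `kde_peak_count()` requires at least two values; singleton families are
  routed to the ratio test by the caller.
* `length_ratio()` rejects non-positive lengths; it is invariant under
  permutation and duplication of members.
* Region strings validate that a segment's start does not follow its end
  (numeric part, insertion codes carried but not ordered).
* Whole-entry regions (`"-"`) resolve to the single chain of the entry and
  error when the entry has several chains — guessing would silently
  misattribute residues.
* The two-letter heterogeneity codes are not standardised anywhere
  machine-readable, so `heterogeneity_codes()` ships a default registry
  (dv, sd, ie, fr, ms, ae, me, nd, hf, nt, ri) that can be replaced from a
  two-column file without code changes; unknown codes parse with a
  warning rather than failing, and whole-clade annotations may carry an
  empty sid list.
* dir.inc sid lists are comma-delimited inside the third tab-delimited
  column; dir.rep serialises the repeat unit as `start-end`, which is why
  negative author numbering is rejected by its writer.

# Problem sizes

The test suite and the acceptance script run entirely on generated data:
releases of 20 families (roughly 150–210 domains), 200 random KDE
instances against the brute-force oracle, 1000+ queries against the
linear-scan oracles, 100-record round-trips per format, and 100 random
trim scenarios. These sizes give exact, reproducible checks of every rule
at interactive runtimes; nothing in the algorithms is size-limited beyond
linear scaling in domains and residues.
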