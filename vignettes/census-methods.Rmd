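---
title: "Building a multi-evidence census of actin-associated proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a multi-evidence census of actin-associated proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aapcensus)
```

## The problem

Actin-binding proteins (ABPs) and the wider set of actin-associated proteins
(AAPs) regulate every step of actin dynamics — nucleation, elongation,
capping, severing, cross-linking, cargo transport. No single database
annotates them completely, so censuses of this kind are assembled by
integrating several imperfect evidence lines and keeping the provenance of
every call. `aapcensus` implements that integration as a reusable, testable
pipeline with three evidence lines:

1. **PPI partners**: proteins interacting with a curated query set of the six
   conventional human actins in scored interaction databases, each filtered
   at its own confidence threshold and restricted to physical interactions;
2. **Actin-binding domains**: proteins whose filtered, overlap-resolved
   domain architecture contains a classical ABD family (CH domain, villin
   headpiece, gelsolin repeat, ...);
3. **GO annotation mining**: proteins annotated with actin-related GO terms,
   either directly (protein-level annotation), through their domains
   (Pfam2GO), or through curated structure-derived and literature lists.

Evidence is unioned into one census entry per canonical accession, then
classified by membrane localization, lipidation, tissue-expression breadth
and COG functional category, and tested for term enrichment against the
whole-proteome background.

## Domain architectures

Domain hits come from a profile-HMM scan of the proteome (`hmmscan`-style;
the scan itself, with its sequence E-value 0.01 and model gathering cutoffs,
is upstream of this package — `read_hmmscan_domtblout()` ingests its
tabular output). Architecture assignment then applies two per-hit filters
and a resolution step:

* **independent E-value ≤ 0.001** — the per-domain significance of a hit
  considered on its own; the boundary value is retained;
* **model coverage ≥ 0.7** — the fraction `(hmm_to − hmm_from + 1) /
  model_length` of the profile spanned by the alignment; the boundary value
  is retained;
* **greedy overlap resolution** — when several models align to the same
  region, candidates are taken in ascending independent E-value and accepted
  iff their residue overlap with *every* already-accepted domain is at most
  **25 residues** (exactly 25 is allowed; 26 conflicts).

Numerical choices where the convention is genuinely open:

* *Coordinates.* Overlaps use alignment coordinates (not envelope
  coordinates), 1-based inclusive — the usual convention for architecture
  building; coverage uses model coordinates.
* *Tie-breaks.* Equal independent E-values are ordered by longer alignment,
  then smaller start, then family name, making resolution deterministic.
* *Pairwise tolerance.* The 25-residue tolerance is applied pairwise against
  each accepted domain, not cumulatively across neighbours — the simplest
  reading of "overlaps of up to 25 residues allowed".
* *Clan-blind resolution.* Overlaps within one Pfam clan are resolved by the
  same rule as cross-clan overlaps. Some annotation pipelines merge
  same-clan overlaps instead; a per-clan policy is left as future work.
* *Isoforms.* Every sequence (canonical or isoform) gets its own
  architecture; census-level counting collapses the `-N` accession suffix
  to the canonical accession.

The resolver's accepted set is *maximal*: every rejected hit overlaps some
accepted hit of lower-or-equal E-value by more than the tolerance. The test
suite checks this, plus exact agreement with an independently written naive
O(n²) implementation of the same greedy definition, on 1,000 random
instances of up to 12 hits.

## PPI evidence

The ten supported databases and their default thresholds
(`threshold_table()`):

| database | threshold | scale |
|---|---|---|
| STRING | score > 700 | 0–1000 |
| BioGRID, IntAct, MINT, mentha | score > 0.6 | 0–1 |
| HIPPIE | score > 0.73 | 0–1 |
| HitPredict | annotation > 0.5 AND method > 0.485 | 0–1 |
| DIP, HINT, HuRI | none (curated high-confidence) | — |

All thresholds are **strict** inequalities, read literally from their usual
published form ("> 700", "> 0.6"); an edge at exactly the threshold is
rejected. Only edges typed `physical` count (configurable per database via
`requires_physical`, since some resources expose a combined rather than a
physical-only score channel). The actin query accessions themselves are
excluded from the census by default: the census targets *associated*
proteins, and the treatment of actin–actin edges is a policy choice exposed
as `include_actins`.

## Classification rules

* **Localization** (disjoint classes, in precedence order): integral
  membrane if any of the `intramembrane` / `topological domain` /
  `transmembrane` annotations is present; else peripheral membrane if the
  subcellular-location text says so or the protein carries a lipid
  modification (farnesylation, myristoylation, palmitoylation,
  geranylgeranylation); else cytoplasmic on a cytoplasm/cytoskeleton
  location; else other. Integral wins over lipidation so that the class
  counts partition the census.
* **Tissue expression**: rows with `uncertain` reliability or
  `not detected` level are removed; breadth is the number of distinct
  tissues with a retained row, binned into 1, 2–5, 6–40 and >40 tissues.
  The middle 6–40 bin is introduced so the bins are exhaustive; breadth = 1
  is used as the operational surrogate for "enriched in a single tissue",
  since atlas-specific enrichment flags are not modelled.
* **COG**: multi-letter category strings are split one category per letter
  and mapped to four broad groups through the fixed 26-letter table
  (`cog_group_table()`); `S` (function unknown) and `R` count as poorly
  characterized.

## Enrichment

`enrich_terms()` is a hypergeometric upper-tail test (identical to a
one-sided Fisher test) of the census against the whole synthetic proteome
as background, with Benjamini–Hochberg step-up adjustment (`bh_fdr()`).
BH is the de-facto default of the enrichment services this replaces; the
conventional stringent reporting cutoff FDR ≤ 0.001 is the default
`fdr_max` of the pipeline. Terms with no background member are dropped
rather than reported at p = 1 — they are uninformative and would only
inflate the multiple-testing burden.

## The synthetic study

Because real censuses depend on versioned snapshots of UniProt, Pfam and
ten interaction databases, the package ships a generator that emulates
every consumed format with a *planted* ground truth, so the full pipeline
is testable offline. The default `simulation_config()` defines the
reference study:

* 500 proteins, of which the 6 conventional actins (curated query
  accessions) and **120 planted true AAPs**;
* evidence mix proportioned like a real census (73% of planted AAPs
  discoverable by PPI, 31% by protein-level GO annotation, 10% by ABD
  membership, 3.5% by Pfam2GO, ~1% structure-derived, 2% literature);
  sources are drawn independently, so most planted proteins carry one line
  and some carry several; any planted protein left without a source is
  given PPI evidence, so every planted AAP is recoverable (with an
  all-zero mix, plans simply stay empty);
* 45 tissues, so all four breadth classes occur (2% single-tissue, 53% in
  2–5, 40% in 6–40, 5% in >40 — proportions chosen to mirror the typical
  shape of atlas tissue-breadth distributions);
* 15% of non-actin proteins get a splice-isoform record, and a fifth of
  planted PPI edges attach to the isoform accession, exercising isoform
  collapsing;
* planted positive scores are drawn uniformly *above* each database's
  threshold and decoy scores uniformly below (or above with a
  non-physical type), so threshold strictness is testable from both sides;
  analogous controlled negatives are planted for the domain filters
  (E-value failures, coverage failures, and overlapping passing pairs
  whose resolution winner is forced).

What the generator deliberately does **not** emulate: biological sequence
content (residues are uniform random — nothing downstream reads them),
field-for-field download formats of the real databases, correlated
evidence (real PPI support correlates with GO annotation), and annotation
errors. Consequently, a perfect recovery on fixtures demonstrates the
*logic* of the integration — thresholds, filters, resolution, collapsing,
union — not robustness to the noise of real annotation databases. The
synthetic clan and Pfam2GO maps use synthetic identifiers (`CLS####`) and
keep the ABD and Pfam2GO family pools disjoint so each evidence line is
separately countable against the truth; the shipped ABD/GO curated lists
are starting points a user would replace with their own curation.

## Problem sizes and reproducibility

The reference synthetic study (500 proteins) runs in a few seconds; the
test suite repeats it across 20 seeds and checks that the census equals
the planted set exactly with per-source counts matching the ground-truth
recounts. Enrichment statistics are validated against exact tail
enumeration for all backgrounds up to N = 30 and a 500-replicate null
calibration. Identical configuration and seed give byte-identical output
trees; every file the pipeline writes is deterministic (timings go to the
message stream, never into files).

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
res <- run_pipeline(pipeline_config("inputs", "outputs", simulate = cfg))
res$summary
```

## Known limitations

* Structural (SCOP-style) domain vocabularies are not assigned; the
  architecture machinery is vocabulary-agnostic, so a second hit table can
  be run through the same filters, but no structure libraries ship with
  the package.
* Ortholog inference is upstream: the COG module consumes an assignment
  table, it does not compute orthology.
* The enrichment module tests user-supplied term maps; it ships no
  pathway/disease catalogs.
* Real-database idiosyncrasies (identifier cross-mapping, score channel
  selection in STRING, directional edges) are reduced to the generic edge
  dialect; users feeding real downloads must map them to it first.
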