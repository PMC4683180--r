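---
title: "Reconstructing the bioenergetics of nitrate-dependent methane oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the bioenergetics of nitrate-dependent methane oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanoredox)
```

## The biological problem

Anaerobic methanotrophic archaea of the ANME-2d clade
(*Methanoperedens*-like organisms) oxidize methane without oxygen by
running the methanogenesis enzyme chain in reverse and discharging the
eight electrons per CH4 onto nitrate, reducing it to nitrite. Building a
metabolic model for such an organism from sequencing data involves a chain
of small, well-defined computations: recovering the genome from a
metagenome assembly by gating contigs on GC content and coverage; scanning
the proteome for covalent heme-c attachment motifs to find the c-type
cytochromes that carry electrons across the wide redox span from CH4
oxidation (-244 mV) to nitrate reduction (+433 mV); calling homologs
against a reference proteome under explicit e-value/identity thresholds;
normalizing transcript counts to RPKM; and checking every proposed
electron transfer against standard redox potentials. `methanoredox`
packages that chain as composable, individually testable stages.

## The thermodynamic model

For an n-electron transfer from a donor half-reaction couple to an
acceptor couple, both at standard pH-7 potentials E0' (stored in mV,
exactly as tabulated),

deltaE0' = E0'(acceptor) - E0'(donor),
deltaG0' = -n F deltaE0',  F = 96.485 kJ mol-1 V-1.

A transfer is EXERGONIC when deltaG0' < 0, ENDERGONIC when > 0 and
ISOERGONIC within a numerical tolerance of 1e-9 kJ of zero (the tolerance
only matters for constructed zero cases; real potentials differ by whole
millivolts). Potentials are converted to volts only inside the free-energy
expression so printed table values remain exact. The engine is
antisymmetric under donor/acceptor exchange and linear in n, and both
properties are enforced by tests.

```{r headline}
couples <- default_redox_couples()
delta_g(8, get_couple(couples, "CO2/CH4"), get_couple(couples, "NO3-/NO2-"))
```

The packaged couple table holds the potentials the reconstruction uses:
NO3-/NO2- +433 mV, CO2/CH4 -244 mV, CoM-S-S-CoB/CoM-SH+CoB-SH -143 mV,
menaquinone -80 mV, methanophenazine -165 mV, F420 -360 mV and ferredoxin
about -500 mV. Which membrane carrier is present matters: thiol-derived
electrons (-143 mV) flow downhill to menaquinone but uphill to
methanophenazine.

```{r quinone}
thiols <- get_couple(couples, "CoM-S-S-CoB/CoM-SH+CoB-SH")
classify_transfer(thiols, get_couple(couples, "menaquinone"))
classify_transfer(thiols, get_couple(couples, "methanophenazine"))
```

### Coupled (confurcating) reactions

`coupled_reaction_dg()` sums branch free energies for electron
bi-/confurcation hypotheses, e.g. thiol oxidation (endergonic towards
F420) driven by ferredoxin oxidation (exergonic towards F420, deltaE0' =
+140 mV). At standard potentials the 2e + 2e confurcation totals about
+14.9 kJ/mol — slightly endergonic. The engine deliberately reports this
computed value instead of forcing a "favorable" classification:
standard-state potentials ignore physiological concentration ratios and
stoichiometry variants that could tip the balance, and an engine that
reports what the numbers say is more useful than one that encodes the
qualitative expectation.

### Electron and charge ledgers

`reverse_methanogenesis_ledger()` fixes the default carrier stoichiometry
per CH4 — 2 F420H2 (4 e-), 1 reduced ferredoxin (2 e-), 1 CoM-SH/CoB-SH
pair (2 e-) against 4 NO3- -> NO2- (8 e-) — and rejects any custom
stoichiometry that breaks electron conservation, naming the imbalance.
`pmf_balance()` then tallies signed translocated charges per CH4. Design
choices here:

- The methyl-transfer step (Mtr) is a fixed -2 charges **per CH4** (it
  imports 2 Na+ per methane), not a per-2e- pump, so it survives any
  routing change, including disabling all pumps.
- The F420H2 dehydrogenase default is the menaquinone-coupled upper bound
  of 3 H+/2e- (configurable down to 2); the Rieske/cyt-b Q-cycle
  translocates 4 H+/2e-.
- The membrane heterodisulfide reductase is routed but pumps 0 charges,
  and the nitrate reductase is disabled outright: whether either
  contributes to the gradient is an open biochemical question, so the
  conservative default is "no contribution". Routing electrons through a
  disabled pump is an error rather than a silent zero.
- Na+ and H+ are summed as indistinguishable charges because the A1AO ATP
  synthase of these organisms can plausibly use both gradients.

```{r pmf}
pmf_balance(reverse_methanogenesis_ledger())
```

## The cytochrome census

`scan_motifs()` tests every window position of a protein against
fixed-length patterns. Decisions that define the count semantics:

- **Overlaps allowed**, within and across classes: every CxxCH occurrence
  is a potential covalent heme attachment site, and the overlap policy
  makes an exhaustive window-enumeration oracle trivially definable (the
  suite compares scanner and oracle on 1,000 random sequences).
- The `x` wildcard positions accept any of the 20 standard residues —
  including C and H; only the anchor residues are exact. CXXCH and CXXXCH
  are counted as separate classes even when sharing a cysteine.
- Windows containing ambiguity codes (X/B/Z/U) or a stop (`*`) never
  match: attachment chemistry cannot be confirmed on an ambiguous residue.
- The multiheme flag is `n_cxxch >= 3` by default; summary percentages
  round half away from zero to whole percent; the abundance filter is
  strictly `RPKM > 500`.

All residue positions and signal-peptide spans are reported 1-based
inclusive. On the abundantly expressed cytochrome set of the organism this
census design reproduces the published summary statistics (70% multiheme,
maximum 21 CxxCH), which the acceptance tests verify from the printed
per-protein counts.

## Homolog calling and expression

Every threshold in a profile is strict (`<`, `>`), matching how the
criteria are stated. Two built-in profiles coexist because the source
analyses used different stringencies (`profile_genome_wide()`:
e-value < 1e-10, identity > 40%; `profile_table_strict()`: e-value <
1e-20, identity > 40%, query coverage > 90%); the profile name is recorded
in every call, and neither is hard-coded anywhere downstream. Query
coverage is computed from the single best-scoring aligned segment, the
simplest reading of "alignment covers X% of the query"; per-query
tie-breaking is lowest e-value, then highest bit score, then lexicographic
subject id, making calls invariant to input row order.

RPKM is `1e9 * reads / (length_bp * total_mapped)`. The default
denominator is the sum of the supplied count table (reads mapped to
annotated features) because the original pipeline's denominator convention
is not recorded; a `total_mapped` override supports library-level totals.
No claim is made that either mode reproduces the published per-gene RPKM
values exactly.

## Contig binning

Bins are inclusive axis-aligned boxes in (GC, coverage); the first gate
containing a contig wins, in gate order. The 500 bp length filter is
`>= 500` by default with a strict-greater flag, because "longer than
500 bp" in the genome description does not disambiguate the boundary.
`kmeans2_suggest_gates()` proposes gates by 2-means clustering in
(GC, log10(coverage + 1)) — the log transform reflects the multiplicative
nature of read depth — but gates are always expressed in linear coverage,
and cluster labels are ordered by gate coordinates so a fixed seed gives
identical output.

## What the synthetic data does and does not emulate

The generators produce proteomes with **exactly** planted motif counts
(backgrounds are scrubbed of accidental motif windows, and planted
instances are spaced at least 6 residues apart so no scan window spans two
of them), two-cluster contig sets with realized GC within 0.02 of target,
count tables whose realized RPKM matches targets up to integer rounding
(a filler gene pins the table total), and alignment tables with an exact
planted pass fraction, including boundary-valued hits that must fail under
strict thresholds. One global seed fans out to fixed per-stream sub-seeds,
so adding a generator call never perturbs earlier streams.

This exactness is deliberately unrealistic: real proteomes contain
chance CxxCH windows, real coverage is not Gaussian, and real alignments
are not one-hit-per-query. Passing the recovery tests therefore
demonstrates correctness of the *computations*, not robustness to the
noise structure of real sequencing data. Problem sizes in the suite (up to
1,000 random sequences for the scanner oracle, 200 contigs, 200 alignment
queries) were chosen as the smallest sets that exercise every code path
and tie-break.

## Full-scale reproduction

`reproduce_fullscale()` reruns the census, the 500 bp contig filter and
the NrfA heme-motif count on locally downloaded copies of the deposited
assembly (accession LKCM01000000); `accession_targets()` records the
expected values (87 CxxCH-containing proteins, 514 contigs, 5 heme motifs
in NrfA). These are accession-gated: they depend on the deposited
annotation's exact protein set and are not asserted by the offline test
suite.

## Known limitations

- Standard-state thermodynamics only; no Nernst concentration correction,
  kinetics, flux balance or ATP yield (no H+/ATP ratio is assumed).
- Binning uses only (GC, coverage); no tetranucleotide or
  differential-coverage signal.
- The census does not attempt structural validation of candidate
  cytochromes; expert curation of true vs. chance motif proteins is out of
  scope.
- Signal peptides and transmembrane helices are consumed from external
  predictor output, never predicted.
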