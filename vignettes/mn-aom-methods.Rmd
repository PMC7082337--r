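---
title: "Models and methods behind mnAOM"
author: "mnAOM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mnAOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnAOM)
```

mnAOM analyses bioreactor enrichments in which anaerobic methanotrophic
archaea oxidize methane with Mn(IV) oxides (birnessite) as the terminal
electron acceptor. This vignette documents the models, conventions,
parameters and deliberate design choices behind each module, and what
the synthetic-data tests do and do not demonstrate about real data.

## Geochemical mass balance

**Gas/liquid partitioning.** Total methane in a closed reactor is the
ideal-gas headspace amount $pV/RT$ plus the dissolved amount from
Henry's law, $c = k_H\,p$. The bundled default $k_H$ for methane near
295 K is `HENRY_CH4_295K` = 1.52e-3 mol L⁻¹ atm⁻¹, the Sander-compilation
298 K value temperature-corrected with
$\mathrm{d}\ln k_H/\mathrm{d}(1/T) = 1750\,$K. At a typical 0.9 atm
headspace this gives a dissolved concentration of ~1.37 mM. Any other
constant can be passed explicitly; the functions never hard-code it.

**Rates.** Consumption/production rates are ordinary least-squares
slopes of concentration against day over all points in the window
("average rate" is ambiguous between an OLS slope, an endpoint
difference, and a mean of interval rates; OLS is the default because it
uses all points of a sparse weekly design and is unbiased under
symmetric noise; `method = "endpoint"` provides the difference-quotient
alternative). Rates are reported as positive magnitudes with the
requested direction; a slope whose sign contradicts the requested
direction sets a flag rather than raising an error, because a flat
noisy series can legitimately fit slightly the "wrong" way.

**Mn(II) pools.** Extraction chemistry partitions reduced manganese
into dissolved, adsorbed and carbonate pools. `mnPoolSummary()` totals
them per timepoint and flags any timepoint whose dissolved fraction
reaches 3% (configurable), the conventional threshold below which the
dissolved pool is omitted from rate mass balances. Zero-total
timepoints yield `NA` fractions, not errors.

## Electron balance and stoichiometry

The central reaction is

$$\mathrm{CH_4(aq) + 4\,MnO_2(s) + 7\,H^+ \rightarrow HCO_3^- +
4\,Mn^{2+} + 5\,H_2O}$$

Carbon is oxidized from −4 to +4 (8 electrons donated per CH₄) and Mn
reduced from +4 to +2 (2 electrons accepted per MnO₂), so electron
conservation predicts 4 mol Mn(II) per mol CH₄.
`electronBalanceRatio()` computes this ratio from user-supplied
oxidation states and *also* cross-checks it against the stoichiometric
coefficient ratio, raising an inconsistency error on disagreement —
the two derivations are independent, so their agreement validates the
configured reaction. Element and charge balance are validated first
(the reaction above balances at charge +7 on each side); the first
unbalanced element is named in the error.

## In-situ Gibbs free energy

$\Delta G = \Delta G^\circ + RT\ln Q$ per mole of the designated donor,
with $R$ = 8.314462618×10⁻³ kJ mol⁻¹ K⁻¹ and $T$ = 295.15 K (22 °C) by
default.

**Activity convention.** Aqueous species take their molar concentration
as activity (unit activity coefficients — no Davies/Debye–Hückel
correction, a deliberate non-goal); solids and liquid water are fixed
at activity 1. The bundled condition set lists an MnO₂ suspension
concentration (8.27 mM) even though MnO₂ is a solid; under the default
convention it does not enter $Q$. `includeSolids = TRUE` lets such
entries enter $Q$ for sensitivity analysis. At the bundled reactor
conditions (CH₄ 1.37 mM, HCO₃⁻ 0.116 mM, Mn²⁺ 0.71 mM, H⁺ 10⁻⁷ M),
$Q \approx 2.15\times10^{35}$ and $RT\ln Q \approx +200$ kJ mol⁻¹.

**Formation energies.** No constant is hard-coded in the ΔG operation;
all come from a `ThermoTable` whose provenance label is mandatory. The
default table uses standard compilations (CODATA, Wagman 1982, Robie &
Hemingway 1995, Amend & Shock 2001 for CH₄(aq)) and offers two MnO₂
phases: crystalline pyrolusite (−465.1 kJ mol⁻¹) and an approximate
layered birnessite value (−453.1 kJ mol⁻¹, the default since birnessite
is the phase fed to such reactors). With the default table the reaction
is strongly exergonic at reactor conditions, ΔG ≈ −639 kJ mol⁻¹ CH₄
(birnessite) or ≈ −591 (pyrolusite). Published figures for this system
of around −383 kJ mol⁻¹ CH₄ imply a substantially different (and
unpublished) constant set; rather than tuning constants to reproduce a
target, the package keeps the table explicit and inspectable — swap in
your own `thermoTable()` (or a YAML config) to explore the sensitivity.
Either way the conclusion that Mn-AOM is thermodynamically highly
favourable is robust: every documented table/convention combination
stays below −300 kJ mol⁻¹ CH₄.

## MHC screen

A putative multiheme *c*-type cytochrome is a protein with ≥3 CXXCH
heme-attachment motifs (one motif ≈ one covalently bound heme *c*).
Choices:

* **Motif pattern** is exactly `CXXCH`; spaced variants (CX₃CH, CX₄CH)
  exist in nature but are excluded by default and available via the
  `patterns` argument.
* **Overlapping matches** are counted (lookahead semantics) — self
  overlap of CXXCH requires contrived sequences, and exhaustive
  counting is the unambiguous convention. Offsets are 0-based.
* **Domain evidence** (cytochrome-family hits from an upstream
  annotator) is recorded as corroboration but is *not* required for
  classification: domain-search internals are consumed as input tables,
  never recomputed, and conditioning the call on them would make the
  screen depend on an external tool's coverage.
* **Extracellular candidates**: signal peptide *and/or* extracellular
  localization, read as inclusive OR. Genes missing from the evidence
  table are treated as no-evidence with a warning.
* **S-layer fusion**: MHC status plus an S-layer domain hit.
* **Cluster context**: an MHC is in oxidoreductase-cluster context when
  a gene labelled as a menaquinone:cytochrome-*c* oxidoreductase
  component (b-type cytochrome, NrfD-like, 4Fe–4S ferredoxin,
  bc1/b6f-like) lies within 5 genes (gene-rank distance, same contig,
  strand-agnostic) — the window default is a judgement call, as typical
  operon spans are a handful of genes; it is an explicit argument.
* **Coordinates** are 1-based inclusive on disk (GFF3); the context
  logic operates on gene ranks, so no base-coordinate arithmetic is
  exposed.

## Expression (TPM)

$$\mathrm{TPM}_g = \frac{r_g\, r_l\, 10^6}{f\!l_g\, T},\qquad
T = \sum_g r_g\, r_l / f\!l_g$$

with $r_g$ reads mapped to gene $g$, $r_l$ the constant read length
(default 150 nt, as for 2×150 bp paired-end sequencing) and $f\!l_g$
the CDS length. $r_l$ cancels algebraically and is factored out of the
implementation, which makes read-length invariance exact rather than
approximate in floating point. TPM sums to 10⁶ by construction.

"Highly expressed" means TPM **strictly greater** than the median TPM
over **all** genes of the gene's genome, zeros included (the
conservative literal reading; ties at the median are not flagged, a
single-gene genome can never exceed its own median). Per-genome
expression fractions use the full-community TPM denominator. Counts are
taken as given — multi-mapping resolution is upstream and out of scope.

## Comparative genomics

BLAST is replaced at desk scale by global Needleman–Wunsch alignment
with BLOSUM62 and affine gaps (open 10, extend 0.5), via Biostrings; a
reader for precomputed tabular hits (`readHitsTable()`) is the import
path for real-data scale. Identity counts identical residue matches
over *all* aligned columns including gaps (published AAI tools differ
here; the denominator choice is documented rather than hidden).
Reciprocal best hits break score ties lexicographically, making results
deterministic and order-symmetric; pairs scoring below `scoreFloor`
(default 0) are discarded since unrelated proteins score negatively
under global BLOSUM62.

AAI is the unweighted mean of RBH pair identities (undefined — an
error, not 0 — with no pairs). MHC ortholog families are connected
components of the cross-genome RBH graph restricted to MHC genes: a
deliberate approximation of graph-clustering orthology tools
(OrthoFinder-style MCL is out of scope), adequate for family counting
but liable to chain paralogs into one family on large gene families.
Family-count matrices cluster under `ward.D2` (squared Euclidean
dissimilarities inside Ward's criterion), with rows pre-sorted
lexicographically so leaf order is reproducible; trees export as
Newick.

## Synthetic data: what it does and does not show

Generators are deterministic given a seed and every fixture carries a
truth table; round-trip tests compare pipeline output to that truth.

* **Proteomes**: background residues are drawn uniformly with cysteine
  down-weighted, then rejection-sampled to be strictly CXXCH-free;
  motifs are planted in non-overlapping 5-residue slots and re-checked,
  so motif recovery is *exact by construction*. Real proteomes have
  biased composition, spaced motif variants and partial genes — the
  exact-recovery result shows correctness of the scanner/classifier
  logic, not robustness to annotation noise.
* **Diverged pairs**: per-site substitution to a uniformly chosen
  different residue at rate $1-t$, no indels; expected identity $t$.
  Real divergence includes indels and rate heterogeneity, so AAI
  recovery here validates the aligner/RBH/AAI chain, not an evolutionary
  model.
* **Counts**: multinomial at fixed total reads (fixed-depth sequencing
  framing; Poisson would behave nearly identically at these depths)
  with per-gene probability ∝ TPM × length, the inverse of the TPM
  transform.
* **Reactor series**: linear trends with i.i.d. Gaussian noise (no
  error model is implied by weekly chemistry data; OLS recovery only
  needs symmetric noise), default design of 4 weekly points over 21
  days at rates 44.5 (CH₄ consumption) and 184.7 (Mn(II) production)
  μmol L⁻¹ d⁻¹, noise σ = 5 μmol L⁻¹, pool fractions
  dissolved/adsorbed/carbonate = 0.02/0.55/0.43 (dissolved kept below
  the 3% threshold), starting concentrations 2000 (CH₄) and 500
  (Mn(II)) μmol L⁻¹ — plausible magnitudes for a fed enrichment
  reactor. Birnessite feed events halve the dissolved pool from that
  day onward (adsorption onto fresh oxide), conserving the extractable
  total.

Problem sizes used in the test-suite simulations (e.g. 1000 seeds for
rate recovery, 10⁴ random sequences for the scanner oracle, proteomes
of tens of proteins for alignment-based checks) were chosen to make
sampling error comfortably smaller than the asserted tolerances while
keeping the suite quick to run routinely.

## Numerical choices and degenerate inputs

* $Q$ is accumulated in log space; reported both as $\ln Q$ and $Q$.
* All-zero count vectors are a degenerate-input error ($T = 0$), not a
  zero vector; empty proteomes yield empty reports; zero-total Mn
  timepoints yield `NA` fractions.
* Balance validation uses a 10⁻⁹ absolute tolerance on element/charge
  sums; the electron-balance cross-check uses the same.
* OLS on two points has residual SE 0 by convention (exact fit).
* Score/identity ties anywhere in RBH and clustering resolve
  lexicographically.

## Known limitations

No activity-coefficient or speciation modelling; no adsorption
kinetics; no de novo localization or domain prediction; no read
mapping or assembly; orthology is RBH-component approximation; AAI
values from different published tools can differ by a few points from
this implementation's convention on real data.
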