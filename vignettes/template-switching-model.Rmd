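---
title: "A concurrent-competition model of template switching and nontemplated addition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A concurrent-competition model of template switching and nontemplated addition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchsim)
```

## The system

MMLV-type reverse transcriptases can *template switch*: having copied an RNA
template to its 5' end, the enzyme jumps to the 3' end of a separate
template-switching oligo (TSO) and keeps synthesizing, producing a
first-strand cDNA flanked by known adaptors in one step. The same enzymes
also carry a terminal-transferase activity that appends *nontemplated*
nucleotides (NTA) to the cDNA 3' end. The textbook picture is sequential:
three nontemplated dCs are added, anneal to the rGrGrG 3' end of the TSO, and
switching follows. `switchsim` implements the alternative that the evidence
supports: NTA and template switching are **concurrent, competing processes**
at every post-template extension opportunity.

The model system is a defined 25-mer RNA template (constant 3' region, first
one or four positions randomized) carrying one of three 5'-end chemistries --
5'-hydroxyl, 5'-monophosphate, or an m7G cap -- reverse transcribed with a
TSO made of a 39-nt DNA body and three 3'-terminal ribonucleotides.

## The generative model

After the full template complement is synthesized (and, for capped
templates, after a possible cap-templated +C; see below), each *opportunity*
draws one event from a categorical distribution with weights:

* **addition** of base $b$: $\eta_b(\ell)\, c_b^{\alpha}$, where
  $\eta$ is the addition-propensity schedule (a row per current overhang
  length $\ell$, last row recycled), $c_b$ the relative dNTP concentration
  and $\alpha$ a concentration exponent;
* **switch**: $\kappa_{ts} \cdot s(\text{overhang}, \text{TSO})$, where the
  annealing score $s$ is the maximum over terminal overlap lengths
  $L \in \{0,1,2,3\}$ of the summed pair weights ($w_{gc}$ per G:C pair,
  $w_{at}$ per A:T/A:U pair; any mismatch voids that overlap), with $L = 0$
  contributing a *blunt* score $\kappa_{blunt}$ -- switching that requires no
  base pairing at all;
* **termination**: $\sigma$.

Only the order and identity of events matter for every observable treated
here (read structures, NTA strings, junction extras, switch counts), so the
competition is modeled as an embedded discrete chain rather than in
continuous time; none of the weights are physical rate constants.

A switch appends the 42-nt cDNA-orientation copy of the TSO
(`cdna_of_tso()`), logs the pre-switch overhang as the *junction extras*, and
re-enters the loop (concatemers), bounded by `max_switches`. A switch that
reaches the bound ends the molecule; this makes a 5'-biotinylated TSO
(`max_switches = 1`) yield products ending exactly in one cTSO copy, which is
how the intact-mass experiment is set up. Termination can also come from the
per-segment addition cap `max_nta` (default 10), and `sigma > 0` guarantees
halting when `max_nta = Inf`.

**Cap templating.** For m7G-capped templates, a +C is appended *before* the
competition loop with probability `cap_c_prob`. It is logged with a separate
`cap_templated_c` flag because it is arguably templated (by the cap
guanosine) rather than nontemplated, but it is included in the `nta_string`:
the sequencing assay physically reads it between the template complement and
the adapter, and the parser round-trip is defined against what the assay can
see. Whether cap templating and blunt switching are the right mechanistic
reading is deliberately left as parameters (`cap_c_prob`, `kappa_blunt`)
rather than asserted.

With a constant (1-row) $\eta$ and no TSO, the NTA string law is closed-form
geometric-categorical:
$P(b_1 \dots b_k) = p_{stop} \prod_i q_{b_i}$ with
$q_b = \eta_b c_b^\alpha / (A + \sigma)$,
$p_{stop} = \sigma/(A+\sigma)$, $A = \sum_b \eta_b c_b^\alpha$
(`nta_closed_form()`), and with an overhang-independent switch weight
$\lambda$ and `max_switches = 1` the switch probability is
$\lambda/(\lambda + \sigma)$. Both identities anchor the test suite and the
acceptance checks, together with the maximum-likelihood inverse
(`estimate_step_propensities()`): per-step frequencies over
`total steps = additions + molecules`, with binomial standard errors.

## Presets

`sim_preset()` ships one parameter table per 5'-end chemistry. The numbers
are calibration choices of this package -- the source measurements are
wet-lab quantities that a desk-scale simulator cannot derive -- chosen once
so the model reproduces the qualitative patterns characteristic of each
chemistry:

* `capped`: modal NTA length 3 with `CAA` the most frequent string (a
  cap-templated C, then adenosines), junction extras modally a single `C`,
  and the highest switching efficiency;
* `oh`, `p` (uncapped): modal NTA length 1 with no strong base preference and
  a substantial "-" (no addition) class; junction extras modally absent,
  i.e. uncapped switching is predominantly blunt in this calibration; overall
  efficiency below the capped preset.

A step-dependent $\eta$ schedule is needed for the capped table: a constant
per-step propensity gives a monotone (geometric) length law that cannot have
its mode at 3.

Two perturbation hooks reproduce the study designs at the model level:
`delay_steps` disables switching for the first opportunities while
termination continues (delayed TSO addition; efficiency falls monotonically),
and `dntp_conc` with $w_{gc} > w_{at}$ makes 10x dCTP raise, and 0.1x dATP
mildly raise, switching efficiency. Directions are properties of the model;
magnitudes depend on the calibration and are not asserted anywhere.

**A deliberate contrast.** Under this purely annealing-scored competition,
the rUrUrG TSO -- a perfect match to the dominant +CAA overhang -- switches
*at least* as well as rGrGrG (`analysis/05_ce_efficiency.R`). The
experimental observation is the opposite: rUrUrG is markedly inferior. The
model thus makes the argument quantitative: if overhang annealing drove
switching, a +CAA-matched TSO would excel; its failure in vitro points to
the cap-proximal event (the first +C, possibly with the cap stalling the
enzyme) as the driver. Users exploring that hypothesis can suppress late
capture via the `eta` schedule and `kappa_ts`.

## Library designs, parsing and profiling

`simulate_library()` assembles one read per molecule, with a truth table:

* `NTA` -- cDNA + App-DNA adapter (3' ssDNA ligation readout of NTA; no TSO);
* `JUNCTION` -- the cDNA of a template-switching reaction; non-switched
  molecules carry no cTSO and fail parsing, mimicking library dropout;
* `COMPOSITION` -- cDNA + geometric-length G run (terminal-transferase
  tailing readout of the randomized template positions).

The parser (`parse_reads()`) canonicalizes orientation against the 21-nt
constant-region complement, then extracts per design. Matching is
substitution-only -- the inserts are short amplicons and indel-bearing reads
fall into counted rejection categories (`NO_ANCHOR`, `NO_ADAPTER`,
`TRIPLET_MISMATCH`, `AMBIGUOUS`) rather than being dropped silently. Two
conventions matter:

* **Junction maximal assignment.** The three bases adjacent to the TSO body
  complement are always assigned to the TSO, so with rGrGrG a run `CCCC`
  parses as extras `C`. This is the only convention under which a
  cap-templated +C is recoverable from capped reads at all, and it makes the
  parse a pure function of the read.
* **Adapter match length.** The App adapter is matched on its first 15 bases
  with the shared mismatch budget (default 2). At 10 bases and 2 mismatches a
  random in-payload offset matches with probability about 4e-4, which
  visibly truncates long payloads; at 15 the false-match rate is below 1e-6.
  Both lengths are configuration (`adapter_match_len`).

Profiling reproduces the reported statistics: positional composition with
ratio-then-renormalize baseline normalization (`normalize_composition()`;
the identities `normalize(x, uniform) = x` and `normalize(x, x) = uniform`
hold exactly), NTA/junction string and length distributions stratified by
the first template base, with the 5% display filter applied to *reporting
only* (`string_freq_raw` always carries the unpooled law, and "-" is a
first-class category). Per-position renormalization was chosen because
per-position fractions are the displayed quantity; a global variant would
mix positions of different information content.

## CE and mass modules

`emit_ce_peaks()` bins molecules by cDNA length into a peak table;
`calibrate_sizes()` maps migration to size by piecewise-linear interpolation
through ladder knots (linear extrapolation at the ends -- chosen over
local-Southern sizing for transparency; the LIZ-120 fragment sizes ship as a
vendor constant). `classify_peaks()` assigns primer / extension /
TS-product / concatemer-k windows (42 nt per switch) and `ts_efficiency()`
is switched-product area over elongation-product area. The unextended primer
is excluded from the denominator by default, since the efficiency contrasts
switched against elongated products; the primer-inclusive variant is an
explicit flag because the printed formula is not stated anywhere.
Concatemer areas count once (molecule-level efficiency). With zero jitter
the CE path equals the molecule-level switch fraction exactly (to 1e-9 in
the tests).

`oligo_mass()` uses average residue masses (A 313.21, C 289.18, G 329.21,
T 304.20; water 18.02; HPO3 79.98 -- standard chemistry constants; a
monoisotopic table is selectable); `enumerate_compositions()` exhaustively
inverts a mass shift into all base compositions within tolerance (default
0.5 Da; near-isobars are all returned, never silently resolved) and
`rank_species()` resolves order-blind compositions into concrete strings via
sequencing priors. The characteristic +CAA shift, 915.60 Da, is unique
within 0.3 Da among compositions of up to six nucleotides.

## What the synthetic data does and does not show

The generator emulates the read *structures* of the three library designs,
the event logs of the competition model, uniform substitution errors, and
count-proportional CE peaks / exact theoretical masses with optional
Gaussian jitter. It does not emulate PCR amplification bias, ligation
sequence preference, quality-score structure, indels, RNase H activity,
premature mid-template termination, or instrument-level CE/MS artifacts
(dye mobility, baseline, charge-state deconvolution). Green tests therefore
certify the *internal consistency* of the model, parsers and statistics --
parsing inverts simulation exactly, estimators recover generating
parameters, orthogonal quantification paths agree -- not the wet-lab
magnitudes, which are measurements, not model outputs.

## Numerical and design choices

* Problem sizes: acceptance-style checks run at 10k reads per design for
  round trips, 50k molecules for closed-form and estimator checks (20
  replicates for CI coverage), 15-20k for pattern and monotonicity checks --
  large enough that 3-SE bands are decisive, small enough to run routinely.
* Reproducibility: every stochastic entry point takes an explicit seed
  (mandatory in run configs, never auto-generated); identical (config, seed)
  give byte-identical artifacts, checksummed in the run manifest.
* 0-based offsets and half-open intervals throughout the parser; all
  cDNA-side sequences in DNA alphabet 5'->3' in synthesis order (so `+CAA`
  reads literally as `CAA`), templates in RNA alphabet.
* The 39-nt TSO body and App adapter defaults are documented placeholders of
  the correct lengths (the concrete oligos are protocol configuration);
  every analysis here depends only on their lengths and on mass/sequence
  differences, not their identities.
* Degenerate inputs: empty overhang scores `kappa_blunt`; empty NTA payload
  is the "-" category, not a missing value; zero-baseline bases in
  normalization are flagged NA with renormalization and a warning;
  `sigma = 0` is accepted only with finite `max_nta`.

## Known limitations

Switching propensity depends on the template only through its 5'-end
chemistry, so the observed first-base (G > C $\approx$ A > U) efficiency
bias is not emergent -- it would enter as chemistry-and-base-specific
parameter tables. TSO-variant magnitudes reflect the annealing score, which
the data contradict for rUrUrG (see the contrast above). CE areas are
count-proportional and ignore length-dependent dye response. These are
modeling scope choices, not parsing or statistical limitations.
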