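---
title: "Layered N-glycopeptide identification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered N-glycopeptide identification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosearch)
```

# The problem

An N-glycopeptide couples two moieties — a peptide backbone and a glycan —
and a stepped-collision-energy (SCE) HCD spectrum carries evidence for both:
peptide b/y ions, intact-peptide-plus-glycan-remnant Y ions, and low-mass
oxonium (B) ions diagnostic of specific monosaccharides. Identifying the
glycopeptide behind a spectrum therefore means scoring two partially
independent hypotheses at once, and controlling error rates for both.

`glycosearch` implements this as a stack of layers over charge-deconvoluted
neutral-mass peak lists: a glycan-first candidate search, a closed-form base
score, a learned fragmentation layer (peak reliability plus predicted
relative intensities), site-specific glycome network smoothing, a relative
retention-time model that resolves quasi-isobaric composition/adduct
ambiguities, and target-decoy FDR control for the peptide, glycan, and joint
channels. Every layer is exercised end to end on seeded synthetic data
generated by the package itself.

# Glycan ladders without topologies

Enumerating fragments from glycan *structures* requires a topology database
and inflates the search space without fragmentation evidence to discriminate
isomers. The engine instead works at *composition* level. For a composition
covering the conserved N-glycan core, the peptide+Y ladder is:

* all rooted sub-structures of the canonical HexNAc2Hex3 core tree, flagged
  as *core* fragments, each optionally carrying one reducing-end dHex or
  Pent when those residues are present; and
* the full core extended by every sub-multiset of the remaining non-labile
  residues. NeuAc and NeuGc are treated as labile and never appended.

Fragments with equal masses are merged; Y0 (the bare peptide) is always
present. Compositions lacking the core — O-glycans in particular — fall back
to combination-only enumeration.

Because the ladder is semi-structured, a structure-level fragment count must
be *approximated* to normalize glycan coverage. With `n_g` the residue count
minus the sialic acids (minus one more when two or more fucoses are
present), the normalizer is

$$d_g = \max\left(\begin{cases} n_g \ln n_g & \text{dHex} > 0 \\ \tfrac12 n_g \ln n_g & \text{dHex} = 0\end{cases},\; n_g\right),$$

reflecting that core fucosylation adds a root-level branch that roughly
doubles the distinct fragment count. For `n_g` of 7 or fewer the
non-fucosylated branch collapses to `d_g = n_g`; for `n_g` below 2 we floor
`d_g` at 1 so coverage stays defined for one- and two-residue O-glycan
cores. Glycan coverage is then the number of distinct matched Y masses
divided by `d_g`, clipped to [0, 1], alongside an exact core-coverage
fraction.

The test suite checks this approximation against a brute-force topology
oracle: canonical complex, hybrid, and high-mannose trees of 5–14 residues
are fragmented exhaustively and their distinct composition masses counted.
We allow at most **three simultaneous glycosidic cleavages** per fragment in
the oracle. This is a physical assumption — multiply-cleaved products
become vanishingly rare under SCE — and it is also the convention under
which the envelope claim holds exactly: with unlimited cleavages the
fucosylated tri/tetra-antennary counts overshoot $n_g\ln n_g$, and with at
most two the non-fucosylated counts undershoot $\tfrac12 n_g\ln n_g$. Under
the 3-cleavage convention every fixture respects the upper bound, every
complex-type fixture respects the lower bound, and high-mannose structures
fall below it because their homogeneous arms collapse to few distinct
masses.

**Decoy glycans** reuse the target ladder with every fragment of glycan size
two or more shifted by an independent Uniform(1, 30) Da draw; Y0 and Y1 keep
their exact masses so a decoy match retains the same trivial baseline as a
target whose glycan is almost entirely eliminated. Shifts are drawn from a
deterministic per-(peptide, glycan) seed so searches are reproducible; the
seeding policy is ours, since only the distribution is prescribed by the
method.

# The base score

Matched fragments contribute `log10(intensity)` weighted by
$1-|\mathrm{ppm}/\mathrm{tol}|^4$, a quartic that forgives small mass errors
and zeroes out at the tolerance boundary. The peptide sum is scaled by
per-bond sequence coverage to the power $\gamma$; the glycan sum by
$\mathrm{coverage}_G^\alpha \cdot \mathrm{coverage}_{G,core}^\beta$. The two
are mixed linearly with weight $w$, plus two bias terms:

* a precursor mass-accuracy bonus
  $-10\log_{10}(1 - e^{-\Delta^2/2\sigma^2})$ with $\sigma$ = 5 ppm. We read
  the denominator as the Gaussian $2\sigma^2$ and floor the log argument at
  $10^{-3}$, capping the bonus at 30 for a perfect precursor match rather
  than letting it diverge;
* a signature-ion consistency term: an observed sialic-acid oxonium with no
  sialic acid in the composition is penalized by $10\log_{10}(1-r)$ with $r$
  its relative intensity (capped at 0.999 so a base-peak oxonium stays
  finite), and an expected oxonium absent (at or below 1% of base peak) by
  $10\log_{10}(1-\min(o/2, 0.99))$ for $o$ expected residues.

Defaults are $\alpha=0.5$, $\beta=0.4$, $\gamma=1$, $w=0.65$, 20 ppm
fragment and 5 ppm precursor tolerances. We use `log10` throughout all score
variants so that the model-layer scores reduce *exactly* to the base scores
when reliabilities and correlation terms vanish; the reduction identities
are asserted to 1e-9 on randomized matches in the test suite.

All masses are neutral: peaks are charge-deconvoluted, so b fragments are
residue sums, y fragments residue sums plus water, and the complement
identity $b_i + y_{n-i} = M_{peptide}$ holds exactly in the observed mass
space. Oxonium ions are likewise matched at their neutral residue masses
(the familiar protonated m/z values, e.g. NeuAc 292.1027/274.0921, are those
masses plus a proton).

# The learned fragmentation layer

Fragmentation behavior shifts with peptide length, glycan size, precursor
charge, and proton mobility (basic residue count versus charge), so models
are partitioned on those axes: 5 length bins ({<=10, 11–15, 16–20, 21–27,
>=28}), 2 glycan-size bins (n_g <= 9 / >= 10), 5 charge bins (1–4, >=5), and
3 mobility classes — 150 cells per glycosylation type. The bin edges are our
reference configuration chosen to realize that printed grid size.

**Reliability** ($\phi$) is a naive-Bayes posterior that a matched peak is a
genuine fragment, built from inter-peak relationship features: partners at
amino-acid residue-mass offsets, at the HexNAc offset (203.0794 Da) for
backbone series, at HexNAc/Hex/dHex offsets for Y series, and b/y
complements to the peptide mass. Each feature's likelihood ratio is
estimated with add-one smoothing from annotated spectra; partitions with
fewer than 50 spectra borrow their adjacent charge bins, and a global model
backs everything. Training considers annotated peaks plus unannotated peaks
at or above 0.1% of base peak — a noise floor standing in for an
intensity-rank rule whose literal reading ("rank below 1") is vacuous —
while inference imposes no restriction.

**Relative intensity** is modeled as a multinomial over each spectrum's
fragment group: observed proportions under a softmax of fragment features
(series, relative cleavage position and its square, basic-residue fraction,
cleavage-context flanks for the backbone; size terms, core flag, HexNAc
fraction, fucose flag for Y ladders). The fit is a damped Newton/IRLS on the
weighted multinomial log-likelihood — spectra weighted by log total matched
signal, peaks by reliability — with convergence at |ΔLL| < 1e-6 or 100
iterations, a ridge retry on singular Hessians, a small L2 penalty (1e-3)
that keeps sparse partitions bounded, and a uniform fallback when nothing is
identifiable. Y ladders are split into *ascending* and *descending*
direction classes by the rank correlation of intensity with glycan size
(ties default to descending, the majority class under SCE), with separate
coefficients per class and no adjacent-charge borrowing. Prediction resolves
a missing partition to the nearest fitted one by Manhattan distance on bin
indices, then to the global model.

The model layer enters the scores as: per-peak evidence reweighted by
$(\phi_i + 1)$ plus a flat $\phi_i$ bonus (peptide), shifted-Pearson
correlation terms between observed and predicted intensities, and for the
glycan score a reliability-times-correlation term scaled by the number of
non-trivial Y fragments (glycan size > 1) and gated by
$s(x) = \min(e^{3x-1}, 1)$ of peptide coverage — Y-ion evidence presumes the
backbone is right, so a poorly covered backbone cannot buy glycan credit.
Pearson correlations on fewer than 3 points or constant vectors are defined
as 0, the neutral value after the +1 shift.

# Site-specific glycome smoothing

Glycans at one site are not independent: biosynthesis relates them. The
package builds a graph whose nodes are the searchable compositions and whose
edges join compositions differing by exactly one residue, plus nine
rule-based biosynthetic neighborhoods (high-mannose, paucimannose, hybrid,
bi/tri/tetra-antennary, fucosylated, sialylated, both) with trapezoidal
membership weights; users may supply their own network as a text file. Per
site, observed glycan scores $y$ (confident identifications only) are spread
into priors $u$ by minimizing

$$\sum_{g\,\mathrm{obs}} (y_g - u_g)^2 \;+\; \lambda\,(u^\top L u + \lVert u - A\tau\rVert^2),$$

solved by block coordinate descent (both blocks are linear solves) to
relative tolerance 1e-8, with $u$ clipped at 0. We gate *both* regularizers
by $\lambda$ — a deliberate reformulation of the fixed-weight neighborhood
term — because it makes $\lambda$ the single smoothing dial with the clean
limit that $\lambda = 0$ returns the observations untouched and propagates
nothing. $\lambda$ is chosen by leave-one-observation-out error over
{0, 0.025, …, 0.2}; the hard cap at 0.2 prevents over-smoothing. The full
estimation machinery of the aggregate-glycome ancestor of this model is
richer; this objective is our documented stand-in honoring its contract
($\tau$, $A$, $\lambda$, $u_g$, the cap, and decoy parity).

$u_g$ is added to the glycan evidence *inside* the bracket, before the
coverage scaling, so an unsupported glycan (zero coverage) gains nothing.
Decoy glycans receive the target's $u_g$ for the same composition, and decoy
peptides resolve through the mirrored site registry to the target site's
model: the smoothing pathway cannot tell targets from decoys, which the
tests assert by symbol equality. No models are fit for O-glycosylation
sites.

# Retention-time modeling and quasi-isobaric revision

Glycoforms of one backbone elute near each other with composition-dependent
offsets. For every backbone with at least two identified glycoforms, a
reference RT and reference composition are the log-abundance-weighted means
over its identifications (log weights, because raw log-normal MS1
abundances let a single feature dominate the reference). Apex deviations are
regressed on signed monosaccharide-count and ammonium-adduct differences
within 8 overlapping RT bins (50% overlap, triangular blending), yielding
time-local minutes-per-residue coefficients. The fit iterates in two senses:
identifications sitting more than 2.5 robust scales off the consensus are
masked — judged against *leave-one-out* references so a misassignment cannot
drag its own reference toward itself — and the model refit; then backbones
not yet covered whose compositions lie within L1 distance 2 of covered ones
are anchored with model-predicted references, to a coverage fixpoint (at
most 10 rounds). The per-bin residual scale is 1.4826 × the median absolute
consensus residual.

The RT agreement score is $\max(0, 1 - 2|r|/\mathrm{span})$: the probability
that a uniformly random time lands within the observed residual of the
prediction is $2|r|/\mathrm{span}$, so a score of 0.75 corresponds to a 25%
chance match — the closed form realizing that gloss.

**Revision.** NeuAc+NH3 and Hex+dHex differ by ~0.0112 Da — within 5 ppm
above ~2.25 kDa — so a sialylated, ammonium-adducted glycopeptide can be
recorded as a fucosylated unsialylated one. The default rule family is this
swap and its inverse (mass closure asserted at registration); pure adduct
add/remove is handled by the parsimony pass over MS1 feature groups, not by
revision. For each covered identification, the identity competes with every
applicable rule-mapped candidate; the minimum-|residual| candidate wins only
if it improves on the identity by more than twice the local residual scale,
diagnostic-ion evidence does not contradict it (removing the last NeuAc is
vetoed when the NeuAc oxonium is present above 1% of base peak; adding the
first NeuAc is vetoed when it is absent), the revised composition exists in
the search space, and an optional FDR guard accepts. Revision records
provenance and is idempotent. Predictions during revision use leave-one-out
references excluding model-masked outliers, for the same self-absorption
reason as above.

# FDR control

Peptide q-values come from a Percolator-style semi-supervised loop: initial
direction is the peptide score; for three rounds, targets at q <= 0.01 train
a linear max-margin classifier (C = 1) against all decoys on the features
(peptide score, peptide coverage, and the linear correlation term
$(\rho+1)\,m_p\,\mathrm{coverage}_P$ when a fragmentation model is in play),
and decision values rescore everything. Counting q-values use
(decoys + 1)/targets with monotonization. Fewer than 20 decoys falls back to
score-only counting with a warning.

Glycan q-values use decoy-glycan counting on the glycan score, with an
optional Gamma fit to the decoy distribution that smooths the sparse
high-score tail (off by default). Compositions of three or fewer residues
produce too few Y ions for the estimate to mean anything: their glycan FDR
is flagged undefined and they are excluded from glycan-thresholded lists.
The joint FDR is the inclusion–exclusion combination
$f_P + f_G - f_P f_G$, falling back to $f_P$ (flag propagated) when the
glycan channel is undefined. Decoy and target candidates flow through
byte-identical scoring code.

# The search engine

Candidates are generated glycan-first: for each ammonium mass shift (0–2 ×
17.0265 Da by default), the sorted glycan mass index is scanned for
compositions whose complement hits a peptide mass at 5 ppm. Surviving pairs
are pre-ranked by a cheap count — matched core Y masses plus matched
top-ten-intensity backbone peaks, our choice for the ranking the cap needs —
and truncated to k = 70 per shift. Each retained target pair then spawns its
decoy-glycan twin, and decoy peptides (whole-protein reversals retaining
glycosites at mirrored positions) enter symmetrically. Every spectrum is
reported at most once: its best-scoring candidate across all channels.

# The synthetic study conditions

The generators emulate exactly the structures the engine consumes, and their
defaults are the package's fixed study conditions:

* **Spectra** (`simulate_spectra`): each glycopeptide emits its full b/y
  series and peptide+Y ladder with intensities drawn from configurable
  softmax models (the same feature spaces the learner fits, so parameter
  recovery is well-posed), oxonium ions when sialylated (8% of total
  signal), multiplicative log-normal peak noise (sdlog 0.3), Poisson noise
  peaks (mean 30), 0.5 ppm precursor and 2 ppm fragment mass errors, charges
  2–4, and one ammonium adduct at rate 0.3. Backbones are random tryptic
  sequences of 9–16 residues with a planted sequon and occasional internal
  proline or missed-cleavage K/R, so every cleavage-context feature of the
  intensity model actually occurs. Truth tables and per-peak labels record
  every origin.
* **LC runs** (`simulate_run`): apex RTs follow a linear composition model
  (defaults: Hex +0.5, HexNAc +0.3, dHex −0.3, NeuAc +2.0 min per residue;
  NH3 −0.8 min; noise sd 0.1 min over a 120-min span), optionally with
  linear coefficient drift; a configured fraction of sialylated+adducted
  identifications is recorded under the NeuAc+NH3 → Hex+dHex swap with truth
  labels.

What passing tests on these conditions shows — and what it does not: the
layers are internally consistent, recover their own generating parameters,
and control error on calibrated score populations. The generator does not
emulate co-isolating precursors, deisotoping artifacts, missing fragments
from poor activation, shared peaks between moieties, or real chromatographic
tailing; performance on real data depends on those, and the engine's
preprocessing (deconvolution) is explicitly out of scope.

Problem sizes used by the checks, chosen as the package's study scale: 500
annotated spectra for intensity-parameter recovery; 480 identifications for
RT-coefficient recovery (sized so the rare-dHex contrast has standard error
well under the 0.1-min tolerance); three replicate 360-identification runs
at 10% planted swap rate for revision (replicate pooling mirrors the
multi-replicate design such experiments use and keeps binomial noise on the
correction rate small); 20 seeded simulations for FDR calibration; and a
200-glycopeptide benchmark (40 backbones × 5 glycoforms, trained on a
disjoint 240-spectrum run) searched with every layer enabled for end-to-end
recovery at 1% joint FDR.

# Numerical choices and degenerate inputs

* Uniform decoy shifts are per-fragment independent, seeded per
  (peptide, glycan) pair.
* `n_g` floors at 0 and `d_g` at `max(n_g, 1)`.
* Pearson correlation on < 3 points or zero variance is 0 everywhere.
* The mass-accuracy log argument floors at 1e-3 (cap +30); the unexpected-ion
  relative intensity caps at 0.999.
* Intensity fits: ridge 1e-4 on singular Hessians, L2 penalty 1e-3, step
  halving on non-improving Newton steps, uniform fallback on degenerate
  (single-fragment) training.
* The smoothing solve special-cases λ = 0; τ uses a QR solve with
  rank-deficiency handled by zeroing undetermined coefficients.
* Empty spectra, empty digests, uncovered backbones, and all-decoy inputs
  all return well-defined empty/NA results rather than errors.

# Known limitations

* O-glycan scoring shares the N-glycan code paths (combination-only ladders)
  but has no site-localization scoring and no smoothing by design.
* The Gamma tail smoother assumes positive decoy scores and falls back to
  counting otherwise.
* The semi-supervised rescorer uses a fixed C = 1 and three iterations for
  determinism; no per-dataset hyperparameter search.
* mzML/raw input is out of scope; the MGF dialect with the `CHARGE=0`
  neutral-mass sentinel is the package's interchange format.

# A minimal session

```{r example, eval = FALSE}
library(glycosearch)

pr <- simulate_proteins(10, seed = 2)
cfg <- sim_config(n_backbones = 10, glycoforms_per_backbone = 4, seed = 1)
sim <- simulate_spectra(cfg, backbones = pr$backbones)

space <- build_search_space(pr$proteins, default_glycans())
res <- search_run(sim$spectra, space, search_config(seed = 1))

merged <- merge(res, sim$truth, by = "scan_id")
mean(merged$peptide.x == merged$peptide.y &
       merged$glycan.x == merged$glycan.y)
```
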