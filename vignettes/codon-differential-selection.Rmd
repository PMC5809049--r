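---
title: "Differential selection and dN/dS codon models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential selection and dN/dS codon models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(codonDS)
```

## The problem

Repeated evolutionary transitions into a new selective regime — the textbook
example being C3 plants repeatedly giving rise to C4 lineages, each time
re-tuning the Rubisco enzyme — leave a molecular signature that is *not* the
classical signature of positive selection. Instead of an elevated
non-synonymous/synonymous rate ratio (dN/dS), convergent directional
selection produces repeated substitutions toward the *same* amino acids at
the *same* sites, specifically on the branches that experienced the
transition. `codonDS` implements two Bayesian codon-model families designed
to separate these signals on a fixed phylogeny:

* **DS (differential selection) models** — mutation-selection codon models
  in the Halpern-Bruno tradition, with an amino-acid fitness profile per
  site *and per branch condition*; and
* **OM (omega) models** — Muse-Gaut style codon models with a dN/dS value
  per site (OM1) or per site and condition (OM3).

Both share one partition machinery that paints every branch of the tree
with a condition index derived from tip phenotypes, one MCMC engine, and
one posterior decision layer.

## The substitution models

All models run on the 61 sense codons of the standard genetic code; stop
codons are excluded from the state space and mutations into them are
treated as absent. The mutation process is a general time-reversible
nucleotide model shared by all sites and branches: exchangeabilities
$\rho$ (pair order AC, AG, AT, CG, CT, GT) and equilibrium frequencies
$\pi$, giving off-diagonal rates $Q_{n_1 n_2} = \rho_{n_1 n_2}\pi_{n_2}$.

**DS models.** Selection acts only on the encoded amino acid. For site $i$
and condition $k$, a 20-vector of fitness values $F^{ik}$ defines the
scaled selection coefficient of a mutation from codon $c_1$ (amino acid
$a_1$) to $c_2$ (amino acid $a_2$),
$S = \log\!\left(F^{ik}_{a_2} / F^{ik}_{a_1}\right)$, and the relative
fixation probability of diffusion theory, $S / (1 - e^{-S})$. Codon pairs
differing at one nucleotide exchange at the mutation rate times this
fixation factor (times 1 for synonymous pairs); pairs differing at two or
more positions have rate zero. The stationary distribution of this process
has the closed form $\propto \pi_{c,1}\pi_{c,2}\pi_{c,3} F^{ik}_{aa(c)}$,
which the package uses both for root-state priors and as the reference in
detailed-balance tests. A useful internal property checked by the test
suite: at mutation-selection balance, the realized dN/dS of a DS process is
always below 1.

**OM models.** The rate of a non-synonymous single-nucleotide change is the
mutation rate times $\omega^{ik}$, the site/condition dN/dS; synonymous
changes occur at the mutation rate.

**Conventions chosen where the formulation leaves freedom:**

* $Q$ is normalized so the neutral process has one expected substitution
  per nucleotide site per unit branch length; branch lengths are read in
  those units. This fixes the non-identifiable common scale of the
  exchangeabilities.
* Fitness profiles are stored simplex-normalized (the process is invariant
  to per-profile rescaling, so the normalization is a gauge choice).
* The gamma distribution of the $\omega^{ik}$ random effects is
  parameterized by **shape $\alpha^k$ and scale $\beta^k$** (mean
  $\alpha^k\beta^k$) — not shape/rate.
* The fixation factor uses the Taylor expansion $1 + S/2 + S^2/12$ for
  $|S| < 10^{-4}$, avoiding the $0/0$ at neutrality; the switch is
  checked to be $C^1$-smooth by finite differences.
* The root-state prior at each site is the stationary distribution of the
  generator of a designated root condition (condition 0 by default). Root
  terms are carried through every conditional update that they involve.

## Branch-condition partition

Given a taxon-to-phenotype map, maximal phenotype-pure clades are
identified (pure clades not nested inside larger pure clades; a lone
derived tip is its own maximal clade). Each clade's branches *and its
subtending (basal) branch* are assigned the clade's condition:

* `ds3` (K = 3): ancestral/interior branches are condition 0, pure C3
  clades condition 1, pure C4 clades condition 2;
* `ds2` (K = 2): pure C4 clades (with basal branches) are condition 1 and
  everything else is condition 0, i.e. a parsimony-style reconstruction
  assuming irreversible C3-to-C4 transitions.

Unrooted input trees are rooted deterministically at the midpoint of the
first edge descending from the basal multifurcation; the allocation runs on
the rooted tree (maximality can depend on rooting, so determinism matters
for reproducibility). The two schemes provably agree on the C4 branch set,
which the test suite checks on random labeled trees.

## Priors

Branch lengths are iid Exponential with mean $\lambda$;
$\lambda \sim$ Exponential(mean 0.1); exchangeabilities iid
Exponential(mean 1); mutational frequencies uniform Dirichlet; fitness
profiles iid uniform Dirichlet over 20 amino acids; $\omega^{ik} \sim$
Gamma($\alpha^k$, $\beta^k$) with $\alpha^k, \beta^k \sim$
Exponential(mean 1). The tree topology is fixed throughout.

## The sampler

The posterior is explored by data augmentation: the latent substitution
history of every site is alternately (a) resampled exactly, conditional on
tip codons and current parameters, and (b) held fixed while all parameters
and random effects undergo Metropolis-Hastings updates whose acceptance
ratios only involve simple sufficient statistics of the history (per-state
dwell times, per-pair substitution counts, per-branch event counts).

**Stochastic mapping.** Per site, a pruning pass computes partial
likelihoods using a symmetrized spectral decomposition of each
site/condition generator (every DS/OM generator is reversible, hence
symmetrizable by $\mathrm{diag}(\sqrt{\pi^*})$ where $\pi^*$ is its
stationary distribution). Node states are then drawn top-down, and each
branch path is drawn by uniformization-based endpoint-conditioned sampling
with uniformization constant $\mu = 1.05\,\max_c |R_{cc}|$: the number of
jumps of the uniformized chain is drawn from its exact conditional
distribution, intermediate states from the corresponding Markov bridge,
jump times as uniform order statistics, and virtual jumps are compressed
out. The required powers $(B^n)_{ab}$ of $B = I + R/\mu$ are accumulated by
repeated multiplication with $B$ itself rather than through the spectral
form: $B$ is elementwise non-negative, so the recursion cannot suffer the
catastrophic cancellation that signed spectral sums exhibit at larger
powers, and the stored power vectors double as the bridge distribution. The test
suite validates this sampler against an independent oracle: rejection
sampling of forward Gillespie paths conditioned on the same endpoints.

**Update schedule.** One "sweep" = one MCMC draw. The mapping is refreshed
every second sweep by default (`map_every = 2`); between refreshes the
stored history is reused — with dwell times rescaled proportionally when
branch lengths change, so all conditionals remain exact. This mirrors the
classic alternation of one mapping with a long series of conditional MH
updates, and roughly halves the cost per draw (the spectral decompositions
dominate). Per sweep:

* fitness profiles (DS) or $\omega$ values (OM), per site and condition:
  a kernel mixture of two Dirichlet-centered random walks (concentrations
  `delta_hi`, `delta_lo`) and an *independence draw from the prior*; the
  independence component is what guarantees global mixing (pure local
  Dirichlet walks measurably fail prior-recovery tests);
* branch lengths: per-edge multiplicative log-normal moves (the
  conditional targets factorize across edges given the mapping; the
  event-time density contributes the $t^{n}$ Jacobian);
* $\lambda$, exchangeabilities, frequencies: log-normal and
  Dirichlet-centered moves against exact conditional likelihoods expressed
  through 4x4 aggregate statistics;
* OM hyperparameters $\alpha^k, \beta^k$: log-normal moves.

Proposal scales adapt toward 20-50% acceptance **during burn-in only**
(default 400 sweeps, user-overridable), so the post-burn-in chain is a
fixed-kernel Markov chain. All randomness flows through R's RNG: seeded
runs are bit-reproducible, and a full analysis runs two chains with seeds
$s$ and $s+1$.

**Diagnostics.** Per scalar statistic the package reports the effective
sample size (Geyer initial-positive-sequence truncation of the
autocorrelation sum) and the between-chain discrepancy
$|\bar x_1 - \bar x_2| / s_{\text{pooled}}$, the convention of the
`tracecomp` tool familiar from phylogenetic MCMC practice.

## Posterior decision rules

For DS fits, the differential effect of amino acid $a$ at site $i$ between
conditions $k_1$ and $k_2$ is $D = \log(F^{ik_2}_a / F^{ik_1}_a)$,
computed per posterior draw; the package reports its posterior mean and
the posterior probabilities $pp(D>0)$ and $pp(D<0)$, calling a direction
when either exceeds 0.90 (configurable). Draws exactly at zero count as
not exceeding. For OM fits, sites are flagged under positive selection in
condition $k$ when $pp(\omega^{ik} > 1) > 0.90$. The unified site report
takes the union of called sites across analyses and mirrors the columns of
a model-comparison inventory; `logo_matrices()` exports absolute
(posterior-mean profile of a reference condition) and differential
(posterior-mean $D$) per-site 20-vectors for logo rendering tools. Under
the three-condition scheme the default contrast is C4 versus C3
(conditions 2 versus 1); internally conditions are always numbered
0..K-1, with labels carried alongside so reports are self-describing.
Reported site coordinates add a configurable offset (e.g. 21 when an
alignment begins at residue 22 of the published protein numbering).

## The synthetic-data generator

`simulate_alignment()` is an exact event-driven (Gillespie) simulator of
the DS/OM processes along a conditioned tree — event-driven rather than
endpoint sampling because tests need full histories (realized dN/dS by
counting, per-branch event counts, time-reversal checks). The root codon
of each site is drawn from the root condition's stationary distribution.

`make_benchmark_fixture()` provides three standard presets. Their design
emulates the *structure* of a convergence study while remaining a
controlled benchmark; the choices and their reasons:

* **Topology** (`ds3-small`): 20 taxa as ten C3 and ten C4 *single-tip
  maximal clades* alternating along an interior backbone — the extreme
  form of repeated independent origins of the derived condition. Clades of
  several tips share their history, so fewer, larger clades give strongly
  correlated realizations in which a single early fixation can erase the
  condition contrast at a site; many independent origins is both the
  cleanest emulation of convergent evolution and the statistically
  best-behaved design.
* **Branch lengths**: terminal (condition) branches of 3.5 expected
  neutral substitutions per nucleotide site and short backbone segments
  (0.15). Terminals must be long relative to the relaxation time of the
  selected amino-acid pair, or tip states simply inherit the backbone
  state and carry little condition signal. This makes the fixture a
  deeply diverged alignment; that is deliberate and documented rather
  than an imitation of any particular empirical dataset.
* **Injected effects**: 4 sites with a swap of a two-amino-acid preference
  between C3 and C4 of magnitude $|D| = \log 4$ per amino acid; the pairs
  (T/A, K/E, N/D, H/Y) are single-nucleotide, *transition-coupled*
  neighbours with balanced codon counts, so the two states exchange
  quickly and neither is favoured by codon multiplicity. The pair holds
  99.9% of the profile mass; the 18 background amino acids share 0.1%.
  Background mass matters more than it looks: background states are
  mutually *neutral*, so a rare excursion (or a root draw) into the
  background can wander across the whole tree, and background codon
  multiplicity (about 50 of 61 codons) amplifies small per-amino-acid
  fitness into visible stationary mass.
* **Null sites**: 96 sites share one strongly concentrated profile
  (spiky Dirichlet draw) across all conditions, emulating the
  near-invariance of most positions of a conserved enzyme. Diffuse null
  profiles would be *correctly* flagged as differentially selected
  whenever the two conditions realize different compositions by chance —
  a property of the model, not an error — so a benchmark that wants null
  sites to stay silent must make them conserved, as real slowly evolving
  proteins are.
* **Mutation model**: transition/transversion exchangeability ratio 2 with
  uniform base frequencies (keeping codon-product effects symmetric
  across the injected pairs).
* **Omega presets**: `om1-small` uses background $\omega = 0.2$ with five
  sites at $\omega = 4$; `neutral` has $\omega = 1$ everywhere as a
  false-positive control. Both use the same topology but *much shallower*
  terminals (0.4): dN/dS likelihoods flatten once branches saturate, so a
  tree deep enough for the DS benchmark leaves $\omega$ unidentifiable
  beyond about 1 and the empirical gamma prior then shrinks true
  positives away. Depth that helps one model family can disable the
  other — one reason the two families see different site sets on real
  data too.

What the generator does **not** emulate: alignment gaps and ambiguity,
mutation-rate variation across sites or lineages, selection on codon
usage, phenotype evolution (conditions are painted on branches, not
evolved), indels, or the shallow divergence of a within-family dataset.
Passing the recovery tests therefore demonstrates correctness of the
inference machinery under the model's own assumptions at benchmark depth,
not performance on any particular empirical alignment.

## Numerical choices and degenerate inputs

* Spectral decompositions use the symmetrized form; uniformization series
  are truncated at $\mu t + 12\sqrt{\mu t + 1} + 40$ terms with
  clamping of tiny negative round-off values.
* Dirichlet-centered proposals that land below $10^{-12}$ in any
  component are rejected outright (numerically degenerate region of
  measure effectively zero under all targets of interest).
* Zero-length branches are valid: they contribute no substitutions and
  their states are forced equal across the branch; their lengths are
  excluded from multiplicative updates.
* Codons containing gaps or ambiguous nucleotides are masked; a fully
  masked alignment is legal and turns the sampler into a prior sampler
  (which the test suite exploits for prior-recovery checks). In-frame
  stop codons, taxon-set mismatches between alignment/tree/phenotypes,
  duplicate names, and missing branch lengths are hard errors raised
  before any sampling.
* Thinning defaults: scalar trace every sweep; random-effect fields every
  10th sweep (`ef_thin`) — the fields dominate memory, and posterior
  probabilities at the 0.90 threshold are insensitive to this cadence.

## Problem sizes used by the test suite

The suite sizes its statistical checks to run on one CPU in well under
half an hour as a deliberate scope choice: prior recovery uses a 4-taxon
masked alignment with 24,000 sweeps; simulation-based calibration uses 48
replicates of a 5-taxon, 10-site two-condition model with 360-sweep
chains (rank statistics over 23 thinned draws, chi-squared uniformity at
alpha 0.01); benchmark recovery runs the `ds3-small` preset with two
3000-sweep chains; dN/dS-at-balance and stationarity oracles use
4,000-10,000 simulated sites. The full-scale reproduction of a published
179-taxon analysis (6000 sweeps, two chains, three model families) ships
as `inst/scripts/reproduce_amaranthaceae.R` and needs the original
supplementary data plus hours of compute; it is an integration run, not a
test.

## Known limitations

* The topology is fixed; there is no tree search, no reversible-jump over
  the number of conditions, and no parallel tempering.
* The mutation process is homogeneous across sites and lineages by model
  assumption.
* Site/condition random effects are iid under the prior; there is no
  pooling across conditions at a site, so weakly informed profiles shrink
  to the uniform Dirichlet rather than to each other. At realistic data
  sizes this makes single-condition fitness estimates diffuse; the
  decision layer works on contrasts, which are better identified.
* The uniform Dirichlet prior on profiles is weakly informative in
  20 dimensions; with few substitutions per site, posterior probabilities
  rarely become extreme — the 0.90 decision threshold should be read with
  that conservatism in mind.
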