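---
title: "Inferring selection from polymorphism and divergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection from polymorphism and divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfemap)
```

# The problem

Polymorphism within species and divergence between species carry
complementary information about natural selection on protein-coding genes.
A gene under widespread constraint with occasional adaptive change can look
unremarkable by divergence alone (dN/dS well below one) and by polymorphism
alone; the contrast between the two — the logic of the McDonald–Kreitman
test — reveals the excess of amino-acid substitutions over what segregating
variation predicts.  `dfemap` implements a joint population-genetics /
phylogenetics model of codon evolution that performs this contrast
site-by-site in a fully probabilistic way: ancestral states are inferred
probabilistically rather than by parsimony, allele frequencies contribute
information, more than two alleles per site are handled natively, and the
output is a posterior distribution over a discrete grid of population-scaled
selection coefficients for every codon on every lineage, together with the
genome-wide distribution of fitness effects (DFE) per lineage.

# The model

## Codon state space and mutation

The alleles at a codon site are the $K = 61$ sense codons; stop codons are
treated as inviable and removed from the state space entirely (they also do
not enter the normaliser below).  Mutation follows a codon-level analogue of
the HKY85 model: single-nucleotide neighbours $i \to j$ mutate at
population-scaled rate
$$ r_{ij} = \frac{\theta}{2}\,\frac{\kappa^{\mathbb{1}[\text{transition}]}}{C}, $$
where $\theta = 2 P N_e \mu$ is the per-codon scaled mutation rate, $\kappa$
the transition:transversion ratio, and $C$ normalises the mean exit rate
under the uniform codon distribution to $\theta/2$ per $P N_e$ generations
($P$ is the ploidy of the compartment analysed, e.g. 1.5 for an X
chromosome).  No base-composition parameters are introduced, so the
stationary distribution over codons is uniform.

## Selection: the recurrent hot-or-not model

Fitness is measured relative to the ancestral allele: every derived allele
encoding an amino acid different from the ancestral codon's ("hot" alleles)
shares the scaled selective advantage $\gamma = 2 P N_e s$; synonymous
variants of the ancestral codon are selectively equivalent to it.  When the
ancestral identity changes the partition re-anchors — recurrent selection.
Over phylogenetic timescales this population process converges to the
Nielsen–Yang codon substitution model with
$$ \omega(\gamma) = \frac{\gamma}{1 - e^{-\gamma}}, $$
the familiar dN/dS multiplier applied to the amino-acid-changing entries of
the mutation generator ($\omega(0) = 1$ by the removable singularity;
$\omega(-500) \approx 0$, effective inviability).  The resulting generator
is symmetric, hence reversible with respect to the uniform stationary law,
and branch transition probabilities are computed by symmetric
eigendecomposition, cached per ($\kappa$, $\gamma$-level) and rescaled by
$\theta T$ at use time.

## The conditional sample likelihood

The observable at a tip is not one sequence but a population sample: the
vector $x$ of allele counts at a site in a sample of $n$ sequences.  Its
probability is computed conditional on the ancestral allele $A$ using the
stationary Wright–Dirichlet law of a parent-independent mutation model with
selection (PIMS), conditioned on $A$ being ancestral through the
low-mutation-limit fixation weight.  Writing $X_A, \Theta_A$ for the sample
count and total mutation rate of alleles encoding the ancestral amino acid,
$X_H = n - X_A$, $\Theta_H = \Theta - \Theta_A$:
$$ \Pr(x \mid A, \gamma) = \mathrm{DirMult}(x;\theta, n)\;
   \frac{\theta_A + x_A}{\Theta_A + X_A}\,\frac{\Theta_A}{\theta_A}\;
   \frac{{}_1F_1(X_H + \Theta_H;\, n + \Theta;\, \gamma) - e^{\gamma}}
        {{}_1F_1(\Theta_H;\, \Theta;\, \gamma) - e^{\gamma}}, $$
with the $\gamma \to 0$ limit
$\Theta (X_A + \Theta_A) / (\Theta_A (n + \Theta))$ for the last factor.
The middle factor is the within-class refinement of the ancestral weight:
selection distinguishes amino-acid classes, but among the selectively
equivalent codons of the ancestral class the ancestral allele itself is the
likely common one (a neutral within-class lottery).  We added this factor
after simulation-based checking of the class-only form; it integrates to one
over within-class allocations, so all class-level distributions are
unchanged, and without it the likelihood acquires an artifactual preference
for extreme $\kappa$ through monomorphic sites.  The sampling distribution
is multinomial (with replacement), and the likelihood is a proper
distribution over samples — the test suite verifies normalisation
exhaustively at $n \le 2$ and against adaptive quadrature on collapsed
two-class systems.

## Parent-dependent mutation via tailored PIMS rates

The codon HKY85 process is parent-dependent, so the Wright–Dirichlet theory
does not apply directly.  Following the averaging idea, the likelihood at a
site uses parent-independent rates *tailored to the ancestral background*
$A$: off-ancestor rates are proportional to the expected occupancy of a
neutral lineage started at $A$ after an exponentially distributed
coalescent path (the resolvent $(I - 2R)^{-1}$, kernel mean 2 in $P N_e$
generations — mutations accumulate along both lineages separating a sampled
copy from the background), rescaled so their total is the scaled mutation
rate away from $A$.  The ancestral allele's own Dirichlet parameter is the
scaled back-mutation flux into $A$ (the occupancy-weighted average of rates
$j \to A$): this choice reproduces the exact biallelic Beta stationary law,
keeps a parent-independent model a fixed point of the construction, and is
the one validated by the forward simulator (total-variation distance
0.006–0.015 between simulated and computed sampling distributions at
$\theta = 0.3$ and $\gamma \in \{-5, 0, 5\}$, against > 0.10 for the
resolvent-occupancy alternative).  A kernel mean of 1 performs comparably
(slightly better at $\gamma \le 0$, slightly worse at $\gamma > 0$); the
default stays at 2 and is configurable.

## Extended pruning

Felsenstein's pruning recursion computes the joint likelihood over species,
with one modification: tip partial vectors are conditional sample
likelihoods rather than 0/1 indicators, so even a single sequence
contributes a non-degenerate vector (the sequence may carry a derived
allele).  The root is the internal node of the unrooted star phylogeny with
a uniform prior over the 61 codons (the stationary law of the recurrent
process); per-node log-scaling guards against underflow.  Pruning is tested
against brute-force summation over root states, tip-swap symmetry,
re-rooting invariance in the reversible neutral case, and the
infinite-branch factorisation limit.

## Intragenic variation: the sliding-window field

Selection coefficients vary along a gene.  Contiguous windows share one
$\gamma$ drawn from the window grid $G_1 = \{-100, -50, -10, -5, -1, 0, 1,
5, 10, 50, 100\}$; junctions between adjacent codons occur independently
with probability $p$, so window lengths are geometric with mean $1/p$
($p = 1$: sitewise; $p = 0$: genewise).  Individual codons may additionally
deviate, independently of the window, to the per-codon grid $G_2 =
\{-500\}$ — so effective inviability is spatially independent while viable
sites keep the spatial dependency.  The DFE is the weight vector $\lambda =
(\lambda_1, \lambda_2)$ over $G_1 \cup G_2$, estimated per lineage without
any parametric shape assumption.  The DFE of amino-acid *substitutions*
reweights $\lambda$ by $\omega(\gamma)$, and substitutions decompose into
A+ (beneficial, attributable to selection: fraction $(\omega - 1)/\omega$
of each positive level), D+ (beneficial but expected under drift,
$1/\omega$), D0 (neutral) and D− (deleterious, fixed in spite of
selection).

## Priors and MCMC

Priors: symmetric Dirichlet($\alpha = 1$) on $\lambda$; Uniform(0,1) on
$p$; improper log-uniform on $\kappa$ and $T$ (truncated to
$[10^{-4}, 10^4]$ so that degenerate and prior-only runs remain proper —
configurable); LogNormal($\mu_\theta, \sigma_\theta^2$) on each
branch-locus $\theta$ with an improper uniform prior on $\mu_\theta$ and a
lognormal prior (log-scale mean 0, variance 4) on $\sigma_\theta^2$.

Each MCMC sweep updates: junction indicators by collapsed Gibbs (window
levels of the two affected windows marginalised, then redrawn); window
levels by Gibbs; per-codon deviation flags by Gibbs; $p$ by its Beta full
conditional; $\lambda$ by Dirichlet-proposal Metropolis–Hastings (the
window/deviation latent structure breaks conjugacy; proposal concentration
60, tuned to roughly 25% acceptance); $\theta_{b,\ell}$, $\kappa_b$, $T_b$
by log-scale random walks; $\mu_\theta$ by its conjugate normal draw; and
$\sigma_\theta$ by a log-scale walk.  The decisive performance choice is
caching: per (branch, locus, $\gamma$-level) the 61-vector tip partials and
root-ward messages are stored and invalidated only when $\theta$, $\kappa$
or $T$ changes.  The published analysis protocol (two chains of 2,000,000
iterations, thinning 40, burn-in 20,000 iterations — interpreted as raw
iterations) is the default configuration; the examples and tests use short
chains on small simulated loci.  Split-$\hat{R}$ and acceptance rates are
reported with every fit.

# The simulator and what passing tests mean

The forward simulator is a haploid Wright–Fisher population of $M$ gene
copies ($M$ generations represent one $P N_e$ unit): multinomial
reproduction with hot-class weight $1 + \gamma/(2M)$, per-copy mutation
probabilities $r_{ij}/M$ (so the diffusion-limit Dirichlet parameters are
$2 r_{ij}$, the scale the likelihood uses), and explicit ancestral-identity
tracking under three operational definitions — last fixed allele, the
allele at the most recent whole-population common-ancestor checkpoint (an
anchor-coalescence approximation to the population MRCA), and the oldest
segregating allele.  Only the last matches the conditioning of the theory,
and the simulator demonstrates the known artefact of the others: an
inflated probability of samples containing no copy of the reported
ancestral allele.  Selection always re-anchors on the oldest segregating
allele.

Defaults: $M = 2000$ for single-site simulation (tests use 300–1000 for
speed; doubling $M$ leaves the sampling distribution stable within
Monte-Carlo error, which is itself a test), burn-in $20 M$ generations.
Validation designs: `known_ancestor` samples a stationary population with
its current oldest segregating allele recorded; `lagged_ancestor` records
the ancestor 10 $P N_e$ generations before sampling; `three_taxon` burns an
ancestral population to stationarity, records the root codon at the split,
and forks the **full population state** (standing variation included) into
the branch populations — forking a monomorphic population instead loses the
in-flight turnover events and depresses divergence well below the
phylogenetic rate on branches comparable to the fixation timescale.

What the simulator does *not* emulate: linkage (sites are simulated
independently, exactly matching the model's independence assumption),
demographic change, selection on synonymous codon usage, dominance.
Agreement between the simulator and the method therefore validates the
mathematics and the implementation, not robustness to these violations on
real data.

# Numerical choices

* $_1F_1(a;b;z)$ is evaluated in log scale by direct summation of
  positive-term series, with the Kummer transform
  $_1F_1(a;b;z) = e^z\,_1F_1(b-a;b;-z)$ for negative arguments and the
  differences $e^z - {}_1F_1$ and $_1F_1 - 1$ summed term-wise (every term
  non-negative, no cancellation); accurate to $\ge 10$ significant digits
  over $z \in [-600, 600]$ against arbitrary-precision references.
* $\gamma = 0$ is handled by the analytic limit, not by perturbation.
* Transition matrices come from symmetric eigendecompositions; negative
  round-off entries are clipped and rows renormalised.
* Ties in Gibbs draws and empty windows need no special casing: a window
  containing only deviated codons keeps a latent level drawn from
  $\lambda_1$.
* Codon columns containing gaps, ambiguity codes or stop codons in any
  sequence are dropped listwise (the model has no missing-data mechanism)
  and reported.

# Design decisions made where the design was open

* **Ancestral PIMS rate.**  Resolved by oracle (see above): back-mutation
  flux, not resolvent self-occupancy.
* **Coalescent kernel mean (1 vs 2 $P N_e$ units).**  Both validated
  within tolerance; 2 kept as default (two lineages diverging from the
  background accumulate mutations along both paths).
* **Within-class ancestral identity.**  The allele-level factor is
  included (resolved by simulation; class-level marginals unchanged).
* **Root prior.**  Uniform over the 61 codons — the stationary law of the
  recurrent-selection substitution process; a mutation-weighted root would
  contradict the model's own equilibrium.
* **Burn-in unit.**  "Iterations" are raw sweeps, so the default discards
  20,000 sweeps (500 retained draws at thinning 40); configurable.
* **MK counting rules** (descriptive companion only): polymorphism counted
  per minor allele against the species' major allele; fixed differences
  require disjoint species allele sets, are polarised by outgroup
  parsimony and skipped (with a count) when the outgroup matches neither
  side; a codon both polymorphic and divergent contributes to both counts.

# Problem sizes used in the tests

The test-suite and the acceptance script run entirely on simulated data:
oracle-equivalence suites use $10^5$ sites at $n = 10$ ($M = 600$, chained
sampling with half-$M$ spacing); credible-interval calibration uses 20
datasets of 30 sequences × 250 codons with known ancestry and 4,000-sweep
chains; the joint three-taxon fits use single loci of 40–60 codons with
short chains.  These sizes were chosen so the full suite completes in
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

# Known limitations

* The composite likelihood treats ancestral-identity turnover as a Markov
  substitution process; on branches shorter than the fixation timescale
  (a couple of $P N_e$ units) the separation of timescales is imperfect
  and branch lengths absorb part of the mismatch.  The published
  validation design uses a 10 $P N_e$-generation branch, where the effect
  is small.
* A single 60-codon locus with small samples identifies $T$, $\theta$ and
  the selection field only weakly; the method is designed for many loci
  sharing branch-level parameters through the hierarchy.
* The MCMC engine supports star phylogenies (every sampled population
  adjacent to one internal node), the regime the three-species analysis
  needs; `prune_site` itself is general.
* Selection on synonymous variation is not modelled.
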