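---
title: "Distance-based ancestry inference on a fixed reference triangle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based ancestry inference on a fixed reference triangle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadmix)
```

## The model

`triadmix` infers continental ancestry without principal components. The
object it manipulates is a vector of *genetic distances*: for subject $i$ and
reference population $j$ with per-SNP reference-allele frequencies $p_{jl}$
(and $q_{jl} = 1 - p_{jl}$),

$$D_{ij} = -\frac{1}{S'}\sum_{l \in \text{genotyped}}
\left[\, g_{il}\ln p_{jl} + (2-g_{il})\ln q_{jl} + g_{il}(2-g_{il})\ln 2 \,\right],$$

the mean negative log likelihood of the subject's genotypes under
Hardy–Weinberg equilibrium at population $j$'s frequencies, in nats per SNP.
Three assumptions matter: the fingerprint SNPs are effectively unlinked (so
the likelihood factorizes), each reference population is approximately
random-mating at these SNPs (so HWE genotype probabilities apply), and the
panel frequencies are estimated from large, correctly labelled reference
cohorts. Missing genotypes are excluded from both the sum and the count $S'$;
nothing is imputed.

The subject's triple $(D_{i1}, D_{i2}, D_{i3})$ — distances to the European,
African and East Asian references — is a point $Q$ in 3-space. For three
anchor groups E, F, A (trusted subsets of those same three populations, with
their own frequencies $u_{rl}$) the *expected* distance triples are available
in closed form, because the expectation of $D$ over HWE genotypes is a
frequency expression:

$$E[D_{rj}] = -\frac{1}{S'}\sum_l \left[\, u_{rl}^2\ln p_{jl}^2
+ 2u_{rl}v_{rl}\ln(2 p_{jl} q_{jl}) + v_{rl}^2 \ln q_{jl}^2 \,\right].$$

The three expected triples form a triangle. Barycentric coordinates of $Q$
with respect to that triangle, clamped to the simplex
($P_m = \max(0,\lambda_m)/\sum_r \max(0,\lambda_r)$), are the ancestry
proportions.

## Why missingness cancels

Both $Q$ and the triangle vertices are per-SNP *means over the same SNP
subset*. When a subject is genotyped on a sliver of the panel, the package
recomputes the expected triangle over exactly that sliver (a masked mean of a
precomputed $S \times 9$ contribution table), computes barycentric
coordinates there, and only then re-expresses them on the full-panel
reference triangle to give the normalized scores GD1/GD2. Subsetting shifts
subject point and triangle together, so placements are unbiased under random
*and* platform-structured missingness; only the per-subject dispersion grows
as $S'$ shrinks. Two scores skip the re-mapping deliberately: GD3, the
out-of-plane coordinate of $Q$ in the subject-specific frame (no reference
re-expression is defined for it), and GD4 $= D_{i5} - D_{i4}$, where the
$\ln 2$ heterozygote term cancels in the subtraction, leaving only
frequency-ratio terms whose per-SNP expectation is unchanged by any
missingness pattern.

Because every quantity is per-subject, scores are independent across
subjects — adding a subject to a file changes nobody else's row, bit for bit.
The implementation accumulates each subject's sums over its own genotyped
SNPs in panel order (rather than through shape-dependent BLAS products)
precisely to keep that guarantee exact, at the cost of a small constant
factor; scoring stays linear in subjects × SNPs (about 4 s per 1,000
subjects × 10,000 SNPs on one core).

## Geometry conventions

The plane transform is fixed so that results are deterministic and signs are
well-defined: origin at vertex F, side FA along the positive x-axis, vertex E
at $y > 0$, and out-of-plane axis $\hat z \propto (V_A - V_F)\times(V_E -
V_F)$. The transform is rigid (pairwise distances preserved to $10^{-12}$ in
the tests). Barycentric coordinates are computed by the ratio-of-determinants
formula and cross-checked against a direct linear solve. A subset triangle
with $|\det T| < 10^{-9}\times(\text{perimeter})^2$ is declared unstable: the
subject keeps its distances and GD3/GD4 but proportions are withheld and the
row is flagged, rather than failing the run — tiny genotyped subsets can
produce near-collinear expected triangles.

## Parameters that matter

* **Frequency clamp** `epsilon` (default $10^{-6}$): both $\ln p$ and
  $\ln q$ appear in the distance, so monomorphic panel frequencies would
  contribute infinities; clamping bounds any single SNP's contribution to
  about $-2\ln\epsilon \approx 27.6$ nats. The clamp is idempotent and
  applied at load time.
* **Quality thresholds**: a `low_snps` flag below 1,000 genotyped SNPs and a
  `strong` annotation at 4,000 or more, reflecting where placements become
  visually tight; around 150 SNPs still separate the three continental
  clusters, with proportionally larger dispersion.
* **Classification cutoffs** (`default_cutoffs()`): the nine-way label rules —
  $P_e \ge 0.87$ European; $P_f \ge 0.95$ African; $P_a \ge 0.95$ East Asian;
  $0.40 \le P_f < 0.95 \wedge P_a < 0.13$ African American; $P_f < 0.40
  \wedge P_e < 0.87 \wedge P_a < 0.13 \wedge P_f \ge P_a$ Latin American 1;
  a South/East-Asian region ($P_f < 0.13 \wedge P_f < P_a$, others below
  threshold) resolved on the (GD1, GD4) plane by
  $\mathrm{GD4} > 5(\mathrm{GD1}-1.69)^2 + 0.042$ (South Asian), else
  $\mathrm{GD1} > 30\,\mathrm{GD4}^2 + 1.73$ (Asian-Pacific Islander), else
  $\mathrm{GD4} < 0$ (Latin American 2); and $P_a \ge 0.13 \wedge P_f \ge
  0.13$ Other. Rules are evaluated in that order, so floating-point boundary
  ties resolve deterministically. These are suggested standards tied to one
  score scale, not laws: users should inspect the scatter and may supply
  their own constants (every cutoff is configurable, and the `classify`
  subcommand re-labels an existing score table). The region's residual case
  — $\mathrm{GD4} \ge 0$ but neither curve satisfied — is not pinned down by
  the curve rules themselves; we assign Asian-Pacific Islander by default because that
  middle sub-cluster adjoins the Asian-Pacific cluster, and expose the choice
  (`residual_popid`, 7 or 9).
* **Harmonization**: variants are matched to the panel by SNP identifier
  (optionally by position), allele order is reconciled by complementing
  ($g \mapsto 2-g$) and strand by base-complementing; A/T and C/G SNPs are
  dropped by default since their strand cannot be resolved reliably at the
  high minor allele frequencies typical of fingerprint panels.

## What the simulator emulates — and what it does not

Real reference panels derive from controlled-access archives, so the package
ships a generator with the statistical structure the method assumes:
ancestral frequencies uniform on $[0.15, 0.85]$ (fingerprint panels are
selected for high MAF), population frequencies drawn from Balding–Nichols
distributions $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, genotypes binomial
under HWE with allele frequency $\sum_r \alpha_r u_{rl}$ for an admixed
subject, and two missingness regimes (per-call MCAR; a shared "platform" SNP
subset). One master seed drives panel, genotypes and masks through split
sub-streams, so fixtures are byte-reproducible.

Drift defaults are $F = 0.15$ for the three anchor populations, $0.12$ for
South Asian, $0.15$ for Mexican/Latino — above genome-wide averages, as
appropriate for a panel selected to be ancestry-informative, and strong
enough that the three continental groups remain separable from ~150 SNPs.
The three anchor populations get *equal* drift deliberately. An admixed
subject's expected heterozygosity exceeds the $\alpha$-mixture of the anchor
heterozygosities (by $2\,\mathrm{Var}_\alpha(u_l)$ per SNP), which shifts its
expected point by a multiple of $(1,1,1)$ relative to the convex combination
of the triangle vertices. In a symmetric reference configuration the triangle
plane's normal is $(1,1,1)/\sqrt3$, so this shift is purely out-of-plane: it
surfaces in GD3 — which is exactly how the method uses GD3, to separate
multi-way admixture from two-way mixtures that land on the same in-plane
spot — and leaves the ancestry proportions unbiased (analytic proportions at
$\alpha = (0.6, 0.3, 0.1)$: $(0.600, 0.301, 0.098)$). With strongly
asymmetric drift part of the shift becomes in-plane and proportions for
admixed subjects acquire a small systematic bias (about $0.03$ at that
$\alpha$); real panels sit between the two cases. The simulator does not
model linkage disequilibrium, realistic site-frequency spectra,
chromosome-block admixture, or genotyping error — the method is single-SNP
by construction of the panel, so passing tests demonstrate the normalization
and classification machinery, not robustness to LD or platform artefacts in
real archives.

## Numerical choices and degenerate inputs

Natural logarithms throughout; distances in nats/SNP. Summation is in panel
order with plain double accumulation ($S \le 10^4$ keeps the error far below
the $10^{-10}$ test tolerances). A subject with zero genotyped SNPs is
flagged (`no_genotypes`) and skipped, never imputed. An unstable subset
triangle flags the row and withholds proportions. Identical anchor-group
frequency columns make the reference triangle degenerate — that is a fatal
panel error, since the coordinate system itself is undefined. Score tables
are written with six decimals in a fixed column order; the classifier can be
re-run on a written table with different cutoffs.

## Problem sizes used in the checks

The test-suite and acceptance-script experiments use the study conditions the
method is designed for: a 10,000-SNP panel with 1,000 subjects per pure
population (classification, few-SNP separability at a 150-SNP platform
subset, dispersion ordering), 500 admixed subjects at
$\alpha = (0.6, 0.3, 0.1)$ (recovery within $\pm 0.03$, and $\pm 0.05$ under
50% MCAR), and a 3,433-SNP panel at 95% MCAR — about 170 genotyped SNPs per
subject — for the centroid-robustness checks (displacement under 2% of the
E–F side). Oracle-equivalence checks run $10^4$ random triangles and $10^3$
random subjects. Runtime scaling is fit over 1,000–4,000 subjects × 10,000
SNPs.

## Known limitations

Scores are internally consistent but on the package's own scale: the absolute
offsets of other implementations of this normalization are not reproduced,
so cutoff constants tied to any one score scale (the two (GD1, GD4) curves
especially) transfer only after inspecting one's own scatter. Proportions are estimated with respect to a three-vertex simplex;
ancestries outside its span (e.g. Indigenous American) project onto it and
show up as apparent mixtures — the five-distance vector and GD3/GD4 carry the
extra information the triangle cannot. Below a few hundred genotyped SNPs,
per-subject dispersion dominates and only the continental-scale calls remain
meaningful; the package flags, but does not refuse, such subjects.
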