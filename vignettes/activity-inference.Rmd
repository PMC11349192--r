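---
title: "Variational inference of promoter and enhancer activities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational inference of promoter and enhancer activities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhact)
```

## The model and its assumptions

`enhact` treats bulk gene expression as the product of a transcriptional
burst size, attributed to the promoter, and a burst frequency, attributed
to the additive, contact-weighted action of candidate enhancers:

$$y_g = k\, v_g \sum_r c_{gr} w_r,$$

with Poisson observation models for the RNA-seq count
($t_g \sim \mathrm{Pois}(l^T_g y_g)$, effective transcript length in kb)
and for accessibility counts over promoter and enhancer elements
($x^P_g \sim \mathrm{Pois}(l^P_g o^P_g)$,
$x^E_r \sim \mathrm{Pois}(l^E_r o^E_r)$, element lengths in kb). The
latent chromatin openness variables $o^P, o^E$ do not enter $y_g$
directly; they tie the activity priors to the accessibility data:

$$v_g \sim \mathrm{Ga}\!\left(\alpha_v, \tfrac{\alpha_v}{s_g o^P_g}\right),
\qquad
w_r \sim \mathrm{Ga}\!\left(\alpha_w, \tfrac{\alpha_w}{l^E_r o^E_r}\right),$$

so the prior mean of a promoter's activity is its (burst-size-scaled)
openness and the prior mean of an enhancer's activity is its
openness-times-length, while $\alpha_v, \alpha_w$ set how far the
expression data may pull activities away from accessibility. Openness and
the scale $k$ have gamma priors
$\mathrm{Ga}(\alpha_o, \beta_o)$, $\mathrm{Ga}(\alpha_k, \beta_k)$.

Key assumptions: enhancers combine additively (no synergy or silencing);
one promoter element per gene, one TSS; contact frequency is a sufficient
proxy for physical regulation; all variation beyond the model is Poisson.

## Inference

The posterior factorizes by mean-field approximation. Activities and the
scale keep gamma posteriors; the openness posteriors are generalized
inverse Gaussian (GIG), because the gamma-prior-through-rate coupling
contributes a $1/o$ term. The intractable
$E[\ln \sum_r c_{gr} w_r]$ is bounded from below via a per-gene auxiliary
probability vector $\rho^{(g)}$ (concavity of the logarithm), tightened
each sweep to
$\rho^{(g)}_r \propto c_{gr} \exp E[\ln w_r]$.

One coordinate-ascent sweep updates, in order:
$\rho \to q(w) \to q(v) \to q(o^E) \to q(o^P) \to q(k)$, refreshing cached
expectations immediately after each family. The order is a design choice
(any order preserves the ascent property); resolving the $\rho$/$w$
coupling first converged fastest in pilot runs. Convergence is declared
when every posterior-mean enhancer activity changes by less than
$5\times10^{-3}$ relative (the statistic of "enhancer activity" is taken
to be the posterior mean, which the model's stopping rule leaves open), or
after 500 sweeps. Inference involves no randomness and is exactly
reproducible.

### Initialization

The initialization table of the original description is not available, so
the package uses a deterministic moment-matched warm start:
$E[o] = (x + \alpha_o)/(l + \beta_o)$ (the openness posterior given only
its own count), activities at their prior means given that openness,
$E[\ln w] = \ln E[w]$, $E[1/o] = 1/E[o]$, and
$E[k] = \sum_g t_g / \sum_g l^T_g E[v_g] \sum_r c_{gr} E[w_r]$. The first
action of the first sweep is the $\rho$ update.

### Numerical choices

* GIG expectations use modified Bessel functions of the second kind.
  `besselK(expon.scaled = TRUE)` is used when finite; when it overflows
  (large order, small argument) the uniform large-order (Debye) asymptotic
  expansion with four correction terms takes over (relative error
  $\sim \nu^{-5}$; the branch is only reached for $\nu \gtrsim 50$).
* $E[1/o]$ is computed from $K_{\lambda-1}/K_\lambda$ rather than the
  recurrence-equivalent $K_{\lambda+1}/K_\lambda - 2\lambda/\chi$ form,
  which cancels catastrophically in the gamma limit $\chi \to 0$.
* $E[\ln o]$ needs $\partial_\lambda \ln K_\lambda$, which has no closed
  form; a central finite difference with step $10^{-4}$ on the log scale
  is used.
* $\rho$ is computed with a per-gene log-sum-exp shift, safe for
  $|E[\ln w]|$ up to at least 700.
* The ELBO omits additive constants independent of the variational
  distribution ($\ln t_g!$, $\ln x!$); traces are comparable across sweeps
  of one fit, not across datasets. The test-suite quadrature oracle applies
  the same omission.
* Degenerate inputs: zero counts are valid (a zero-count gene keeps its
  prior shape $\alpha_v$); an element with no contacts receives its pure
  accessibility posterior; genes require at least one positive contact,
  enforced at assembly. Ties in top-N peak selection break by genomic
  order; ties in per-gene rankings break by distance then element id.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `alpha_v` | 80 | promoter-activity prior shape; larger = activities track `s·oP` more tightly |
| `alpha_w` | 10 | enhancer-activity prior shape; smaller = more dispersed, data-driven |
| `alpha_o`, `beta_o` | 1, 1e-3 | weak openness prior (counts dominate at real depths) |
| `alpha_k`, `beta_k` | 1, 1e-3 | weak scale prior; `beta_k` small keeps scores contact-scale invariant |
| `window` | 5 Mb | max TSS-to-element distance for candidate pairs |
| `cutoff_tpm` | 8 | expression filter (strict `>`); 4–8 is the useful range |
| `tol`, `max_iter` | 5e-3, 500 | convergence rule |
| power-law `gamma` | 0.7 | contact decay exponent; `d_min` = 5 kb caps d = 0 |

`alpha_o, beta_o, alpha_k, beta_k` come from an unavailable supplement;
the weakly informative defaults above are used, and the acceptance suite
verifies that parameter recovery is unchanged under ±10× perturbation of
all four.

Model variants: `no_sg` drops the sequence-based burst size from the
promoter prior (s ≡ 1); `no_lE` drops the element length from the
*enhancer prior only* — the accessibility observation model keeps the true
length. Flat-input ablations (constant accessibility or RNA counts) are
input rewrites, not model changes.

### Open points, resolved

* The prior rate of $v$ is read as $\alpha_v/(s_g o^P_g)$ — the only
  grouping consistent between the prior, the GIG parameter
  $\chi^P = 2\alpha_v E[v]/s$, and the $q(v)$ rate update.
* Whether peak read counts are recomputed after resizing is unspecified
  upstream; constituent counts are summed (counts are conserved by
  merging, a tested invariant).
* "Four neighbouring entries" of a contact-map diagonal cell is
  implemented as the four matrix cells adjacent along its row and column,
  which for a symmetric map is the max of the two stored upper-triangle
  neighbours. Only stored diagonal entries are replaced (sparse-zero
  semantics).
* The pseudocount magnitude is unspecified; the default is the power-law
  expectation at `min(distance, 1 Mb)`, with a fixed-constant mode
  available. Its choice is logged in every run configuration.
* Bookended elements (end = next start) are not merged; only strict
  overlap merges.
* $\rho$ is recomputed fresh each sweep (no damping).

## What the simulator emulates — and what it does not

`sample_dataset()` draws from exactly the generative model above: openness
from its gamma prior, activities from their conditional priors, counts
from the Poisson observation models, and $y$ from the exact product
identity. Its stated world: one synthetic chromosome, ~30 kb element
spacing (a realistic genome-wide density of candidate elements), element
widths log-uniform 500–2000 bp, effective transcript lengths log-uniform
0.5–5 kb, burst sizes log-uniform 0.5–2. A subset of elements doubles as
promoter elements (promoters can act as enhancers of other genes); each
element gets one accessibility count, shared with its gene's promoter
count, as both views observe the same region. Contacts follow
`distance^-0.7` with multiplicative log-normal noise (sdlog 0.25) to mimic
contact-map dispersion, rescaled globally so the mean RNA-seq count is
1000 per gene (inference is invariant to that scale, a tested property).

The generator does **not** emulate: read-level noise or mappability,
peak-calling artifacts, KR normalization failure modes, trans-acting
regulation, silencers, multi-TSS genes, or inter-chromosomal contacts.
A green recovery test therefore establishes that the inference machinery
inverts the model it states — not that the model is true of any particular
cell type; the published benchmark evaluations against CRISPRi and eQTL
data require external datasets and are out of scope here.

```{r recovery, eval = FALSE}
ds <- make_fixture("medium")     # 200 genes x 600 elements, seed 1
st <- run_inference(ds$input)
cor(ds$truth$w[match(ds$input$element_id, ds$elements$element_id)],
    st$Ew, method = "spearman")  # ~0.96 (acceptance threshold: >= 0.8)
```

## Known limitations

* One promoter element and one TSS per gene; isoform-level modelling is
  out of scope.
* Openness cannot be removed from the model (the "no accessibility"
  ablation is a structurally different model).
* The contact-map reader consumes pre-normalized sparse text dumps; KR
  balancing itself and binary `.hic` parsing are upstream concerns.
* Per-gene score vectors are relative: `h` says nothing about absolute
  regulatory strength across genes (that is what `v`, `w`, `y` are for).
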