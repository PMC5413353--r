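# DeBias

Decoupling global bias from local interactions in paired cell-biological
variables.

## The problem

Many questions in cell biology reduce to asking how strongly two spatially
matched variables are coupled: how well microtubules align with vimentin
filaments, how closely a cell's velocity follows its principal stress
orientation (plithotaxis), how much transferrin receptor co-localizes with
clathrin-coated pits. The observed coupling, however, is a mixture of two
very different mechanisms:

* **global bias** — a common effector (cell polarity, the wound edge, shared
  illumination) that shapes *both* marginal distributions and makes the
  variables agree without any point-wise interaction, and
* **local interaction** — genuine coupling between the two members of each
  matched pair.

A single correlation- or overlap-style score confounds the two. DeBias
separates them. Given matched pairs \((x_i, y_i)\), it computes the
alignment of each pair — the folded axial angle
\(\theta_i = |x_i - y_i|\) if \(|x_i - y_i| \le 90\), else
\(180 - |x_i - y_i|\) for orientations, or the difference of
5th/95th-percentile-normalized intensities for co-localization — and
quantizes it into a K-bin histogram (*observed*). A null histogram
(*resampled*) is built the same way after resampling each marginal
independently with replacement, which preserves the global bias but
destroys the local pairing. Both are compared against the analytic uniform
histogram with the one-dimensional Earth Mover's Distance
\(EMD(A,B) = \sum_{i=1}^{K} \bigl|\sum_{j\le i} a_j - \sum_{j\le i} b_j\bigr|\):

* **global index**: `GI = EMD(uniform, resampled)`
* **local index**: `LI = EMD(uniform, observed) − GI`

GI measures how much coupling the marginals alone produce; LI measures the
extra coupling contributed by the true point-wise matching. LI can be
negative (anti-alignment). Both are in bin units; indices are comparable
only when computed with the same K.

The package also provides the two synthetic-data generators that define
the method's benchmark scenarios (truncated-normal co-orientation with a
Bernoulli-selected shift, and multiplicative co-localization with partial
interacting subgroups), automatic bin selection by the Freedman–Diaconis
rule, a subsampling permutation test for comparing conditions, readers for
two-column CSV/TSV tables and paired TIFF images, and a CLI.

## Worked example

Two scenarios with the *same* observed mean alignment (~19°) but opposite
mechanisms — strong global bias (narrow marginals, no interaction) versus
weak bias plus strong interaction:

```r
library(DeBias)

a <- simulateCoorientation(orientationSimConfig(
  n = 10000, seed = 17, sigmaX = 17, alpha = 0))    # pure global bias
b <- simulateCoorientation(orientationSimConfig(
  n = 10000, seed = 18, sigmaX = 40, alpha = 0.5))  # strong interaction

meanAlignment(a)   # 19.0186
meanAlignment(b)   # 19.44752

computeDeBias(a, k = 15, seed = 17)
#> DeBias decomposition (orientation mode, N = 10000, K = 15)
#>   global index GI: 4.3354
#>   local index  LI: -0.0199
computeDeBias(b, k = 15, seed = 18)
#> DeBias decomposition (orientation mode, N = 10000, K = 15)
#>   global index GI: 1.2189
#>   local index  LI: 3.0202

permutationTest(a, b, k = 15, statistic = "LI", nIter = 100, seed = 19)
#> Subsampling permutation test on LI
#>   full-data LI: A = -0.0089, B = 2.9679 (a_less)
#>   contradicting fraction: 0.000 over 100 iterations (50% subsamples)
#>   p-value: <= 0.01
```

The indistinguishable mean alignments decompose into (GI ≈ 4.3, LI ≈ 0)
for the biased scenario and (GI ≈ 1.2, LI ≈ 3.0) for the interacting one:
the decomposition recovers the generating mechanism that the scalar
summary hides. The permutation test reports the floored p-value 0.01 —
no subsampling iteration reversed the LI ordering.

The same workflow is available from a shell:

```sh
debias=$(Rscript -e 'cat(system.file("scripts", "debias", package = "DeBias"))')
$debias simulate orientation --n 10000 --seed 17 --sigma-x 17 --alpha 0 --out a.csv
$debias run --mode orientation --input a.csv --k 15 --seed 17 --out a.json
$debias compare --a a.csv --b b.csv --mode orientation --k 15 --out cmp.json
```

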