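# phca — persistent-homology classification of landmark point clouds

Sign-language alphabets and other static hand gestures can be recognised
from landmark coordinates alone: 21 keypoints per hand (wrist and finger
joints), each with x, y and relative depth — 63 real features per item.
`phca` implements a topological classifier for such data and the full
protocol needed to compare it against classical baselines. It is aimed at
researchers in topological data analysis and gesture recognition who want a
transparent, interpretable alternative to deep networks, plus the
statistical machinery to say whether it actually competes.

## The algorithm

The core is the **Persistent Homology Classification Algorithm (PHCA)**.
Training computes, per class $i$, the Vietoris–Rips persistence diagram
$\mathcal{P}(X_i)$ of the class's point cloud — every feature's
$(\dim, b_q, d_q)$ with lifespan $l_q = d_q - b_q$, radii up to the horizon
$\mathrm{maxsc} = \frac12 \max_{x,y} d(x,y)$ — and caches the total
lifespan. A query $\alpha$ is scored against each class by how much that
total changes when the query is inserted,

$$\mathrm{Score}(X_i) = \Bigl|\sum_{q \in \mathcal{P}(X_i \cup \{\alpha\})} l_q - \sum_{q \in \mathcal{P}(X_i)} l_q\Bigr|,$$

and classified to $\arg\min_i \mathrm{Score}(X_i)$: the class whose
topology is perturbed least. With homology dimension 0 (the default and the
configuration that wins validation), the total has the closed form
$\mathrm{maxsc} + \frac12\sum_{e \in MST} w(e)$, so scoring runs on minimum
spanning trees; dimension 1 (loops) runs through the package's compiled
boundary-matrix reduction, which is verified in the tests against an
independent brute-force oracle.

Around the classifier sits the evaluation harness of a tuned comparison
study: stratified 90–10 splits, standard scaling fit on training data only,
random-search tuning (20 draws, stratified 5-fold cross-validation) for
PHCA and five baselines (SVM, random forest, k-NN, LDA, CART), macro
precision/recall/F1/specificity plus overall accuracy, cumulative confusion
and misclassification reports, and Friedman + Nemenyi rank comparison with
the critical difference $CD = q_\alpha\sqrt{k(k+1)/(6N)}$. A synthetic
hand-landmark generator makes the whole pipeline testable without images;
an optional front-end port accepts any image-to-landmark backend.

## A worked example

```r
library(phca)

# Vietoris-Rips persistence of the unit square's corners
vrPersistence(PointCloud(rbind(c(0,0), c(1,0), c(1,1), c(0,1))))
#> PersistenceDiagram: 7 bars (horizon 0.707107)
#>   dim 0: 4 bars, total lifespan 2.20711
#>   dim 1: 3 bars, total lifespan 0.207107
```

Four components (three die at radius 0.5 when the sides connect; the last
is capped at the horizon $\sqrt2/2$) and one persistent loop born 0.5, dead
$\sqrt2/2$ — the square's hole.

```r
m <- phcaFit(matrix(c(0, 3, 10, 13), ncol = 1), c("A", "A", "B", "B"))
c(A = scoreClass(m, "A", 1.4), B = scoreClass(m, "B", 1.4))
#>   A   B
#> 0.0 8.6
predictOne(m, 1.4)
#> [1] "A"
```

Inserting 1.4 between 0 and 3 leaves class A's total lifespan unchanged
(score 0); forcing it into B would stretch B's cloud by 8.6 — so the query
is an A.

```r
hands <- makeHandLike(k = 4, classSize = 40, jitterSd = 0.03, rho = 0.05,
                      seed = 1)
res <- runTrials(list(data = hands$dataset, roster = c("PHCA", "SVM", "CART"),
                      nTrials = 2, nIter = 5, folds = 5, baseSeed = 1))
res
#> phcaTrials: 2 trials, classifiers PHCA, SVM, CART
#>   CART  accuracy mean 1.0000 [1.0000, 1.0000]
#>   PHCA  accuracy mean 1.0000 [1.0000, 1.0000]
#>   SVM   accuracy mean 1.0000 [1.0000, 1.0000]
significanceTable(res$blockMatrices, focal = "PHCA")
#>   trial PHCA-SVM PHCA-CART sig.SVM sig.CART
#> 1     1      0.9       0.9   FALSE    FALSE
#> 2     2      0.9       0.9   FALSE    FALSE
```

On this gently jittered four-class set every classifier is perfect, so all
metric blocks tie and every Nemenyi p-value sits at the 0.900 reporting
cap: no significant differences. Harder conditions (more classes, larger
jitter, per-item translation/scale) separate the roster — see the methods
vignette.

The same pipeline is scriptable:
`phca simulate | run | compare | persistence | extract` (launcher in
`inst/cli/`), with JSON/YAML configs and CSV/JSON artifacts.

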