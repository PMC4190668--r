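---
title: "Methods: detecting and reading gel diagrams in figure images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and reading gel diagrams in figure images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelminer)
```

# The problem

Gel electrophoresis images report molecular measurements as dark bands in
rectangular strips, and the semantics — which gene or protein, which cell
line, which condition — lives in the short text labels arranged around the
strip grid. `gelminer` detects the strips, groups them into panels,
attaches their labels, and recognizes gene symbols in the label text. This
vignette records the model, the tunable parameters, the numerical choices,
and what the synthetic test bed does and does not establish.

# Coordinate conventions

All boxes are integer pixel rectangles with a 0-based top-left origin,
half-open on both axes: `c(x0, y0, x1, y1)` covers columns `x0..x1-1` and
rows `y0..y1-1`, so `width = x1 - x0` with no off-by-one ambiguity. For
distance computations a box is treated as the closed continuous rectangle
`[x0, x1] × [y0, y1]`; two boxes that touch are at distance 0. Grayscale
is ITU-R 601 luma, `round(0.299 R + 0.587 G + 0.114 B)`, the conventional
choice when no weighting is specified.

# Segmentation

The upstream layout-analysis system that this kind of pipeline normally
builds on is substituted by a documented baseline behind the same
contract (segments in, panels out):

* **Connected-region detector.** Otsu binarization (dark foreground) and
  4-connected component labeling; components smaller than
  `min_segment_area` (default 100 px) are dropped. 4-connectivity is
  deliberate: 8-connectivity would bridge adjacent gel lanes through
  corner pixels. The cost is that text glyphs with diagonal-only joints
  fragment into several components; a real OCR front-end would own that
  problem.
* **Low-contrast rectangle detector.** Binarization misses the typical
  light-gray gel strip on a white page. The complementary detector scans
  Sobel edge maps for long horizontal edge runs (≥ `rect_edge_min_len`,
  default 40 px; vertical support runs may be a quarter of that, since
  strips are wide and short), closes top/bottom run pairs with
  left/right support into axis-aligned boxes, and accepts a box when the
  standard deviation of its interior (measured 3 px inside the border)
  is at most `rect_fill_tolerance × 255` (default 0.12). The two
  candidate sets are merged with duplicate suppression: at IoU > 0.8 the
  rectangle-detector box wins, since it traces the strip outline rather
  than the content. Every detail of this detector is a gap-fill — the
  only stated requirement is that it is very simple and targets
  low-internal-contrast rectangles — and it is isolated behind this
  module's interface.
* **OCR adapter.** OCR is injected as `(crop) -> list(text, confidence)`.
  The bundled adapter template-matches connected components against the
  package's own 5×7 bitmap font (tight-bbox resize, with aspect-ratio
  and ink-density similarity factors, line clustering by vertical
  center, and a background-plausibility prior that down-weights mid-gray
  surrounds so gel bands are not read as dashes). A segment is TEXT when
  confidence ≥ 0.5 and at least one character is recognized, else
  GRAPHIC. The adapter is deliberately matched to the generator's font:
  it makes OCR tests deterministic without proprietary software, and any
  real engine can be substituted through the same contract.

# The 39 segment features

Per segment: relative center position (2), relative and absolute
width/height (4), 16 equal-width grayscale histogram bins over [0,255]
normalized by pixel count (area-free), per-channel color means (3), 13
texture features, and the count of recognized non-whitespace characters
(1). The texture block is six Tamura-style statistics — coarseness,
contrast, directionality, line-likeness, regularity, roughness — plus
seven log-spaced radial spectral-power bands ("ripples", band edges
`0.5·2^-7 … 0.5` cycles/pixel, fractions of total AC power). The exact
composition of the 13 is pinned by count and by the named exemplars
(coarseness, ripples); since the source feature list is not fully
reproducible, the set is versioned with the model schema so retraining
absorbs any substitution. Patches smaller than 16×16 are measured on a
zero-padded 16×16 canvas. Position uses the bbox *center* so that
translation within a figure moves exactly two features; all 35 content
features are bit-identical under translation (a tested invariant).

# The classifier and its operating points

A 75-tree random forest (CART, Gini impurity, bootstrap resampling,
`mtry = floor(sqrt(p))`, leaves grown pure by default) scores a segment
by its **tree-vote fraction**, so the decision thresholds 0.15 / 0.30 /
0.60 are directly meaningful: the same forest is read as a high-recall,
balanced, or high-precision classifier. Threshold nesting (positives at
0.6 ⊆ 0.3 ⊆ 0.15, recall non-increasing) is structural and tested.
Class imbalance — gel segments are a small minority of figure segments —
is handled by thresholding only, no resampling. Training is
bit-reproducible given a seed: all randomness flows through R's RNG.
Forest hyperparameters beyond the tree count are not externally
specified; the chosen defaults are recorded in `training_meta`. Models
persist as versioned JSON (text-only, diffable); loading another format
version or scoring against a mismatched feature schema is an error.

# Panel detection rules

* **Adjacency.** Two segments are neighbors when their closest-point
  Euclidean box distance is ≤ 50 px *and* no text segment lies between
  them. "Between" is the open corridor — the axis-aligned hull of the
  two boxes minus the boxes — and a text box counts only if it covers a
  positive-area part of that corridor (edge touches do not). This
  geometry captures the evident purpose of the rule: a caption row
  separating two stacked gels.
* **Seed and expand.** Groups are connected components of the adjacency
  relation restricted to high-recall positives; a component survives
  only if it contains at least one high-precision positive. Formulating
  the repeated expansion as connected components makes it a fixpoint and
  order-independent, and subsumes both readings of "repeatedly expand"
  (HR applied up front or lazily).
* **Label attribution.** The panel region is the axis-aligned hull of
  the member boxes. A text segment is attributed when its nearest edge
  is ≤ 30 px from the region border (closest-point distance) and its
  farthest corner is ≤ 150 px from the border (corner distance bounds
  the label's full extent, which is what the cap plausibly limits).
  Distances are absolute pixels, not resolution-scaled — a noted
  possible refinement that is deliberately not done.

All three rules are verified against independent oracles (pixel
enumeration, area arithmetic, BFS component enumeration) on 1,000 seeded
random layouts with 100% agreement required.

# Gene recognition

Label text is tokenized on any run of non-letter, non-digit characters;
hyphens split, which is what lets the recognizable tail of a compound
name ("actin" in "β-actin") surface as its own token. Exclusion rules
fire in fixed precedence — `TOO_SHORT` (< 3 characters; 3-character
tokens pass), `NUMBER` (Arabic digits, or a *valid* Roman numeral,
case-insensitive: "VV" is not a number), `FREQUENT_WORD`
(case-insensitive, ~100-entry editable stopword list; the bundled list
is a standard English/biomedical one and is documented as non-faithful
to any specific corpus), `DOMAIN_WORD` (the fixed 22 gel-context words,
matched case-sensitively against their canonical forms). Surviving
tokens are looked up in the lexicon with exact case, because gel labels
are dominated by acronyms where capitalization is the signal. Domain
words are excluded even when they are legitimate gene symbols — that is
the point of the list. Disambiguation to database identifiers is out of
scope.

# The synthetic test bed

`generator_config()` defines the stated world: 480×360 px figures; a gel
panel appears with probability 0.25 and is an r×c grid (rows 1–2,
columns 2–4) of equally sized strips with 8–30 px gaps (all ≤ 50 px, so
gold panels are connectable); strips are light-gray rectangles
(background 180–220) with 1–8 dark blurred elliptical bands (depth
60–140, Gaussian blur σ 1.2), or the exact 255-complement for the
white-on-black variant (20% of gel figures under the MIXED default);
column labels sit above and row labels left of the grid at 6–22 px gaps
(inside the 30/150 px window by construction), decoy labels are placed
at > 40 px from the region (outside the window); 4–7 distractor panels
per figure (bar graphs, line graphs, photo-like patches, text blocks)
are kept ≥ 60 px from the gel region; pixel noise is Gaussian with
σ = 2 intensity units. Per-figure seeds are derived from the corpus
seed, so corpora are byte-reproducible.

Choices that deserve justification:

* **Gel minority, but not 3%.** In real corpora only about 3% of
  segments are gels. The generator's defaults give roughly 10–15% —
  still a clear minority, but dense enough that a 300-figure training
  corpus contains a few hundred positive examples. Reproducing 3% at
  desk scale would multiply corpus size (and test runtime) by ~4 while
  testing nothing new about the method, which handles imbalance by
  thresholding alone.
* **Distractor separation (≥ 60 px).** Keeps a misclassified distractor
  from silently joining a gold panel, so panel-level precision measures
  the rules rather than layout accidents. Real figures also separate
  panels visually, if less uniformly.
* **What a green test does not establish.** The synthetic classes are
  cleanly separable — held-out ROC AUC reaches 1.0 — so the recovery
  criterion (AUC ≥ 0.95, panel precision ≥ 0.9 on the noiseless
  setting) validates the machinery, not real-world difficulty. Real
  figures bring JPEG artifacts, anti-aliased fonts, overlapping panels
  and OCR noise that this generator deliberately does not model
  (photorealism and scanned-page artifacts are non-goals).

# Numerical and degenerate-input choices

* Histogram bin b covers `[16b, 16(b+1))` with the last bin closed at
  255; empty regions are an error, constant regions put all mass in one
  bin.
* Constant patches: contrast 0, all ripple bands 0 (zero AC power), by
  convention rather than 0/0.
* ROC AUC is the rank statistic (Mann–Whitney) with mean ranks for
  ties; a constant scorer yields exactly 0.5.
* Tree-vote ties in a leaf predict the negative class (conservative for
  a precision-first pipeline).
* Precision/recall with empty denominators are `NA`, and ratio fields
  with undefined denominators serialize as JSON `null`.
* Unreadable or truncated images raise a classed formatting error that
  the batch runner counts as attrition (`skipped$format_error`) instead
  of aborting; figures with no detectable segments are counted under
  `skipped$no_segments`.
* JPEG and TIFF are recognized by magic bytes but rejected: no offline
  decoder is available in the package's dependency budget, and the
  skip-and-count path makes that a per-figure attrition event, not a
  batch failure. PNG (8-bit, non-interlaced) and PGM/PPM are decoded by
  the built-in codec.

# Known limitations

The segmentation baseline is far below a production layout analyzer;
the bundled OCR adapter only reads the bundled font; panel recall on
real figures would be limited by upstream segmentation quality, which is
exactly the error-accumulation behavior pipeline architectures are known
for. The package's scope ends at gene-token recognition: relation
extraction (aligning bands with labels and quantifying expression) is
future work by design.
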