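---
title: "Methods: hybrid feature fusion for histopathology classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid feature fusion for histopathology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

histofusion implements a two-class classifier for H&E-stained tissue-slide
images (normal vs malignant, with oral squamous cell carcinoma as the
motivating malignancy). The method is a hybrid: a deep convolutional
backbone supplies a 4096-dimensional representation per image, four
classical descriptor blocks supply a 244-dimensional handcrafted
representation, and the two are fused after PCA compression of the deep
block. Two classifier heads are supported:

* a **linear SVM** on the PCA-reduced deep features (4096 → 1024), and
* a **feed-forward network (ANN)** on the fused vector
  (1024 + 244 = 1268 inputs, one tanh hidden layer, a 2-unit softmax
  output).

Every stage is a pure function of its inputs and a seed, so a pipeline run
is reproducible end to end from its configuration.

## Stages and their assumptions

**Enhancement.** Slides vary in staining and illumination, so each image is
first pulled to a common colour balance by gray-world normalisation: each
RGB channel is scaled by (target mean / channel mean), the target being the
mean of the three channel means. Contrast is then enhanced by computing
`gaussian_smooth(img) − laplacian(img)` per channel in signed arithmetic and
clamping to 0..255. The Gaussian term (σ = 1 px, 5×5 kernel, entries
summing to 1) suppresses pixel noise; subtracting the 4-neighbour Laplacian
(`[[0,1,0],[1,−4,1],[0,1,0]]`) accentuates edges, the classic unsharp-mask
behaviour. Both filters use edge-inclusive reflect padding, which keeps
constant images exactly constant. The subtraction order is a convention;
`enhance(sign = -1)` flips it for users who prefer the opposite reading.
σ = 1 with a 5×5 support is a deliberately light denoising choice suited to
high-magnification histology, where nuclear texture must survive smoothing.

**Split.** The stratified split applies an 80/20 train+validation/test
division and then an 80/20 train/validation division within the first part,
with floor rounding at both levels and per-class seeded permutations. Floor
rounding is not incidental: it is the unique rounding rule under which
class sizes 2494/2698 produce the counts 1596/399/499 and 1726/432/540.

**Augmentation.** Each training image is expanded into exactly 12
deterministic variants: rotations by 90/180/270°, horizontal and vertical
flips, ±10% shifts along each axis with reflect fill, and the three
rotations of the horizontally flipped image. A fixed menu (rather than
random draws) makes the ×12 factor exact and the output reproducible;
1596 and 1726 training images become 19,152 and 20,712. Validation and
test images are never augmented, and the API enforces this: augmenting an
id outside the train phase is an error.

**Deep features.** The package ships the convolution, max/average pooling
and ReLU primitives, plus two seeded test backbones meeting the fixed-width
contract (default 4096): a `stub` (images bilinearly down-sampled to 32×32,
flattened, passed through a fixed seeded Gaussian linear map) and a
`minicnn` (three conv/ReLU/max-pool blocks with 8/16/32 channels and 3×3
filters, pooled to a 4×4 grid, flattened, then a seeded linear map).
Neither is trained: they are fixed random projections whose job is to
exercise the contract and carry colour/texture information, which random
projections provably preserve in expectation. Pretrained networks
(AlexNet, ResNet-18) plug in through `register_backbone_adapter()`; note
that ResNet-18's natural penultimate width is 512, not 4096, so an adapter
must state which layer it taps and how it reaches the contract width.
Input resize for the mini-CNN is bilinear to 227×227 by default.

**Handcrafted features (244 = 12 + 203 + 16 + 13).** Gray conversion uses
the fixed luminance weights (0.299, 0.587, 0.114) and is shared by the
three gray-level blocks.

* *Wavelet statistics (12).* One-level orthonormal 2×2 Haar decomposition
  into LL/LH/HL/HH subbands; mean, population variance and standard
  deviation per subband. Haar was chosen as the basis because its
  orthonormal form makes energy conservation (Parseval) an exactly
  testable invariant; odd image sides are reflect-padded to even.
* *Local binary patterns (203).* The 24 neighbours of each pixel are the
  full 5×5 window minus the centre, scanned row-major; neighbour p
  contributes 2^p when its value is ≥ the centre (ties count as 1, the
  standard convention), giving a 24-bit code. The histogram partitions the
  code space [0, 2^24) into 203 equal-width bins (the last absorbs the
  integer-division remainder) and is L1-normalised. The 203-bin reading is
  the design choice that makes the block arithmetic consistent with the
  244 total (12+203+16+13); it is a histogram compression of the code
  space, not one of the classical uniform/rotation-invariant LBP variants.
  Because codes depend only on the sign of gray differences, the features
  are invariant to constant brightness offsets.
* *Fuzzy colour histogram (16).* Hue is computed per pixel; 16 bin centres
  sit evenly on the hue circle and each pixel splits a unit mass between
  its two nearest centres by triangular membership with circular
  wraparound, after which the histogram is L1-normalised. Soft assignment
  is the point: two colours falling just either side of a hard bin edge
  remain similar in feature space. Achromatic pixels (zero saturation,
  undefined hue) are assigned to bin 1 by convention.
* *Haralick statistics (13).* Gray levels are quantised to L = 8
  equal-width bins over 0..255; for each direction θ ∈ {0°, 45°, 90°,
  135°} (d = 1 axially, the unit diagonal offset diagonally) the
  co-occurrence matrix is symmetrised and normalised, 13 statistics are
  computed (angular second moment, contrast, correlation, sum-of-squares
  variance, inverse difference moment, sum average, sum variance, sum
  entropy, entropy, difference variance, difference entropy, and both
  information measures of correlation), and the four directions are
  averaged. Direction-averaging is what yields 13 features rather than 52.
  Degenerate cases are defined explicitly: 0·log 0 = 0, and correlation
  and the first information measure are 0 when their denominators vanish
  (constant image).

**Fusion.** PCA is fit on training-phase rows only — fitting on all rows
would leak validation/test statistics into the projection; the leaky
variant remains available via `pca$fit_on = "all"` for users who want to
mirror protocols that reduce the whole matrix at once. The requested 1024
components are silently capped at min(k, n−1, d), so small runs degrade
gracefully. Each component's largest-magnitude coordinate is made
positive, removing the sign ambiguity of singular vectors and making
outputs bit-reproducible across row orderings. Fusion itself is plain
column concatenation with block labels, and is lossless by construction.

**Heads.** The SVM head standardises features internally (population
standard deviation, which makes the model invariant to duplicating the
training set) and delegates the hinge-loss optimisation to libsvm with a
linear kernel, C = 1 by default; the decision function is oriented so
positive scores mean malignant, and a score of exactly zero is assigned to
the positive class. The ANN head is implemented in the package: tanh
hidden units, softmax output, cross-entropy loss (squared error by flag),
full-batch gradient descent at a fixed learning rate of 0.01, seeded
initialisation scaled by 1/√fan-in. After every epoch the validation loss
is checked; six consecutive checks without improvement stop training and
the best-validation weights are restored. The per-epoch log (training
loss, validation loss, gradient norm) and the stop reason are kept on the
model object. The hidden layout is configurable: the default is a single
hidden layer of 15 units — for a two-class pattern-recognition problem on
a fixed feature vector, one moderately wide layer is the conventional
choice, and both "10" and "15" readings of the architecture are
expressible via `hidden_layout`.

**Evaluation.** Malignant is the positive class throughout. The panel
reports accuracy, specificity, sensitivity and precision as percentages,
each computed exactly from TP/FP/FN/TN; a metric with a zero denominator
is reported as undefined (`NA`), never as 0. Two AUC-like quantities are
reported: `auc_ratio`, the sensitivity/specificity ratio, and `roc_auc`,
the trapezoidal area under the ROC curve (via pROC). The ratio is not the
standard ROC area; `roc_auc` is the headline quantity. A 20-bin error
histogram over the observed residual range is provided as the standard
training diagnostic.

## The synthetic generator

Real two-class histology data cannot ship with the package, so a seeded
generator emulates the features the pipeline actually consumes: a
per-class base colour (pale eosin pink for normal tissue, darker
hematoxylin purple for malignant — chosen so malignant images are darker
and bluer-shifted in the way H&E malignancies typically over-stain), dark
nucleus-like disks with Gaussian-soft edges placed uniformly at a per-class
density, a sinusoidal texture field at a per-class frequency, and additive
Gaussian noise. Pixels are rounded to integers so PNG round-trips are
lossless. Two presets are fixed: `separable` (the defaults above, far
apart in colour and texture) and `hard` (base colours 15 units apart,
noise sd 18).

What the generator does *not* emulate: stain physics and stain variation
within a class, tissue architecture (glands, stroma, cell clustering),
scanner artifacts, and intra-class heterogeneity of real slides. Passing
tests on the `separable` preset therefore demonstrates that the pipeline's
plumbing, feature mathematics and training loop are correct and that the
features carry colour/texture signal — it says nothing about clinical
accuracy on real slides, which is why the package makes no such claim.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
64×64-pixel images with 100 images per class for the end-to-end accuracy
checks, 32×32 images with 803 per class (1026 training rows, the minimum
that supports the full 1024 PCA components) for the dimensionality run,
and 6×6 to 8×8 patches for the brute-force oracle comparisons. The
class-separation presets themselves are independent of image size, and
the stub backbone's 32×32 down-sampling means its features are unchanged
by the smaller canvases.

Other numerical conventions: reflect padding everywhere a filter meets a
border; Gaussian kernels normalised to sum exactly 1; zero-variance
feature columns given scale 1 during standardisation; softmax computed
with row-max subtraction; cross-entropy clipped at 1e−12 before the log;
non-finite losses abort training with the epoch number rather than
continuing silently.

## Known limitations

* The untrained backbones are contract stubs; results with them say
  nothing about pretrained-transfer performance.
* The 203-bin LBP histogram is a design reading (see above), and coarse:
  bins aggregate many unrelated 24-bit codes.
* Full-batch gradient descent is slow on large fused matrices compared to
  the conjugate-gradient trainers of dedicated neural-network toolboxes;
  it was chosen for determinism and transparency, not speed.
* `auc_ratio` can exceed 1 and is not bounded like a true AUC; it is
  reported for completeness, with `roc_auc` as the recommended quantity.
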