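# raycap

Automatic report generation for chest radiographs with two cooperating
language models, implemented entirely in R and runnable on a single CPU.

Radiologists describe each chest X-ray in a free-text report; drafting
these reports is slow, and automating a first draft is a long-standing
goal of medical image captioning. `raycap` implements a complete
desk-scale version of a two-model architecture for this task:

1. **An attention captioner** ("show, attend and tell" family). A CNN
   encoder turns the image into a grid of spatial feature vectors
   *a* = {*a*₁, …, *a*_N}; an LSTM decoder generates the report word by
   word. At step *t* the attention MLP scores every location,
   *e*ᵢ = *w*ᵀ relu(*U a*ᵢ + *V h*ₜ₋₁ + *b*), the weights
   αₜ = softmax(*e*) sum to one, and the context vector
   â*ₜ* = Σᵢ αₜᵢ *a*ᵢ feeds the LSTM together with the previous word
   embedding. The next word comes from a deep output layer,
   P(zₜ) = softmax(*L*ₒ(*L*ₕ*h*ₜ + *L*ₐâₜ + *E z*ₜ₋₁)). Because the
   weights αₜ are spatial, they double as localization heatmaps for the
   pathology being described.
2. **A decoder-only transformer language model** over byte-pair-encoded
   subwords, fine-tuned self-supervised on report text.

The models are fused two ways: *Approach 1* learns a joint next-word
distribution by concatenating both models' word scores through a small
feed-forward head; *Approach 2* lets the transformer continue the
caption produced by the captioner (seed + start-of-continuation marker,
generation until end-of-text).

The package also provides: the report preprocessing used upstream
(impression/findings assembly with the empty-report exclusion rule,
normalization, abbreviation expansion, label-token prefixing, vocabulary
building, length-sorted batching), BLEU-1..4 / ROUGE-L / CIDEr /
geometric-mean-BLEU caption metrics and micro-averaged clinical-efficacy
metrics, attention-heatmap export, and a deterministic **chest-phantom
simulator** (synthetic torso/lung/heart images with planted, localized
pathologies and template-grammar reports) so the whole pipeline trains
and evaluates without any restricted data. All neural models run on a
compact reverse-mode autodiff engine included in the package — no
external deep-learning framework is required.

## Tests

```r
testthat::test_dir("tests/testthat", package = "raycap")
```

The suite includes property checks (attention weights sum to one,
beam-vs-exhaustive search equivalence, BPE round-trips, metric
equivalence against an independent Python implementation) and learning
properties (a tiny captioner memorizing 10 phantoms, attention
localization on held-out phantoms). The full run takes roughly a quarter
of an hour on one CPU.

## Worked example

```r
library(raycap)

spec <- phantom_spec(seed = 1)
generate_phantom(spec, 0)
#> <phantom_sample> phantom_000000
#>   labels: none
#>   report: none . no acute cardiopulmonary abnormality. no acute cardiopulmonary abnormality.

cfg <- run_config(seed = 1, n_phantoms = 200)   # "desk" profile
res <- run_pipeline(cfg)
res$metrics
```

On the 200-phantom desk run above (20-sample held-out test split, seed
1) the pipeline reports, for the captioner alone (`sat`) and the two
fusion approaches:

```
      model bleu1 bleu4 rouge_l cider ce_accuracy ce_f1
        sat 0.563 0.437   0.680 4.911        0.90 0.783
  approach1 0.217 0.098   0.305 1.368        0.71 0.293
  approach2 0.592 0.450   0.653 4.444        0.90 0.783
```

`bleu1`/`bleu4` are clipped n-gram precisions (1 = perfect match),
`rouge_l` the LCS F-measure, `cider` the consensus metric on its 0–10
scale, and `ce_accuracy`/`ce_f1` the micro-averaged clinical-efficacy
scores obtained by comparing the pathology terms extracted from
generated vs. reference reports. Stacked generation (`approach2`) edges
out the captioner on BLEU, while the joint-distribution fusion
(`approach1`) pays a visible price for discretizing the transformer onto
the word vocabulary at this scale. The companion localization
measurement (`res$localization`) reports the attention mass inside the
true lesion mask at the step where the pathology word is predicted; on
these held-out phantoms the mean mass is 0.477 against a
uniform-attention baseline of 0.060 (the mask's mean area fraction) —
attention concentrates on the planted lesion about eight times more than
chance.

Heatmaps for a decoded caption:

```r
g <- greedy_decode(res$sat, generate_phantom(spec, 300)$image)
maps <- attention_heatmap(g$alphas, D = 7, image_size = 224)
plot_attention(generate_phantom(spec, 300)$image, maps[[1]], g$tokens[1])
```

A thin command-line front end ships in `inst/cli/raycap`
(`simulate`, `run-all`, `caption`, `continue`, `evaluate`).

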