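Package: raycap
Title: Chest X-Ray Report Generation with Visual Attention and a
    Transformer Language Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic radiology report generation from chest
    radiographs using two cooperating language models: a soft-attention
    encoder-decoder captioner (a compact CNN feeding an LSTM that attends
    over spatial feature locations) and a small decoder-only transformer
    language model over byte-pair-encoded subwords.  The two models can be
    fused either by learning a joint next-word distribution or by letting
    the transformer continue the caption produced by the attention model.
    Includes a deterministic chest-phantom simulator with planted,
    localized pathologies and template-grammar reports, radiology report
    preprocessing (section assembly, normalization, abbreviation
    expansion, label prefixing), caption evaluation metrics (BLEU-1..4,
    ROUGE-L, CIDEr, geometric-mean BLEU) and micro-averaged clinical
    efficacy metrics, and attention heatmap export for pathology
    localization.  All models are trained with a small built-in
    reverse-mode automatic differentiation engine, so the package runs on
    a single CPU without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rhdf5,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
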