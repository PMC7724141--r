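Package: scwm
Title: Retinotopic Encoding Models of Spatial Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how retinotopically organized brain regions
    encode spatial working memory from fMRI time series. Implements population
    receptive field (pRF) model fitting with a two-stage (coarse grid plus
    derivative-free refinement) estimator including hemodynamic delay and
    baseline parameters; retinotopy summaries (visual field coverage,
    polar-angle fractional volume, size-eccentricity scaling); a spatial
    inverted encoding model (IEM) over polar angle with raised-cosine channels,
    twofold trial averaging and bootstrap resampling; a modified
    representational fidelity statistic with permutation-null inference at the
    subject and group level; circular-statistics comparison of pRF and IEM
    polar-angle tuning; and a synthetic-data module that simulates bar-sweep
    retinotopy runs and memory-guided saccade sessions with known ground truth
    so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
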