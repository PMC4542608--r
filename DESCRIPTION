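Package: otoraman
Title: Chemometric Classification of Middle-Ear Lesions from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested chemometric pipeline for differentiating proliferative
    middle-ear lesions (cholesteatoma versus mineralized and non-mineralized
    myringosclerosis) from fingerprint-region Raman spectra. Provides cosmic-ray
    despiking (Hampel filter), phosphate nu1-band (960 1/cm) mineralization
    screening, per-class and pooled principal component analysis, RadViz radial
    embedding of principal component scores, class-balanced resampled PLS-DA
    built from the NIPALS recursion with a random-label negative control, and
    ROC/diagnostic-metric reporting. Includes a forward model that simulates
    labelled tissue Raman spectra (Lorentzian/Gaussian bands over a broad
    autofluorescence background, shot noise, sparse cosmic-ray spikes) so the
    whole decision chain can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
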