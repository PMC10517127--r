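Package: perivasc
Title: Perivascular Reflectivity Quantification for En-Face OCT/OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies corrected perivascular reflectivity on paired en-face
    structural OCT and OCT angiography (OCTA) images of the retinal deep
    capillary plexus. Images are split into quadrants, the OCTA quadrant is
    binarized at mean + 2 SD, connected high-signal-strength (HSS) particles
    of at least three pixels are retained, and the mask is transferred to the
    structural image to form the ratio of mean reflectivity on the HSS area to
    the overall en-face mean reflectivity. Also provides vessel density with
    foveal avascular zone exclusion, FAZ morphometrics, the accompanying
    statistical analysis chain (intraclass correlation, one-way ANOVA with
    Bonferroni post-hoc tests, paired quadrant comparison, standardized-beta
    regression with a univariate entry rule, and a disease-duration
    sub-analysis), and a seeded synthetic cohort generator for end-to-end
    validation without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
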