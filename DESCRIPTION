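Package: actionrec
Title: Two-Pathway Form and Motion Model for Recognition of Biological
    Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Biologically inspired recognition of single-person actions in
    grayscale video through two interacting processing streams. The ventral
    (form) stream learns deformable active-basis templates of Gabor wavelet
    elements with a shared sketch algorithm and scores frames against action
    prototypes; the dorsal (motion) stream estimates variational optical
    flow, stabilised by a time-dependent fuzzy inference system over four
    spatial cells. Frame-level decisions are fused either by limb-group
    gating or by an extreme learning machine classifier, and video labels
    are obtained by majority voting. Includes a synthetic generator of
    articulated stick-figure action videos for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
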