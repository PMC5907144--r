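Package: gcstripe
Title: GC-Bias Correction of Tumor/Normal Read-Count Ratios for Subclonal
    Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects the GC-content bias of tumor versus matched-normal
    read-count ratios at the scale of somatic copy-number alteration (SCNA)
    segments.  Segments sharing one average copy number form linear "stripes"
    in the GC versus log-ratio plane whose common slope equals the difference
    in GC-bias curvature between the two libraries; the slope is estimated by
    a Metropolis sampler whose likelihood is the summed height of the top
    kernel-density peaks of the corrected log-ratios, so that the correction
    sharpens stripes instead of regressing through them.  Also provides
    B-allele-frequency based selection of copy-neutral baseline segments by
    hierarchical clustering, ploidy and subclonal-frequency estimation, a
    forward simulator with known truth for validation, and export of corrected
    segment tables for downstream subclonal-reconstruction tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
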