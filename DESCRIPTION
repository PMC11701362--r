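Package: wellkinetics
Title: Multi-Region Colour Kinetics from Well-Plate Reaction Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-well colour kinetics from videos of parallel
    reactions filmed on multi-well plates or racks of vessels. Builds grids
    of circular regions of interest, averages each region's colour per frame
    in sRGB and converts to CIE-L*a*b* and HSV, computes the CIE76 delta-E
    contrast profile against the first frame, and derives kinetic summaries:
    reaction end points by plateau analysis of the delta-E gradient,
    induction times from the maximum rate of colour change, and area under
    the delta-E curve for sedimentation grading. Also quantifies glare via
    pixel dispersion in the L*-b* plane, ranks colour channels against
    offline measurements (e.g. HPLC conversion) by normalised mutual
    information, and renders synthetic plate videos with programmed kinetics
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    tibble,
    readr,
    jsonlite,
    yaml,
    png,
    tiff,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
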