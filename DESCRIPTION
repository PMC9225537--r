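Package: silentsub
Title: Design and Analysis of Melanopsin-Isolating Metameric Light Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for silent-substitution stimulus design targeting
    intrinsically photosensitive retinal ganglion cells (ipRGCs).  Builds an
    orthogonal spectral basis over the five human photoreceptor sensitivities
    (L, M, S cones, rods, melanopsin) so that one basis coefficient modulates
    melanopsin excitation while cone and rod excitations stay fixed; computes
    the feasible melanopsin-modulation interval of a bounded-output
    multispectral projector at any target chromaticity; scans chromaticity
    space for the achievable modulation gamut; constructs metameric and
    five-way metameric (pentameric) stimulus pairs; verifies designs
    colorimetrically (xy chromaticity, CIELAB); and analyses discrimination
    experiment response tables, including a synthetic response generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    sp,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
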