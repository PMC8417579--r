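Package: ovadce
Title: Quantitative DCE-MRI Mapping of Ovarian Follicular Vasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise pharmacokinetic analysis of dynamic contrast-enhanced
    MRI with a macromolecular (albumin-based) contrast agent: variable
    flip-angle SPGR T1 mapping, conversion of dynamic signal to contrast
    concentration via relaxivity, and linear-regression derivation of
    fractional blood volume (fBV), permeability surface area product (PS)
    and late-enhancement rate maps. Includes ROI histogram statistics with
    per-bin and paired t-tests, a dominant/subordinate follicle
    classification rule, and a digital ovary phantom generator with known
    ground truth for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
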