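Package: lvind
Title: Inward Displacement Analysis of Regional Left Ventricular Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes inward displacement (InD), a regional measure of left
    ventricular systolic function, from endocardial contours of the three
    standard long-axis cine views (2CH, 3CH, 4CH) at end-diastole and
    end-systole.  Point-wise displacement toward a base-to-apex dependent
    centre of contraction is normalised to the theoretical shrink-to-centre
    limit and aggregated onto the AHA 17-segment bullseye.  Also derives
    ventricular volumes, ejection fraction and global longitudinal strain by
    a triplane method of disks, ships normal reference ranges with z-score
    comparison and wall-motion classification, provides interobserver
    agreement statistics (Pearson regression, Bland-Altman) and cohort
    summary tables, and includes a parametric contracting-ventricle phantom
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
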