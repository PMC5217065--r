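Package: coquina
Title: Orientation Fabrics of Fossil Shell Beds from Virtual Serial Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of shell concentrations (coquinas) built from
    serial-section data: synthetic three-dimensional shell-bed generation with
    controlled orientation fabrics, virtual slicing at a fixed grinding interval,
    specimen reconstruction by cross-section connectivity, landmark-based
    measurement of planispiral and helical shell orientations (lineation
    trend/plunge, aperture direction, sagittal-plane dip and dip direction),
    circular and spherical directional statistics (rose diagrams, lower-hemisphere
    stereographic projections, Fisher mean with cone of confidence, preferred
    orientation), stratigraphic overturn correction, and abundance extrapolation
    from a reference block to a bed's mapped extent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
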