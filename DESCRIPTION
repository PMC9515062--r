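Package: fidloc
Title: Automatic Fiducial Marker Localization in CT and MRI Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects a reattachable eight-sphere fiducial skin marker in CT
    and MRI volumes and estimates its rigid pose. A self-adjusting filter
    pipeline reduces the volume to bright-sphere candidate features, a
    pairwise-distance configuration matcher establishes the
    candidate-to-geometry correspondence, and Horn's closed-form
    unit-quaternion method yields the marker-to-image transform. Includes
    the associated assessment statistics (point prediction error, clipping
    precision, target registration error), readers and writers for
    MetaImage, NIfTI-1 and uncompressed DICOM series, a rigid-transform
    algebra with CT-to-ultrasound chain composition, and a ground-truthed
    synthetic phantom generator reproducing a point-symmetric six-station
    evaluation setup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
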