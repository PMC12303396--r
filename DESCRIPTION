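Package: scalpmorph
Title: Photogrammetric Scalp Morphology Estimation from Colored 3D Head Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating participant-specific scalp morphology from a
    colored 3D surface scan of a photogrammetric cap, for use in functional
    near-infrared spectroscopy (fNIRS) and high-density diffuse optical
    tomography (HD-DOT) head modelling. The pipeline isolates red triangular
    fiducials on cap-mounted modules by color filtering, partitions them into
    per-module clusters, recovers each module's six degree-of-freedom pose from
    the 3-4-5 fiducial triangle, projects the module feet through hair onto the
    scalp, and fits a template head surface to the resulting sparse scalp
    sample. Validation machinery constructs geodesic 10-20 and modified 10-5
    electrode montages on head surfaces, computes rigid, four-point affine and
    anisotropically scaled registrations, and summarises per-position Euclidean
    errors. A synthetic phantom generator produces cap scans with known ground
    truth (hair envelope, black module bodies, red fiducial triangles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
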