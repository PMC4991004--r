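Package: topolight
Title: Topology-Aware Illumination Design for Direct Volume Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simplifies the contour tree of a 3D scalar field,
    derives per-branch topological attributes (persistence, volume,
    hypervolume, depth, siblings, saliency), and automatically generates
    per-structure illumination parameters by four mechanisms: Stokes-law
    lighting attenuation, topological saliency, topological distance, and a
    two-phase Just-Noticeable-Difference perceptual contrast model. Includes
    a CPU ray-casting volume renderer with Blinn-Phong shading indexed by the
    contour-tree segmentation, synthetic volume generators with analytically
    known topology, and raw/NRRD volume IO.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
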