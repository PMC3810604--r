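Package: scenestats
Title: Object-Scene Context Statistics for Polygon-Annotated Scene Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the contextual statistics of objects in
    annotated natural-scene photographs. Reads and cleans LabelMe-style
    polygon annotations, computes per-scene ensemble statistics (object
    density, variety, size, center of mass, spacing regularity), bag-of-words
    statistics (object frequency, Zipf rank-frequency, diagnosticity,
    scene-object specificity, co-occurrence, frequent object groups, entropy,
    mutual information), and structural statistics (position variance,
    occupancy maps, indoor/outdoor location contrasts, quadrant features),
    and evaluates each representation's sufficiency for basic- and
    superordinate-level scene categorization with leave-one-out linear
    support-vector classification. Includes a seeded synthetic-annotation
    generator emulating the statistical structure of hand-labeled scene
    databases so every analysis stage can be exercised without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
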