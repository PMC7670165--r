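Package: coronoid
Title: Bilateral Coronoid-Process Morphometry from Proximal-Ulna Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphometric analysis of the ulnar coronoid process from
    CT-derived surface models of the proximal ulna. Builds the anatomical
    local coordinate system from the shaft axis and the ridge of the greater
    sigmoid notch, trims the upper-40% coronoid target fragment with a
    cutting plane parallel to the posterior flat spot of the olecranon,
    measures fragment height, length, width and the medial and lateral facet
    radii, mirror-registers the left coronoid onto the right, and quantifies
    articular-surface similarity as a Delaunay-area covering percentage.
    Includes a parametric synthetic ulna-pair generator with full measurement
    ground truth, cohort-level Student t comparisons by sex, age group and
    laterality, and readers/writers for PLY, STL, OBJ and XYZ point-cloud
    surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RANN,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
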