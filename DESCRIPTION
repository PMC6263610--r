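Package: leaffacet
Title: Individual Leaf Segmentation of Dense Plant Point Clouds by Facet
    Region Growing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments individual leaves from dense, unorganized 3D point
    clouds of greenhouse plants. Implements the full facet-based pipeline:
    outlier and non-leaf filtering (ground plane, excess-green, radius and
    statistical outlier removal), per-point normal and smoothness
    estimation by iterative PCA over a shrinking inlier neighborhood,
    facet over-segmentation with local K-means boundary refinement,
    breadth-first facet region growing under adjacency and coplanarity
    constraints, and leaf-level segmentation quality metrics (recall,
    precision, F-measure and cover rate under a 70 percent coverage rule).
    Ships a labelled synthetic canopy generator (curved leaves, ground,
    pot, sparse outliers) so every stage can be exercised without scanned
    data, plus readers and writers for PLY, PCD and XYZ point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
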