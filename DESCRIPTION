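Package: mitotyper
Title: Mitochondrial Pathway Scoring and Prioritization (Mitotyping)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mitochondrial specialization ("mitotypes") from bulk
    transcriptomic or proteomic expression matrices. Computes MitoPathway
    composite scores (mean expression of MitoCarta3.0 pathway member genes)
    and mitochondrial Pathway Prioritization Scores (mitoPPS), a ratio-based
    metric of how much a sample prioritizes each mitochondrial pathway
    relative to all other pathways and samples, invariant to overall
    mitochondrial content. Includes readers for common expression formats
    (GCT, long-format tissue consensus TSV, delimited matrices), TMM
    library-size normalization via edgeR, half-minimum imputation for
    proteomics intensities, the multivariate mapping layer (PCA, Ward.D2
    hierarchical clustering, k-means, Spearman correlation networks), a
    two-group test decision tree with Hedges' g effect sizes, and a
    synthetic-data generator with planted pathway prioritizations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
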