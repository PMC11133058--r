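Package: fmgen
Title: Automated Generation of DRM False-Memory Stimulus Lists from Vector Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds Deese-Roediger-McDermott (DRM) false-memory stimulus lists
    directly from any vector space (word embeddings or other item
    representations) instead of human association norms. Lists are seeded by
    k-means clustering of the space, studied items are drawn from an
    iteratively re-centred cosine neighborhood ("close space"), and new items
    (critical and unrelated lures) are selected either at random or stratified
    over logarithmically spaced distance bins. Includes readers and writers
    for word2vec/GloVe text embedding formats, a synthetic clustered-space
    generator for testing, tab-separated list outputs, a command-line
    interface, and the small closed-form statistics used to validate
    generated lists (A-prime discriminability screening and AIC evidence
    ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
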