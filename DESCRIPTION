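Package: browningnet
Title: Condition-Responsive lncRNA Discovery and Guilt-by-Association Networks
    in Adipose Browning
Version: 0.1.0
Authors@R:
    person("browningnet", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering condition-responsive long noncoding RNAs in
    multi-condition adipose browning/whitening RNA-seq designs and inferring
    their function by guilt-by-association. Implements per-contrast
    differential-regulation calling on FPKM with cross-condition consensus
    filters, shrinkage (Schaefer-Strimmer) partial-correlation network
    inference with mixture-null edge FDR, fast-greedy modularity community
    detection, hypergeometric/binomial set enrichment and preranked GSEA,
    tissue-specificity calling over a multi-tissue panel, strand-aware
    promoter-window ChIP-peak overlap enrichment, a sliding-window UGU-density
    scan of 3'UTRs for RNA-binding-protein site candidates, sample ordination
    (PCA, Ward/Spearman clustering), and a seeded synthetic-study generator
    with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
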