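Package: cfnips
Title: Aneuploidy Screening from Low-Pass Cell-Free DNA Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bin-based non-invasive prenatal screening (NIPS) pipeline for
    shallow shotgun cell-free DNA sequencing. Takes per-bin read counts over a
    binned genome, normalizes by autosomal totals, corrects GC bias with local
    polynomial (loess) regression, removes high-order artifacts with a PCA
    model fitted on euploid training samples, and applies robust bin-level
    smoothing. Chromosome and region representations are scored as
    MAD-calibrated Z-scores against a plate-median reference to call trisomies
    13, 18 and 21 and microdeletion/microduplication regions. Fetal fraction
    is estimated by four X/Y-based methods with a median consensus for male
    fetuses and by an L1-regularized autosomal regression for female fetuses.
    Sex-chromosome aneuploidies are classified in the (X-based, Y-based)
    fetal-fraction plane with maternal-mosaicism safeguards, and reporting
    rules screen out maternal microduplications and global copy-number
    abnormalities before a positive call. A negative-binomial cohort simulator
    with known truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
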