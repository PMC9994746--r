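Package: preplink
Title: Preprint to Publication Record Linkage
Version: 0.1.0
Authors@R: person("preplink", "maintainers", email = "maintainers@preplink.invalid", role = c("aut", "cre"))
Description: Links biomedical preprints to their peer-reviewed published
    versions. Parses MEDLINE/PubMed-dialect citation XML and preprint metadata,
    trains subword-aware word embeddings on corpus samples, retrieves match
    candidates by top-k cosine similarity over out-of-core vector indices,
    scores author overlap with a Jaccard statistic robust to flipped name
    fields, and decides matches with a support vector machine plus a layer of
    rescue and veto rules. Ships an evaluation harness (test-set construction
    flow, recall/precision/F1, exact McNemar paired comparison, feature
    ablations, time-gap reporting) and a synthetic corpus generator with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
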