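Package: rxsig
Title: Annotation, Tagging and Normalization of Prescription Directions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured annotation of free-text prescription
    directions ("sigs"). Provides a 19-label medication-regimen annotation
    schema with typed, validated attributes; a numeric retokenizer that
    canonicalizes English number expressions while preserving character
    offsets; a linear-chain sequence tagger (BIO encoding) with a
    decode-time precision/recall bias; attribute normalization by baseline,
    literal-match, Levenshtein-fallback, maximum-entropy classifier and
    hybrid methods; span/label scoring and pairwise inter-annotator
    agreement by F-measure; a seeded synthetic sig generator with paired
    structured prescription records; export to FHIR-Dosage-shaped JSON and
    inline XML; and discrepancy detection between text-derived regimens and
    pharmacist-entered structured fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
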