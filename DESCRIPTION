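Package: hybdiag
Title: Hybrid Diagnosis from Character Additivity in Multi-Copy Nuclear
    Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies hybrid individuals from direct Sanger reads of
    multi-copy nuclear markers (ITS, 5S-NTS) by scoring IUPAC character
    additivity at positions diagnostic between two candidate parental
    taxa.  Includes a four-channel trace model for calling 'major' and
    sensitive sequences from polymorphic electropherograms, simulating
    skewed two-ribotype mixtures (with 1-bp indel frame shifts) and the
    winner-take-all base-caller artifact that produces chimeric reads;
    simple indel coding of alignment gaps into binary characters;
    in-silico restriction (RFLP) pre-screen design for rare ribotypes,
    including clone-screen sizing; and a synthetic-data generator with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
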