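Package: metawax
Title: Wax Ester and Triacylglycerol Biosynthetic Potential of Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the wax-ester/triacylglycerol biosynthetic potential of
    microbial communities from metagenome protein sets. Detects homologs of the
    wax ester synthase/acyl-CoA:diacylglycerol acyltransferase (WS/DGAT) marker
    domain with a calibrated position-specific scoring matrix or ingested
    domain-hit tables, estimates scaffold-depth-corrected gene copies,
    normalizes them against a panel of twelve single-copy ribosomal-protein
    genes, bins homologs taxonomically by weighted lowest common ancestor,
    clusters them into operational protein units (OPUs) at a fixed identity
    cutoff, runs the associated community statistics (Wisconsin
    standardization, Bray-Curtis, NMDS, ANOSIM, exact rank tests, ANCOM W),
    and profiles the lipid-metabolism gene neighborhood of marker hits.
    Includes a synthetic-metagenome generator with planted ground truth so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
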