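Package: sexlinkr
Title: Sex-Linked Marker Discovery and Homeolog Filtering for Family Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering the sex-determination system of a species
    from genotype-by-sequencing (GBS) data on a single two-parent family
    cross.  Provides family-based genotype quality control with correction of
    heterozygote undercalling (allele dropout), a scan for completely
    sex-biased inheritance with classification of each marker as a W-, Z-,
    X- or Y-chromosome pattern, inference of female (ZZ/ZW) versus male
    (XX/XY) heterogamety, a phylogeny-based filter that separates orthologous
    from homeologous sequences in allotetraploid gene families, classification
    of short sequence tags by their homology-hit pattern against a reference
    genome, and small phylogenetic utilities (harmonic-mean Bayes factors for
    clock-model comparison and chronogram rescaling to a drawn root age).
    Includes simulators for family-cross genotype data and for gene families
    evolving through a whole-genome duplication, with ground truth, so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
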