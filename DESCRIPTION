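Package: tetramap
Title: Linkage Mapping and Homeology Detection for Pseudo-Tetraploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building dense SNP linkage maps in species with a
    residually duplicated (pseudo-tetraploid) genome such as Atlantic salmon.
    Provides deterministic one-dimensional Gaussian-mixture clustering of
    allelic-ratio intensity data to classify markers as diploid SNPs or
    multisite variants (MSV-3/MSV-5), polyploid dosage calling and family-based
    resolution of MSV-5 genotypes into their two duplicated loci, two-point
    recombination-fraction and LOD estimation by EM over parental phase,
    stepwise linkage grouping with anchor markers, marker ordering with
    window-permutation refinement, phase-string construction with
    double-recombinant genotype correction, sex-specific multipoint maps under
    Kosambi or Haldane mapping functions, detection of male-specific
    pseudo-linkage, and identification of homeologous chromosome-arm pairs from
    dual-locus MSV-5 placements, within-genome paralogous sequence hits and
    outgroup synteny anchors. A synthetic-data generator simulates the whole
    study design (genome model, half-sib/full-sib pedigrees, sex-specific
    crossover landscapes, bead-array style intensities, flanking and outgroup
    sequences) so every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
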