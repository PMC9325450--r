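Package: SweepScan
Title: Windowed Selective-Sweep Scans and Population-Genomic Summaries
    from SNP Genotype Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population-genomic analysis of multi-sample SNP call sets,
    built around the joint windowed scan used in domestication genomics:
    per-subgroup nucleotide diversity (pi), Hudson's FST as a windowed
    ratio of averages, log2 pi-ratio between a wild and a cultivated
    group, and selective-sweep calling as windows jointly in the top 5%
    empirical percentiles of both statistics, followed by window merging
    and gene overlap. Also provides site-level VCF quality filtering
    (depth, RMS mapping quality, minor-allele frequency, missingness),
    SNP region classification against a GFF3 annotation, subgroup SNP
    sharing, per-accession heterozygosity, an allele-sharing p-distance
    matrix with a neighbor-joining tree, and genotype PCA with Patterson
    normalization. A Balding-Nichols multi-population genotype simulator
    with planted sweeps supplies ground-truth datasets so every stage is
    verifiable without large resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'pipeline.R'
    'popgen.R'
    'qc.R'
    'simulate.R'
    'structure.R'
    'sweeps.R'
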