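Package: genoImputeQC
Title: Benchmarking Pre-Imputation SNP Filtering and Genotype Imputation Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates genotype-imputation quality under different
    pre-imputation SNP-filtering strategies. Provides per-SNP quality
    statistics (minor allele frequency, call rate, exact Hardy-Weinberg
    test) and the sixteen named filter scenarios built from them; nested
    random masking of high-quality genotypes or whole SNPs with stored
    truth; genotype-level imputation quality scores based on the Hellinger
    affinity of trinomial genotype distributions and on scaled Euclidean
    agreement of expected allele doses, together with re-implementations of
    the MaCH-rsq and IMPUTE-info SNP-wise certainty measures; paired
    McNemar comparisons of dichotomised well-imputed flags with
    Bonferroni-Holm adjustment; and a synthetic-data module (LD-structured
    haplotype panels, genotyping error, missingness, low-quality SNP
    contamination) with two built-in posterior-producing imputers so the
    whole evaluation chain runs without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
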