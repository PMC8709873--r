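# Annotated-variant fixtures shared across filter tests.

variantRow <- function(id, impact = "MODERATE", sift = "deleterious",
                       polyphen = "probably_damaging",
                       consequence = "missense", caseHet = 28, caseHom = 0,
                       caseN = 4376, famCarriers = 6,
                       kgAc = 29, kgAn = 8758, gnomadAc = 413,
                       gnomadAn = 126558) {
  data.frame(id = id, chrom = "2", pos = 50847195L, ref = "G", alt = "A",
             rsid = NA_character_, impact = impact, sift = sift,
             polyphen = polyphen, consequence = consequence,
             caseHet = caseHet, caseHom = caseHom, caseN = caseN,
             famCarriers = famCarriers,
             controlAc_1kg = kgAc, controlAn_1kg = kgAn,
             controlAc_gnomad = gnomadAc, controlAn_gnomad = gnomadAn,
             stringsAsFactors = FALSE)
}

# The two cohort target variants (28 and 10 heterozygous carriers among
# 4376 cases, damaging SIFT/PolyPhen annotations, rare in both control
# panels) plus planted decoys, each designed to fail exactly one rule.
cohortFixture <- function() {
  rbind(
    variantRow("P469S", polyphen = "possibly_damaging",
               caseHet = 28, kgAc = 29, kgAn = 8758,
               gnomadAc = 413, gnomadAn = 126558),
    variantRow("H885Y", caseHet = 10, kgAc = 11, kgAn = 8762,
               gnomadAc = 134, gnomadAn = 127740),
    variantRow("decoy_synonymous", consequence = "synonymous", caseHet = 30),
    variantRow("decoy_benign", sift = "tolerated", polyphen = "benign",
               caseHet = 30),
    variantRow("decoy_too_rare", caseHet = 3),
    variantRow("decoy_common_controls", caseHet = 40, kgAc = 200, kgAn = 8758),
    variantRow("decoy_unannotated", sift = NA, polyphen = NA)
  )
}
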