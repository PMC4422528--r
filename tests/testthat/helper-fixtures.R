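# shared in-code fixtures: every test input is built programmatically

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# a small genome with two genes whose exons are known substrings, so that
# lift-over results can be checked against exact coordinates
toyGenomePair <- function(seed = 11L) {
  set.seed(seed)
  chr1 <- randomDna(4000)
  chr2 <- randomDna(3000)
  # gene G1 (+): exons at chr1:1001-1150 and chr1:1401-1520
  # gene G2 (-): exon at chr2:501-700
  catalog <- exonCatalog(
    exonId = c("E1", "E2", "E3"),
    geneId = c("G1", "G1", "G2"),
    geneName = c("Abc", "Abc", "Xyz"),
    chromosome = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    sequence = c(substr(chr1, 1001, 1150), substr(chr1, 1401, 1520),
                 substr(chr2, 501, 700)))
  list(genome = c(chr1 = chr1, chr2 = chr2), catalog = catalog)
}

# minimal annotated cohort: 3 lines x 2 samples, hand-set genotypes
toyVariantSet <- function(chrom, pos, ref, alt, geno, info = NULL) {
  variantSet(chrom = chrom, pos = pos, ref = ref, alt = alt, geno = geno,
             info = info)
}

toyLines <- function(nLines = 3L, samplesPerLine = 2L,
                     inheritance = NULL, regions = NULL) {
  if (is.null(inheritance))
    inheritance <- rep_len(c("recessive", "dominant"), nLines)
  specs <- lapply(seq_len(nLines), function(i) {
    lineSpec(sprintf("L%d", i),
             sprintf("L%d_s%d", i, seq_len(samplesPerLine)),
             inheritance[i],
             if (!is.null(regions) && i <= length(regions)) regions[[i]]
             else NULL)
  })
  names(specs) <- vapply(specs, lineId, "")
  specs
}

cohortSamples <- function(lines) unname(unlist(lapply(lines, lineSamples)))

# genotype matrix where every sample is hom-ref except explicit overrides;
# overrides: list of list(line = "L1", gt = "1/1") per record
genoMatrix <- function(nRecords, lines, overrides = vector("list", nRecords)) {
  samples <- cohortSamples(lines)
  g <- matrix("0/0", nrow = nRecords, ncol = length(samples),
              dimnames = list(NULL, samples))
  for (r in seq_len(nRecords)) {
    ov <- overrides[[r]]
    if (is.null(ov)) next
    for (o in ov) {
      cols <- if (o$line == "*") samples else lineSamples(lines[[o$line]])
      if (!is.null(o$sample)) cols <- o$sample
      g[r, cols] <- o$gt
    }
  }
  g
}

quietly <- function(expr) suppressMessages(expr)
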