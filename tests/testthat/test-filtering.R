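# inheritance-model genotype selection, privacy, gene restriction,
# one-per-gene exclusion, linkage restriction and ENU typing

test_that("expected genotypes follow the inheritance model", {
  expect_equal(expectedGenotype("recessive"), "1/1")
  expect_equal(expectedGenotype("dominant"), "0/1")
  expect_error(expectedGenotype("additive"), "additive")
})

test_that("privacy keeps sites with the expected genotype in the line and hom-ref elsewhere", {
  lines <- toyLines(3L, 2L, inheritance = c("recessive", "dominant", "dominant"))
  ov <- list(
    list(list(line = "L1", gt = "1/1")),                       # kept for L1
    list(list(line = "L1", gt = "1/1"),
         list(line = "L2", sample = "L2_s1", gt = "0/1")),     # other line not ref
    list(list(line = "L1", gt = "1/1"),
         list(line = "L1", sample = "L1_s2", gt = ".")),       # target missing
    list(list(line = "*", gt = "1/1")),                        # shared
    list(list(line = "L2", gt = "0/1"))                        # kept for L2
  )
  vs <- toyVariantSet(rep("chr1", 5), c(10L, 20L, 30L, 40L, 50L),
                      rep("A", 5), rep("T", 5), genoMatrix(5, lines, ov))
  expect_equal(privateLineFilter(vs, lines, "L1")@pos, 10L)
  expect_equal(privateLineFilter(vs, lines, "L2")@pos, 50L)
  expect_equal(length(privateLineFilter(vs, lines, "L3")), 0L)
})

test_that("the lenient missing policy tolerates missing calls in other lines only", {
  lines <- toyLines(2L, 2L, inheritance = c("recessive", "dominant"))
  ov <- list(
    list(list(line = "L1", gt = "1/1"),
         list(line = "L2", sample = "L2_s1", gt = ".")),
    list(list(line = "L1", gt = "1/1"),
         list(line = "L1", sample = "L1_s1", gt = ".")))
  vs <- toyVariantSet(rep("chr1", 2), c(10L, 20L), rep("A", 2), rep("T", 2),
                      genoMatrix(2, lines, ov))
  expect_equal(length(privateLineFilter(vs, lines, "L1", "strict")), 0L)
  expect_equal(privateLineFilter(vs, lines, "L1", "lenient")@pos, 10L)
  # a missing call in the target line always excludes
  expect_false(20L %in% privateLineFilter(vs, lines, "L1", "lenient")@pos)
})

test_that("a sample mismatch between VCF and line config is reported by name", {
  lines <- toyLines(2L, 2L)
  vs <- toyVariantSet("chr1", 10L, "A", "T",
                      matrix("0/0", 1, 1, dimnames = list(NULL, "L1_s1")))
  expect_error(privateLineFilter(vs, lines, "L1"), "L1_s2")
})

infoVs <- function(infos) {
  n <- length(infos)
  variantSet(chrom = rep("chr1", n), pos = seq(10L, by = 10L, length.out = n),
             ref = rep("A", n), alt = rep("T", n),
             geno = matrix("0/1", n, 1, dimnames = list(NULL, "s1")),
             info = infos)
}

test_that("exon-level containment requires EID; gene level requires GIR", {
  vs <- infoVs(list(list(EID = "E1", GID = "G1", GIR = "G1"),
                    list(GIR = "G1"),
                    list()))
  expect_equal(exonicFilter(vs, "exon")@pos, 10L)
  expect_equal(exonicFilter(vs, "gene")@pos, c(10L, 20L))
})

test_that("one-per-gene excludes every record of a multi-hit gene, including overlaps", {
  vs <- infoVs(list(list(GIR = "G"), list(GIR = "G"),
                    list(GIR = "H"),
                    list(GIR = c("G", "H"))))
  kept <- onePerGeneFilter(vs)
  # G holds records 1,2,4 (>= 2) so all three go; H holds 3,4 -> record 3 goes too
  expect_equal(length(kept), 0L)
  vs2 <- infoVs(list(list(GIR = "G"), list(GIR = "G"), list(GIR = "H")))
  expect_equal(onePerGeneFilter(vs2)@pos, 30L)
})

test_that("exactly the four ENU base changes flag, and the set is closed under reverse complement", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  flagged <- pairs[enuTypeFlag(pairs$ref, pairs$alt), ]
  expect_equal(nrow(pairs), 12L)
  expect_setequal(paste0(flagged$ref, ">", flagged$alt),
                  c("T>C", "A>G", "T>A", "A>T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(pairs)))
    expect_equal(enuTypeFlag(comp[[pairs$ref[i]]], comp[[pairs$alt[i]]]),
                 enuTypeFlag(pairs$ref[i], pairs$alt[i]))
  expect_false(enuTypeFlag("T", "TA"))
  expect_false(enuTypeFlag("TT", "C"))
})

test_that("linkage restriction keeps in-region records and marks absence as not applicable", {
  vs <- variantSet(chrom = c("chr1", "chr2"), pos = c(500L, 500L),
                   ref = c("A", "A"), alt = c("T", "T"),
                   geno = matrix("0/1", 2, 1, dimnames = list(NULL, "s1")))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  kept <- linkageRestrict(vs, region)
  expect_equal(kept@chrom, "chr1")
  expect_true(attr(kept, "linkage_applied"))
  all <- linkageRestrict(vs, NULL)
  expect_equal(length(all), 2L)
  expect_false(attr(all, "linkage_applied"))
})

test_that("the cascade isolates planted variants and excludes shared ones", {
  cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 40000L, nGenes = 8L,
                   nLines = 3L, nSharedVariants = 0L, nNoisePerLine = 0L,
                   seed = 3L)
  pair <- simulateGenomePair(cfg)
  cohort <- simulateCohort(cfg, pair)
  lift <- quietly(liftoverExons(pair$catalog, pair$target))
  ann <- annotateVariants(cohort$variants,
                          buildFeatureIndex(c(lift$exons, lift$genes)))
  res <- runCascade(ann, cohort$lines)
  # noise-free: each line's candidate list is exactly its planted variant
  for (ln in names(cohort$lines)) {
    cand <- res$candidates[[ln]]
    tr <- cohort$truth$planted[cohort$truth$planted$line_id == ln, ]
    expect_equal(length(cand), 1L)
    expect_equal(cand@chrom, tr$chrom)
    expect_equal(cand@pos, tr$pos)
    expect_equal(variantInfo(cand)[[1]]$ENU, "1")
  }
  expect_true(all(res$summary$n_candidates == 1L))

  # adding a shared strain variant (all lines non-reference) changes nothing
  cfg2 <- simConfig(nChromosomes = 2L, chromosomeLength = 40000L, nGenes = 8L,
                    nLines = 3L, nSharedVariants = 25L, nNoisePerLine = 0L,
                    seed = 3L)
  pair2 <- simulateGenomePair(cfg2)
  cohort2 <- simulateCohort(cfg2, pair2)
  lift2 <- quietly(liftoverExons(pair2$catalog, pair2$target))
  ann2 <- annotateVariants(cohort2$variants,
                           buildFeatureIndex(c(lift2$exons, lift2$genes)))
  res2 <- runCascade(ann2, cohort2$lines)
  sharedKeys <- paste(cohort2$truth$shared$chrom, cohort2$truth$shared$pos)
  for (ln in names(cohort2$lines)) {
    cand <- res2$candidates[[ln]]
    expect_false(any(paste(cand@chrom, cand@pos) %in% sharedKeys))
  }
})

test_that("two planted variants in one gene are both removed at the one-per-gene stage", {
  lines <- toyLines(2L, 2L, inheritance = c("recessive", "dominant"))
  ov <- lapply(1:3, function(i) list(list(line = "L1", gt = "1/1")))
  vs <- toyVariantSet(rep("chr1", 3), c(10L, 20L, 30L), c("T", "T", "A"),
                      c("C", "A", "G"), genoMatrix(3, lines, ov),
                      info = list(list(EID = "E1", GID = "G1", GIR = "G1"),
                                  list(EID = "E2", GID = "G1", GIR = "G1"),
                                  list(EID = "E9", GID = "G9", GIR = "G9")))
  res <- runCascade(vs, lines)
  s <- res$summary[res$summary$line_id == "L1", ]
  expect_equal(s$n_private, 3L)
  expect_equal(s$n_exonic, 3L)
  expect_equal(s$n_one_per_gene, 1L)
  expect_equal(res$candidates$L1@pos, 30L)
})

test_that("every cascade stage count is non-increasing and candidates are line-exclusive", {
  for (seed in 1:10) {
    co <- randomCohort(seed + 100L)
    res <- runCascade(co$variants, co$lines)
    s <- res$summary
    expect_true(all(s$n_exonic <= s$n_private))
    expect_true(all(s$n_one_per_gene <= s$n_exonic))
    link <- ifelse(is.na(s$n_in_linkage), s$n_one_per_gene, s$n_in_linkage)
    expect_true(all(link <= s$n_one_per_gene))
    expect_true(all(s$n_enu_type <= link))
    expect_true(all(s$n_candidates <= link))
    keys <- lapply(res$candidates, candidateKeys)
    for (a in seq_along(keys))
      for (b in seq_along(keys))
        if (a < b) expect_equal(length(intersect(keys[[a]], keys[[b]])), 0L)
  }
})

test_that("more sequenced animals per line reduce expected candidate counts", {
  # with genotypes drawn independently per sample, a site passes the
  # within-line test with probability p^k, so candidate counts must fall
  # (in expectation) as animals are added; verified by simulation
  set.seed(77)
  meanCandidates <- function(k, trials = 300L) {
    counts <- vapply(seq_len(trials), function(t) {
      lines <- toyLines(2L, k, inheritance = c("recessive", "dominant"))
      n <- 30L
      g <- matrix(sample(c("0/0", "0/1", "1/1"), n * 2L * k, TRUE,
                         prob = c(0.6, 0.2, 0.2)),
                  nrow = n, dimnames = list(NULL, cohortSamples(lines)))
      vs <- toyVariantSet(rep("chr1", n), seq_len(n) * 10L, rep("A", n),
                          rep("T", n), g,
                          info = rep(list(list(EID = "E", GID = "G",
                                               GIR = "G")), n))
      length(privateLineFilter(vs, lines, "L1"))
    }, 0L)
    mean(counts)
  }
  m2 <- meanCandidates(2L)
  m4 <- meanCandidates(4L)
  expect_true(m4 <= m2)
})

test_that("multi-allelic genotypes are tested literally against the expected pair", {
  lines <- toyLines(2L, 2L, inheritance = c("recessive", "dominant"))
  ov <- list(list(list(line = "L1", gt = "2/2")),
             list(list(line = "L1", gt = "1/1")))
  vs <- toyVariantSet(rep("chr1", 2), c(10L, 20L), rep("A", 2),
                      list(c("T", "G"), c("T", "G")),
                      genoMatrix(2, lines, ov))
  kept <- privateLineFilter(vs, lines, "L1")
  expect_equal(kept@pos, 20L)  # {2,2} does not satisfy recessive {1,1}
})
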