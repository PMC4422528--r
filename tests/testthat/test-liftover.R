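# seed index, best-hit alignment, feature derivation and identity summary

test_that("k-mer index reports exact positions and honours reverse-complement lookup", {
  idx <- buildKmerIndex(c(chr1 = "ACGTACGTACGT"), k = 8)
  hits <- kmerPositions(idx, "ACGTACGT")
  expect_equal(hits$pos, c(1L, 5L))
  expect_equal(hits$chrom, c("chr1", "chr1"))
  expect_equal(nrow(kmerPositions(idx, "TTTTTTTT")), 0L)
  # minus strand looks up the reverse complement
  rc <- kmerPositions(idx, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ACGTACGT"))),
    strand = "-")
  expect_equal(rc$pos, c(1L, 5L))
})

test_that("index of a genome and of its reverse complement find mirrored seeds", {
  set.seed(5)
  L <- 500L; k <- 12L
  g <- randomDna(L)
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  idx <- buildKmerIndex(c(c1 = g), k = k)
  idxRC <- buildKmerIndex(c(c1 = grc), k = k)
  for (i in 1:25) {
    p <- sample.int(L - k + 1L, 1L)
    kmer <- substr(g, p, p + k - 1L)
    fwd <- kmerPositions(idx, kmer)$pos
    mir <- kmerPositions(idxRC, kmer, strand = "-")$pos
    expect_setequal(L - k + 2L - mir, fwd)
  }
})

test_that("index construction rejects k larger than every sequence", {
  expect_error(buildKmerIndex(c(chr1 = "ACGTACGTAC"), k = 16), "larger")
  expect_error(buildKmerIndex(c(chr1 = "ACGTACGTAC"), k = 4), ">= 8")
})

test_that("best hit of an exact substring is the substring's coordinates at identity 100", {
  toy <- toyGenomePair()
  idx <- buildKmerIndex(toy$genome, k = 16)
  h <- findBestHit(as.character(exonSequences(toy$catalog)[["E1"]]), idx,
                   queryId = "E1")
  expect_equal(as.character(GenomeInfoDb::seqnames(h)), "chr1")
  expect_equal(GenomicRanges::start(h), 1001L)
  expect_equal(GenomicRanges::end(h), 1150L)
  expect_equal(h$percent_identity, 100)
  expect_equal(as.character(GenomicRanges::strand(h)), "+")
})

test_that("one substitution in a 100-base query yields identity 99.0", {
  set.seed(9)
  g <- randomDna(5000)
  idx <- buildKmerIndex(c(chr1 = g), k = 16)
  q <- substr(g, 2001, 2100)
  mid <- substr(q, 50, 50)
  substr(q, 50, 50) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  h <- findBestHit(q, idx, queryId = "q")
  expect_equal(h$percent_identity, 99.0)
  expect_equal(h$mismatches, 1L)
  expect_equal(GenomicRanges::start(h), 2001L)
  expect_equal(GenomicRanges::end(h), 2100L)
})

test_that("a reverse-complement query maps to the same interval on the minus strand", {
  toy <- toyGenomePair()
  idx <- buildKmerIndex(toy$genome, k = 16)
  q <- as.character(Biostrings::reverseComplement(
    exonSequences(toy$catalog)[["E1"]]))
  h <- findBestHit(q, idx, queryId = "E1rc")
  expect_equal(GenomicRanges::start(h), 1001L)
  expect_equal(GenomicRanges::end(h), 1150L)
  expect_equal(as.character(GenomicRanges::strand(h)), "-")
  expect_equal(h$percent_identity, 100)
})

test_that("hits below minimum query coverage are discarded", {
  set.seed(10)
  g <- randomDna(3000)
  idx <- buildKmerIndex(c(chr1 = g), k = 16)
  # only half the query matches anywhere
  q <- paste0(substr(g, 501, 560), randomDna(60))
  expect_equal(length(findBestHit(q, idx, minCoverage = 0.7)), 0L)
  expect_equal(length(findBestHit(q, idx, minCoverage = 0.4)), 1L)
})

makeHit <- function(chrom, start, end, strand = "+", score = 50,
                    identity = 100, len = NULL, qid = "E1") {
  if (is.null(len)) len <- end - start + 1L
  gr <- GenomicRanges::GRanges(
    factor(chrom, levels = c("chr1", "chr2", "chr7", "chr9")),
    IRanges::IRanges(start, end), strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    query_id = qid, percent_identity = identity,
    alignment_length = as.integer(len), mismatches = 0L, gap_opens = 0L,
    score = score)
  gr
}

test_that("selectBest maximizes score, identity, length then lowest chromosome and start", {
  h <- c(makeHit("chr1", 100, 199, score = 50),
         makeHit("chr1", 300, 399, score = 40))
  expect_equal(GenomicRanges::start(selectBest(h)), 100L)
  h <- c(makeHit("chr1", 100, 199, score = 50, identity = 99),
         makeHit("chr1", 300, 399, score = 50, identity = 100))
  expect_equal(GenomicRanges::start(selectBest(h)), 300L)
  h <- c(makeHit("chr2", 500, 599), makeHit("chr1", 900, 999))
  expect_equal(as.character(GenomeInfoDb::seqnames(selectBest(h))), "chr1")
  expect_equal(GenomicRanges::start(selectBest(h)), 900L)
  expect_error(selectBest(emptyHits()), "empty")
})

test_that("selectBest is invariant under permutation of the hit list", {
  set.seed(21)
  hits <- do.call(c, lapply(1:12, function(i) {
    s <- sample(1000, 1)
    makeHit(sample(c("chr1", "chr2"), 1), s, s + 99,
            score = sample(40:50, 1), identity = sample(95:100, 1),
            qid = sample(c("A", "B", "C"), 1))
  }))
  ref <- selectBest(hits)
  ref <- ref[order(ref$query_id)]
  for (i in 1:10) {
    perm <- selectBest(hits[sample(length(hits))])
    perm <- perm[order(perm$query_id)]
    expect_equal(as.data.frame(perm), as.data.frame(ref))
  }
})

test_that("feature strand is the composition of gene strand and hit strand", {
  # all four combinations, enumerated against the group product {+,-}
  cat4 <- exonCatalog(exonId = sprintf("E%d", 1:4), geneId = sprintf("G%d", 1:4),
                      geneName = rep("", 4), chromosome = rep("chr1", 4),
                      strand = c("+", "+", "-", "-"),
                      sequence = rep("ACGTACGTACGTACGTACGT", 4))
  hits <- do.call(c, lapply(1:4, function(i)
    makeHit("chr1", i * 1000, i * 1000 + 19,
            strand = c("+", "-", "+", "-")[i], qid = sprintf("E%d", i))))
  feats <- quietly(liftExons(cat4, hits))
  expect_equal(as.character(GenomicRanges::strand(feats)),
               c("+", "-", "-", "+"))
  expect_equal(feats$kind, rep("exon", 4))
  expect_equal(feats$exon_id, sprintf("E%d", 1:4))
})

test_that("exons without hits are dropped and counted; unknown hits are an error", {
  toy <- toyGenomePair()
  hits <- c(makeHit("chr1", 1001, 1150, qid = "E1"),
            makeHit("chr1", 1401, 1520, qid = "E2"))
  expect_message(feats <- liftExons(toy$catalog, hits), "2/3")
  expect_equal(length(feats), 2L)
  bad <- makeHit("chr1", 1, 100, qid = "nope")
  expect_error(quietly(liftExons(toy$catalog, bad)), "nope")
})

test_that("gene spans cover outermost exon coordinates on the majority chromosome", {
  mk <- function(chrom, start, end, strand, eid, gid) {
    gr <- GenomicRanges::GRanges(
      factor(chrom, levels = c("chr1", "chr2")),
      IRanges::IRanges(start, end), strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = "exon", exon_id = eid, gene_id = gid, gene_name = "nm",
      percent_identity = 100)
    gr
  }
  ex <- c(mk("chr1", 100, 200, "+", "E1", "G1"),
          mk("chr1", 500, 600, "+", "E2", "G1"),
          mk("chr2", 50, 80, "+", "E3", "G2"))
  spans <- deriveGeneSpans(ex)
  g1 <- spans[spans$gene_id == "G1"]
  expect_equal(GenomicRanges::start(g1), 100L)
  expect_equal(GenomicRanges::end(g1), 600L)
  # single-exon gene span equals the exon interval
  g2 <- spans[spans$gene_id == "G2"]
  expect_equal(GenomicRanges::start(g2), 50L)
  expect_equal(GenomicRanges::end(g2), 80L)
  # majority rule: 3 exons on chr1, 1 on chr2
  ex2 <- c(mk("chr1", 100, 200, "-", "E1", "G3"),
           mk("chr1", 300, 400, "-", "E2", "G3"),
           mk("chr1", 700, 800, "-", "E3", "G3"),
           mk("chr2", 10, 90, "-", "E4", "G3"))
  expect_message(span3 <- deriveGeneSpans(ex2), "excluded")
  expect_equal(as.character(GenomeInfoDb::seqnames(span3)), "chr1")
  expect_equal(GenomicRanges::start(span3), 100L)
  expect_equal(GenomicRanges::end(span3), 800L)
  expect_equal(as.character(GenomicRanges::strand(span3)), "-")
})

test_that("identity summary aggregates per source chromosome and conserves counts", {
  toy <- toyGenomePair()
  hits <- c(makeHit("chr9", 1, 150, identity = 100, qid = "E1"),
            makeHit("chr9", 200, 350, identity = 99, qid = "E2"),
            makeHit("chr7", 1, 200, identity = 98.5, qid = "E3"))
  s <- identitySummary(hits, toy$catalog)
  expect_equal(nrow(s$per_chromosome), 2L)
  expect_equal(sum(s$per_chromosome$n), 3L)
  chr1 <- s$per_chromosome[s$per_chromosome$chromosome == "chr1", ]
  expect_equal(chr1$min_identity, 99)
  expect_equal(chr1$mean_identity, 99.5)
  chr2 <- s$per_chromosome[s$per_chromosome$chromosome == "chr2", ]
  expect_equal(chr2$min_identity, chr2$mean_identity)
  expect_equal(s$overall_mean, mean(c(100, 99, 98.5)))
  empty <- quietly(identitySummary(emptyHits(), toy$catalog))
  expect_equal(nrow(empty$per_chromosome), 0L)
  expect_true(is.na(empty$overall_mean))
})

test_that("self-lift reproduces exact source coordinates at identity 100", {
  toy <- toyGenomePair()
  res <- quietly(liftoverExons(toy$catalog, toy$genome))
  expect_equal(length(res$unmapped), 0L)
  truth <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1001L, 1401L, 501L),
                      end = c(1150L, 1520L, 700L))
  ord <- match(c("E1", "E2", "E3"), res$exons$exon_id)
  expect_equal(as.character(GenomeInfoDb::seqnames(res$exons))[ord],
               truth$chrom)
  expect_equal(GenomicRanges::start(res$exons)[ord], truth$start)
  expect_equal(GenomicRanges::end(res$exons)[ord], truth$end)
  expect_true(all(res$exons$percent_identity == 100))
  # E3's gene is on the minus strand; its sequence is genome-forward, so the
  # hit is on plus and the lifted feature keeps the gene's minus orientation
  expect_equal(as.character(GenomicRanges::strand(res$exons))[ord[3]], "-")
})

test_that("external tabular hits drive the same lift-over path as the aligner", {
  toy <- toyGenomePair()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "E1\tchr1\t100.00\t150\t0\t0\t1\t150\t1001\t1150\t0.0\t300",
    "E1\tchr2\t90.00\t150\t15\t0\t1\t150\t101\t250\t1e-10\t100",
    "E3\tchr2\t100.00\t200\t0\t0\t1\t200\t700\t501\t0.0\t400"), f)
  best <- selectBest(readTabularHits(f))
  feats <- quietly(liftExons(toy$catalog, best))
  e1 <- feats[feats$exon_id == "E1"]
  expect_equal(GenomicRanges::start(e1), 1001L)
  e3 <- feats[feats$exon_id == "E3"]
  expect_equal(GenomicRanges::start(e3), 501L)
  expect_equal(GenomicRanges::end(e3), 700L)
  # minus-strand hit composed with the minus-strand gene gives plus
  expect_equal(as.character(GenomicRanges::strand(e3)), "+")
})
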