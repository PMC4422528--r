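# Brute-force oracle for the filtering cascade: a direct, loop-based
# evaluation of the filtration rules, written independently of the package's
# vectorized implementation. Only accessors and slots are used; no package
# filter function is called.

oracleCascade <- function(vs, lines, targetLine, level = "exon",
                          missing = "strict", enuOnly = FALSE) {
  g <- genotypes(vs)
  info <- variantInfo(vs)
  n <- length(vs)
  spec <- lines[[targetLine]]
  expected <- if (inheritanceModel(spec) == "recessive") "1/1" else "0/1"
  otherSamples <- unlist(lapply(lines[names(lines) != targetLine],
                                lineSamples))

  # stage 1: privacy
  private <- integer(0)
  for (r in seq_len(n)) {
    ok <- TRUE
    for (s in lineSamples(spec)) if (g[r, s] != expected) ok <- FALSE
    for (s in otherSamples) {
      gt <- g[r, s]
      if (missing == "strict") {
        if (gt != "0/0") ok <- FALSE
      } else {
        if (!(gt %in% c("0/0", "."))) ok <- FALSE
      }
    }
    if (ok) private <- c(private, r)
  }

  # stage 2: exon/gene containment
  tag <- if (level == "exon") "EID" else "GIR"
  exonic <- integer(0)
  for (r in private) {
    v <- info[[r]][[tag]]
    if (!is.null(v) && length(v) > 0) exonic <- c(exonic, r)
  }

  # stage 3: one per gene (against the exonic set, any containing gene)
  geneCount <- list()
  for (r in exonic)
    for (gid in info[[r]][["GIR"]])
      geneCount[[gid]] <- (if (is.null(geneCount[[gid]])) 0L
                           else geneCount[[gid]]) + 1L
  onePer <- integer(0)
  for (r in exonic) {
    multi <- FALSE
    for (gid in info[[r]][["GIR"]])
      if (geneCount[[gid]] >= 2L) multi <- TRUE
    if (!multi) onePer <- c(onePer, r)
  }

  # stage 4: linkage regions
  regions <- linkageRegions(spec)
  if (is.null(regions) || length(regions) == 0L) {
    linked <- onePer
    applied <- FALSE
  } else {
    applied <- TRUE
    linked <- integer(0)
    rch <- as.character(GenomeInfoDb::seqnames(regions))
    rs <- GenomicRanges::start(regions)
    re <- GenomicRanges::end(regions)
    for (r in onePer) {
      inside <- FALSE
      for (k in seq_along(rch))
        if (vs@chrom[r] == rch[k] && vs@pos[r] >= rs[k] && vs@pos[r] <= re[k])
          inside <- TRUE
      if (inside) linked <- c(linked, r)
    }
  }

  # stage 5: ENU-type flag on the carried alt allele
  enuPairs <- c("T>C", "A>G", "T>A", "A>T")
  flagged <- logical(length(linked))
  for (i in seq_along(linked)) {
    r <- linked[i]
    a <- vs@alt[[r]]
    a1 <- if (length(a) >= 1L) a[[1L]] else ""
    flagged[i] <- nchar(vs@ref[r]) == 1L && nchar(a1) == 1L &&
      paste0(vs@ref[r], ">", a1) %in% enuPairs
  }
  candidates <- if (enuOnly) linked[flagged] else linked

  list(n_private = length(private), n_exonic = length(exonic),
       n_one_per_gene = length(onePer),
       n_in_linkage = if (applied) length(linked) else NA_integer_,
       n_enu_type = sum(flagged), candidates = candidates)
}

# randomized cohort with arbitrary genotypes, INFO structure, linkage
# regions and occasional multi-allelic or indel records
randomCohort <- function(seed) {
  set.seed(seed)
  nLines <- sample(2:4, 1L)
  lines <- list()
  for (i in seq_len(nLines)) {
    regions <- NULL
    if (stats::runif(1) < 0.4) {
      st <- sample(1:5000, sample(1:2, 1L))
      regions <- GenomicRanges::GRanges(
        sample(c("chr1", "chr2"), length(st), TRUE),
        IRanges::IRanges(st, st + sample(500:3000, length(st), TRUE)))
    }
    lines[[i]] <- lineSpec(sprintf("L%d", i),
                           sprintf("L%d_s%d", i, seq_len(sample(2:4, 1L))),
                           sample(c("dominant", "recessive"), 1L), regions)
  }
  names(lines) <- vapply(lines, lineId, "")
  samples <- unname(unlist(lapply(lines, lineSamples)))
  stopifnot(length(samples) <= 16L)

  n <- sample(10:50, 1L)
  chrom <- sample(c("chr1", "chr2"), n, TRUE)
  pos <- sample(1:10000, n)
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- lapply(seq_len(n), function(i) {
    u <- stats::runif(1)
    if (u < 0.1) c(sample(c("A", "C", "G", "T"), 1L), "TA")   # multi-allelic
    else if (u < 0.2) paste0(ref[i], "A")                     # indel
    else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
  })
  geno <- matrix("0/0", nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (r in seq_len(n)) {
    pool <- c("0/0", "0/0", "0/1", "1/1", ".")
    if (length(alt[[r]]) >= 2L) pool <- c(pool, "0/2", "2/2", "1/2")
    geno[r, ] <- sample(pool, length(samples), TRUE)
    # bias some rows toward passing privacy so the kept set is non-trivial
    if (stats::runif(1) < 0.3) {
      ln <- sample(names(lines), 1L)
      exp <- if (inheritanceModel(lines[[ln]]) == "recessive") "1/1" else "0/1"
      geno[r, lineSamples(lines[[ln]])] <- exp
      others <- setdiff(samples, lineSamples(lines[[ln]]))
      geno[r, others] <- sample(c("0/0", "0/0", "0/0", "."), length(others),
                                TRUE)
    }
  }
  genePool <- sprintf("G%d", 1:6)
  info <- lapply(seq_len(n), function(i) {
    u <- stats::runif(1)
    if (u < 0.45) {
      gids <- sample(genePool, sample(1:2, 1L))
      list(EID = sprintf("E%d", sample(1:50, 1L)), GID = gids[1L],
           GIR = gids, GNM = "nm", GNR = "nm")
    } else if (u < 0.7) {
      list(GIR = sample(genePool, 1L), GNR = "nm")
    } else list()
  })
  vs <- variantSet(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   geno = geno, info = info)
  list(variants = vs, lines = lines)
}

# set equality of candidates between runCascade output and the oracle
candidateKeys <- function(vs) paste(vs@chrom, vs@pos, sep = ":")
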