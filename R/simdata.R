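# Deterministic simulator: a diverged genome pair (annotated source
# assembly vs un-annotated target strain assembly), an exon catalog, and a
# multi-line cohort VCF with strain-shared background variants, per-line
# private noise, and one planted causative exonic ENU-type variant per line.

DNA_BASES <- c("A", "C", "G", "T")

#' Create a simulation configuration
#'
#' Defaults mirror the targeted study design: 8 lines sequenced with
#' 4,4,4,4,2,2,2,2 animals, inheritance recessive, dominant, dominant,
#' recessive, then dominant, linkage regions for lines 4 and 7 only, 5000
#' shared strain variants, 200 private noise variants per line, and 1\%
#' source-to-target divergence. Genome scale (4 chromosomes x 200 kb, 40
#' genes) is desk scale. When \code{nLines} differs from 8, per-line
#' defaults are recycled from those patterns.
#'
#' @param nChromosomes,chromosomeLength,nGenes genome layout.
#' @param exonsPerGene,exonLength,intronLength (min, max) integer ranges.
#' @param divergence per-base substitution rate in [0, 0.1).
#' @param nIndels,indelLength optional small-indel divergence (0 = none,
#'   keeping source and target coordinates aligned).
#' @param nLines,samplesPerLine,inheritance cohort design.
#' @param nSharedVariants,nNoisePerLine,noiseFractions variant structure;
#'   noise is split between intergenic, intronic and multi-hit-gene exonic
#'   placements.
#' @param linkageLines,linkageWidth which lines carry a linkage region and
#'   its width as a fraction of the chromosome length.
#' @param seed integer seed; every simulator output is a pure function of
#'   the configuration.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nChromosomes = 4L, chromosomeLength = 200000L,
                      nGenes = 40L, exonsPerGene = c(4L, 8L),
                      exonLength = c(80L, 250L), intronLength = c(50L, 400L),
                      divergence = 0.01, nIndels = 0L, indelLength = c(1L, 5L),
                      nLines = 8L, samplesPerLine = NULL, inheritance = NULL,
                      nSharedVariants = 5000L, nNoisePerLine = 200L,
                      noiseFractions = c(intergenic = 0.7, intronic = 0.2,
                                         multiGene = 0.1),
                      linkageLines = NULL, linkageWidth = 0.3, seed = 1L) {
  nLines <- as.integer(nLines)
  if (is.null(samplesPerLine))
    samplesPerLine <- rep_len(c(4L, 4L, 4L, 4L, 2L, 2L, 2L, 2L), nLines)
  if (is.null(inheritance))
    inheritance <- rep_len(c("recessive", "dominant", "dominant", "recessive",
                             "dominant", "dominant", "dominant", "dominant"),
                           nLines)
  if (is.null(linkageLines))
    linkageLines <- intersect(c(4L, 7L), seq_len(nLines))
  new("SimConfig", nChromosomes = as.integer(nChromosomes),
      chromosomeLength = as.integer(chromosomeLength),
      nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
      exonLength = as.integer(exonLength),
      intronLength = as.integer(intronLength),
      divergence = as.numeric(divergence), nIndels = as.integer(nIndels),
      indelLength = as.integer(indelLength), nLines = nLines,
      samplesPerLine = as.integer(samplesPerLine),
      inheritance = as.character(inheritance),
      nSharedVariants = as.integer(nSharedVariants),
      nNoisePerLine = as.integer(nNoisePerLine),
      noiseFractions = noiseFractions,
      linkageLines = as.integer(linkageLines),
      linkageWidth = as.numeric(linkageWidth), seed = as.integer(seed))
}

randRange <- function(range, n) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a diverged genome pair with an exon catalog
#'
#' The source genome is uniform-random DNA with non-overlapping stranded
#' genes; the target genome is the source with i.i.d. substitutions at the
#' configured divergence rate (plus optional small indels, whose coordinate
#' shifts are recorded in the coordinate map). Deterministic given the
#' configuration seed.
#'
#' @param config a [SimConfig-class].
#' @return a list: \code{source}, \code{target}
#'   (\link[Biostrings]{DNAStringSet}), \code{catalog}
#'   ([ExonCatalog-class], forward-genome oriented sequences),
#'   \code{exons} and \code{genes} (\link[GenomicRanges]{GRanges} of true
#'   source coordinates), and \code{coordMap} (data.frame chrom,
#'   source_start, offset; empty when no indels).
#' @export
simulateGenomePair <- function(config) {
  validObject(config)
  set.seed(config@seed)
  L <- config@chromosomeLength
  chromNames <- sprintf("chr%d", seq_len(config@nChromosomes))
  genesPerChrom <- tabulate(rep_len(seq_len(config@nChromosomes),
                                    config@nGenes),
                            nbins = config@nChromosomes)
  minGap <- 500L

  srcChars <- list()
  exonRows <- list()
  geneRows <- list()
  gid <- 0L
  eid <- 0L
  for (ci in seq_len(config@nChromosomes)) {
    chars <- sample(DNA_BASES, L, replace = TRUE)
    gc <- genesPerChrom[ci]
    if (gc > 0) {
      nEx <- randRange(config@exonsPerGene, gc)
      struct <- lapply(seq_len(gc), function(i) {
        ex <- randRange(config@exonLength, nEx[i])
        intr <- if (nEx[i] > 1) randRange(config@intronLength, nEx[i] - 1L)
                else integer(0)
        list(ex = ex, intr = intr, len = sum(ex) + sum(intr))
      })
      lens <- vapply(struct, `[[`, 0, "len")
      needed <- sum(lens) + minGap * (gc + 1L)
      if (needed > L)
        stop(sprintf(
          "gene placement impossible: %d genes need %d bases on a %d-base chromosome",
          gc, needed, L))
      extra <- as.vector(stats::rmultinom(1L, L - needed, rep(1, gc + 1L)))
      pos <- minGap + extra[1L]
      for (i in seq_len(gc)) {
        gid <- gid + 1L
        geneId <- sprintf("G%03d", gid)
        geneName <- if (stats::runif(1) < 0.1) "" else sprintf("Gene%03d", gid)
        strand <- sample(c("+", "-"), 1L)
        start <- pos + 1L
        cur <- start
        exStarts <- integer(0); exEnds <- integer(0)
        for (e in seq_along(struct[[i]]$ex)) {
          eid <- eid + 1L
          exEnd <- cur + struct[[i]]$ex[e] - 1L
          exStarts <- c(exStarts, cur); exEnds <- c(exEnds, exEnd)
          exonRows[[eid]] <- data.frame(
            exon_id = sprintf("EX%05d", eid), gene_id = geneId,
            gene_name = geneName, chromosome = chromNames[ci],
            strand = strand, start = cur, end = exEnd)
          cur <- exEnd + 1L
          if (e < length(struct[[i]]$ex)) cur <- cur + struct[[i]]$intr[e]
        }
        geneRows[[gid]] <- data.frame(
          gene_id = geneId, gene_name = geneName,
          chromosome = chromNames[ci], strand = strand, start = start,
          end = cur - 1L)
        pos <- cur - 1L + minGap + extra[i + 1L]
      }
    }
    srcChars[[chromNames[ci]]] <- chars
  }
  exonTab <- do.call(rbind, exonRows)
  geneTab <- do.call(rbind, geneRows)

  # target = source + substitutions (+ optional indels)
  tgtChars <- srcChars
  for (ch in chromNames) {
    subs <- which(stats::runif(L) < config@divergence)
    for (p in subs)
      tgtChars[[ch]][p] <- sample(setdiff(DNA_BASES, tgtChars[[ch]][p]), 1L)
  }
  coordMap <- data.frame(chrom = character(0), source_start = integer(0),
                         offset = integer(0))
  if (config@nIndels > 0L) {
    perChrom <- tabulate(sample(seq_len(config@nChromosomes),
                                config@nIndels, replace = TRUE),
                         nbins = config@nChromosomes)
    for (ci in seq_len(config@nChromosomes)) {
      ch <- chromNames[ci]
      if (perChrom[ci] == 0L) next
      evPos <- sort(sample(seq(100L, L - 100L), perChrom[ci]))
      evLen <- randRange(config@indelLength, perChrom[ci])
      evIns <- sample(c(TRUE, FALSE), perChrom[ci], replace = TRUE)
      parts <- list(); cur <- 1L; offset <- 0L
      for (i in seq_len(perChrom[ci])) {
        p <- evPos[i]
        if (evIns[i]) {
          parts <- c(parts, list(tgtChars[[ch]][cur:p]),
                     list(sample(DNA_BASES, evLen[i], replace = TRUE)))
          cur <- p + 1L
          offset <- offset + evLen[i]
          after <- p + 1L
        } else {
          if (p > cur) parts <- c(parts, list(tgtChars[[ch]][cur:(p - 1L)]))
          cur <- min(p + evLen[i], L + 1L)
          offset <- offset - (cur - p)
          after <- cur
        }
        coordMap <- rbind(coordMap,
                          data.frame(chrom = ch, source_start = after,
                                     offset = offset))
      }
      if (cur <= L) parts <- c(parts, list(tgtChars[[ch]][cur:L]))
      tgtChars[[ch]] <- unlist(parts)
    }
  }

  collapse <- function(lst) Biostrings::DNAStringSet(
    vapply(lst, paste, "", collapse = ""))
  catalog <- exonCatalog(
    exonId = exonTab$exon_id, geneId = exonTab$gene_id,
    geneName = exonTab$gene_name, chromosome = exonTab$chromosome,
    strand = exonTab$strand,
    sequence = vapply(seq_len(nrow(exonTab)), function(i) {
      paste(srcChars[[exonTab$chromosome[i]]][
        exonTab$start[i]:exonTab$end[i]], collapse = "")
    }, ""))
  exons <- GenomicRanges::GRanges(
    exonTab$chromosome, IRanges::IRanges(exonTab$start, exonTab$end),
    strand = exonTab$strand, exon_id = exonTab$exon_id,
    gene_id = exonTab$gene_id)
  genes <- GenomicRanges::GRanges(
    geneTab$chromosome, IRanges::IRanges(geneTab$start, geneTab$end),
    strand = geneTab$strand, gene_id = geneTab$gene_id,
    gene_name = geneTab$gene_name)
  list(source = collapse(srcChars), target = collapse(tgtChars),
       catalog = catalog, exons = exons, genes = genes, coordMap = coordMap)
}

#' Map a source-assembly position to the target assembly
#'
#' @param coordMap the coordinate map from [simulateGenomePair()].
#' @param chrom,pos source chromosome and 1-based position (vectorized over
#'   \code{pos}).
#' @return target positions; NA for positions removed by a deletion.
#' @export
mapSourceToTarget <- function(coordMap, chrom, pos) {
  if (nrow(coordMap) == 0L) return(pos)
  m <- coordMap[coordMap$chrom == chrom, , drop = FALSE]
  prevOff <- c(0L, m$offset[-nrow(m)])
  delLen <- pmax(prevOff - m$offset, 0L)  # > 0 marks a deletion event
  vapply(pos, function(p) {
    inDeleted <- any(delLen > 0L & p >= m$source_start - delLen &
                       p < m$source_start)
    if (inDeleted) return(NA_integer_)
    rows <- which(m$source_start <= p)
    off <- if (length(rows) == 0L) 0L else m$offset[max(rows)]
    p + off
  }, 0L)
}

enuAltFor <- function(refBase) {
  switch(refBase, T = sample(c("C", "A"), 1L), A = sample(c("G", "T"), 1L),
         stop("ENU-type variants require a T or A reference base"))
}

#' Simulate a multi-line cohort with planted causative variants
#'
#' Emits a multi-sample variant set on the target assembly: shared strain
#' variants non-reference (1/1) in every sample of every line, per-line
#' private noise variants carrying the line's expected genotype (placed
#' intergenic, intronic, or as exonic pairs inside one gene to stress the
#' downstream filters), and exactly one planted causative exonic ENU-type
#' variant per line, with the expected genotype in all the line's samples
#' and homozygous reference elsewhere. Noise avoids every line's planted
#' gene, so the planted variant is recoverable by construction.
#'
#' @param config a [SimConfig-class].
#' @param pair output of [simulateGenomePair()] for the same config.
#' @return a list: \code{variants} ([VariantSet-class]), \code{lines}
#'   (named list of [LineSpec-class], linkage regions centred on the
#'   planted variant for the configured lines), and \code{truth} (list of
#'   data.frames \code{planted}, \code{shared}, \code{noise}).
#' @export
simulateCohort <- function(config, pair) {
  validObject(config)
  set.seed(config@seed + 1L)
  chromNames <- names(pair$target)
  tchars <- lapply(as.character(pair$target), function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  tlen <- vapply(tchars, length, 0L)

  lineIds <- sprintf("line%d", seq_len(config@nLines))
  samplesByLine <- lapply(seq_len(config@nLines), function(i)
    sprintf("%s_s%d", lineIds[i], seq_len(config@samplesPerLine[i])))
  names(samplesByLine) <- lineIds
  allSamples <- unname(unlist(samplesByLine))

  used <- lapply(tlen, function(n) logical(n))
  takePos <- function(chrom, pos) {
    if (used[[chrom]][pos]) return(FALSE)
    used[[chrom]][pos] <<- TRUE
    TRUE
  }

  # target-coordinate gene/exon layout
  mapSafe <- function(c, p, step) {
    # boundary bases removed by a deletion fall back to the nearest kept base
    for (q in seq(p, p + 50L * step, by = step)) {
      t <- mapSourceToTarget(pair$coordMap, c, q)
      if (!is.na(t)) return(t)
    }
    stop("coordinate map has no mapping near position ", p)
  }
  mapGR <- function(gr) {
    ch <- as.character(GenomeInfoDb::seqnames(gr))
    st <- mapply(function(c, p) mapSafe(c, p, 1L),
                 ch, GenomicRanges::start(gr))
    en <- mapply(function(c, p) mapSafe(c, p, -1L),
                 ch, GenomicRanges::end(gr))
    GenomicRanges::GRanges(ch, IRanges::IRanges(as.integer(st),
                                                as.integer(en)),
                           strand = GenomicRanges::strand(gr))
  }
  exonsT <- mapGR(pair$exons)
  S4Vectors::mcols(exonsT) <- S4Vectors::mcols(pair$exons)
  genesT <- mapGR(pair$genes)
  S4Vectors::mcols(genesT) <- S4Vectors::mcols(pair$genes)

  inGene <- lapply(chromNames, function(ch) {
    mask <- logical(tlen[[ch]])
    g <- genesT[as.character(GenomeInfoDb::seqnames(genesT)) == ch]
    for (i in seq_along(g))
      mask[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    mask
  })
  names(inGene) <- chromNames
  inExon <- lapply(chromNames, function(ch) {
    mask <- logical(tlen[[ch]])
    e <- exonsT[as.character(GenomeInfoDb::seqnames(exonsT)) == ch]
    for (i in seq_along(e))
      mask[GenomicRanges::start(e)[i]:GenomicRanges::end(e)[i]] <- TRUE
    mask
  })
  names(inExon) <- chromNames

  geneIdsAll <- genesT$gene_id
  if (length(geneIdsAll) < config@nLines)
    stop("not enough genes to assign one planted gene per line")

  # exonic positions of one gene, margin bases away from every exon edge
  exonicPositions <- function(geneId, margin = 5L) {
    e <- exonsT[exonsT$gene_id == geneId]
    unlist(lapply(seq_along(e), function(i) {
      s <- GenomicRanges::start(e)[i] + margin
      en <- GenomicRanges::end(e)[i] - margin
      if (s > en) integer(0) else s:en
    }))
  }
  geneChrom <- function(geneId)
    as.character(GenomeInfoDb::seqnames(
      genesT[genesT$gene_id == geneId]))[1L]

  # --- planted causative variants ---------------------------------------
  plantGenes <- sample(geneIdsAll, config@nLines)
  planted <- list()
  for (i in seq_len(config@nLines)) {
    placed <- FALSE
    candidates <- c(plantGenes[i],
                    sample(setdiff(geneIdsAll, plantGenes)))
    for (g in candidates) {
      ch <- geneChrom(g)
      posPool <- exonicPositions(g)
      posPool <- posPool[!used[[ch]][posPool]]
      posPool <- posPool[tchars[[ch]][posPool] %in% c("T", "A")]
      if (length(posPool) == 0L) next
      p <- if (length(posPool) == 1L) posPool else sample(posPool, 1L)
      takePos(ch, p)
      ref <- tchars[[ch]][p]
      planted[[i]] <- data.frame(line_id = lineIds[i], chrom = ch, pos = p,
                                 ref = ref, alt = enuAltFor(ref),
                                 gene_id = g, enu = TRUE)
      plantGenes[i] <- g
      placed <- TRUE
      break
    }
    if (!placed)
      stop("not enough exonic T/A positions to plant a causative variant per line")
  }
  planted <- do.call(rbind, planted)

  randomGlobalPos <- function(accept) {
    repeat {
      ch <- sample(chromNames, 1L)
      p <- sample.int(tlen[[ch]], 1L)
      if (!used[[ch]][p] && accept(ch, p)) {
        takePos(ch, p)
        return(list(chrom = ch, pos = p))
      }
    }
  }

  # --- shared strain variants -------------------------------------------
  shared <- NULL
  if (config@nSharedVariants > 0L) {
    sh <- lapply(seq_len(config@nSharedVariants), function(i)
      randomGlobalPos(function(ch, p) TRUE))
    shared <- data.frame(chrom = vapply(sh, `[[`, "", "chrom"),
                         pos = vapply(sh, `[[`, 0L, "pos"))
  } else {
    shared <- data.frame(chrom = character(0), pos = integer(0))
  }

  # --- per-line noise ----------------------------------------------------
  fr <- config@noiseFractions
  nNoise <- config@nNoisePerLine
  nIntronic <- round(fr[["intronic"]] * nNoise)
  nPairs <- floor(round(fr[["multiGene"]] * nNoise) / 2)
  nIntergenic <- nNoise - nIntronic - 2L * nPairs
  nonPlantGenes <- setdiff(geneIdsAll, plantGenes)
  if (length(nonPlantGenes) == 0L && (nIntronic > 0 || nPairs > 0))
    stop("no genes left for noise placement outside planted genes")
  noise <- list()
  for (i in seq_len(config@nLines)) {
    rows <- list()
    for (j in seq_len(nIntergenic)) {
      gp <- randomGlobalPos(function(ch, p) !inGene[[ch]][p])
      rows <- c(rows, list(data.frame(line_id = lineIds[i], chrom = gp$chrom,
                                      pos = gp$pos,
                                      category = "intergenic")))
    }
    for (j in seq_len(nIntronic)) {
      repeat {
        g <- sample(nonPlantGenes, 1L)
        ch <- geneChrom(g)
        gr <- genesT[genesT$gene_id == g]
        span <- GenomicRanges::start(gr):GenomicRanges::end(gr)
        pool <- span[!inExon[[ch]][span] & !used[[ch]][span]]
        if (length(pool) == 0L) next
        p <- if (length(pool) == 1L) pool else sample(pool, 1L)
        takePos(ch, p)
        rows <- c(rows, list(data.frame(line_id = lineIds[i], chrom = ch,
                                        pos = p, category = "intronic")))
        break
      }
    }
    for (j in seq_len(nPairs)) {
      repeat {
        g <- sample(nonPlantGenes, 1L)
        ch <- geneChrom(g)
        pool <- exonicPositions(g, margin = 0L)
        pool <- pool[!used[[ch]][pool]]
        if (length(pool) < 2L) next
        ps <- sample(pool, 2L)
        takePos(ch, ps[1L]); takePos(ch, ps[2L])
        rows <- c(rows, list(data.frame(line_id = lineIds[i], chrom = ch,
                                        pos = ps, category = "multiGene")))
        break
      }
    }
    noise[[i]] <- do.call(rbind, rows)
  }
  noise <- if (length(noise)) do.call(rbind, noise) else
    data.frame(line_id = character(0), chrom = character(0),
               pos = integer(0), category = character(0))

  # --- assemble the variant matrix --------------------------------------
  siteChrom <- c(planted$chrom, shared$chrom, noise$chrom)
  sitePos <- c(planted$pos, shared$pos, noise$pos)
  n <- length(sitePos)
  ref <- mapply(function(ch, p) tchars[[ch]][p], siteChrom, sitePos,
                USE.NAMES = FALSE)
  alt <- character(n)
  geno <- matrix("0/0", nrow = n, ncol = length(allSamples),
                 dimnames = list(NULL, allSamples))
  expectedByLine <- vapply(config@inheritance, expectedGenotype, "")

  idx <- seq_len(nrow(planted))
  alt[idx] <- planted$alt
  for (r in idx) {
    li <- match(planted$line_id[r], lineIds)
    geno[r, samplesByLine[[li]]] <- expectedByLine[li]
  }
  off <- nrow(planted)
  if (nrow(shared) > 0L) {
    idx <- off + seq_len(nrow(shared))
    alt[idx] <- vapply(ref[idx], function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
    geno[idx, ] <- "1/1"
  }
  off <- off + nrow(shared)
  if (nrow(noise) > 0L) {
    idx <- off + seq_len(nrow(noise))
    alt[idx] <- vapply(ref[idx], function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
    for (k in seq_len(nrow(noise))) {
      r <- off + k
      li <- match(noise$line_id[k], lineIds)
      geno[r, samplesByLine[[li]]] <- expectedByLine[li]
    }
  }

  ord <- order(factor(siteChrom, levels = chromNames), sitePos)
  vs <- variantSet(chrom = siteChrom[ord], pos = sitePos[ord],
                   ref = ref[ord], alt = alt[ord],
                   geno = geno[ord, , drop = FALSE])

  # --- line specs ---------------------------------------------------------
  lines <- lapply(seq_len(config@nLines), function(i) {
    regions <- NULL
    if (i %in% config@linkageLines) {
      pr <- planted[planted$line_id == lineIds[i], ]
      w <- round(config@linkageWidth * config@chromosomeLength / 2)
      regions <- GenomicRanges::GRanges(
        pr$chrom, IRanges::IRanges(max(1L, pr$pos - w),
                                   min(tlen[[pr$chrom]], pr$pos + w)))
    }
    lineSpec(lineIds[i], samplesByLine[[i]], config@inheritance[i], regions)
  })
  names(lines) <- lineIds

  list(variants = vs, lines = lines,
       truth = list(planted = planted, shared = shared, noise = noise))
}

#' Compare candidate lists against the simulation truth
#'
#' @param candidates named list of per-line [VariantSet-class] objects, as
#'   returned by [runCascade()].
#' @param truth the truth list from [simulateCohort()].
#' @return a list: \code{per_line} (data.frame line_id, planted_found,
#'   n_candidates, false_positives), \code{sensitivity}, \code{mean_false_positives},
#'   and \code{shared_leakage} (candidate records matching a shared strain
#'   variant position, summed over lines).
#' @export
evaluateRecovery <- function(candidates, truth) {
  key <- function(ch, p) paste(ch, p, sep = ":")
  plantKey <- with(truth$planted,
                   setNames(key(chrom, pos), line_id))
  sharedKeys <- key(truth$shared$chrom, truth$shared$pos)
  rows <- lapply(names(candidates), function(ln) {
    cand <- candidates[[ln]]
    ck <- key(cand@chrom, cand@pos)
    tr <- truth$planted[truth$planted$line_id == ln, ]
    found <- nrow(tr) == 1L && plantKey[[ln]] %in% ck &&
      cand@ref[match(plantKey[[ln]], ck)] == tr$ref &&
      tr$alt %in% cand@alt[[match(plantKey[[ln]], ck)]]
    data.frame(line_id = ln, planted_found = found,
               n_candidates = length(cand),
               false_positives = length(cand) - as.integer(found),
               shared_hits = sum(ck %in% sharedKeys))
  })
  per <- do.call(rbind, rows)
  list(per_line = per[, c("line_id", "planted_found", "n_candidates",
                          "false_positives")],
       sensitivity = mean(per$planted_found),
       mean_false_positives = mean(per$false_positives),
       shared_leakage = sum(per$shared_hits))
}
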