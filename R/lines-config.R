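# line-definition configuration: YAML or TSV mapping line IDs to sample
# IDs, inheritance model and optional linkage regions

# "chr1:100-5000" (1-based inclusive) -> GRanges
parseRegionStrings <- function(strs) {
  if (length(strs) == 0L) return(NULL)
  m <- regmatches(strs, regexec("^([^:]+):([0-9]+)-([0-9]+)$", strs))
  bad <- lengths(m) != 4L
  if (any(bad))
    formatError("malformed region string(s): %s",
                paste(strs[bad], collapse = ", "))
  GenomicRanges::GRanges(
    vapply(m, `[[`, "", 2L),
    IRanges::IRanges(as.integer(vapply(m, `[[`, "", 3L)),
                     as.integer(vapply(m, `[[`, "", 4L))))
}

regionStrings <- function(regions) {
  if (is.null(regions) || length(regions) == 0L) return(character(0))
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(regions)),
          GenomicRanges::start(regions), GenomicRanges::end(regions))
}

#' Read a line-definition configuration
#'
#' YAML files carry a top-level \code{lines} list whose entries have
#' \code{line_id}, \code{samples}, \code{inheritance} and optional
#' \code{regions}; TSV files carry columns \code{line_id}, \code{samples}
#' (comma-joined), \code{inheritance} and optional \code{regions}
#' (comma-joined). Regions are \code{chrom:start-end}, 1-based inclusive.
#' Sample IDs must be disjoint across lines.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or \code{.tsv}).
#' @return a named list of [LineSpec-class] objects.
#' @export
readLineConfig <- function(path) {
  if (!file.exists(path)) formatError("line config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$lines))
      formatError("%s: no top-level 'lines' entry", path)
    specs <- lapply(cfg$lines, function(x) {
      for (f in c("line_id", "samples", "inheritance"))
        if (is.null(x[[f]]))
          formatError("%s: line entry missing '%s'", path, f)
      lineSpec(x$line_id, unlist(x$samples), x$inheritance,
               parseRegionStrings(unlist(x$regions)))
    })
  } else {
    tab <- read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE)
    missing <- setdiff(c("line_id", "samples", "inheritance"), colnames(tab))
    if (length(missing))
      formatError("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", "))
    specs <- lapply(seq_len(nrow(tab)), function(i) {
      regions <- if ("regions" %in% colnames(tab) &&
                     nzchar(tab$regions[i]) && !is.na(tab$regions[i]))
        parseRegionStrings(strsplit(tab$regions[i], ",", fixed = TRUE)[[1L]])
      else NULL
      lineSpec(tab$line_id[i],
               strsplit(tab$samples[i], ",", fixed = TRUE)[[1L]],
               tab$inheritance[i], regions)
    })
  }
  names(specs) <- vapply(specs, lineId, "")
  if (anyDuplicated(names(specs)))
    formatError("%s: duplicate line IDs", path)
  allSamples <- unlist(lapply(specs, lineSamples))
  if (anyDuplicated(allSamples))
    formatError("%s: sample IDs shared across lines: %s", path,
                paste(unique(allSamples[duplicated(allSamples)]),
                      collapse = ", "))
  specs
}

#' Write a line-definition configuration as YAML
#'
#' @param lines a named list of [LineSpec-class] objects.
#' @param path output YAML file.
#' @return invisibly, \code{path}.
#' @export
writeLineConfig <- function(lines, path) {
  entries <- lapply(unname(lines), function(l) {
    e <- list(line_id = lineId(l), samples = as.list(lineSamples(l)),
              inheritance = inheritanceModel(l))
    rs <- regionStrings(linkageRegions(l))
    if (length(rs)) e$regions <- as.list(rs)
    e
  })
  yaml::write_yaml(list(lines = entries), path)
  invisible(path)
}
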