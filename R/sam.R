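#' Write posterior-annotated alignments as SAM
#'
#' Emits one SAM line per candidate alignment, with MAPQ derived from the
#' mismap probability via [mismap_to_mapq()] and the raw mismap kept at full
#' precision in the `mp:f:` optional tag (posterior in `pp:f:`). FLAG bits
#' set: paired (0x1), unmapped (0x4), mate unmapped (0x8), read/mate reverse
#' strand (0x10/0x20), first/second in pair (0x40/0x80). When a
#' `mate_unmapped` column is present it drives 0x8; when `mate_chrom` /
#' `mate_pos` / `mate_strand` columns are present (the pipeline fills them
#' with the mate's best candidate) they populate RNEXT/PNEXT and 0x20.
#' SEQ and QUAL are omitted (`*`): the posterior annotation, not the
#' sequence, is this writer's payload.
#'
#' Rows with `NA` chromosome are written as unmapped records, so reads
#' where neither end aligned remain visible downstream.
#'
#' @param records Posterior record table; see [write_annotated()].
#' @param genome A [genome_info()]; required for the `@SQ` header lines.
#' @param path File path or connection.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, genome, path) {
  if (is.null(genome))
    stop("SAM output needs genome_info for the @SQ header")
  chrom_length(genome, unique(records$chrom[!is.na(records$chrom)]))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chrom_lengths),
                   as.integer(genome$chrom_lengths)),
           "@PG\tID:pairprob\tPN:pairprob")
  n <- nrow(records)
  if (!n) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  unmapped <- is.na(records$chrom)
  mate_unmapped <- if ("mate_unmapped" %in% names(records))
    records$mate_unmapped else rep(FALSE, n)
  flag <- 1L +
    ifelse(unmapped, 4L, 0L) +
    ifelse(mate_unmapped, 8L, 0L) +
    ifelse(!unmapped & records$strand == "-", 16L, 0L) +
    ifelse(records$mate == 1L, 64L, 128L)
  rnext <- rep("*", n); pnext <- rep(0L, n)
  if (all(c("mate_chrom", "mate_pos", "mate_strand") %in% names(records))) {
    has_mate <- !is.na(records$mate_chrom)
    flag <- flag + ifelse(has_mate & records$mate_strand == "-", 32L, 0L)
    rnext[has_mate] <- ifelse(
      records$mate_chrom[has_mate] == records$chrom[has_mate] & !unmapped[has_mate],
      "=", records$mate_chrom[has_mate])
    pnext[has_mate] <- as.integer(records$mate_pos[has_mate]) + 1L
  }
  cigar <- rep("*", n)
  if (any(!unmapped)) {
    i <- which(!unmapped)
    m <- records$qend[i] - records$qstart[i]
    refspan <- records$ref_end[i] - records$ref_start[i]
    lead <- ifelse(records$strand[i] == "+", records$qstart[i],
                   records$read_len[i] - records$qend[i])
    trail <- records$read_len[i] - m - lead
    mid <- ifelse(refspan == m, paste0(m, "M"),
           ifelse(refspan > m, paste0(m, "M", refspan - m, "D"),
                  paste0(refspan, "M", m - refspan, "I")))
    cigar[i] <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""), mid,
                       ifelse(trail > 0, paste0(trail, "S"), ""))
  }
  mapq <- ifelse(unmapped | is.na(records$mapq), 0L, records$mapq)
  tags <- ifelse(is.na(records$mismap), "",
                 paste0("\tmp:f:", formatC(records$mismap, format = "e",
                                           digits = 6),
                        "\tpp:f:", formatC(records$posterior, format = "e",
                                           digits = 6)))
  lines <- paste0(
    records$read_id, "\t", flag, "\t",
    ifelse(unmapped, "*", records$chrom), "\t",
    ifelse(unmapped, 0L, as.integer(records$ref_start) + 1L), "\t",
    mapq, "\t", cigar, "\t", rnext, "\t", pnext, "\t0\t*\t*", tags)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
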