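#' @name io_formats
#' @title Candidate-alignment file formats
#' @description
#' Two input dialects are supported for candidate alignments. The 12-column
#' tabular dialect has fields
#' `score refName refStart refAlnSize refStrand refSeqSize readName
#' readStart readAlnSize readStrand readSeqSize blocks`, tab-separated,
#' 0-based coordinates, with coordinates of a `-`-strand line counted on the
#' reversed sequence. MAF blocks carry an `a score=...` line followed by two
#' `s` lines (reference first, then read) with the same coordinate
#' convention. Internally everything is converted to forward-strand 0-based
#' half-open coordinates at the boundary.
#'
#' The score scale `T` and score cutoff `e` are properties of the alignment
#' run and travel in comment headers (`# T=... e=...`), as does a fitted
#' fragment model (see [model_header()]).
NULL

TAB_NCOL <- 12L

# internal: parse tab data lines (comments removed) to the internal record
# data frame; `offset` is the file line number before the first line.
parse_tab_lines <- function(lines, offset = 0L) {
  if (!length(lines)) return(empty_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < TAB_NCOL)) {
    bad <- which(nf < TAB_NCOL)[1L]
    stop("line ", offset + bad, ": expected ", TAB_NCOL,
         " tab-separated columns, found ", nf[bad])
  }
  m <- matrix(unlist(lapply(parts, `[`, seq_len(TAB_NCOL))),
              ncol = TAB_NCOL, byrow = TRUE)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  score <- num(1); ref_start0 <- num(3); ref_aln <- num(4)
  ref_len <- num(6); read_start0 <- num(8); read_aln <- num(9)
  read_len <- num(11)
  if (anyNA(score) || anyNA(ref_start0) || anyNA(read_start0)) {
    bad <- which(is.na(score) | is.na(ref_start0) | is.na(read_start0))[1L]
    stop("line ", offset + bad, ": unparseable numeric field")
  }
  ref_strand <- m[, 5]; read_strand <- m[, 10]
  # strand-relative coordinates -> forward-strand coordinates
  ref_start <- ifelse(ref_strand == "-", ref_len - ref_start0 - ref_aln,
                      ref_start0)
  qstart <- ifelse(read_strand == "-", read_len - read_start0 - read_aln,
                   read_start0)
  mismap <- rep(NA_real_, nrow(m))
  extra <- nf > TAB_NCOL
  if (any(extra)) {
    ex <- vapply(parts[extra], function(p)
      paste(p[-seq_len(TAB_NCOL)], collapse = " "), "")
    kv <- regmatches(ex, regexpr("mismap=[^ \t]+", ex))
    mismap[extra][grepl("mismap=", ex)] <- as.numeric(sub("mismap=", "", kv))
  }
  data.frame(
    name = m[, 7], chrom = m[, 2],
    strand = ifelse(ref_strand == read_strand, "+", "-"),
    ref_start = ref_start, ref_end = ref_start + ref_aln,
    score = score, qstart = qstart, qend = qstart + read_aln,
    read_len = read_len, ref_len = ref_len, blocks = m[, 12],
    mismap = mismap, stringsAsFactors = FALSE)
}

# internal: parse MAF lines (comments removed) to the internal record frame.
# Incomplete trailing blocks are a caller error; the iterator never splits one.
parse_maf_lines <- function(lines, offset = 0L) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_records())
  a_idx <- which(startsWith(lines, "a"))
  if (!length(a_idx)) stop("no MAF 'a' lines found")
  recs <- vector("list", length(a_idx))
  for (k in seq_along(a_idx)) {
    i <- a_idx[k]
    if (i + 2L > length(lines) || !startsWith(lines[i + 1L], "s ") ||
        !startsWith(lines[i + 2L], "s "))
      stop("malformed MAF block near line ", offset + i,
           ": expected two 's' lines after 'a'")
    kv <- parse_key_values(sub("^a\\s*", "", lines[i]))
    if (!"score" %in% names(kv))
      stop("MAF block near line ", offset + i, " lacks score=")
    sref <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    srd <- strsplit(trimws(lines[i + 2L]), "\\s+")[[1L]]
    if (length(sref) < 7L || length(srd) < 7L)
      stop("malformed MAF 's' line near line ", offset + i)
    ref_start0 <- as.numeric(sref[3]); ref_aln <- as.numeric(sref[4])
    ref_len <- as.numeric(sref[6])
    rd_start0 <- as.numeric(srd[3]); rd_aln <- as.numeric(srd[4])
    rd_len <- as.numeric(srd[6])
    ref_start <- if (sref[5] == "-") ref_len - ref_start0 - ref_aln
                 else ref_start0
    qstart <- if (srd[5] == "-") rd_len - rd_start0 - rd_aln else rd_start0
    recs[[k]] <- data.frame(
      name = srd[2], chrom = sref[2],
      strand = if (sref[5] == srd[5]) "+" else "-",
      ref_start = ref_start, ref_end = ref_start + ref_aln,
      score = as.numeric(kv[["score"]]),
      qstart = qstart, qend = qstart + rd_aln,
      read_len = rd_len, ref_len = ref_len,
      blocks = NA_character_,
      mismap = if ("mismap" %in% names(kv)) as.numeric(kv[["mismap"]])
               else NA_real_,
      ref_text = sref[7], read_text = srd[7],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

# internal: data-frame row slice without [.data.frame overhead; used in the
# per-pair hot loops where millions of tiny subsets would dominate runtime
slice_df <- function(cols, idx, class = "data.frame") {
  out <- lapply(cols, `[`, idx)
  structure(out, row.names = c(NA_integer_, -length(idx)), class = class)
}

empty_records <- function() {
  data.frame(name = character(), chrom = character(), strand = character(),
             ref_start = numeric(), ref_end = numeric(), score = numeric(),
             qstart = numeric(), qend = numeric(), read_len = numeric(),
             ref_len = numeric(), blocks = character(), mismap = numeric(),
             stringsAsFactors = FALSE)
}

# internal: split read names into (pair id, mate) by suffix convention
split_mate_suffix <- function(names) {
  has <- grepl("/[12]$", names)
  if (!all(has))
    stop("read name(s) without /1 or /2 mate suffix: ",
         paste(utils::head(unique(names[!has]), 3L), collapse = ", "),
         " (use mate_from = \"interleave\" for suffix-free input)")
  list(pid = sub("/[12]$", "", names),
       mate = as.integer(sub("^.*/", "", names)))
}

# internal: records column list + row indices -> candidate table
as_candidates <- function(cols, idx, pid, mate) {
  n <- length(idx)
  out <- c(list(read_id = rep.int(pid, n), mate = rep.int(mate, n)),
           lapply(cols[c("chrom", "strand", "ref_start", "ref_end", "score",
                         "qstart", "qend", "read_len", "ref_len")],
                  `[`, idx),
           lapply(cols[intersect(c("blocks", "ref_text", "read_text",
                                   "mismap"), names(cols))], `[`, idx))
  structure(out, row.names = c(NA_integer_, -n),
            class = c("candidate_df", "data.frame"))
}

# internal: one parsed chunk of records -> per-pair callback invocations.
# `pending` holds records whose pair group may continue in the next chunk.
emit_pairs <- function(rec, mate_from, callback, final) {
  if (is.null(rec) || !nrow(rec)) return(NULL)
  if (mate_from == "suffix") {
    sm <- split_mate_suffix(rec$name)
    pid <- sm$pid; mate <- sm$mate
  } else {
    # interleaved: consecutive name groups alternate first/second mate
    grp <- cumsum(c(TRUE, rec$name[-1L] != rec$name[-nrow(rec)]))
    mate <- ifelse(grp %% 2L == 1L, 1L, 2L)
    pid <- rec$name[match(((grp + 1L) %/% 2L) * 2L - 1L, grp)]
  }
  upid <- unique(pid)
  hold <- if (final) character() else upid[length(upid)]
  idx <- split(seq_len(nrow(rec)), factor(pid, levels = upid))
  cols <- as.list(rec)
  for (p in setdiff(upid, hold)) {
    i <- idx[[p]]
    m <- mate[i]
    callback(p, as_candidates(cols, i[m == 1L], p, 1L),
             as_candidates(cols, i[m == 2L], p, 2L))
  }
  rec[pid %in% hold, , drop = FALSE]
}

#' Stream candidate alignments pair-by-pair
#'
#' Reads a candidate file in chunks and invokes `callback(read_id, A, B)`
#' for each read pair, holding in memory only the current chunk plus any
#' group that may continue past the chunk boundary. Input must be grouped
#' by read name (both mates' records adjacent, in either order). Comment
#' headers carrying `T`, `e` and an optional fragment model are collected
#' and returned.
#'
#' @param input File path or connection.
#' @param format `"tab"` or `"maf"`.
#' @param mate_from `"suffix"`: mates identified by `/1` `/2` name suffixes;
#'   `"interleave"`: suffix-free names, consecutive name groups alternating
#'   first/second mate.
#' @param callback Function of `(read_id, A, B)`; either candidate table may
#'   have zero rows when that mate produced no alignments.
#' @param chunk_lines Lines read per chunk.
#' @return Invisibly, a list with `T`, `e` (numeric or `NULL`), `model`
#'   (a [fragment_model()] or `NULL`) and `n_pairs`.
#' @export
iterate_pairs <- function(input, format = c("tab", "maf"),
                          mate_from = c("suffix", "interleave"),
                          callback, chunk_lines = 65536L) {
  format <- match.arg(format)
  mate_from <- match.arg(mate_from)
  con <- if (is.character(input)) {
    on.exit(close(co), add = TRUE)
    co <- file(input, "r")
    co
  } else input
  headers <- character()
  pending_rec <- NULL
  pending_maf <- character()
  n_pairs <- 0L
  lineno <- 0L
  count_cb <- function(p, A, B) {
    n_pairs <<- n_pairs + 1L
    callback(p, A, B)
  }
  repeat {
    lines <- readLines(con, n = chunk_lines)
    final <- length(lines) < chunk_lines
    is_com <- startsWith(lines, "#")
    headers <- c(headers, lines[is_com])
    lines <- lines[!is_com]
    if (format == "tab") {
      rec <- parse_tab_lines(lines, offset = lineno)
    } else {
      lines <- c(pending_maf, lines)
      if (!final) {
        # never split a MAF block: hold back everything after the last
        # blank line
        blanks <- which(!nzchar(trimws(lines)))
        cut <- if (length(blanks)) max(blanks) else 0L
        pending_maf <- if (cut < length(lines))
          lines[(cut + 1L):length(lines)] else character()
        lines <- lines[seq_len(cut)]
      } else pending_maf <- character()
      rec <- parse_maf_lines(lines, offset = lineno)
    }
    lineno <- lineno + length(lines)
    if (!is.null(rec) && !nrow(rec)) rec <- NULL
    cur <- if (is.null(pending_rec)) rec
           else if (is.null(rec)) pending_rec
           else rbind(pending_rec, rec)
    pending_rec <- emit_pairs(cur, mate_from, count_cb, final = final)
    if (final) break
  }
  kv <- parse_key_values(paste(gsub("^#\\s*", "", headers), collapse = " "))
  invisible(list(
    T = if ("T" %in% names(kv)) as.numeric(kv[["T"]]) else NULL,
    e = if ("e" %in% names(kv)) as.numeric(kv[["e"]]) else NULL,
    model = parse_model_header(headers),
    n_pairs = n_pairs))
}

#' Read candidate alignments grouped per read pair
#'
#' Convenience wrapper around [iterate_pairs()] that materializes the whole
#' input: a list of read pairs (each `list(read_id, A, B)`, preserving the
#' input order of first appearance) plus the header parameters.
#'
#' @inheritParams iterate_pairs
#' @return A list with `pairs`, `T`, `e`, `model`.
#' @export
read_candidates <- function(input, format = c("tab", "maf"),
                            mate_from = c("suffix", "interleave")) {
  acc <- new.env(parent = emptyenv())
  acc$pairs <- list(); acc$i <- 0L
  hdr <- iterate_pairs(input, format, mate_from, function(pid, A, B) {
    acc$i <- acc$i + 1L
    acc$pairs[[acc$i]] <- list(read_id = pid, A = A, B = B)
  })
  list(pairs = acc$pairs, T = hdr$T, e = hdr$e, model = hdr$model)
}

# internal: candidate/record table -> tab dialect lines
format_tab_lines <- function(df, annotate = FALSE) {
  read_name <- if ("name" %in% names(df)) df$name
               else paste0(df$read_id, "/", df$mate)
  ref_aln <- df$ref_end - df$ref_start
  read_aln <- df$qend - df$qstart
  read_start <- ifelse(df$strand == "-", df$read_len - df$qend, df$qstart)
  blocks <- if ("blocks" %in% names(df) && !anyNA(df$blocks)) df$blocks
            else format_num(ref_aln)
  line <- paste(format_num(df$score), df$chrom, format_num(df$ref_start),
                format_num(ref_aln), "+", format_num(df$ref_len), read_name,
                format_num(read_start), format_num(read_aln), df$strand,
                format_num(df$read_len), blocks, sep = "\t")
  if (annotate && "mismap" %in% names(df))
    line <- paste0(line, "\tmismap=", formatC(df$mismap, format = "e",
                                              digits = 2))
  line
}

# internal: candidate/record table -> MAF lines
format_maf_lines <- function(df, annotate = FALSE) {
  read_name <- if ("name" %in% names(df)) df$name
               else paste0(df$read_id, "/", df$mate)
  ref_aln <- df$ref_end - df$ref_start
  read_aln <- df$qend - df$qstart
  read_start <- ifelse(df$strand == "-", df$read_len - df$qend, df$qstart)
  ref_text <- if ("ref_text" %in% names(df) && !anyNA(df$ref_text))
    df$ref_text else strrep("N", ref_aln)
  read_text <- if ("read_text" %in% names(df) && !anyNA(df$read_text))
    df$read_text else strrep("N", read_aln)
  a_line <- paste0("a score=", format_num(df$score),
                   if (annotate && "mismap" %in% names(df))
                     paste0(" mismap=", formatC(df$mismap, format = "e",
                                                digits = 2)) else "")
  s_ref <- paste("s", df$chrom, format_num(df$ref_start), format_num(ref_aln),
                 "+", format_num(df$ref_len), ref_text)
  s_read <- paste("s", read_name, format_num(read_start),
                  format_num(read_aln), df$strand, format_num(df$read_len),
                  read_text)
  as.vector(rbind(a_line, s_ref, s_read, ""))
}

format_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

# internal: ensure records carry ref_len (reference sequence length)
fill_ref_len <- function(df, genome) {
  if (!"ref_len" %in% names(df) || anyNA(df$ref_len)) {
    if (is.null(genome))
      stop("records lack reference sequence lengths and no genome_info ",
           "was supplied")
    df$ref_len <- chrom_length(genome, df$chrom)
  }
  df
}

#' Write candidate alignments (with parameter headers)
#'
#' @param df Candidate table ([candidates()] columns).
#' @param path File path or connection.
#' @param params A [pair_params()]; its `T` and `e` are written as a comment
#'   header.
#' @param genome A [genome_info()] (for reference sequence lengths, if the
#'   table lacks a `ref_len` column).
#' @param model Optional [fragment_model()] header to include.
#' @param format `"tab"` or `"maf"`.
#' @export
write_candidates <- function(df, path, params, genome = NULL, model = NULL,
                             format = c("tab", "maf")) {
  format <- match.arg(format)
  df <- fill_ref_len(df, genome)
  hdr <- c(sprintf("# T=%.17g e=%s", params$T, format_num(params$e)),
           if (!is.null(model)) model_header(model))
  body <- if (format == "tab") format_tab_lines(df) else format_maf_lines(df)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write posterior-annotated alignments
#'
#' MAF and tab outputs reproduce the candidate records with a
#' `mismap=` annotation (raw probability, scientific notation, 3 significant
#' digits); SAM output goes through [write_sam()]. An optional filter drops
#' records with mismap above a threshold; at a threshold of 0.5 at most one
#' record per read survives, since marginal posteriors over a read's
#' candidates sum to at most 1.
#'
#' @param records Posterior record table (candidate columns plus
#'   `posterior`, `mismap`, `mapq`; see [pair_posteriors()]).
#' @param path File path or connection.
#' @param format `"tab"`, `"maf"` or `"sam"`.
#' @param genome A [genome_info()] (required for SAM; used to fill missing
#'   reference lengths otherwise).
#' @param params Optional [pair_params()] echoed as a header (tab/maf).
#' @param model Optional [fragment_model()] echoed as a header (tab/maf).
#' @param filter Optional mismap threshold; records with `mismap > filter`
#'   are dropped.
#' @export
write_annotated <- function(records, path, format = c("tab", "maf", "sam"),
                            genome = NULL, params = NULL, model = NULL,
                            filter = NULL) {
  format <- match.arg(format)
  if (!is.null(filter))
    records <- records[is.na(records$mismap) | records$mismap <= filter, ,
                       drop = FALSE]
  if (format == "sam")
    return(write_sam(records, genome, path))
  mapped <- !is.na(records$chrom)
  records <- fill_ref_len(records[mapped, , drop = FALSE], genome)
  hdr <- c(if (!is.null(params))
             sprintf("# T=%.17g e=%s", params$T, format_num(params$e)),
           if (!is.null(model)) model_header(model))
  body <- if (format == "tab") format_tab_lines(records, annotate = TRUE)
          else format_maf_lines(records, annotate = TRUE)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Genome summary from a FASTA file or a two-column length table
#'
#' @param path FASTA file (extension `.fa`, `.fasta`, `.fna`) or a
#'   whitespace-separated two-column `name length` table.
#' @param circular Passed to [genome_info()].
#' @return A [genome_info()].
#' @export
read_genome_info <- function(path, circular = NULL) {
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    lens <- stats::setNames(Biostrings::width(seqs),
                            sub("\\s.*$", "", names(seqs)))
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("name", "length"),
                             stringsAsFactors = FALSE)
    lens <- stats::setNames(tab$length, tab$name)
  }
  genome_info(lens, circular = circular)
}
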