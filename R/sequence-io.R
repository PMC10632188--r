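# Genomic file formats and window plumbing.
#
# Coordinate conventions: all internal coordinates are 0-based, half-open.
# GFF3 is read as 1-based inclusive and converted at the boundary; BED and
# bedGraph are read as 0-based half-open.

#' Construct a genome store
#'
#' A genome store is a named character vector of uppercase chromosome
#' sequences over the IUPAC alphabet, the container consumed by every
#' analysis in the package.
#'
#' @param records named character vector, chromosome id -> sequence.
#' @return an object of class `genome_store`.
#' @export
genome_store <- function(records) {
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all chromosome ids must be non-empty")
  }
  if (anyDuplicated(names(records))) {
    stop(sprintf("duplicate chromosome id '%s'",
                 names(records)[anyDuplicated(names(records))]))
  }
  records <- toupper(records)
  if (any(!nzchar(records))) {
    stop(sprintf("empty sequence for chromosome '%s'",
                 names(records)[!nzchar(records)][1L]))
  }
  ok <- paste0(IUPAC_LETTERS, collapse = "")
  for (i in seq_along(records)) {
    bad <- gsub(sprintf("[%s]", ok), "", records[[i]])
    if (nzchar(bad)) {
      stop(sprintf("non-IUPAC letter '%s' in chromosome '%s'",
                   substr(bad, 1L, 1L), names(records)[i]))
    }
  }
  structure(records, class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat(sprintf("<genome_store> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_len(min(length(x), 10L))) {
    cat(sprintf("  %s: %d bp\n", names(x)[i], nchar(x[[i]])))
  }
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop(sprintf("unknown chromosome '%s'", chrom))
  nchar(genome[[chrom]])
}

#' Read a multi-record FASTA file into a genome store
#'
#' Sequences are uppercase-normalized and validated against the IUPAC
#' alphabet; record order is preserved and ids (first whitespace-delimited
#' token of the header) must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [genome_store()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s' in %s", ids[anyDuplicated(ids)], path))
  }
  recs <- as.character(set)
  names(recs) <- ids
  genome_store(recs)
}

#' Write a genome store to FASTA
#'
#' @param genome a [genome_store()].
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(sprintf("(^|;)\\s*%s=[^;]+", key), attr))
  if (length(m) == 0L || !nzchar(m)) return(NA_character_)
  sub(sprintf("^.*%s=", key), "", m)
}

#' Read a GFF3 file into a feature table
#'
#' Minimal GFF3 reader: nine tab-separated columns, `ID` and `Parent`
#' attributes extracted. Malformed lines raise an error naming the line
#' number. Coordinates are kept 1-based inclusive as in the file.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns seqid, source, type, start, end, score,
#'   strand, phase, attributes, ID, Parent.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    stop(sprintf("malformed GFF line %d in %s (%d fields, expected 9)",
                 keep[which(nf != 9L)[1L]], path, nf[nf != 9L][1L]))
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed GFF line %d in %s (non-numeric coordinate)",
                 keep[which(is.na(start) | is.na(end))[1L]], path))
  }
  data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = start, end = end, score = m[, 6L], strand = m[, 7L],
    phase = m[, 8L], attributes = m[, 9L],
    ID = vapply(m[, 9L], .parse_gff_attr, character(1L), key = "ID",
                USE.NAMES = FALSE),
    Parent = vapply(m[, 9L], .parse_gff_attr, character(1L), key = "Parent",
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write a GFF3 feature table
#'
#' @param gff data.frame as produced by [read_gff3()] (columns seqid, source,
#'   type, start, end, score, strand, phase, attributes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(gff$seqid, gff$source, gff$type, gff$start, gff$end,
                   gff$score, gff$strand, gff$phase, gff$attributes,
                   sep = "\t"), con)
  invisible(path)
}

#' Extract transcription start sites from a GFF3 annotation
#'
#' The TSS of a gene is the first base of its annotated 5' UTR (the most
#' 5' base in transcription direction). Per gene a single isoform is used:
#' the one whose ID ends in ".1" when present, otherwise the
#' lexicographically first. Genes without a `five_prime_UTR` feature are
#' skipped; TSSs outside chromosome bounds are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @param genome a [genome_store()] used for bounds checking.
#' @return data.frame with columns gene_id, chrom, pos (0-based genomic index
#'   of the first transcribed base), strand.
#' @export
read_tss_from_gff <- function(path, genome) {
  gff <- read_gff3(path)
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  iso2gene <- stats::setNames(
    ifelse(is.na(mrna$Parent), mrna$ID, mrna$Parent), mrna$ID)
  utr <- gff[gff$type == "five_prime_UTR", , drop = FALSE]
  if (nrow(utr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character()))
  }
  iso <- ifelse(is.na(utr$Parent), utr$ID, utr$Parent)
  gene <- ifelse(iso %in% names(iso2gene), unname(iso2gene[iso]), iso)
  out <- list()
  skipped <- 0L
  for (g in unique(gene)) {
    rows <- utr[gene == g, , drop = FALSE]
    isos <- iso[gene == g]
    pick <- isos[endsWith(isos, ".1")]
    chosen <- if (length(pick) > 0L) pick[1L] else sort(isos)[1L]
    rows <- rows[isos == chosen, , drop = FALSE]
    strand <- rows$strand[1L]
    if (!strand %in% c("+", "-")) next
    pos <- if (strand == "+") min(rows$start) - 1L else max(rows$end) - 1L
    chrom <- rows$seqid[1L]
    if (!chrom %in% names(genome) || pos < 0L ||
        pos >= chrom_length(genome, chrom)) {
      skipped <- skipped + 1L
      next
    }
    out[[g]] <- data.frame(gene_id = g, chrom = chrom, pos = pos,
                           strand = strand, stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(sprintf("%d TSS record(s) outside chromosome bounds skipped",
                    skipped))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character())
  }
  rownames(res) <- NULL
  res
}

#' Tile a genome into fixed-size windows
#'
#' Windows of `window` bp are placed at starts 0, step, 2*step, ... on the
#' plus strand of every chromosome. Windows containing any letter outside
#' A,C,G,T (IUPAC ambiguity codes) are discarded; windows straddling the
#' chromosome end are never emitted.
#'
#' @param genome a [genome_store()].
#' @param window window length in bp (>= 2), default 50.
#' @param step step size in bp (>= 1), default 50.
#' @return data.frame with columns chrom, start (0-based), end (exclusive),
#'   strand, seq.
#' @export
tile_genome <- function(genome, window = 50L, step = 50L) {
  stopifnot(window >= 2L, step >= 1L)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    L <- nchar(genome[[i]])
    if (L < window) next
    starts <- seq.int(0L, L - window, by = step)
    seqs <- substring(genome[[i]], starts + 1L, starts + window)
    keep <- !grepl("[^ACGT]", seqs)
    if (!any(keep)) next
    out[[i]] <- data.frame(chrom = names(genome)[i], start = starts[keep],
                           end = starts[keep] + window, strand = "+",
                           seq = seqs[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      seq = character())
  }
  rownames(res) <- NULL
  res
}

#' Extract anchor-centered, strand-oriented regions
#'
#' For each anchor the sequence covering offsets -flank..+flank relative to
#' the anchor position is returned, oriented so that offsets increase in
#' transcription direction: minus-strand regions are reverse-complemented.
#' Anchors closer than `flank` to a chromosome edge yield `NA` and a single
#' summary warning.
#'
#' @param genome a [genome_store()].
#' @param anchors data.frame with columns chrom, pos (0-based), strand.
#' @param flank flank size in bp (>= 25).
#' @return character vector of length `nrow(anchors)`; each non-NA entry has
#'   length `2*flank + 1` and its (flank+1)-th character sits on the anchor.
#' @export
extract_anchored_regions <- function(genome, anchors, flank) {
  stopifnot(flank >= 25L)
  n <- nrow(anchors)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    chrom <- anchors$chrom[i]
    pos <- anchors$pos[i]
    L <- chrom_length(genome, chrom)
    if (pos - flank < 0L || pos + flank >= L) next
    s <- substr(genome[[chrom]], pos - flank + 1L, pos + flank + 1L)
    if (anchors$strand[i] == "-") {
      if (grepl("[^ACGT]", s)) next   # cannot orient ambiguous region
      s <- revcomp(s)
    }
    out[i] <- s
  }
  if (anyNA(out)) {
    warning(sprintf("%d anchor(s) skipped (chromosome edge or ambiguous)",
                    sum(is.na(out))))
  }
  out
}

#' Strip fixed terminal adapters from loop-seq sequences
#'
#' Loop-seq constructs carry 25 fixed bases at either terminus around a
#' 50-bp variable probe. Length-100 inputs return bases 26..75; length-50
#' inputs are returned unchanged; any other length is an error.
#'
#' @param seq character vector of raw sequences (length 50 or 100 each).
#' @return character vector of 50-bp probe sequences.
#' @export
strip_adapters <- function(seq) {
  len <- nchar(seq)
  if (any(!len %in% c(50L, 100L))) {
    stop(sprintf("sequence length %d is neither 50 nor 100",
                 len[!len %in% c(50L, 100L)][1L]))
  }
  ifelse(len == 100L, substr(seq, 26L, 75L), seq)
}

#' Read a loop-seq style score table
#'
#' Tab-separated with header columns `sequence` and `c0`. Sequences are
#' uppercased; non-finite scores are an error.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sequence, c0.
#' @export
read_loopseq_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "c0") %in% names(df))) {
    stop("loop-seq TSV must have header columns 'sequence' and 'c0'")
  }
  df$sequence <- toupper(df$sequence)
  df$c0 <- as.numeric(df$c0)
  if (any(!is.finite(df$c0))) stop("non-finite c0 score in loop-seq table")
  df[, c("sequence", "c0")]
}

#' Write a loop-seq style score table
#' @param library data.frame with columns sequence, c0.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loopseq_tsv <- function(library, path) {
  utils::write.table(library[, c("sequence", "c0")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like interval file (0-based, half-open)
#'
#' @param path path to a BED file with at least chrom/start/end; optional
#'   columns 4-6 are named name/score/strand, further columns kept as V7...
#' @return data.frame with columns chrom, start, end (+ extras).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(ncol(df), 6L))] <- base[seq_len(min(ncol(df), 6L))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("BED interval with end <= start")
  df
}

#' Read a bedGraph track into per-position values
#'
#' Intervals (0-based half-open) are expanded to one row per base.
#'
#' @param path path to a bedGraph file.
#' @return data.frame with columns chrom, pos (0-based), value.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4L) stop("bedGraph file needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  w <- df$end - df$start
  data.frame(
    chrom = rep(df$chrom, w),
    pos = unlist(lapply(seq_len(nrow(df)),
                        function(i) seq.int(df$start[i], df$end[i] - 1L))),
    value = rep(df$value, w)
  )
}
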