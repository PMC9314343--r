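#' Read genomic regions from BED or BEDPE text
#'
#' BED3/6 rows become intervals; BEDPE rows become 2D features with
#' `kind = "loop"`. Coordinates are kept 0-based half-open as on disk.
#'
#' @param path file path.
#' @param format `"BED"` or `"BEDPE"`; default guessed from the extension.
#' @return interval or feature data.frame.
#' @export
read_regions <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("bedpe$", path, ignore.case = TRUE)) "BEDPE" else "BED"
  format <- match.arg(toupper(format), c("BED", "BEDPE"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(if (format == "BED") empty_intervals() else
             features2d(character(), numeric(), numeric(), numeric(), numeric()))
  fields <- strsplit(lines, "[ \t]+")
  nmin <- if (format == "BED") 3L else 6L
  for (i in seq_along(fields))
    if (length(fields[[i]]) < nmin)
      stop("malformed ", format, " line ", i, ": fewer than ", nmin, " fields")
  get <- function(j, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= j) f[j] else default, character(1))
  num <- function(j) {
    v <- suppressWarnings(as.numeric(get(j)))
    bad <- which(is.na(v))
    if (length(bad)) stop("malformed ", format, " line ", bad[1],
                          ": non-numeric coordinate")
    v
  }
  if (format == "BED") {
    start <- num(2); end <- num(3)
    bad <- which(start >= end)
    if (length(bad)) stop("malformed BED line ", bad[1], ": start >= end")
    sc <- suppressWarnings(as.numeric(get(5)))
    strand <- get(6); strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
    nm <- get(4); nm[is.na(nm)] <- "."
    return(intervals(get(1), start, end, name = nm, score = sc, strand = strand))
  }
  s1 <- num(2); e1 <- num(3); s2 <- num(5); e2 <- num(6)
  bad <- which(s1 >= e1 | s2 >= e2)
  if (length(bad)) stop("malformed BEDPE line ", bad[1], ": start >= end")
  c1 <- get(1); c2 <- get(4)
  bad <- which(c1 != c2)
  if (length(bad)) stop("BEDPE line ", bad[1],
                        ": interchromosomal pairs are not supported")
  nm <- get(7); nm[is.na(nm)] <- paste0("loop_", seq_along(fields))[is.na(nm)]
  features2d(c1, s1, e1, s2, e2, kind = "loop", name = nm)
}

#' Write regions as BED or BEDPE text
#' @param x interval or feature data.frame.
#' @param path output path.
#' @export
write_regions <- function(x, path) {
  if (all(c("start1", "start2") %in% names(x))) {
    out <- data.frame(x$chrom, fmt_coord(x$start1), fmt_coord(x$end1),
                      x$chrom, fmt_coord(x$start2), fmt_coord(x$end2), x$name)
  } else {
    out <- data.frame(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
                      x$name %||% ".",
                      ifelse(is.na(x$score %||% NA), ".", as.character(x$score %||% ".")),
                      x$strand %||% ".")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read or write a bedGraph track
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(df$start >= df$end)) stop("malformed bedGraph: start >= end")
  df
}

#' @rdname read_bedgraph
#' @param x bedGraph data.frame.
#' @export
write_bedgraph <- function(x, path) {
  out <- data.frame(x$chrom, fmt_coord(x$start), fmt_coord(x$end), x$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a per-bin track to bedGraph intervals
#' @param track a [bin_track()].
#' @param drop_na drop missing bins (default TRUE).
#' @return bedGraph data.frame.
#' @export
bintrack_to_bedgraph <- function(track, drop_na = TRUE) {
  n <- length(track$values)
  df <- data.frame(chrom = track$chrom,
                   start = (seq_len(n) - 1) * track$resolution,
                   end = seq_len(n) * track$resolution,
                   value = track$values)
  if (drop_na) df <- df[!is.na(df$value), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read or write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package's plain character
#' representation.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Count tables of non-negative integer counts
#'
#' @param counts integer matrix, features x samples.
#' @param conditions per-sample condition labels.
#' @param lengths optional per-feature lengths (bp).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, conditions = NULL, lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (!is.null(conditions) && length(conditions) != ncol(counts))
    stop("one condition label per sample required")
  if (!is.null(lengths) && length(lengths) != nrow(counts))
    stop("one length per feature required")
  structure(list(counts = counts, conditions = conditions, lengths = lengths),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  if (!is.null(x$conditions)) cat("conditions:", paste(x$conditions, collapse = " "), "\n")
  invisible(x)
}

#' @rdname count_table
#' @param path TSV path (feature ids in first column, samples in header).
#' @export
read_count_table <- function(path, conditions = NULL) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  count_table(as.matrix(m), conditions = conditions)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(feature = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
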