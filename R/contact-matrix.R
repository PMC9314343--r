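#' Binned Hi-C contact matrix for one chromosome
#'
#' Counts are stored dense and symmetric. The matrix total counts the
#' diagonal once: `total = sum(upper triangle including diagonal)`. This
#' policy is used consistently by depth normalisation.
#'
#' @param chrom chromosome name.
#' @param resolution bin size (bp).
#' @param counts symmetric non-negative numeric matrix.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, resolution, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("negative contact count")
  if (max(abs(counts - t(counts))) > 1e-9 * max(1, max(abs(counts))))
    stop("counts matrix is not symmetric")
  counts <- (counts + t(counts)) / 2
  structure(list(chrom = chrom, resolution = resolution, counts = counts,
                 total = matrix_total(counts)),
            class = "contact_matrix")
}

matrix_total <- function(counts) sum(counts[upper.tri(counts, diag = TRUE)])

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "@", x$resolution, "bp,",
      nrow(x$counts), "bins, total", format(x$total, big.mark = ","), "\n")
  invisible(x)
}

#' Per-bin scalar track aligned to a binning
#'
#' @param chrom chromosome name.
#' @param resolution bin size (bp).
#' @param values numeric vector, one value per bin; `NA` marks missing bins.
#' @param layout optional layout to check `length(values)` against.
#' @return object of class `bin_track`.
#' @export
bin_track <- function(chrom, resolution, values, layout = NULL) {
  if (!is.null(layout) && length(values) != n_bins(layout, chrom, resolution))
    stop("values length does not match ceil(chrom_length/resolution)")
  structure(list(chrom = chrom, resolution = resolution,
                 values = as.numeric(values)),
            class = "bin_track")
}

#' Read a contact matrix from dense or triplet text
#'
#' Dense format is a whitespace-separated square matrix. Triplet format has
#' rows `bin1 bin2 count` (0-based bin indices); entries are mirrored into
#' both triangles, so each pair should be listed once.
#'
#' @param path file path.
#' @param layout [genome_layout()].
#' @param chrom chromosome the matrix belongs to.
#' @param resolution bin size (bp).
#' @param format `"dense"` or `"triplet"`.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, layout, chrom, resolution,
                                format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  nb <- n_bins(layout, chrom, resolution)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nb) stop("dense matrix has ", nrow(m), " rows, expected ", nb)
    if (any(m < 0)) stop("negative contact count")
    if (max(abs(m - t(m))) > 1e-9)
      stop("asymmetric dense matrix (tolerance 1e-9)")
    return(contact_matrix(chrom, resolution, m))
  }
  tr <- utils::read.table(path, header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  if (any(tr$count < 0)) stop("negative contact count")
  if (any(tr$bin1 < 0 | tr$bin1 >= nb | tr$bin2 < 0 | tr$bin2 >= nb))
    stop("triplet bin index outside layout")
  m <- matrix(0, nb, nb)
  for (k in seq_len(nrow(tr))) {
    i <- tr$bin1[k] + 1; j <- tr$bin2[k] + 1
    m[i, j] <- m[i, j] + tr$count[k]
    if (i != j) m[j, i] <- m[j, i] + tr$count[k]
  }
  contact_matrix(chrom, resolution, m)
}

#' Write a contact matrix as dense or triplet text
#' @param x a [contact_matrix()].
#' @param path output path.
#' @param format `"triplet"` (nonzero upper triangle, 0-based) or `"dense"`.
#' @export
write_contact_matrix <- function(x, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  ut <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0, arr.ind = TRUE)
  out <- data.frame(bin1 = ut[, 1] - 1, bin2 = ut[, 2] - 1,
                    count = x$counts[ut])
  out <- out[order(out$bin1, out$bin2), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
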