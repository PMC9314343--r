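#' Genome layout
#'
#' A minimal description of the genome the analysis runs on: chromosome
#' names and lengths in base pairs. All coordinates in the package are
#' 0-based half-open (BED convention); 1-based inputs are converted at the
#' reader boundary only.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths (bp), > 0.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e7, 2e7))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  if (!chrom %in% layout$chrom_names)
    stop("unknown chromosome: ", chrom)
  unname(layout$chrom_lengths[chrom])
}

#' Number of bins of a chromosome at a given resolution
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @return integer bin count, `ceiling(length / resolution)`.
#' @export
n_bins <- function(layout, chrom, resolution) {
  as.integer(ceiling(chrom_length(layout, chrom) / resolution))
}
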