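#' Genome layout
#'
#' An ordered set of chromosomes with lengths and a fixed bin size. All binned
#' signal in the package lives on the global bin index defined by a layout:
#' bins are numbered chromosome by chromosome, in layout order, each bin
#' covering `[i * bin_size, min((i + 1) * bin_size, chrom_length))` in 0-based
#' half-open coordinates.
#'
#' @param lengths named numeric vector of chromosome lengths in bp, in the
#'   order chromosomes should be iterated.
#' @param bin_size bin width in bp (default 1000, i.e. 1 kb resolution).
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(lengths, bin_size = 1000) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths))) stop("duplicated chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (length(bin_size) != 1L || bin_size <= 0) stop("bin_size must be > 0")
  n_bins <- as.integer(ceiling(lengths / bin_size))
  structure(
    list(
      chrom = names(lengths),
      length = unname(as.numeric(lengths)),
      bin_size = as.numeric(bin_size),
      n_bins = n_bins,
      offset = c(0L, cumsum(n_bins)[-length(n_bins)])
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom), "chromosome(s),",
      sum(x$n_bins), "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Total number of bins in a layout
#' @param layout a `genome_layout`.
#' @export
n_bins <- function(layout) sum(layout$n_bins)

total_bp <- function(layout) sum(layout$length)

chrom_index <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  i
}

#' Global bin index of positions
#'
#' @param layout a `genome_layout`.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer global bin indices (1-based).
#' @export
bin_of <- function(layout, chrom, pos) {
  ci <- chrom_index(layout, chrom)
  if (any(pos < 0) || any(pos >= layout$length[ci]))
    stop("position outside chromosome bounds")
  as.integer(layout$offset[ci] + floor(pos / layout$bin_size) + 1)
}

#' Per-bin coordinate table
#'
#' @param layout a `genome_layout`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and the
#'   global `bin` index, one row per bin.
#' @export
bin_table <- function(layout) {
  chrom <- rep(layout$chrom, layout$n_bins)
  start <- unlist(lapply(seq_along(layout$chrom), function(i)
    seq(0, by = layout$bin_size, length.out = layout$n_bins[i])), use.names = FALSE)
  end <- pmin(start + layout$bin_size, rep(layout$length, layout$n_bins))
  data.frame(chrom = chrom, start = start, end = end,
             bin = seq_len(sum(layout$n_bins)))
}

#' Global bin indices covered by an interval set
#'
#' @param layout a `genome_layout`.
#' @param set an `interval_set`.
#' @return integer vector of distinct global bin indices touched by any
#'   interval.
#' @export
bins_of_intervals <- function(layout, set) {
  if (nrow(set) == 0L) return(integer(0))
  ci <- chrom_index(layout, set$chrom)
  b0 <- floor(set$start / layout$bin_size)
  b1 <- floor((set$end - 1) / layout$bin_size)
  idx <- unlist(lapply(seq_len(nrow(set)), function(i)
    layout$offset[ci[i]] + (b0[i]:b1[i]) + 1L), use.names = FALSE)
  sort(unique(as.integer(idx)))
}

#' Read / write a chrom-sizes file (name<TAB>length)
#' @param path file path.
#' @param bin_size bin width for the resulting layout.
#' @return `read_chrom_sizes` returns a `genome_layout`.
#' @export
read_chrom_sizes <- function(path, bin_size = 1000) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  lens <- stats::setNames(x$length, x$chrom)
  genome_layout(lens, bin_size = bin_size)
}

#' @rdname read_chrom_sizes
#' @param layout a `genome_layout` to write.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(data.frame(layout$chrom, format(layout$length, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
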