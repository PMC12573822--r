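#' Genomic interval sets
#'
#' The package's interval container: a data frame with columns `chrom`,
#' `start`, `end`, `name`, `score`, `strand`, in 0-based half-open (BED)
#' coordinates. Interval algebra (overlap, merge, nearest) is delegated to
#' GenomicRanges behind this surface.
#'
#' @param chrom chromosome names (or a data.frame with the columns above).
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name optional identifiers (NA allowed).
#' @param score optional numeric scores.
#' @param strand one of `+`, `-`, `.` per interval.
#' @param sorted logical, whether the input is already sorted.
#' @return an object of class `interval_set` (also a data.frame).
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), name = NA_character_,
                         score = NA_real_, strand = ".", sorted = FALSE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    for (col in c("name", "score", "strand")) {
      if (is.null(df[[col]]))
        df[[col]] <- rep_len(switch(col, name = NA_character_,
                                    score = NA_real_, strand = "."), nrow(df))
    }
    df <- df[, unique(c("chrom", "start", "end", "name", "score", "strand",
                        names(df))), drop = FALSE]
  } else {
    n <- max(length(chrom), length(start), length(end))
    df <- data.frame(chrom = rep_len(as.character(chrom), n),
                     start = rep_len(as.numeric(start), n),
                     end = rep_len(as.numeric(end), n),
                     name = rep_len(as.character(name), n),
                     score = rep_len(as.numeric(score), n),
                     strand = rep_len(as.character(strand), n),
                     stringsAsFactors = FALSE)
  }
  validate_intervals(df)
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"),
            sorted = isTRUE(sorted))
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-finite interval coordinates")
  if (any(df$start < 0)) stop("negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("empty or inverted interval(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set with", nrow(x), "interval(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Sort an interval set by (chrom, start, end)
#' @param x an `interval_set`.
#' @param decreasing unused (for generic compatibility).
#' @param ... unused.
#' @export
sort.interval_set <- function(x, decreasing = FALSE, ...) {
  o <- order(x$chrom, x$start, x$end)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  out
}

as_granges <- function(set) {
  GenomicRanges::GRanges(
    seqnames = set$chrom,
    ranges = IRanges::IRanges(start = set$start + 1, end = set$end),
    strand = ifelse(set$strand == ".", "*", set$strand)
  )
}

from_granges <- function(gr, name = NA_character_, score = NA_real_) {
  st <- as.character(BiocGenerics::strand(gr))
  interval_set(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1,
               end = BiocGenerics::end(gr),
               name = name, score = score,
               strand = ifelse(st == "*", ".", st))
}

#' Merge intervals closer than a maximum gap
#'
#' Same-chromosome intervals whose gap is `<= max_gap` bp are unioned
#' (inclusive comparison, the ROSE stitching convention: a gap of exactly
#' `max_gap` merges). Output is sorted and non-overlapping; each merged
#' interval records its constituent input names in `name`
#' (comma-separated) and their count in `score`.
#'
#' @param set an `interval_set`.
#' @param max_gap maximum gap in bp (>= 0); 0 merges touching intervals only.
#' @return a sorted `interval_set` with columns `name` (constituents) and
#'   `score` (number of constituents).
#' @export
merge_within <- function(set, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(set) == 0L) return(set)
  s <- sort(set)
  ids <- s$name
  ids[is.na(ids)] <- paste0("iv", which(is.na(ids)))
  gr <- as_granges(s)
  BiocGenerics::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  constituents <- vapply(revmap, function(ix) paste(ids[ix], collapse = ","), "")
  n_const <- lengths(revmap)
  from_granges(red, name = constituents, score = as.numeric(n_const))
}

#' Base-pair Jaccard index of two interval sets
#'
#' `bp(a intersect b) / bp(a union b)`. Returns 0 when the union is empty
#' (both sets empty), by convention.
#'
#' @param a,b `interval_set`s on the same genome.
#' @return a scalar in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  ga <- GenomicRanges::reduce(as_granges(a), ignore.strand = TRUE)
  gb <- GenomicRanges::reduce(as_granges(b), ignore.strand = TRUE)
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(ga, gb, ignore.strand = TRUE)))
  if (uni == 0) return(0)
  inter / uni
}

#' Distance from intervals to the nearest gene TSS
#'
#' The TSS is treated as a point coordinate: distance is 0 when a TSS lies
#' inside the interval, otherwise the bp gap to the nearest interval edge.
#' Chromosomes with no gene return `Inf` (documented sentinel).
#'
#' @param set an `interval_set` (one or more intervals).
#' @param genes a gene-model data.frame from [read_gtf_genes()] (needs
#'   `chrom` and `tss` columns).
#' @return numeric vector of distances, one per interval.
#' @export
distance_to_nearest_tss <- function(set, genes) {
  if (nrow(set) == 0L) return(numeric(0))
  out <- rep(Inf, nrow(set))
  for (ch in unique(set$chrom)) {
    tss <- genes$tss[genes$chrom == ch]
    rows <- which(set$chrom == ch)
    if (!length(tss)) next
    tss <- sort(tss)
    for (i in rows) {
      s <- set$start[i]; e <- set$end[i]
      if (any(tss >= s & tss < e)) { out[i] <- 0; next }
      out[i] <- min(pmin(abs(tss - s), abs(tss - e)))
    }
  }
  out
}

#' Fraction of query intervals overlapping a subject set
#'
#' Count-based (not bp-based): the fraction of query intervals with at least
#' 1 bp overlap with any subject interval. An empty subject yields 0.
#'
#' @param query,subject `interval_set`s.
#' @return a scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(query, subject) {
  if (nrow(query) == 0L) return(NaN)
  if (nrow(subject) == 0L) return(0)
  hits <- GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                       ignore.strand = TRUE)
  mean(hits > 0)
}

#' Which query intervals overlap a subject set
#' @param query,subject `interval_set`s.
#' @return logical vector, one per query interval.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                               ignore.strand = TRUE) > 0
}

#' Count subject intervals overlapping each query interval
#' @param query,subject `interval_set`s.
#' @return integer vector, one per query interval.
#' @export
count_overlaps <- function(query, subject) {
  if (nrow(query) == 0L) return(integer(0))
  if (nrow(subject) == 0L) return(rep(0L, nrow(query)))
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                               ignore.strand = TRUE)
}
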