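#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open coordinates. `track`, `browser` and `#`
#' comment lines are skipped. Malformed lines (non-integer coordinates,
#' `start >= end`, too few columns) raise a parse error naming the line
#' number.
#'
#' @param path file path.
#' @return an `interval_set` in file order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(interval_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 fields")
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": empty or inverted interval (start >= end)")
  name <- if (any(nf >= 4)) get(4) else NA_character_
  score <- if (any(nf >= 5)) suppressWarnings(as.numeric(get(5))) else NA_real_
  strand <- if (any(nf >= 6)) get(6) else "."
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  name[!is.na(name) & name == "."] <- NA_character_
  interval_set(chrom = get(1), start = start, end = end,
               name = name, score = score, strand = strand)
}

#' Write an interval set as BED
#'
#' Writes BED6 when any of name/score/strand carries information, BED3
#' otherwise. Round-trips losslessly through [read_bed()] for BED6 content.
#'
#' @param set an `interval_set`.
#' @param path output path.
#' @export
write_bed <- function(set, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (nrow(set) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  bed6 <- any(!is.na(set$name)) || any(!is.na(set$score)) || any(set$strand != ".")
  if (bed6) {
    nm <- ifelse(is.na(set$name), ".", set$name)
    sc <- ifelse(is.na(set$score), "0", fmt(set$score))
    out <- paste(set$chrom, fmt(set$start), fmt(set$end), nm, sc, set$strand,
                 sep = "\t")
  } else {
    out <- paste(set$chrom, fmt(set$start), fmt(set$end), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Keeps `gene` features of a GENCODE-dialect GTF. GTF coordinates are
#' 1-based closed; they are converted to the package's 0-based half-open
#' convention at this boundary. The TSS is the strand-aware 5' end
#' (`start` for `+`, `end - 1` for `-`).
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `length`.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  feat <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_, "")
  keep <- which(feat == "gene")
  if (!length(keep)) return(data.frame(gene_id = character(), gene_name = character(),
                                       chrom = character(), strand = character(),
                                       start = numeric(), end = numeric(),
                                       tss = numeric(), length = numeric()))
  fields <- fields[keep]
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0 & nzchar(m),
           sub(paste0(key, ' "([^"]*)"'), "\\1", m), NA_character_)
  }
  attrs <- vapply(fields, function(f) f[9], "")
  gene_id <- vapply(seq_along(fields), function(i) {
    m <- regmatches(attrs[i], regexpr('gene_id "[^"]*"', attrs[i]))
    if (!length(m)) NA_character_ else sub('gene_id "([^"]*)"', "\\1", m)
  }, "")
  if (anyNA(gene_id))
    stop("GTF parse error: gene feature without gene_id attribute (record ",
         which(is.na(gene_id))[1], ")")
  gene_name <- vapply(seq_along(fields), function(i) {
    m <- regmatches(attrs[i], regexpr('gene_name "[^"]*"', attrs[i]))
    if (!length(m)) NA_character_ else sub('gene_name "([^"]*)"', "\\1", m)
  }, "")
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  chrom <- vapply(fields, function(f) f[1], "")
  start1 <- as.numeric(vapply(fields, function(f) f[4], ""))
  end1 <- as.numeric(vapply(fields, function(f) f[5], ""))
  strand <- vapply(fields, function(f) f[7], "")
  start <- start1 - 1  # 0-based half-open
  end <- end1
  tss <- ifelse(strand == "-", end - 1, start)
  data.frame(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
             strand = strand, start = start, end = end, tss = tss,
             length = end - start, stringsAsFactors = FALSE)
}

#' Write gene models as a GENCODE-dialect GTF
#' @param genes gene-model data.frame (see [read_gtf_genes()]).
#' @param path output path.
#' @export
write_gtf_genes <- function(genes, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "protein_coding";',
                   genes$gene_id, genes$gene_name)
  out <- paste(genes$chrom, "synthetic", "gene",
               fmt(genes$start + 1), fmt(genes$end), ".", genes$strand, ".",
               attrs, sep = "\t")
  writeLines(c("##description: synthetic gene annotation", out), path)
  invisible(path)
}

#' Read / write a 4-column bedGraph
#' @param path file path.
#' @return `read_bedgraph` returns an `interval_set` with the value in
#'   `score`.
#' @export
read_bedgraph <- function(path) {
  set <- read_bed(path)  # first 3 columns identical; 4th parsed as name
  if (nrow(set) && any(!is.na(set$name)))
    set$score <- suppressWarnings(as.numeric(set$name))
  set$name <- NA_character_
  set
}

#' @rdname read_bedgraph
#' @param set an `interval_set` whose `score` holds the track value.
#' @export
write_bedgraph <- function(set, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- paste(set$chrom, fmt(set$start), fmt(set$end), fmt(set$score), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#' @param path file path (set name, description, then member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  sets
}

#' Read position weight matrices in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections over the
#' DNA alphabet.
#'
#' @param path file path.
#' @return named list of 4-column (A, C, G, T) probability matrices.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  midx <- grep("^MOTIF", lines)
  if (!length(midx)) stop("no MOTIF records in ", path)
  motifs <- list()
  for (i in seq_along(midx)) {
    header <- strsplit(trimws(lines[midx[i]]), "\\s+")[[1]]
    name <- if (length(header) >= 2) header[2] else paste0("motif", i)
    to <- if (i < length(midx)) midx[i + 1] - 1 else length(lines)
    block <- lines[midx[i]:to]
    lp <- grep("letter-probability matrix", block)
    if (!length(lp)) stop("MOTIF ", name, " lacks a letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w= *([0-9]+).*", "\\1", block[lp[1]])))
    rows <- block[(lp[1] + 1):(lp[1] + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(mat) != 4) stop("MOTIF ", name, ": expected 4 columns (ACGT)")
    colnames(mat) <- c("A", "C", "G", "T")
    motifs[[name]] <- mat
  }
  motifs
}

#' Write motifs in MEME minimal format
#' @param motifs named list of 4-column probability matrices.
#' @param path output path.
#' @param background length-4 background frequencies (A, C, G, T).
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                   background[3], background[4]), "")
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    out <- c(out, paste("MOTIF", nm),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(m)),
             apply(m, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                             r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write FASTA sequences
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences.
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
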