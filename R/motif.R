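#' Motif enrichment by log-odds scanning and Fisher's exact test
#'
#' A simplified Fisher-mode motif enrichment: each motif's PWM is scanned as
#' log-odds against the 0-order background composition of the background
#' sequence set; a sequence is a hit when any window scores above the
#' `score_quantile` of all background window scores for that motif. Hit
#' counts in target vs background sequences are compared by a one-sided
#' Fisher exact (hypergeometric) test, BH-corrected across motifs.
#'
#' @param target,background named character vectors of DNA sequences.
#' @param motifs named list of 4-column (A, C, G, T) probability matrices
#'   (see [read_meme_motifs()]).
#' @param score_quantile background score quantile defining a hit window
#'   (default 0.999).
#' @return data.frame with per-motif hit counts, odds ratio, `p` and `padj`.
#' @export
motif_enrichment <- function(target, background, motifs,
                             score_quantile = 0.999) {
  bases <- c("A", "C", "G", "T")
  enc <- function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], bases)
    if (anyNA(v)) stop("sequence alphabet mismatch: not ACGT")
    v
  }
  tgt <- lapply(target, enc)
  bg <- lapply(background, enc)
  bg_freq <- tabulate(unlist(bg), nbins = 4)
  bg_freq <- (bg_freq + 1) / sum(bg_freq + 4)

  scan_max <- function(seq_enc, lom) {
    w <- nrow(lom)
    n <- length(seq_enc)
    if (n < w) return(-Inf)
    sc <- numeric(n - w + 1)
    for (j in seq_len(w)) sc <- sc + lom[j, seq_enc[j:(j + n - w)]]
    sc
  }
  rows <- lapply(names(motifs), function(nm) {
    pwm <- motifs[[nm]]
    if (ncol(pwm) != 4) stop("PWM must have 4 columns (ACGT)")
    if (any(vapply(c(tgt, bg), length, 0L) < nrow(pwm)))
      stop("sequence shorter than motif ", nm)
    lom <- log((pwm + 1e-4) / matrix(bg_freq, nrow(pwm), 4, byrow = TRUE))
    bg_scores <- unlist(lapply(bg, scan_max, lom = lom))
    thr <- stats::quantile(bg_scores, score_quantile, names = FALSE)
    hit_t <- vapply(tgt, function(s) any(scan_max(s, lom) > thr), TRUE)
    hit_b <- vapply(bg, function(s) any(scan_max(s, lom) > thr), TRUE)
    a <- sum(hit_t); b <- sum(hit_b)
    nt <- length(tgt); nb <- length(bg)
    # one-sided Fisher exact = hypergeometric upper tail on the 2x2 table
    p <- stats::phyper(a - 1, a + b, nt + nb - a - b, nt, lower.tail = FALSE)
    or <- (a + 0.5) / (nt - a + 0.5) / ((b + 0.5) / (nb - b + 0.5))
    data.frame(motif = nm, width = nrow(pwm), hits_target = a,
               n_target = nt, hits_background = b, n_background = nb,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p), ]
}
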