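#' Trimmed mean of M-values normalization factors
#'
#' Robinson-Oshlack TMM: per sample, the weighted trimmed mean of log2
#' expression ratios (M-values) against a reference sample, with precision
#' weights from the delta method, double trimming on M (default 30%) and A
#' (default 5%), and factors rescaled to geometric mean 1. The reference
#' defaults to the sample whose upper-quartile expression is closest to the
#' mean upper quartile. Features with a zero count in either sample of a
#' pair are excluded.
#'
#' @param counts features x samples count matrix.
#' @param lib_sizes library sizes (default column sums).
#' @param ref_sample reference column index (default: upper-quartile rule).
#' @param trim_m,trim_a two-sided trim fractions for M and A values.
#' @return list of class `norm_factors` with `factors` (geometric mean 1),
#'   `lib_sizes` and `effective_lib_sizes`.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  if (ns < 2) stop("TMM needs at least 2 samples")
  if (any(lib_sizes == 0)) stop("sample with all-zero counts")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_len(ns), function(i) {
    if (i == ref_sample) return(1)
    tmm_pair(counts[, i], counts[, ref_sample],
             lib_sizes[i], lib_sizes[ref_sample], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, lib_sizes = lib_sizes,
                 effective_lib_sizes = lib_sizes * f,
                 ref_sample = ref_sample),
            class = "norm_factors")
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(M, ties.method = "first"); ra <- rank(A, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Per-feature negative-binomial dispersion with trend shrinkage
#'
#' Method-of-moments dispersion per feature on normalized counts (pooled
#' within-group variance, corrected for the Poisson component), shrunk in
#' log space toward a lowess mean-dispersion trend; floored at `1e-8`.
#'
#' @param counts features x samples count matrix.
#' @param norm a `norm_factors` object (or effective library sizes).
#' @param group two-level factor of group membership.
#' @param trend_weight weight of the trend in the log-space shrinkage
#'   (default 0.7).
#' @return numeric dispersion per feature.
#' @export
nb_dispersion <- function(counts, norm, group, trend_weight = 0.7) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (any(table(group) < 2)) stop("need >= 2 replicates per group")
  eff <- if (inherits(norm, "norm_factors")) norm$effective_lib_sizes
         else as.numeric(norm)
  sf <- eff / mean(eff)
  q <- sweep(counts, 2, sf, `/`)
  levs <- levels(group)
  n <- ncol(counts)
  df <- n - length(levs)
  ss <- 0; mu_w <- 0; mu2_w <- 0
  for (g in levs) {
    idx <- group == g
    m <- rowMeans(q[, idx, drop = FALSE])
    ss <- ss + rowSums((q[, idx, drop = FALSE] - m)^2)
    mu_w <- mu_w + (sum(idx) - 1) * m
    mu2_w <- mu2_w + (sum(idx) - 1) * m^2
  }
  v <- ss / df
  mu_w <- mu_w / df; mu2_w <- mu2_w / df
  pois_part <- mu_w * mean(1 / sf)
  raw <- (v - pois_part) / pmax(mu2_w, 1e-12)
  raw <- pmax(raw, 1e-8)
  mu_all <- rowMeans(q)
  ok <- mu_all > 0
  if (sum(ok) >= 20 && length(unique(mu_all[ok])) >= 5) {
    lx <- log(mu_all[ok]); ly <- log(pmax(raw[ok], 1e-4))
    fit <- stats::lowess(lx, ly, f = 0.5)
    trend <- exp(stats::approx(fit$x, fit$y, xout = log(pmax(mu_all, min(mu_all[ok]))),
                               rule = 2, ties = mean)$y)
    disp <- exp((1 - trend_weight) * log(raw) + trend_weight * log(trend))
  } else {
    disp <- exp((1 - trend_weight) * log(raw) +
                  trend_weight * log(stats::median(raw)))
  }
  pmax(disp, 1e-8)
}

#' Negative-binomial Wald test between two groups
#'
#' Per-feature NB GLM with a group indicator and log link, offsets from the
#' effective library sizes: group means are fitted by Newton iterations on
#' the NB score equation, the Wald statistic is `z = beta / SE(beta)` with
#' the standard errors from the Fisher information, and
#' `log2FC = beta / ln 2` contrasts `group2 vs group1` (the second factor
#' level versus the first). Two-sided p-values use a t reference with
#' `n - 2` degrees of freedom (a small-sample correction for the estimated
#' dispersion). All-zero features get `p = 1`, `log2FC = 0` by convention.
#'
#' @param counts features x samples integer count matrix.
#' @param norm a `norm_factors` object (or effective library sizes).
#' @param group two-level factor; the contrast is level 2 vs level 1.
#' @param dispersions per-feature dispersions (default estimated by
#'   [nb_dispersion()]).
#' @return a `diff_result` data.frame with `id`, `base_mean`, `log2fc`,
#'   `wald_p`, `padj` and `class` (all `ns` until [classify()] is applied).
#' @export
nb_wald_test <- function(counts, norm, group, dispersions = NULL) {
  counts <- as.matrix(counts)
  if (any(counts != floor(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("both groups need >= 2 samples")
  if (is.null(dispersions)) dispersions <- nb_dispersion(counts, norm, group)
  eff <- if (inherits(norm, "norm_factors")) norm$effective_lib_sizes
         else as.numeric(norm)
  sf <- eff / mean(eff)
  fit_group <- function(idx) {
    Y <- counts[, idx, drop = FALSE]
    s <- sf[idx]
    q <- (rowSums(Y) + 0.125) / sum(s)
    beta <- log(q)
    for (it in 1:12) {
      mu <- q %o% s
      w <- 1 + dispersions * mu
      U <- rowSums((Y - mu) / w)
      I <- rowSums(mu / w)
      step <- U / pmax(I, 1e-12)
      step <- pmin(pmax(step, -3), 3)
      beta <- beta + step
      q <- exp(beta)
    }
    mu <- q %o% s
    I <- rowSums(mu / (1 + dispersions * mu))
    list(beta = beta, info = I)
  }
  g1 <- fit_group(group == levels(group)[1])
  g2 <- fit_group(group == levels(group)[2])
  beta <- g2$beta - g1$beta
  se <- sqrt(1 / pmax(g1$info, 1e-12) + 1 / pmax(g2$info, 1e-12))
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df = ncol(counts) - 2)
  log2fc <- beta / log(2)
  allzero <- rowSums(counts) == 0
  p[allzero] <- 1; log2fc[allzero] <- 0
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("f%05d", seq_len(nrow(counts)))
  out <- data.frame(id = ids,
                    base_mean = rowMeans(sweep(counts, 2, sf, `/`)),
                    log2fc = log2fc, wald_p = p,
                    padj = bh_adjust(p), class = "ns",
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to `stats::p.adjust`); p-values outside
#' `[0, 1]` are an error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential results into gain / loss / ns
#'
#' Gain iff `padj < p_cut` (strict) and `log2fc` passes `lfc_cut`; loss is
#' the symmetric condition when `two_sided`. The fold-change comparison is
#' inclusive (`>=`) for the enhancer-style rule and strict (`>`) for the
#' treatment-response rule, matching the operators of the published
#' thresholds; choose with `lfc_strict`.
#'
#' @param diff a `diff_result` data.frame.
#' @param p_cut adjusted-p cutoff (strict `<`).
#' @param lfc_cut log2 fold-change cutoff.
#' @param two_sided also call losses (default TRUE).
#' @param lfc_strict use `>` instead of `>=` for the fold-change comparison.
#' @return the data.frame with `class` set to gain/loss/ns.
#' @export
classify <- function(diff, p_cut = 0.05, lfc_cut = 1, two_sided = TRUE,
                     lfc_strict = FALSE) {
  pass_lfc <- function(x) if (lfc_strict) x > lfc_cut else x >= lfc_cut
  cls <- rep("ns", nrow(diff))
  sig <- !is.na(diff$padj) & diff$padj < p_cut
  cls[sig & pass_lfc(diff$log2fc)] <- "gain"
  if (two_sided) cls[sig & pass_lfc(-diff$log2fc)] <- "loss"
  diff$class <- cls
  diff
}

#' Preset classification rules
#'
#' `"enhancer"`: padj < 0.05 and log2FC >= 1 (inclusive fold cut);
#' `"atra"`: padj < 0.05 and |log2FC| > 2 (strict);
#' `"h3k27me3"`: same thresholds as the enhancer rule, two-sided.
#'
#' @param diff a `diff_result`.
#' @param rule preset name.
#' @return classified data.frame.
#' @export
classify_preset <- function(diff, rule = c("enhancer", "atra", "h3k27me3")) {
  rule <- match.arg(rule)
  switch(rule,
         enhancer = classify(diff, 0.05, 1, two_sided = TRUE, lfc_strict = FALSE),
         atra = classify(diff, 0.05, 2, two_sided = TRUE, lfc_strict = TRUE),
         h3k27me3 = classify(diff, 0.05, 1, two_sided = TRUE, lfc_strict = FALSE))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (length_kb x library_millions)`.
#'
#' @param counts features x samples matrix (or vector).
#' @param lengths feature lengths in bp.
#' @param lib_sizes per-sample library sizes.
#' @return RPKM matrix of the same shape.
#' @export
rpkm <- function(counts, lengths, lib_sizes) {
  if (any(lengths <= 0)) stop("zero or negative feature length")
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  kb <- lengths / 1000
  mil <- lib_sizes / 1e6
  sweep(sweep(counts, 1, kb, `/`), 2, mil, `/`)
}
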