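#' Chromatin-state hidden Markov model
#'
#' A discrete-time HMM with independent Bernoulli emissions per histone mark
#' (the multivariate Bernoulli emission model of ChromHMM-style segmentation)
#' trained by Baum-Welch EM over one or more binarized sequences.
#'
#' @name chromhmm_model
NULL

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

log_emission <- function(X, emission) {
  # X: T x M in {0,1}; emission: K x M
  p <- clip01(emission)
  X %*% t(log(p)) + (1 - X) %*% t(log(1 - p))
}

as_seq_list <- function(data) {
  if (is.matrix(data)) data <- list(data)
  lapply(data, function(X) {
    if (is.data.frame(X)) X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (!all(X %in% c(0, 1))) stop("binarized input must be 0/1")
    X
  })
}

#' Train a Bernoulli-emission HMM by Baum-Welch EM
#'
#' Runs seeded random-restart EM and keeps the restart with the highest
#' log-likelihood. The log-likelihood is asserted non-decreasing across
#' iterations (up to numerical slack); convergence is declared when the
#' per-bin log-likelihood improvement drops below `tol`.
#'
#' @param data a bins x marks 0/1 matrix or a list of such matrices (each an
#'   independent sequence, e.g. one per chromosome and pooled cohort).
#' @param K number of hidden states.
#' @param seed integer seed for the restarts.
#' @param n_restarts number of random restarts (default 3).
#' @param tol per-bin log-likelihood convergence tolerance (default `1e-4`).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @return an object of class `chromhmm_model` with `emission` (K x M),
#'   `transition` (K x K), `initial`, `marks`, `loglik`, `n_iter`.
#' @export
baum_welch_train <- function(data, K, seed = 1, n_restarts = 3,
                             tol = 1e-4, max_iter = 200) {
  seqs <- as_seq_list(data)
  M <- ncol(seqs[[1]])
  marks <- colnames(seqs[[1]])
  total_T <- sum(vapply(seqs, nrow, 0L))
  if (K < 1) stop("K must be >= 1")
  if (K > total_T) stop("K exceeds the number of bins")
  if (any(vapply(seqs, nrow, 0L) < 2) && K > 1)
    stop("sequences must have length >= 2")

  ## restart initialization anchors states at jittered prototypes taken
  ## from the distinct observed mark combinations: the first restart uses
  ## the K most frequent combinations (so every coherent pattern, even a
  ## rare single-mark one, can seed its own state), later restarts sample
  ## combinations with frequency-damped weights; the best restart is kept
  ## by log-likelihood
  sub <- do.call(rbind, lapply(seqs, function(X)
    X[seq(1, nrow(X), by = max(1L, nrow(X) %/% 20000L)), , drop = FALSE]))
  key <- apply(sub, 1, paste, collapse = "")
  freq <- sort(table(key), decreasing = TRUE)
  pat <- do.call(rbind, lapply(strsplit(names(freq), ""), as.numeric))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    emission <- matrix(stats::runif(K * M, 0.1, 0.9), K, M)
    n_proto <- min(K, nrow(pat))
    ix <- if (r == 1) seq_len(n_proto)
          else sample.int(nrow(pat), n_proto, prob = sqrt(as.numeric(freq)))
    emission[seq_len(n_proto), ] <- 0.15 + 0.7 * pat[ix, , drop = FALSE]
    transition <- matrix(0.2 / max(K - 1, 1), K, K); diag(transition) <- 0.8
    if (K == 1) transition <- matrix(1, 1, 1)
    transition <- transition / rowSums(transition)
    initial <- rep(1 / K, K)

    ll_prev <- -Inf
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      ll <- 0
      Nk <- rep(0, K); Sx <- matrix(0, K, M)
      Xi <- matrix(0, K, K); pi0 <- rep(0, K)
      for (X in seqs) {
        fb <- hmm_forward_backward(log_emission(X, emission), transition, initial)
        ll <- ll + fb$loglik
        Nk <- Nk + colSums(fb$gamma)
        Sx <- Sx + t(fb$gamma) %*% X
        Xi <- Xi + fb$xisum
        pi0 <- pi0 + fb$gamma[1, ]
      }
      if (ll < ll_prev - 1e-8 * (abs(ll_prev) + 1))
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
      ll_trace <- c(ll_trace, ll)
      converged <- is.finite(ll_prev) && (ll - ll_prev) / total_T < tol
      ll_prev <- ll
      if (converged) break
      emission <- clip01(Sx / pmax(Nk, 1e-12))
      if (K > 1) {
        rs <- rowSums(Xi)
        transition <- Xi / ifelse(rs > 0, rs, 1)
        transition[rs == 0, ] <- 1 / K
      }
      initial <- pi0 / sum(pi0)
    }
    if (is.null(best) || ll_prev > best$loglik) {
      best <- list(K = K, emission = emission, transition = transition,
                   initial = initial, marks = marks, loglik = ll_prev,
                   n_iter = length(ll_trace), ll_trace = ll_trace,
                   restart = r)
    }
  }
  structure(best, class = "chromhmm_model")
}

#' @export
print.chromhmm_model <- function(x, ...) {
  cat("chromhmm_model:", x$K, "states,", length(x$marks), "marks, loglik",
      format(x$loglik), "\n")
  invisible(x)
}

#' Forward log-likelihood of a sequence under a model
#' @param model a `chromhmm_model`.
#' @param X a bins x marks 0/1 matrix.
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(model, X) {
  X <- as_seq_list(X)[[1]]
  hmm_forward_backward(log_emission(X, model$emission), model$transition,
                       model$initial)$loglik
}

#' Posterior-decode a binarized sequence
#'
#' Maximum-posterior (not Viterbi) state per bin, the MakeSegmentation-style
#' decoding rule.
#'
#' @param model a `chromhmm_model`.
#' @param data a 0/1 matrix or list of matrices with the model's marks.
#' @param return_posterior also return the bins x K posterior matrix.
#' @return integer state vector (1..K) per sequence (concatenated in input
#'   order), or a list with `state` and `posterior`.
#' @export
decode <- function(model, data, return_posterior = FALSE) {
  seqs <- as_seq_list(data)
  if (ncol(seqs[[1]]) != ncol(model$emission))
    stop("mark dimension mismatch between model and data")
  if (!is.null(model$marks) && !is.null(colnames(seqs[[1]])) &&
      !identical(colnames(seqs[[1]]), model$marks))
    stop("mark names of data do not match the model")
  states <- list(); posts <- list()
  for (i in seq_along(seqs)) {
    fb <- hmm_forward_backward(log_emission(seqs[[i]], model$emission),
                               model$transition, model$initial)
    states[[i]] <- max.col(fb$gamma, ties.method = "first")
    if (return_posterior) posts[[i]] <- fb$gamma
  }
  state <- unlist(states, use.names = FALSE)
  if (return_posterior) list(state = state, posterior = do.call(rbind, posts))
  else state
}

#' Simulate a sequence from a Bernoulli-emission HMM
#'
#' Used for parameter-recovery validation: draws a hidden path from the
#' Markov chain and Bernoulli mark calls from the emission matrix.
#'
#' @param model a `chromhmm_model` (or list with `emission`, `transition`,
#'   `initial`).
#' @param T sequence length in bins.
#' @param seed integer seed.
#' @return list with `X` (T x M 0/1 matrix) and `path` (true states).
#' @export
simulate_hmm <- function(model, T, seed = 1) {
  set.seed(seed)
  K <- nrow(model$emission); M <- ncol(model$emission)
  path <- integer(T)
  path[1] <- sample.int(K, 1, prob = model$initial)
  for (t in 2:T) path[t] <- sample.int(K, 1, prob = model$transition[path[t - 1], ])
  X <- matrix(stats::rbinom(T * M, 1, model$emission[path, ]), T, M)
  colnames(X) <- model$marks
  list(X = X, path = path)
}

#' Emission-vector correlation between two models
#'
#' Pearson correlation between all state pairs' emission vectors, with a
#' greedy best-match assignment without replacement; the summary score is
#' the mean matched correlation. Used for comparing models across state
#' numbers.
#'
#' @param model_a,model_b `chromhmm_model`s over the same mark set.
#' @return list with the full `correlation` matrix (Ka x Kb), the greedy
#'   `matching` (data.frame state_a, state_b, r) and `summary` (mean matched
#'   r).
#' @export
model_correlation <- function(model_a, model_b) {
  if (ncol(model_a$emission) != ncol(model_b$emission))
    stop("models have different mark sets")
  R <- stats::cor(t(model_a$emission), t(model_b$emission))
  ka <- nrow(R); kb <- ncol(R)
  avail_a <- rep(TRUE, ka); avail_b <- rep(TRUE, kb)
  match_rows <- list()
  for (i in seq_len(min(ka, kb))) {
    Rm <- R
    Rm[!avail_a, ] <- -Inf; Rm[, !avail_b] <- -Inf
    ij <- arrayInd(which.max(Rm), dim(Rm))
    match_rows[[i]] <- data.frame(state_a = ij[1], state_b = ij[2],
                                  r = R[ij[1], ij[2]])
    avail_a[ij[1]] <- FALSE; avail_b[ij[2]] <- FALSE
  }
  matching <- do.call(rbind, match_rows)
  list(correlation = R, matching = matching, summary = mean(matching$r))
}

#' Serialize / restore a model as JSON
#' @param model a `chromhmm_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(K = model$K, marks = model$marks,
                            emission = model$emission,
                            transition = model$transition,
                            initial = model$initial, loglik = model$loglik),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(K = x$K, emission = as.matrix(x$emission),
                 transition = as.matrix(x$transition), initial = x$initial,
                 marks = x$marks, loglik = x$loglik),
            class = "chromhmm_model")
}

## ---- segmentation ----------------------------------------------------------

#' Decode a genome-wide segmentation
#'
#' Decodes a bins x marks binarized matrix chromosome by chromosome
#' (chromosomes are independent sequences) into a `segmentation`: one state
#' per bin plus state labels.
#'
#' @param model a `chromhmm_model`.
#' @param binarized bins x marks 0/1 matrix on the layout's global bin order.
#' @param layout the `genome_layout`.
#' @param labels optional character labels per state (default `E1..EK`).
#' @return an object of class `segmentation`.
#' @export
decode_segmentation <- function(model, binarized, layout, labels = NULL) {
  if (nrow(binarized) != n_bins(layout))
    stop("binarized matrix does not match the layout's bins")
  seqs <- lapply(seq_along(layout$chrom), function(ci) {
    idx <- layout$offset[ci] + seq_len(layout$n_bins[ci])
    binarized[idx, , drop = FALSE]
  })
  state <- decode(model, seqs)
  if (is.null(labels)) labels <- paste0("E", seq_len(model$K))
  structure(list(layout = layout, state = state, K = model$K,
                 labels = labels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation:", x$K, "states over", length(x$state), "bins\n")
  print(table(factor(x$labels[x$state], levels = unique(x$labels))))
  invisible(x)
}

#' Segments of one state (or label) as an interval set
#'
#' Contiguous runs of bins in the given state are merged into segments.
#'
#' @param seg a `segmentation`.
#' @param state integer state index, or a character label (all states with
#'   that label are unioned).
#' @return an `interval_set` of segments.
#' @export
segments_of_state <- function(seg, state) {
  layout <- seg$layout
  if (is.character(state)) {
    ks <- which(seg$labels == state)
    if (!length(ks)) return(interval_set())
    mask <- seg$state %in% ks
  } else mask <- seg$state == state
  rows <- list()
  for (ci in seq_along(layout$chrom)) {
    idx <- layout$offset[ci] + seq_len(layout$n_bins[ci])
    r <- rle(mask[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = layout$chrom[ci],
        start = (starts[i] - 1) * layout$bin_size,
        end = min(ends[i] * layout$bin_size, layout$length[ci]))
    }
  }
  if (!length(rows)) return(interval_set())
  df <- do.call(rbind, rows)
  df$name <- sprintf("%s_%05d", if (is.character(state)) state else paste0("E", state),
                     seq_len(nrow(df)))
  interval_set(df)
}

#' Write a segmentation as a dense 4-column BED
#' @param seg a `segmentation`.
#' @param path output path.
#' @export
write_segmentation_bed <- function(seg, path) {
  rows <- list()
  layout <- seg$layout
  for (ci in seq_along(layout$chrom)) {
    idx <- layout$offset[ci] + seq_len(layout$n_bins[ci])
    r <- rle(seg$state[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    rows[[ci]] <- data.frame(
      chrom = layout$chrom[ci],
      start = (starts - 1) * layout$bin_size,
      end = pmin(ends * layout$bin_size, layout$length[ci]),
      name = seg$labels[r$values])
  }
  df <- do.call(rbind, rows)
  writeLines(paste(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE), df$name,
                   sep = "\t"), path)
  invisible(path)
}
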