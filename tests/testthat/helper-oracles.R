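# Independent brute-force oracles used across test files.

# bp-level Jaccard by enumerating covered positions (small coordinates only)
oracle_jaccard <- function(a, b) {
  pos <- function(set) {
    if (nrow(set) == 0L) return(character(0))
    unlist(lapply(seq_len(nrow(set)), function(i)
      paste0(set$chrom[i], ":", seq(set$start[i], set$end[i] - 1))))
  }
  pa <- unique(pos(a)); pb <- unique(pos(b))
  u <- union(pa, pb)
  if (!length(u)) return(0)
  length(intersect(pa, pb)) / length(u)
}

# all-pairs overlap check
oracle_overlap_fraction <- function(query, subject) {
  if (nrow(query) == 0L) return(NaN)
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] & subject$end > query$start[i])
  }, TRUE)
  mean(hit)
}

# Benjamini-Hochberg step-up written out explicitly
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# forward likelihood by summing over all K^T hidden paths
oracle_hmm_loglik <- function(X, emission, transition, initial) {
  K <- nrow(emission); T <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    pr <- initial[path[1]]
    for (t in seq_len(T)) {
      pr <- pr * prod(emission[path[t], ]^X[t, ] *
                        (1 - emission[path[t], ])^(1 - X[t, ]))
      if (t < T) pr <- pr * transition[path[t], path[t + 1]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# tangent cutoff by explicit loop over all candidate points of the scaled
# curve; ties resolved toward the larger rank (fewer super-enhancers)
oracle_tangent_index <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  if (max(s) == min(s)) return(n)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  best <- 1; bestd <- Inf
  for (i in seq_len(n)) {
    d <- y[i] - x[i]
    if (d <= bestd) { bestd <- d; best <- i }
  }
  best
}

# random interval set on a small coordinate space
random_interval_set <- function(n, max_pos = 300, chroms = c("c1", "c2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(20, n, replace = TRUE)
  interval_set(data.frame(chrom = sample(chroms, n, replace = TRUE),
                          start = start, end = start + len))
}

# small deterministic gene table
toy_genes <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             gene_name = c("g1", "g2", "g3"),
             chrom = c("c1", "c1", "c2"), strand = c("+", "-", "+"),
             start = c(1000, 5000, 2000), end = c(2000, 6000, 3000),
             tss = c(1000, 5999, 2000), length = c(1000, 1000, 1000),
             stringsAsFactors = FALSE)
}
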