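# Independent brute-force oracles. These deliberately re-derive results
# from first principles (quadratic scans, literal loops) and never call the
# package's fast paths.

# longest substring of `s` that is a window of the infinite repetition of
# `unit` at any phase; quadratic over all (start, length) pairs
bf_longest_tract <- function(s, unit) {
  s <- toupper(chartr("U", "T", s))
  unit <- toupper(chartr("U", "T", unit))
  n <- nchar(s)
  windows <- unique(unlist(lapply(0:2, function(p)
    vapply(3:max(3, n), function(l) periodic_sequence(unit, l, p), ""))))
  best_len <- 0L
  best_start <- NA_integer_
  for (st in seq_len(n)) {
    for (l in 3:(n - st + 1)) {
      if (n - st + 1 < 3) break
      sub <- substr(s, st, st + l - 1L)
      if (sub %in% windows && (l > best_len)) {
        best_len <- l
        best_start <- st - 1L
      }
    }
  }
  if (best_len == 0L) NULL else list(len = best_len, start = best_start)
}

# literal evaluation of the weighted KS running sum
bf_enrichment_score <- function(scores, hit, p = 1) {
  n <- length(scores)
  m <- sum(hit)
  nr <- sum(abs(scores[hit])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) cur <- cur + abs(scores[i])^p / nr
    else cur <- cur - 1 / (n - m)
    running[i] <- cur
  }
  es_pos <- max(running)
  es_neg <- min(running)
  # same documented tie rule as the package: positive extreme wins ties
  if (abs(es_pos) >= abs(es_neg) - 1e-12) es_pos else es_neg
}

# substring search by explicit position-wise comparison (no regex)
bf_contains <- function(s, kmer) {
  n <- nchar(s)
  k <- nchar(kmer)
  if (k > n) return(FALSE)
  for (st in seq_len(n - k + 1L))
    if (substr(s, st, st + k - 1L) == kmer) return(TRUE)
  FALSE
}

bf_assign_group <- function(s, defs) {
  s <- toupper(chartr("U", "T", s))
  in1 <- any(vapply(defs$group1, function(k) bf_contains(s, k), TRUE))
  in2 <- any(vapply(defs$group2, function(k) bf_contains(s, k), TRUE))
  if (in1) "group1" else if (in2) "group2" else "group3"
}

random_seq <- function(n, len, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    if (n_prob > 0) ch[runif(len) < n_prob] <- "N"
    paste(ch, collapse = "")
  }, "")
}
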