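# Independent oracles. These re-derive expected values by brute force or
# first principles and must stay independent of the implementation paths
# they check.

# Exhaustive Otsu: scan all 255 split points of the same 256-bin histogram
# definition (bins over the observed range) with explicit per-class sums.
brute_otsu <- function(x) {
  x <- as.vector(x)
  rng <- range(x)
  nbins <- 256L
  width <- diff(rng) / nbins
  bin <- pmin(floor((x - rng[1]) / width), nbins - 1L) + 1L
  counts <- tabulate(bin, nbins)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  best_k <- NA_integer_
  best_v <- -Inf
  n <- sum(counts)
  for (k in 1:(nbins - 1L)) {
    n0 <- sum(counts[1:k])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * centers[(k + 1):nbins]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {   # strict improvement: ties keep lower k
      best_v <- v
      best_k <- k
    }
  }
  centers[best_k]
}

# All motif occurrence offsets (1-based), by direct per-position character
# comparison.
oracle_matches <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (m == 0 || n < m) return(integer(0))
  sc <- strsplit(toupper(seq), "")[[1]]
  mc <- strsplit(toupper(motif), "")[[1]]
  hits <- integer(0)
  for (i in seq_len(n - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      s <- sc[i + j - 1]
      if (!(s %in% c("A", "C", "G", "T"))) { ok <- FALSE; break }
      if (mc[j] != "N" && mc[j] != s) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Maximum number of mutually non-overlapping occurrences: optimal interval
# selection by recursion over the sorted occurrence list (memoised from the
# back), independent of the greedy scan.
oracle_max_nonoverlap <- function(seq, motif) {
  off <- oracle_matches(seq, motif)
  m <- nchar(motif)
  k <- length(off)
  if (k == 0) return(0L)
  best <- integer(k + 1L)        # best[i] = optimum using occurrences i..k
  for (i in k:1) {
    nxt <- which(off >= off[i] + m)
    nxt <- nxt[nxt > i]
    take <- 1L + if (length(nxt) > 0) best[min(nxt)] else 0L
    best[i] <- max(best[i + 1L], take)
  }
  best[1L]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_motif <- function(max_len = 6L) {
  len <- sample(1:max_len, 1)
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
}

# small standard scenes used across test files
small_scene_config <- function(n_nuclei = 12L, field_shape = c(300L, 300L),
                               seed = 42L, ...) {
  scene_config(field_shape = field_shape, n_nuclei = n_nuclei,
               radius_range = c(10, 14), seed = seed, ...)
}

# multinomial 3-sigma check on category counts
within_3sigma <- function(counts, n, probs) {
  all(abs(counts - n * probs) <= 3 * sqrt(n * probs * (1 - probs)))
}
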