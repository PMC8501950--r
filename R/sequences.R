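#' Generate an i.i.d. random DNA sequence
#'
#' @param length sequence length (>= 0).
#' @param base_probs named probabilities for A, C, G, T; must sum to 1.
#' @param seed integer seed; deterministic given seed.
#' @return a single character string over A/C/G/T.
#' @export
random_sequence <- function(length,
                            base_probs = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            seed = 1L) {
  stop_if_not_number(length, "length", lower = 0)
  bases <- c("A", "C", "G", "T")
  if (is.null(names(base_probs)) || !setequal(names(base_probs), bases))
    stop("`base_probs` must be named with exactly A, C, G, T", call. = FALSE)
  p <- as.numeric(base_probs[bases])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("base probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (length == 0) return("")
  with_seed(seed,
            paste(sample(bases, length, replace = TRUE, prob = p),
                  collapse = ""))
}

#' Overwrite motif copies at given offsets in a sequence
#'
#' Later plants overwrite earlier ones; offsets are 0-based.
#'
#' @param sequence DNA string.
#' @param motif DNA string to write.
#' @param positions integer vector of 0-based offsets.
#' @return the edited sequence.
#' @export
plant_motifs <- function(sequence, motif, positions) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(motif), length(motif) == 1L)
  n <- nchar(sequence); m <- nchar(motif)
  positions <- as.integer(positions)
  if (length(positions) == 0) return(sequence)
  if (any(positions < 0) || any(positions + m > n))
    stop("plant position out of range", call. = FALSE)
  for (p in positions)
    substr(sequence, p + 1L, p + m) <- motif
  sequence
}
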