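# Internal helpers shared across modules.

# Character matrix (n x L) of fixed-length sequences, as integer codes.
.seq_mat <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  matrix(utf8ToInt(paste(seqs, collapse = "")), ncol = L, byrow = TRUE)
}

#' Pairwise Hamming distances between two sets of equal-length sequences
#'
#' @param query,reference Character vectors of equal-length DNA sequences.
#' @return Integer matrix of dimension `length(query) x length(reference)`.
#' @export
hamming_distances <- function(query, reference) {
  if (unique(nchar(query))[1] != unique(nchar(reference))[1])
    stop("query and reference sequence lengths differ", call. = FALSE)
  qm <- .seq_mat(query)
  out <- matrix(0L, nrow = length(query), ncol = length(reference))
  for (j in seq_along(reference)) {
    rv <- utf8ToInt(reference[j])
    out[, j] <- as.integer(rowSums(qm != matrix(rv, nrow(qm), length(rv), byrow = TRUE)))
  }
  dimnames(out) <- list(query, reference)
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# One-dimensional Otsu threshold over a numeric vector: the cut maximizing
# between-class variance on a fixed-width histogram.
.otsu_1d <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values for thresholding", call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  # cut after the argmax bin, so the threshold separates the two classes
  breaks[which.max(sigma_b) + 1L]
}

# Random DNA sequences of fixed length.
.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

.is_dna <- function(x) grepl("^[ACGT]+$", x)

# Coefficient of variation (population sd); 0 for degenerate input
# (single value or zero mean), so single-row grids report no stripes.
.cv <- function(x) {
  n <- length(x)
  if (n < 2L || mean(x) == 0) return(0)
  sqrt(sum((x - mean(x))^2) / n) / mean(x)
}
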