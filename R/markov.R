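# Markov sequence background: trained from a genome, used to generate null
# sequences for motif-score threshold calibration.

#' Train a Markov background model from a genome
#'
#' Conditional probabilities p(base | preceding k bases) are estimated from
#' observed (k+1)-mer counts with a pseudocount; windows containing N are
#' skipped.  The initial k-mer distribution is the observed k-mer frequency.
#'
#' @param g A [genome()] object or character vector of training sequences.
#' @param order Markov order k (default 2).
#' @param pseudocount Added to every (k+1)-mer and k-mer count.
#' @return Object of class `markov_background`: list with `order`, `cond`
#'   (4^k x 4 conditional probability matrix), `cond_cum` (row cumsums),
#'   `initial` (k-mer distribution), `base_freqs` (mononucleotide
#'   frequencies of the training sequence) and `train_bases`.
#' @export
train_background <- function(g, order = 2L, pseudocount = 1) {
  if (order < 0L) stop("order must be >= 0")
  seqs <- if (inherits(g, "genome")) g$seq else as.character(g)
  k <- as.integer(order)
  total_len <- sum(nchar(seqs))
  if (total_len <= 4^(k + 1L))
    stop("training sequence too short for order ", k)

  nctx <- 4L^k
  kmer_counts <- numeric(max(nctx, 1L))
  trans_counts <- matrix(0, nrow = max(nctx, 1L), ncol = 4L)
  base_counts <- numeric(4L)

  for (s in seqs) {
    x <- .seq_codes(s)
    ok <- x <= 4L
    base_counts <- base_counts + tabulate(x[ok], nbins = 4L)
    n <- length(x)
    if (n < k + 1L) next
    if (k == 0L) {
      trans_counts <- trans_counts + matrix(tabulate(x[ok], 4L), 1L, 4L,
                                            byrow = TRUE)
      kmer_counts <- kmer_counts + sum(ok)
      next
    }
    # sliding (k+1)-mer context/next-base indices, vectorized over shifts
    m <- n - k
    ctx <- integer(m)        # context of positions 1..m -> next base at i+k
    valid <- rep(TRUE, m)
    for (j in seq_len(k)) {
      xj <- x[j:(j + m - 1L)]
      valid <- valid & xj <= 4L
      ctx <- ctx * 4L + (pmin(xj, 4L) - 1L)
    }
    nb <- x[(k + 1L):n]
    v <- valid & nb <= 4L
    if (any(v))
      trans_counts <- trans_counts +
        matrix(tabulate((ctx[v]) * 4L + nb[v], nbins = nctx * 4L),
               nrow = nctx, ncol = 4L, byrow = TRUE)
    # k-mer counts for the initial distribution (all k-windows)
    mk <- n - k + 1L
    ctx2 <- integer(mk); valid2 <- rep(TRUE, mk)
    for (j in seq_len(k)) {
      xj <- x[j:(j + mk - 1L)]
      valid2 <- valid2 & xj <= 4L
      ctx2 <- ctx2 * 4L + (pmin(xj, 4L) - 1L)
    }
    kmer_counts <- kmer_counts + tabulate(ctx2[valid2] + 1L, nbins = nctx)
  }

  trans_counts <- trans_counts + pseudocount
  cond <- trans_counts / rowSums(trans_counts)
  kmer_counts <- kmer_counts + pseudocount
  initial <- kmer_counts / sum(kmer_counts)
  base_freqs <- (base_counts + pseudocount) / sum(base_counts + 4 * pseudocount)
  names(base_freqs) <- c("A", "C", "G", "T")
  structure(
    list(order = k, cond = cond, cond_cum = t(apply(cond, 1L, cumsum)),
         initial = initial, base_freqs = base_freqs,
         train_bases = sum(base_counts)),
    class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("markov_background: order", x$order, "trained on",
      format(x$train_bases, big.mark = ","), "bases\n")
  invisible(x)
}

#' Log2-likelihood of sequences under a Markov background
#'
#' Initial k-mer term plus conditional terms; sequences containing N score
#' `-Inf`.
#'
#' @param bg A [train_background()] model.
#' @param seqs Character vector.
#' @return Numeric vector of log2 likelihoods.
#' @export
sequence_loglik <- function(bg, seqs) {
  k <- bg$order
  vapply(seqs, function(s) {
    x <- .seq_codes(s)
    if (any(x > 4L)) return(-Inf)
    n <- length(x)
    if (n <= k) {
      # marginalize the initial k-mer distribution over the first n bases
      idx <- .kmer_prefix_indices(x, k)
      return(log2(sum(bg$initial[idx])))
    }
    ctx0 <- sum((x[seq_len(k)] - 1L) * 4L^((k - 1L):0)) + 1L
    ll <- if (k > 0L) log2(bg$initial[ctx0]) else 0
    ctx <- ctx0 - 1L
    for (i in (k + 1L):n) {
      row <- if (k > 0L) ctx + 1L else 1L
      ll <- ll + log2(bg$cond[row, x[i]])
      if (k > 0L) ctx <- (ctx %% 4L^(k - 1L)) * 4L + (x[i] - 1L)
    }
    ll
  }, numeric(1L), USE.NAMES = FALSE)
}

# indices of all k-mers whose first length(x) bases equal x
.kmer_prefix_indices <- function(x, k) {
  n <- length(x)
  base <- sum((x - 1L) * 4L^((k - 1L):(k - n)))
  base + seq_len(4L^(k - n)) # 1-based block of k-mers sharing the prefix
}

#' Sample i.i.d. sequences from a Markov background
#'
#' @param bg A [train_background()] model.
#' @param n Number of sequences.
#' @param length Sequence length (default 100).
#' @param seed Optional RNG seed.
#' @return Character vector of `n` sequences.
#' @export
sample_sequences <- function(bg, n, length = 100L, seed = NULL) {
  stopifnot(n >= 1L, length >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- bg$order
  L <- as.integer(length)
  codes <- matrix(0L, nrow = n, ncol = L)

  if (k > 0L) {
    km <- sample.int(4L^k, n, replace = TRUE, prob = bg$initial) - 1L
    kmer_codes <- matrix(0L, nrow = n, ncol = k)
    for (j in k:1L) {           # decode base-4 digits, first base = high digit
      kmer_codes[, j] <- km %% 4L + 1L
      km <- km %/% 4L
    }
    if (L <= k)                 # short sequences: initial-distribution marginal
      return(.codes_to_strings(kmer_codes[, seq_len(L), drop = FALSE]))
    codes[, seq_len(k)] <- kmer_codes
    ctx <- integer(n)
    for (j in seq_len(k)) ctx <- ctx * 4L + (codes[, j] - 1L)
    nr <- nrow(bg$cond_cum)
    for (t in (k + 1L):L) {
      u <- stats::runif(n)
      r <- ctx + 1L
      b <- 1L + (u > bg$cond_cum[r]) + (u > bg$cond_cum[r + nr]) +
        (u > bg$cond_cum[r + 2L * nr])
      codes[, t] <- b
      ctx <- (ctx %% 4L^(k - 1L)) * 4L + (b - 1L)
    }
  } else {
    p <- bg$cond[1L, ]
    codes[] <- sample.int(4L, n * L, replace = TRUE, prob = p)
  }
  .codes_to_strings(codes)
}

.codes_to_strings <- function(codes) {
  bases <- charToRaw("ACGTN")
  n <- nrow(codes)
  vapply(seq_len(n), function(i) rawToChar(bases[codes[i, ]]), character(1L))
}
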