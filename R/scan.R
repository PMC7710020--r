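# PWM log-likelihood scanning and empirical-FDR threshold calibration.

#' Build a scored motif (log-odds matrix vs background)
#'
#' Window scores are `sum_i log2(p_motif(b_i) / p_bg(b_i))` with mononucleotide
#' background frequencies.  A pseudocount is added to every PWM cell (rows
#' renormalized) before the log transform; windows containing N score `-Inf`.
#'
#' @param mm A [motif_model()].
#' @param background A [train_background()] model (its `base_freqs` are used)
#'   or a numeric vector of 4 base frequencies (A, C, G, T).
#' @param pseudocount Per-cell PWM pseudocount (default 0.01).
#' @return Object of class `scored_motif`: list with `motif`, `lodds`
#'   (width x 5, column 5 is N = -Inf), `lodds_rc` (reverse-complement
#'   matrix), `bg_freqs`, `threshold` (NA until calibrated), `calibration`.
#' @export
score_motif <- function(mm, background, pseudocount = 0.01) {
  stopifnot(inherits(mm, "motif_model"))
  bg <- if (inherits(background, "markov_background")) background$base_freqs
        else as.numeric(background)
  if (length(bg) != 4L || any(bg <= 0)) stop("background must be 4 positive frequencies")
  bg <- bg / sum(bg)
  p <- mm$prob + pseudocount
  p <- p / rowSums(p)
  lodds <- log2(sweep(p, 2L, bg, "/"))
  lodds <- cbind(lodds, N = -Inf)
  w <- mm$width
  # reverse-complement matrix: position j on - strand reads complement of w+1-j
  comp <- c(4L, 3L, 2L, 1L, 5L)
  lodds_rc <- lodds[w:1L, comp, drop = FALSE]
  colnames(lodds_rc) <- colnames(lodds)
  structure(
    list(motif = mm, lodds = lodds, lodds_rc = lodds_rc, bg_freqs = bg,
         threshold = NA_real_, calibration = NULL),
    class = "scored_motif")
}

#' @export
print.scored_motif <- function(x, ...) {
  cat("scored_motif", x$motif$name, "width", x$motif$width,
      if (is.finite(x$threshold)) paste("threshold", round(x$threshold, 3))
      else "(uncalibrated)", "\n")
  invisible(x)
}

# score all windows of a code vector with a w x 5 log-odds matrix
.scan_codes_vec <- function(codes, lodds) {
  w <- nrow(lodds)
  nw <- length(codes) - w + 1L
  if (nw < 1L) return(numeric(0L))
  sc <- numeric(nw)
  for (k in seq_len(w)) {
    contrib <- lodds[k, codes[k:(k + nw - 1L)]]
    sc <- sc + contrib
  }
  sc[is.nan(sc)] <- -Inf
  sc
}

# score all windows of an n x L code matrix; returns n x (L-w+1) matrix
.scan_codes_matrix <- function(codes, lodds) {
  w <- nrow(lodds)
  L <- ncol(codes)
  nw <- L - w + 1L
  if (nw < 1L) return(matrix(numeric(0), nrow = nrow(codes), ncol = 0L))
  out <- matrix(0, nrow = nrow(codes), ncol = nw)
  for (j in seq_len(nw)) {
    sc <- lodds[1L, codes[, j]]
    for (k in 2:w) sc <- sc + lodds[k, codes[, j + k - 1L]]
    out[, j] <- sc
  }
  out[is.nan(out)] <- -Inf
  out
}

#' Scan a sequence with a scored motif
#'
#' Scores every window on the forward strand and (optionally) the reverse
#' strand; reverse-strand windows are scored with the reverse-complement
#' matrix at the same window start, so a - hit at `start` denotes the motif on
#' the reverse complement of `[start, start + w)`.
#'
#' @param sequence A character scalar.
#' @param sm A [score_motif()] object.
#' @param both_strands Scan both strands (default TRUE).
#' @return data.table with columns `start` (0-based window start), `strand`,
#'   `score`, one row per scanned window; empty if the sequence is shorter
#'   than the motif.
#' @export
scan_pwm <- function(sequence, sm, both_strands = TRUE) {
  stopifnot(inherits(sm, "scored_motif"), length(sequence) == 1L)
  codes <- .seq_codes(sequence)
  fwd <- .scan_codes_vec(codes, sm$lodds)
  if (length(fwd) == 0L)
    return(data.table::data.table(start = integer(), strand = character(),
                                  score = numeric()))
  out <- data.table::data.table(start = seq_along(fwd) - 1L, strand = "+",
                                score = fwd)
  if (both_strands) {
    rev <- .scan_codes_vec(codes, sm$lodds_rc)
    out <- rbind(out, data.table::data.table(start = seq_along(rev) - 1L,
                                             strand = "-", score = rev))
  }
  out
}

#' Best score per sequence
#'
#' Maximum window score over both strands for each sequence (sequences may
#' have differing lengths; equal-length groups are scored in one vectorized
#' pass).
#'
#' @param seqs Character vector.
#' @param sm A [score_motif()] object.
#' @param both_strands Scan both strands.
#' @return Numeric vector of per-sequence maxima (`-Inf` when no window fits).
#' @export
scan_max_scores <- function(seqs, sm, both_strands = TRUE) {
  out <- rep(-Inf, length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L < sm$motif$width) next
    codes <- .seq_code_matrix(seqs[idx])
    m <- .scan_codes_matrix(codes, sm$lodds)
    best <- do.call(pmax, c(as.data.frame(m), list(-Inf)))
    if (both_strands) {
      m2 <- .scan_codes_matrix(codes, sm$lodds_rc)
      best <- pmax(best, do.call(pmax, c(as.data.frame(m2), list(-Inf))))
    }
    out[idx] <- best
  }
  out
}

#' Calibrate an empirical-FDR score threshold
#'
#' Using per-sequence maximum scores, the `ratio` method returns the smallest
#' threshold s such that `null hit-rate(s) / query hit-rate(s) <= fdr_target`,
#' evaluated over the observed score values.  Candidate thresholds must be
#' supported by at least `min_support` query sequences (guards the rate-ratio
#' estimate against its own sampling noise in the extreme tail).  The
#' `null_quantile` method ignores the query set and returns the
#' `(1 - fdr_target)` quantile of the null maxima.
#'
#' @param sm A [score_motif()] object.
#' @param query_seqs Sequences representing the positive set.
#' @param null_seqs Background sequences (e.g. from [sample_sequences()]).
#' @param fdr_target Target false discovery rate (default 0.1).
#' @param method "ratio" (default) or "null_quantile".
#' @param min_support Minimum query sequences at/above a candidate threshold.
#' @return The `scored_motif` with `threshold` and `calibration` filled in;
#'   when no threshold achieves the target, `threshold` is NA and
#'   `calibration$status` is `"no_discriminative_threshold"`.
#' @export
calibrate_threshold <- function(sm, query_seqs, null_seqs, fdr_target = 0.1,
                                method = c("ratio", "null_quantile"),
                                min_support = 10L) {
  method <- match.arg(method)
  if (length(query_seqs) == 0L) stop("query_seqs is empty")
  if (length(null_seqs) == 0L) stop("null_seqs is empty")
  qs <- scan_max_scores(query_seqs, sm)
  ns <- scan_max_scores(null_seqs, sm)
  nq <- length(qs); nn <- length(ns)
  qs_sorted <- sort(qs); ns_sorted <- sort(ns)

  status <- "ok"; thr <- NA_real_
  if (method == "null_quantile") {
    thr <- as.numeric(stats::quantile(ns, 1 - fdr_target, type = 7))
  } else {
    cand <- sort(unique(qs[is.finite(qs)]))
    if (length(cand) > 0L) {
      q_ge <- nq - findInterval(cand - 1e-12, qs_sorted)
      n_ge <- nn - findInterval(cand - 1e-12, ns_sorted)
      ratio <- (n_ge / nn) / (q_ge / nq)
      ok <- ratio <= fdr_target & q_ge >= min_support
      if (any(ok)) thr <- cand[which(ok)[1L]]
    }
    if (is.na(thr)) status <- "no_discriminative_threshold"
  }

  realized <- if (is.finite(thr)) {
    c(null_rate = mean(ns >= thr), query_rate = mean(qs >= thr))
  } else c(null_rate = NA_real_, query_rate = NA_real_)
  sm$threshold <- thr
  sm$calibration <- list(
    method = method, fdr_target = fdr_target, n_null = nn, n_query = nq,
    status = status, null_rate = unname(realized["null_rate"]),
    query_rate = unname(realized["query_rate"]),
    realized_ratio = unname(realized["null_rate"] / realized["query_rate"]))
  sm
}

#' Flag peaks containing motif hits near their summit
#'
#' A peak is flagged when any window whose start offset from the summit lies
#' in `[-within, +within]` scores at or above the calibrated threshold.
#' Windows running off the chromosome end are clipped away.
#'
#' @param peaks data.frame/data.table with columns `chrom` and `summit`.
#' @param g A [genome()].
#' @param sm A calibrated [score_motif()] object.
#' @param within Maximum |offset| of the motif start from the summit (bp).
#' @return List with `flagged` (logical per peak) and `hits` (data.table:
#'   `peak` index, `offset`, `strand`, `score`).
#' @export
peaks_with_hits <- function(peaks, g, sm, within = 50L) {
  if (!is.finite(sm$threshold))
    stop("scored motif has no calibrated threshold")
  peaks <- data.table::as.data.table(peaks)
  w <- sm$motif$width
  n <- nrow(peaks)
  flagged <- logical(n)
  hits <- vector("list", n + 1L)
  # extract clipped scan regions, then score equal-length groups vectorized
  s0 <- peaks$summit - within
  e0 <- peaks$summit + within + w              # half-open end
  seqs <- character(n); starts <- integer(n)
  for (i in seq_len(n)) {
    cl <- .genome_seq_clipped(g, peaks$chrom[i], s0[i], e0[i])
    seqs[i] <- cl$seq; starts[i] <- cl$start
  }
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    if (L < w) next
    idx <- which(lens == L)
    codes <- .seq_code_matrix(seqs[idx])
    for (str in c("+", "-")) {
      m <- .scan_codes_matrix(codes, if (str == "+") sm$lodds else sm$lodds_rc)
      hit_ij <- which(m >= sm$threshold, arr.ind = TRUE)
      if (nrow(hit_ij) == 0L) next
      pk <- idx[hit_ij[, 1L]]
      off <- starts[pk] + (hit_ij[, 2L] - 1L) - peaks$summit[pk]
      keep <- abs(off) <= within
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.table::data.table(
        peak = pk[keep], offset = off[keep], strand = str,
        score = m[hit_ij[keep, , drop = FALSE]])
      flagged[pk[keep]] <- TRUE
    }
  }
  hits <- data.table::rbindlist(hits)
  if (nrow(hits) > 0L) data.table::setorder(hits, peak, offset, strand)
  if (nrow(hits) == 0L)
    hits <- data.table::data.table(peak = integer(), offset = integer(),
                                   strand = character(), score = numeric())
  list(flagged = flagged, hits = hits)
}

#' Motif over-representation versus random genomic sequence
#'
#' Compares the query hit rate with the hit rate of windows sampled uniformly
#' from the genome; significance from Fisher's exact test on the 2x2 table.
#'
#' @param query_flags Logical vector: per-peak motif presence (from
#'   [peaks_with_hits()]).
#' @param g A [genome()].
#' @param sm A calibrated [score_motif()] object.
#' @param n_background Number of random genomic windows (default 10000).
#' @param length Window length (default 100).
#' @param seed Optional RNG seed.
#' @param background_seqs Optional pre-sampled genomic windows (e.g. from
#'   [sample_genome_windows()]), reused across calls for the same motif set.
#' @return List: `rate_query`, `rate_background`, `ratio` (Inf when the
#'   background rate is zero), `p`.
#' @export
overrepresentation <- function(query_flags, g, sm, n_background = 10000L,
                               length = 100L, seed = NULL,
                               background_seqs = NULL) {
  if (!is.finite(sm$threshold))
    stop("scored motif has no calibrated threshold")
  seqs <- if (!is.null(background_seqs)) background_seqs
          else sample_genome_windows(g, n_background, length, seed)
  n_background <- base::length(seqs)
  bs <- scan_max_scores(seqs, sm)
  bg_hits <- sum(bs >= sm$threshold)
  q_hits <- sum(query_flags); nq <- length(query_flags)
  tab <- matrix(c(q_hits, nq - q_hits, bg_hits, n_background - bg_hits), 2L)
  p <- stats::fisher.test(tab)$p.value
  rq <- q_hits / nq; rb <- bg_hits / n_background
  list(rate_query = rq, rate_background = rb,
       ratio = if (rb > 0) rq / rb else Inf, p = p)
}

#' Sample windows uniformly from a genome
#'
#' @param g A [genome()].
#' @param n Number of windows.
#' @param length Window length in bp.
#' @param seed Optional RNG seed.
#' @return Character vector of `n` sequences.
#' @export
sample_genome_windows <- function(g, n, length = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(g$lengths < length)) stop("genome chromosome shorter than window")
  cn <- sample(g$chroms, n, replace = TRUE, prob = as.numeric(g$lengths))
  st <- floor(stats::runif(n) * (g$lengths[cn] - length))
  vapply(seq_len(n), function(i)
    genome_seq(g, cn[i], st[i], st[i] + length), character(1L))
}

#' Histogram of motif hit offsets around peak summits
#'
#' @param hits data.table of hits with an `offset` column (e.g. from
#'   [peaks_with_hits()]).
#' @param half_window Half-width of the tallied range (default 250).
#' @param bin Bin width in bp (default 10).
#' @return data.table with `bin_start`, `bin_end`, `count`; hits outside
#'   `[-half_window, half_window)` are dropped.
#' @export
hit_position_histogram <- function(hits, half_window = 250L, bin = 10L) {
  breaks <- seq(-half_window, half_window, by = bin)
  off <- hits$offset[hits$offset >= -half_window & hits$offset < half_window]
  idx <- findInterval(off, breaks)
  data.table::data.table(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1L],
    count = tabulate(idx, nbins = length(breaks) - 1L))
}
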