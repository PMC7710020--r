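# Position-probability motif models.

#' Construct a motif model
#'
#' Either supply a width x 4 probability matrix (columns A, C, G, T; rows sum
#' to 1) or a consensus string plus a per-position consensus probability
#' (`fidelity`), from which a matrix is built with the remaining mass spread
#' evenly over the three off-consensus bases.
#'
#' @param name Motif name.
#' @param prob Optional width x 4 probability matrix.
#' @param consensus Optional consensus string over A/C/G/T.
#' @param fidelity Consensus-base probability when building from a consensus
#'   (default 0.995, i.e. planted instances are near-exact consensus matches).
#' @return Object of class `motif_model`: list(name, prob, consensus, width).
#' @export
motif_model <- function(name, prob = NULL, consensus = NULL, fidelity = 0.995) {
  if (is.null(prob)) {
    if (is.null(consensus)) stop("supply prob or consensus")
    consensus <- toupper(consensus)
    b <- .seq_codes(consensus)
    if (any(b > 4L)) stop("consensus must be over A/C/G/T")
    w <- length(b)
    prob <- matrix((1 - fidelity) / 3, nrow = w, ncol = 4L)
    prob[cbind(seq_len(w), b)] <- fidelity
  }
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L) stop("prob must have 4 columns (A,C,G,T)")
  if (nrow(prob) < 4L) stop("motif width must be >= 4")
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop("each probability row must sum to 1")
  colnames(prob) <- c("A", "C", "G", "T")
  cons <- paste(c("A", "C", "G", "T")[max.col(prob, ties.method = "first")],
                collapse = "")
  structure(list(name = name, prob = prob, consensus = cons,
                 width = nrow(prob)), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model", x$name, ": width", x$width, "consensus", x$consensus, "\n")
  invisible(x)
}

#' Default motif models
#'
#' Homeodomain-style motif set used by the synthetic landscape: an anterior
#' 6-mer with a TAAT core, a central TAAT-core variant, a pan 6-mer bound by
#' all factors, a posterior 7-mer with a TTTAT core, and a TTTAC-core 7-mer.
#'
#' @param fidelity Per-position consensus probability for all models.
#' @return Named list of [motif_model()] objects.
#' @export
default_motif_models <- function(fidelity = 0.995) {
  list(
    anterior  = motif_model("anterior",  consensus = "TTAATT",  fidelity = fidelity),
    central   = motif_model("central",   consensus = "CTAATT",  fidelity = fidelity),
    pan       = motif_model("pan",       consensus = "TAATTA",  fidelity = fidelity),
    posterior = motif_model("posterior", consensus = "TTTATGG", fidelity = fidelity),
    hox13     = motif_model("hox13",     consensus = "TTTACGA", fidelity = fidelity))
}

#' Sample sequence instances from a motif model
#'
#' @param mm A [motif_model()].
#' @param n Number of instances.
#' @return Character vector of length `n`.
#' @export
sample_motif_instances <- function(mm, n) {
  stopifnot(inherits(mm, "motif_model"), n >= 0)
  if (n == 0L) return(character())
  codes <- vapply(seq_len(mm$width), function(j)
    sample.int(4L, n, replace = TRUE, prob = mm$prob[j, ]), integer(n))
  codes <- matrix(codes, nrow = n)
  bases <- charToRaw("ACGT")
  vapply(seq_len(n), function(i) rawToChar(bases[codes[i, ]]), character(1L))
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of [motif_model()] objects.
#' @param path Output path.
#' @param bg Background letter frequencies (length 4, A C G T).
#' @export
write_meme <- function(motifs, path, bg = rep(0.25, 4)) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (mm in motifs) {
    writeLines(sprintf("MOTIF %s", mm$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", mm$width),
      con)
    writeLines(apply(mm$prob, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path Input path.
#' @return Named list of [motif_model()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability", lines[j]))
        j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      prob <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
      prob <- prob / rowSums(prob)  # absorb printed rounding
      out[[name]] <- motif_model(name, prob = prob)
      i <- j + w
    }
    i <- i + 1L
  }
  out
}
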