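# Genome container: named set of chromosome sequences over {A,C,G,T,N}.
# All coordinates in the package are 0-based, half-open [start, end).

#' Construct a genome object
#'
#' A genome is an ordered set of named chromosome sequences restricted to the
#' alphabet A, C, G, T, N.  Sequences are case-folded to upper case; any other
#' IUPAC ambiguity code is collapsed to N.
#'
#' @param sequences Named character vector, one element per chromosome.
#' @return An object of class `genome` with fields `chroms` (ordered names),
#'   `seq` (named character vector) and `lengths` (named integer vector).
#' @export
genome <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("sequences must be a non-empty named character vector")
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    stop("every sequence must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1L])
  sequences <- toupper(sequences)
  # fold non-ACGT IUPAC ambiguity codes to N
  sequences <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", sequences)
  for (i in seq_along(sequences)) {
    if (!nzchar(sequences[[i]]))
      stop("empty record: ", nm[i])
    if (grepl("[^ACGTN]", sequences[[i]]))
      stop("non-IUPAC character in record: ", nm[i])
  }
  structure(
    list(chroms = nm, seq = sequences,
         lengths = stats::setNames(nchar(sequences), nm)),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$chroms), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are case-folded to upper case on load and restricted to the
#' A/C/G/T/N alphabet (other IUPAC ambiguity codes become N).  Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [genome()] object.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  handle <- function(c) {
    bad <- .find_bad_fasta_record(path)
    stop("FASTA format error, non-IUPAC character in record: ", bad,
         " (", conditionMessage(c), ")", call. = FALSE)
  }
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path), error = handle),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w))) handle(w)
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  w <- Biostrings::width(set)
  if (any(w == 0L)) stop("empty record: ", nm[which(w == 0L)[1L]])
  if (anyDuplicated(nm)) stop("duplicate record name: ", nm[duplicated(nm)][1L])
  genome(stats::setNames(as.character(set), nm))
}

# identify the record containing a non-IUPAC character, for error reporting
.find_bad_fasta_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- "<unknown>"
  for (ln in lines) {
    if (startsWith(ln, ">")) rec <- sub("\\s.*$", "", substring(ln, 2L))
    else if (grepl("[^ACGTNRYSWKMBDHVUacgtnryswkmbdhvu]", ln)) return(rec)
  }
  rec
}

#' Write a genome to FASTA
#'
#' @param g A [genome()] object.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$seq)
  names(set) <- g$chroms
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract genome sequence on a 0-based half-open interval
#'
#' @param g A [genome()] object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return Character scalar of length `end - start`.
#' @export
genome_seq <- function(g, chrom, start, end) {
  stopifnot(inherits(g, "genome"))
  len <- unname(g$lengths[chrom])
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > len || start >= end)
    stop("invalid interval [", start, ",", end, ") on ", chrom,
         " of length ", len)
  substr(g$seq[[chrom]], start + 1L, end)
}

# clipped variant: returns list(seq, start) with start possibly moved right
.genome_seq_clipped <- function(g, chrom, start, end) {
  len <- g$lengths[[chrom]]
  s <- max(0L, as.integer(start)); e <- min(len, as.integer(end))
  if (s >= e) return(list(seq = "", start = s))
  list(seq = substr(g$seq[[chrom]], s + 1L, e), start = s)
}

#' Validate a set of genomic intervals against a genome
#'
#' Intervals are 0-based half-open with `0 <= start < end <= chrom length`.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param g A [genome()] object.
#' @return Invisibly `TRUE`; stops on the first violation.
#' @export
validate_intervals <- function(intervals, g) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!all(intervals$chrom %in% g$chroms))
    stop("interval on unknown chromosome: ",
         setdiff(unique(intervals$chrom), g$chroms)[1L])
  len <- g$lengths[intervals$chrom]
  bad <- intervals$start < 0 | intervals$end > len |
    intervals$start >= intervals$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("invalid interval ", intervals$chrom[i], ":[", intervals$start[i],
         ",", intervals$end[i], ")")
  }
  invisible(TRUE)
}

# reverse-complement plain character strings (vectorized)
.revcomp <- function(x) {
  vapply(x, function(s) {
    r <- rev(charToRaw(chartr("ACGTN", "TGCAN", s)))
    rawToChar(r)
  }, character(1L), USE.NAMES = FALSE)
}

# map sequence string(s) to integer codes A=1,C=2,G=3,T=4,N=5
.code_lookup <- local({
  tbl <- rep.int(5L, 256L)
  tbl[as.integer(charToRaw("A")) + 1L] <- 1L
  tbl[as.integer(charToRaw("C")) + 1L] <- 2L
  tbl[as.integer(charToRaw("G")) + 1L] <- 3L
  tbl[as.integer(charToRaw("T")) + 1L] <- 4L
  tbl
})

.seq_codes <- function(s) .code_lookup[as.integer(charToRaw(s)) + 1L]

# equal-length sequences -> n x L integer matrix of codes
.seq_code_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == L))
  m <- matrix(.code_lookup[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L],
              nrow = n, ncol = L, byrow = TRUE)
  m
}
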