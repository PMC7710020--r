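# Tag libraries: an experiment's aligned reads reduced to stranded 5' positions.

#' Construct a tag library
#'
#' A tag library holds one sequencing experiment (or replicate) reduced to the
#' 5' positions of its reads.  Positions are 0-based.
#'
#' @param tags data.table/data.frame with columns `chrom` (character),
#'   `pos` (integer, 0-based 5' coordinate) and `strand` ("+" or "-").
#' @param experiment_id,condition,replicate_id Metadata strings.
#' @param genome Optional [genome()]; when given, tag positions are validated
#'   against chromosome bounds.
#' @return Object of class `tag_library` with fields `experiment_id`,
#'   `condition`, `replicate_id`, `tags` and `total` (number of tags).
#' @export
tag_library <- function(tags, experiment_id = "exp", condition = NA_character_,
                        replicate_id = NA_character_, genome = NULL) {
  tags <- data.table::as.data.table(tags)
  if (nrow(tags) == 0L)
    tags <- data.table::data.table(chrom = character(), pos = integer(),
                                   strand = character())
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tags)))
  if (nrow(tags) > 0L) {
    if (!all(tags$strand %in% c("+", "-")))
      stop("tag strand must be '+' or '-'")
    if (!is.null(genome)) {
      if (!all(tags$chrom %in% genome$chroms))
        stop("tag on unknown chromosome: ",
             setdiff(unique(tags$chrom), genome$chroms)[1L])
      len <- genome$lengths[tags$chrom]
      if (any(tags$pos < 0 | tags$pos >= len))
        stop("tag position outside chromosome bounds")
    }
  }
  tags[, pos := as.integer(pos)]
  structure(
    list(experiment_id = experiment_id, condition = condition,
         replicate_id = replicate_id, tags = tags, total = nrow(tags)),
    class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library", x$experiment_id, "(", x$condition, "/", x$replicate_id,
      "):", format(x$total, big.mark = ","), "tags\n")
  invisible(x)
}

#' Load aligned tags from BED or tagAlign
#'
#' Each record is reduced to its 5' coordinate: `start` for + strand reads,
#' `end - 1` for - strand reads.  BED and tagAlign share the six-column layout
#' (chrom, start, end, name/sequence, score, strand).
#'
#' @param path Input file (plain text, tab separated).
#' @param format "bed" or "tagAlign" (same column layout).
#' @inheritParams tag_library
#' @return A [tag_library()].
#' @export
load_tags <- function(path, format = c("bed", "tagAlign"),
                      experiment_id = basename(path),
                      condition = NA_character_,
                      replicate_id = NA_character_, genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(tag_library(NULL, experiment_id, condition, replicate_id, genome))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 6L)
    stop("expected >= 6 columns (", format, "), got ", ncol(dt))
  data.table::setnames(dt, 1:6, c("chrom", "start", "end", "name", "score",
                                  "strand")[1:6])
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start < 0 |
                 dt$start >= dt$end | !(dt$strand %in% c("+", "-")))
  if (length(bad) > 0L)
    stop("malformed ", format, " record at line ", bad[1L], " of ", path)
  tags <- data.table::data.table(
    chrom = dt$chrom,
    pos = as.integer(ifelse(dt$strand == "+", dt$start, dt$end - 1L)),
    strand = dt$strand)
  tag_library(tags, experiment_id, condition, replicate_id, genome)
}

#' Write a tag library as BED6
#'
#' Each tag becomes a 1 bp interval anchored at its 5' position, so that
#' loading the file back reproduces the identical tag set.  Output is sorted
#' by chromosome then start (deterministic).
#'
#' @param lib A [tag_library()].
#' @param path Output path.
#' @export
write_tags <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  t <- data.table::copy(lib$tags)
  data.table::setorder(t, chrom, pos, strand)
  out <- data.table::data.table(
    chrom = t$chrom, start = t$pos, end = t$pos + 1L,
    name = if (nrow(t)) paste0("t", seq_len(nrow(t))) else character(),
    score = if (nrow(t)) 0L else integer(), strand = t$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Extend tags 3'-ward into fixed-length intervals
#'
#' Each tag becomes an interval of `length_bp` bases extending 3'-ward from
#' its 5' end, clipped at chromosome bounds: `[pos, pos + L)` for + tags and
#' `[pos - L + 1, pos + 1)` for - tags.
#'
#' @param lib A [tag_library()].
#' @param genome A [genome()] (for clipping).
#' @param length_bp Extension length in bp (default 100).
#' @return data.table with columns `chrom`, `start`, `end`, `strand`.
#' @export
extend_tags <- function(lib, genome, length_bp = 100L) {
  stopifnot(inherits(lib, "tag_library"), length_bp >= 1L)
  t <- lib$tags
  if (nrow(t) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character()))
  plus <- t$strand == "+"
  start <- ifelse(plus, t$pos, t$pos - length_bp + 1L)
  end <- ifelse(plus, t$pos + length_bp, t$pos + 1L)
  len <- genome$lengths[t$chrom]
  data.table::data.table(
    chrom = t$chrom,
    start = as.integer(pmax(0L, start)),
    end = as.integer(pmin(len, end)),
    strand = t$strand)
}

#' Bin 5' tag counts along each chromosome
#'
#' Tag at position p is assigned to bin `floor(p / bin_width)`; the sum over
#' bins of a chromosome equals the library's tag count there (conservation).
#'
#' @param lib A [tag_library()].
#' @param genome A [genome()].
#' @param bin_width Bin width in bp.
#' @return Object of class `binned_coverage`: list with `bin_width` and
#'   `counts`, a named list of per-chromosome integer vectors.
#' @export
bin_counts <- function(lib, genome, bin_width = 100L) {
  stopifnot(inherits(lib, "tag_library"), bin_width >= 1L)
  counts <- lapply(stats::setNames(genome$chroms, genome$chroms), function(cn) {
    nb <- ceiling(genome$lengths[[cn]] / bin_width)
    p <- lib$tags[chrom == cn, pos]
    tabulate(p %/% bin_width + 1L, nbins = nb)
  })
  structure(list(bin_width = as.integer(bin_width), counts = counts),
            class = "binned_coverage")
}

#' Export binned coverage as bedGraph
#'
#' Zero bins are omitted; rows are sorted by chromosome order then start.
#'
#' @param bc A `binned_coverage` from [bin_counts()].
#' @param path Output path.
#' @export
write_bedgraph <- function(bc, path) {
  stopifnot(inherits(bc, "binned_coverage"))
  rows <- lapply(names(bc$counts), function(cn) {
    v <- bc$counts[[cn]]
    i <- which(v > 0L)
    if (length(i) == 0L) return(NULL)
    data.table::data.table(chrom = cn, start = (i - 1L) * bc$bin_width,
                           end = i * bc$bin_width, count = v[i])
  })
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Count tags in a window
#'
#' In `five_prime` mode, counts tags whose 5' end lies in `[start, end)`.
#' In `extended` mode, counts tags whose `extend`-bp 3'-ward extension
#' overlaps the window.
#'
#' @param lib A [tag_library()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @param mode "five_prime" or "extended".
#' @param extend Extension length for `mode = "extended"`.
#' @return Integer count.
#' @export
count_in_window <- function(lib, chrom, start, end,
                            mode = c("five_prime", "extended"), extend = 100L) {
  mode <- match.arg(mode)
  if (start >= end) stop("invalid window [", start, ",", end, ")")
  row_idx <- which(lib$tags[["chrom"]] == chrom)
  if (length(row_idx) == 0L) return(0L)
  t <- lib$tags[row_idx]
  if (mode == "five_prime") {
    sum(t$pos >= start & t$pos < end)
  } else {
    plus <- t$strand == "+"
    s <- ifelse(plus, t$pos, t$pos - extend + 1L)
    e <- ifelse(plus, t$pos + extend, t$pos + 1L)
    sum(s < end & e > start)
  }
}

# Fast multi-window 5' counts on one chromosome.
# pos need not be sorted; starts/ends are parallel vectors (0-based half-open).
.count_in_windows <- function(pos, starts, ends) {
  ps <- sort(pos)
  findInterval(ends - 0.5, ps) - findInterval(starts - 0.5, ps)
}

# library totals helper
.lib_total <- function(lib) lib$total

# pooled positions of several libraries on one chromosome
.pooled_pos <- function(libs, cn) {
  unlist(lapply(libs, function(l) l$tags[chrom == cn, pos]), use.names = FALSE)
}
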