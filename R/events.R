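# Point-source binding event calling: sliding windows scored by pooled signal
# versus a control-derived local expectation under a Poisson upper-tail test,
# BH correction over all tested windows, merge, summit refinement.

#' Event-calling configuration
#'
#' @param q_bind Binding q-value threshold (default 0.001).
#' @param q_diff Differential q-value threshold (default 0.01).
#' @param window Scoring window width W in bp (default 200).
#' @param step Window step in bp (default 50; must divide `window`).
#' @param local_bg Width of the local control window (default 5000).
#' @param merge_radius Cross-experiment summit merge radius (default 100).
#' @param min_category Minimum events to retain a category (default 500).
#' @param top_n Ranked-site cut for profile analyses (default 10000).
#' @param default_phi Dispersion fallback without replication.
#' @param pseudocount Pseudocount for log fold changes vs input.
#' @return Configuration list.
#' @export
event_config <- function(q_bind = 0.001, q_diff = 0.01, window = 200L,
                         step = 50L, local_bg = 5000L, merge_radius = 100L,
                         min_category = 500L, top_n = 10000L,
                         default_phi = 0.1, pseudocount = 1) {
  stopifnot(q_bind > 0, q_bind < 1, q_diff > 0, q_diff < 1,
            window %% step == 0L)
  list(q_bind = q_bind, q_diff = q_diff, window = as.integer(window),
       step = as.integer(step), local_bg = as.integer(local_bg),
       merge_radius = as.integer(merge_radius),
       min_category = as.integer(min_category), top_n = as.integer(top_n),
       default_phi = default_phi, pseudocount = pseudocount)
}

#' Call point-source binding events against an input control
#'
#' Slides `window`-bp windows at `step`-bp intervals over the genome, scores
#' the pooled replicate 5' tag count against the larger of a local
#' control-derived expectation (control count in `local_bg` bp, scaled by the
#' signal/control total-tag ratio) and the genome-wide expectation, under a
#' Poisson upper-tail test.  Benjamini-Hochberg correction is applied over
#' all tested windows; windows passing `q_bind` are merged when overlapping
#' and each merged region is summarized by the position maximizing smoothed
#' 5' tag density (its summit).
#'
#' @param signal_libs List of replicate [tag_library()] objects.
#' @param control_lib A [tag_library()] (input control), or NULL to use the
#'   genome-wide expectation only.
#' @param g A [genome()].
#' @param config From [event_config()].
#' @return data.table of events sorted by significance: `chrom`, `summit`,
#'   `start`, `end` (merged region), `count` (pooled tags in the best
#'   window), `signal` (count per million pooled tags), `p_binding`,
#'   `q_binding`.  Empty (with a warning) when the signal has no tags.
#' @export
call_events <- function(signal_libs, control_lib, g, config = event_config()) {
  if (inherits(signal_libs, "tag_library")) signal_libs <- list(signal_libs)
  total_sig <- sum(vapply(signal_libs, .lib_total, 0))
  empty <- data.table::data.table(
    chrom = character(), summit = integer(), start = integer(),
    end = integer(), count = integer(), signal = numeric(),
    p_binding = numeric(), q_binding = numeric())
  if (total_sig == 0L) {
    warning("signal libraries contain no tags; no events called")
    return(empty)
  }
  total_ctl <- if (is.null(control_lib)) 0 else control_lib$total
  W <- config$window; step <- config$step
  k <- W %/% step
  genome_len <- sum(as.numeric(g$lengths))
  global_rate <- total_sig * W / genome_len

  per_chrom <- vector("list", length(g$chroms))
  names(per_chrom) <- g$chroms
  for (cn in g$chroms) {
    len <- g$lengths[[cn]]
    nb <- ceiling(len / step)
    pos <- .pooled_pos(signal_libs, cn)
    sig_bins <- tabulate(pos %/% step + 1L, nbins = nb)
    nw <- nb - k + 1L
    if (nw < 1L) next
    cs <- c(0L, cumsum(sig_bins))
    x <- cs[(k + 1L):(nb + 1L)] - cs[1L:nw]          # pooled count per window
    lam <- rep(global_rate, nw)
    if (total_ctl > 0) {
      cpos <- control_lib$tags[chrom == cn, pos]
      ctl_bins <- tabulate(cpos %/% step + 1L, nbins = nb)
      cc <- c(0, cumsum(ctl_bins))
      half <- config$local_bg %/% (2L * step)
      ws <- seq_len(nw)                              # window start bin index
      lo <- pmax(ws - half, 1L)
      hi <- pmin(ws + k - 1L + half, nb)
      local_ct <- cc[hi + 1L] - cc[lo]
      local_len <- (hi - lo + 1L) * step
      local_exp <- local_ct * (total_sig / total_ctl) * (W / local_len)
      lam <- pmax(lam, local_exp)
    }
    p <- stats::ppois(x - 1L, lam, lower.tail = FALSE)
    per_chrom[[cn]] <- data.table::data.table(
      chrom = cn, wstart = (seq_len(nw) - 1L) * step, count = x, p = p)
  }
  win <- data.table::rbindlist(per_chrom)
  if (nrow(win) == 0L) return(empty)
  win[, q := stats::p.adjust(p, method = "BH")]
  sig <- win[q < config$q_bind]
  if (nrow(sig) == 0L) return(empty)

  # merge overlapping significant windows per chromosome
  events <- sig[, {
    o <- order(wstart)
    s <- wstart[o]; cnt <- count[o]; pp <- p[o]; qq <- q[o]
    grp <- cumsum(c(1L, as.integer(s[-1L] >= s[-length(s)] + W)))
    res <- data.table::data.table(grp = grp, s = s, cnt = cnt, pp = pp,
                                  qq = qq)[
      , .(start = min(s), end = max(s) + W, count = max(cnt),
          p_binding = min(pp), q_binding = min(qq)), by = grp]
    res[, grp := NULL]
    res
  }, by = chrom]

  # summit: position with maximum smoothed 5' density inside the region
  events[, summit := NA_integer_]
  for (cn in unique(events$chrom)) {
    pos <- sort(.pooled_pos(signal_libs, cn))
    idx <- which(events$chrom == cn)
    for (i in idx) {
      s <- events$start[i]; e <- events$end[i]
      pp <- pos[pos >= s & pos < e]
      if (length(pp) == 0L) { events$summit[i] <- as.integer((s + e) %/% 2); next }
      cnts <- tabulate(pp - s + 1L, nbins = e - s)
      sm <- .running_sum(cnts, 51L)
      events$summit[i] <- s + which.max(sm) - 1L
    }
  }
  events[, signal := count * 1e6 / total_sig]
  data.table::setcolorder(events, c("chrom", "summit", "start", "end",
                                    "count", "signal", "p_binding",
                                    "q_binding"))
  data.table::setorder(events, p_binding, -signal, chrom, summit)
  events[]
}

# centered running sum with window w (odd); same length as x
.running_sum <- function(x, w) {
  half <- w %/% 2L
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

#' Rank binding events and keep the best n
#'
#' Order: ascending binding q-value, then descending signal, then coordinate;
#' the output of `rank_top(e, n)` is a prefix of `rank_top(e, m)` for
#' `n <= m`.
#'
#' @param events Event table from [call_events()].
#' @param n Number of events to keep; all when fewer.
#' @return Reordered (and truncated) event table.
#' @export
rank_top <- function(events, n = 10000L) {
  events <- data.table::as.data.table(events)
  o <- order(events$q_binding, -events$signal, events$chrom, events$summit)
  events[o][seq_len(min(n, nrow(events)))]
}

#' Export events as BED6+
#'
#' Name column carries the event (or category) label; score is
#' `-10 log10(q)`, capped at 1000.
#'
#' @param events Event table (needs `chrom`, `summit`, `q_binding`; optional
#'   `label`).
#' @param path Output path.
#' @param half_width Half-width of the written interval around the summit.
#' @export
write_events_bed <- function(events, path, half_width = 100L) {
  e <- data.table::as.data.table(events)
  lab <- if ("label" %in% names(e)) e$label else sprintf("event_%d", seq_len(nrow(e)))
  out <- data.table::data.table(
    chrom = e$chrom,
    start = pmax(0L, e$summit - half_width),
    end = e$summit + half_width,
    name = lab,
    score = pmin(1000, round(-10 * log10(pmax(e$q_binding, 1e-100)))),
    strand = ".")
  data.table::setorder(out, chrom, start)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
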