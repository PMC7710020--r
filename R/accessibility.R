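# Accessible-domain calling from ATAC tags and prior-accessibility
# quantification at binding-site sets.

#' Call accessible domains from ATAC tag libraries
#'
#' Bins pooled 5' counts, flags bins whose count exceeds the Poisson upper
#' tail of the genome-average rate at `p_thresh`, merges flagged bins across
#' gaps of at most `merge_gap` bp and drops domains shorter than `min_len`.
#'
#' @param atac_libs List of [tag_library()] objects (pooled).
#' @param g A [genome()].
#' @param bin Bin width in bp (default 50).
#' @param p_thresh Poisson upper-tail threshold (default 1e-3).
#' @param merge_gap Maximum gap bridged between flagged bins (default 200).
#' @param min_len Minimum domain length (default 200).
#' @return data.table of non-overlapping sorted domains: `chrom`, `start`,
#'   `end`, `density` (tags per million per bp).  Empty for empty libraries.
#' @export
call_domains <- function(atac_libs, g, bin = 50L, p_thresh = 1e-3,
                         merge_gap = 200L, min_len = 200L) {
  if (inherits(atac_libs, "tag_library")) atac_libs <- list(atac_libs)
  total <- sum(vapply(atac_libs, .lib_total, 0))
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), density = numeric())
  if (total == 0) return(empty)
  rate <- total * bin / sum(as.numeric(g$lengths))
  gap_bins <- merge_gap %/% bin
  out <- vector("list", length(g$chroms))
  for (ci in seq_along(g$chroms)) {
    cn <- g$chroms[ci]
    nb <- ceiling(g$lengths[[cn]] / bin)
    pos <- .pooled_pos(atac_libs, cn)
    cnt <- tabulate(pos %/% bin + 1L, nbins = nb)
    hot <- which(stats::ppois(cnt - 1L, rate, lower.tail = FALSE) < p_thresh)
    if (length(hot) == 0L) next
    grp <- cumsum(c(1L, as.integer(diff(hot) > gap_bins + 1L)))
    dt <- data.table::data.table(hot = hot, grp = grp)[
      , .(start = (min(hot) - 1L) * bin,
          end = pmin(max(hot) * bin, g$lengths[[cn]])), by = grp]
    dt <- dt[end - start >= min_len]
    if (nrow(dt) == 0L) next
    ps <- sort(pos)
    n_in <- findInterval(dt$end - 0.5, ps) - findInterval(dt$start - 0.5, ps)
    out[[ci]] <- data.table::data.table(
      chrom = cn, start = dt$start, end = dt$end,
      density = n_in * 1e6 / total / (dt$end - dt$start))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  data.table::setorder(res, chrom, start)
  res[]
}

#' Per-site normalized read density
#'
#' For each site, the 5' tag count in a centered window is scaled to tags per
#' million library tags; replicates are normalized first and then averaged.
#'
#' @param sites data.frame/data.table with `chrom` and `summit` columns.
#' @param atac_libs List of [tag_library()] objects (replicates).
#' @param window Window width in bp (default 2000).
#' @return List: `densities` (data.table `chrom`, `summit`, `density`) and
#'   `summary` (a quartile summary, see [quartile_summary()]).
#' @export
site_density <- function(sites, atac_libs, window = 2000L) {
  if (inherits(atac_libs, "tag_library")) atac_libs <- list(atac_libs)
  sites <- data.table::as.data.table(sites)
  if (window < 1L) stop("window must be >= 1")
  half <- window %/% 2L
  acc <- numeric(nrow(sites))
  for (lib in atac_libs) {
    v <- numeric(nrow(sites))
    for (cn in unique(sites$chrom)) {
      i <- which(sites$chrom == cn)
      p <- lib$tags[chrom == cn, pos]
      v[i] <- .count_in_windows(p, sites$summit[i] - half,
                                sites$summit[i] + half)
    }
    acc <- acc + v * 1e6 / max(lib$total, 1L)
  }
  d <- acc / length(atac_libs)
  out <- data.table::data.table(chrom = sites$chrom, summit = sites$summit,
                                density = d)
  list(densities = out, summary = quartile_summary(d))
}

#' Quartile summary of a numeric vector
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param x Numeric vector.
#' @return List: `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
quartile_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  list(min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
       n = length(x))
}

#' Fraction of site points falling inside accessible domains
#'
#' Membership is judged by the summit point (point-in-interval), matching the
#' point-source nature of binding events.
#'
#' @param sites data.table with `chrom` and `summit` (or `pos`).
#' @param domains Non-overlapping domain table (`chrom`, `start`, `end`).
#' @return Fraction in `[0, 1]` (0 when there are no domains).
#' @export
fraction_in_domains <- function(sites, domains) {
  sites <- data.table::as.data.table(sites)
  pt <- if ("summit" %in% names(sites)) sites$summit else sites$pos
  if (nrow(sites) == 0L) return(NA_real_)
  if (is.null(domains) || nrow(domains) == 0L) return(0)
  domains <- data.table::as.data.table(domains)
  inside <- logical(nrow(sites))
  for (cn in unique(sites$chrom)) {
    i <- which(sites$chrom == cn)
    d <- domains[chrom == cn][order(start)]
    if (nrow(d) == 0L) next
    j <- findInterval(pt[i], d$start)
    inside[i] <- j >= 1L & pt[i] < d$end[pmax(j, 1L)]
  }
  mean(inside)
}

#' Composite read-density profile around site points
#'
#' Per replicate, each read is extended `extend` bp 3'-ward from its 5' end
#' and its base-level overlap with every offset in `[-half_window,
#' half_window)` around each site point is summed over sites; the profile is
#' scaled to tags per million per 1000 sites and finally averaged over
#' replicates.
#'
#' @param sites data.table with `chrom` and `summit` (or `pos`).
#' @param atac_libs List of replicate [tag_library()] objects.
#' @param half_window Half window in bp (default 1000).
#' @param extend Read extension in bp (default 100).
#' @return Object of class `composite_profile`: list with `offsets`
#'   (`-half_window ... half_window-1`), `density` (replicate-averaged),
#'   `per_replicate` (matrix offsets x replicates), `raw_overlap`
#'   (pre-normalization integer base-overlap per replicate), `n_sites`.
#' @export
composite_profile <- function(sites, atac_libs, half_window = 1000L,
                              extend = 100L) {
  if (inherits(atac_libs, "tag_library")) atac_libs <- list(atac_libs)
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0L) stop("no sites supplied")
  pt <- if ("summit" %in% names(sites)) sites$summit else sites$pos
  hw <- as.integer(half_window)
  L <- 2L * hw
  nrep <- length(atac_libs)
  per_rep <- matrix(0, nrow = L, ncol = nrep)
  raw <- numeric(nrep)
  for (r in seq_len(nrep)) {
    lib <- atac_libs[[r]]
    delta <- numeric(L + 1L)
    for (cn in unique(sites$chrom)) {
      si <- which(sites$chrom == cn)
      t <- lib$tags[chrom == cn]
      if (nrow(t) == 0L) next
      plus <- t$strand == "+"
      rs <- sort(ifelse(plus, t$pos, t$pos - extend + 1L))  # read starts
      ai_all <- integer(0); bi_all <- integer(0)
      for (s in pt[si]) {
        lo <- findInterval(s - hw - extend - 0.5, rs) + 1L
        hi <- findInterval(s + hw - 0.5, rs)
        if (hi < lo) next
        a <- pmax(rs[lo:hi] - s, -hw)
        b <- pmin(rs[lo:hi] + extend - s, hw)
        keep <- b > a
        if (!any(keep)) next
        ai_all <- c(ai_all, a[keep] + hw + 1L)
        bi_all <- c(bi_all, b[keep] + hw + 1L)
      }
      if (length(ai_all)) {
        delta <- delta + tabulate(ai_all, nbins = L + 1L) -
          tabulate(bi_all, nbins = L + 1L)
      }
    }
    prof <- cumsum(delta[seq_len(L)])
    raw[r] <- sum(prof)
    per_rep[, r] <- prof * (1e6 / max(lib$total, 1L)) * (1000 / nrow(sites))
  }
  structure(list(offsets = seq(-hw, hw - 1L), density = rowMeans(per_rep),
                 per_replicate = per_rep, raw_overlap = raw,
                 n_sites = nrow(sites)),
            class = "composite_profile")
}

#' Accessibility change at sites between two conditions
#'
#' Per site, `delta = after - before` normalized density (each condition
#' per-million normalized and replicate-averaged, as in [site_density()]).
#'
#' @param sites data.table with `chrom`, `summit` (or `pos`), optionally a
#'   `category` column for grouped summaries.
#' @param libs_before,libs_after Replicate library lists for the two
#'   conditions.
#' @param window Window width in bp (default 2000; must be >= 1).
#' @return List: `per_site` (sites with `before`, `after`, `delta`) and
#'   `by_category` (mean, standard error, n per category; NULL without a
#'   category column).
#' @export
accessibility_change <- function(sites, libs_before, libs_after,
                                 window = 2000L) {
  if (window < 1L) stop("window must be >= 1")
  sites <- data.table::as.data.table(sites)
  if (!"summit" %in% names(sites) && "pos" %in% names(sites))
    sites <- data.table::copy(sites)[, summit := pos]
  before <- site_density(sites, libs_before, window)$densities$density
  after <- site_density(sites, libs_after, window)$densities$density
  per_site <- data.table::copy(sites)
  per_site[, c("before", "after", "delta") :=
             .(before, after, after - before)]
  by_cat <- NULL
  if ("category" %in% names(sites)) {
    by_cat <- per_site[, .(mean_delta = mean(delta),
                           se_delta = stats::sd(delta) / sqrt(.N), n = .N),
                       by = category]
  }
  list(per_site = per_site[], by_category = by_cat)
}
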