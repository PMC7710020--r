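# Cross-experiment binding-profile PCA and heatmap matrices.

#' Union of top-ranked binding sites across TFs
#'
#' Takes the top `n` events per TF (via [rank_top()]) and merges summits
#' within `merge_radius` bp into unique locations (single-linkage, midpoint
#' summit).
#'
#' @param per_tf_events Named list of event tables.
#' @param n Top events per TF (default 10000).
#' @param merge_radius Merge radius in bp (default 50).
#' @return data.table: `chrom`, `summit`.
#' @export
union_top_sites <- function(per_tf_events, n = 10000L, merge_radius = 50L) {
  tops <- lapply(per_tf_events, rank_top, n = n)
  all <- data.table::rbindlist(lapply(tops, function(e)
    e[, .(chrom, summit)]))
  if (nrow(all) == 0L) return(all)
  all[, grp := .merge_points(summit, merge_radius), by = chrom]
  out <- all[, .(summit = as.integer(round(mean(range(summit))))),
             by = .(chrom, grp)]
  out[, grp := NULL]
  data.table::setorder(out, chrom, summit)
  out[]
}

#' Site-by-experiment count matrix
#'
#' Window 5' tag counts at each site for each library.
#'
#' @param sites data.table with `chrom`, `summit`.
#' @param libs Named list of [tag_library()] objects (one column each).
#' @param window Window width in bp (default 200).
#' @return Integer matrix sites x experiments with library names as columns.
#' @export
count_matrix <- function(sites, libs, window = 200L) {
  m <- .site_count_matrix(data.table::as.data.table(sites), libs, window)
  colnames(m) <- if (!is.null(names(libs)) && all(nzchar(names(libs))))
    names(libs) else vapply(libs, function(l) l$experiment_id, "")
  rownames(m) <- paste0(sites$chrom, ":", sites$summit)
  m
}

#' PCA of binding profiles across experiments
#'
#' Experiments are the observations; counts are `log2(c + 1)` transformed and
#' (by default) centered per site.  The sign of each component is fixed by
#' making its largest-magnitude loading positive.
#'
#' @param mat Sites x experiments count matrix (e.g. [count_matrix()]).
#' @param log_transform Apply `log2(x + 1)` (default TRUE).
#' @param center Center site profiles (default TRUE).
#' @return List: `scores` (experiments x PCs), `loadings` (sites x PCs),
#'   `var_frac` (variance fractions summing to 1).
#' @export
pca_profiles <- function(mat, log_transform = TRUE, center = TRUE) {
  if (ncol(mat) < 2L || nrow(mat) < 2L)
    stop("need >= 2 experiments and >= 2 sites")
  x <- if (log_transform) log2(mat + 1) else mat
  if (all(abs(x - mean(x)) < 1e-12))
    stop("constant matrix: no variance to decompose")
  pr <- stats::prcomp(t(x), center = center, scale. = FALSE)
  scores <- pr$x
  loadings <- pr$rotation
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings,
       var_frac = pr$sdev^2 / sum(pr$sdev^2))
}

#' Heatmap matrix of binned extended-read counts around events
#'
#' Reads are extended `extend` bp 3'-ward and counted in `bin`-bp bins over a
#' `window`-bp window centered on each event summit (a read contributes to
#' every bin its extension overlaps).  Rows are ordered by binding
#' significance (q ascending, then signal descending).  The color maximum is
#' the count at the given percentile of all bins (ordered by count), floored
#' at `floor`; the minimum is `floor`.
#'
#' @param events Event table (needs `chrom`, `summit`, `q_binding`,
#'   `signal`).
#' @param lib A [tag_library()] or list of libraries (pooled).
#' @param g A [genome()].
#' @param window Window width in bp (default 1000).
#' @param bin Bin width in bp (default 100).
#' @param extend Read extension in bp (default 100).
#' @param floor Color-scale minimum in read counts (default 5).
#' @param percentile Percentile of ordered bins setting the color maximum
#'   (default 85).
#' @return Object of class `heatmap_matrix`: list with `matrix` (events x
#'   bins, ordered), `bounds` (c(min, max) color bounds), `order` (row order
#'   into the input), `bin`, `window`.
#' @export
heatmap_matrix <- function(events, lib, g, window = 1000L, bin = 100L,
                           extend = 100L, floor = 5, percentile = 85) {
  if (inherits(lib, "tag_library")) lib <- list(lib)
  events <- data.table::as.data.table(events)
  o <- order(events$q_binding, -events$signal, events$chrom, events$summit)
  ev <- events[o]
  nb <- window %/% bin
  half <- window %/% 2L
  m <- matrix(0L, nrow = nrow(ev), ncol = nb)
  for (cn in unique(ev$chrom)) {
    i <- which(ev$chrom == cn)
    starts <- integer(0); ends <- integer(0)
    for (l in lib) {
      t <- l$tags[chrom == cn]
      if (nrow(t) == 0L) next
      plus <- t$strand == "+"
      starts <- c(starts, ifelse(plus, t$pos, t$pos - extend + 1L))
    }
    if (length(starts) == 0L) next
    ends <- starts + extend          # half-open read intervals
    ss <- sort(starts); es <- sort(ends)
    for (b in seq_len(nb)) {
      bs <- ev$summit[i] - half + (b - 1L) * bin
      be <- bs + bin
      # reads overlapping [bs, be): start < be and end > bs
      m[i, b] <- findInterval(be - 0.5, ss) - findInterval(bs + 0.5, es)
    }
  }
  vals <- sort(as.vector(m))
  vmax <- if (length(vals)) vals[max(1L, ceiling(percentile / 100 * length(vals)))]
          else 0
  bounds <- c(floor, max(floor, vmax))
  structure(list(matrix = m, bounds = bounds, order = o, bin = bin,
                 window = window),
            class = "heatmap_matrix")
}
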