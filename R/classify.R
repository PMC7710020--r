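# Multi-way differential binding classification: cross-TF site matching,
# per-site NB exact tests, and the closed category vocabulary
# ("A=B=C", "A>B,C", "A,B>C", ... pairwise "A=B", "A>B", "B>A").

# single-linkage merge of sorted-able points within radius; returns group id
# per input point (in input order)
.merge_points <- function(pos, radius) {
  o <- order(pos)
  p <- pos[o]
  grp_sorted <- cumsum(c(1L, as.integer(diff(p) > radius)))
  grp <- integer(length(pos))
  grp[o] <- grp_sorted
  grp
}

#' Merge binding events from several experiments into a site union
#'
#' Summits on the same chromosome within `radius` bp are merged
#' (single-linkage); each merged site is placed at the midpoint of its
#' summits.
#'
#' @param event_tables Named list of event tables (one per TF).
#' @param radius Merge radius in bp (default 100).
#' @return data.table: `chrom`, `summit`, plus one `q_<tf>` column per input
#'   table holding the minimum binding q-value of that TF's events in the
#'   site (NA when the TF has no event there).
#' @export
site_union <- function(event_tables, radius = 100L) {
  tf_names <- names(event_tables)
  stopifnot(!is.null(tf_names), all(nzchar(tf_names)))
  ev <- data.table::rbindlist(lapply(tf_names, function(tf) {
    e <- event_tables[[tf]]
    data.table::data.table(tf = tf, chrom = e$chrom, summit = e$summit,
                           q = e$q_binding)
  }))
  if (nrow(ev) == 0L) {
    out <- data.table::data.table(chrom = character(), summit = integer())
    for (tf in tf_names) out[, (paste0("q_", tf)) := numeric()]
    return(out)
  }
  ev[, grp := .merge_points(summit, radius), by = chrom]
  sites <- ev[, .(summit = as.integer(round(mean(range(summit))))),
              by = .(chrom, grp)]
  qs <- ev[, {
    res <- lapply(tf_names, function(nm) {
      v <- q[tf == nm]
      if (length(v)) min(v) else NA_real_
    })
    names(res) <- paste0("q_", tf_names)
    res
  }, by = .(chrom, grp)]
  out <- sites[qs, on = c("chrom", "grp")]
  out[, grp := NULL]
  data.table::setorder(out, chrom, summit)
  out[]
}

# window count matrix: sites x replicate libraries (5' mode)
.site_count_matrix <- function(sites, libs, window) {
  half <- window %/% 2L
  n <- nrow(sites)
  mat <- matrix(0L, nrow = n, ncol = length(libs))
  for (j in seq_along(libs)) {
    lib <- libs[[j]]
    for (cn in unique(sites$chrom)) {
      i <- which(sites$chrom == cn)
      p <- lib$tags[chrom == cn, pos]
      mat[i, j] <- .count_in_windows(p, sites$summit[i] - half,
                                     sites$summit[i] + half)
    }
  }
  mat
}

#' Classify a site union by multi-way differential binding
#'
#' Implements the category rules: a site is shared ("A=B=C") when significant
#' binding events were called for all TFs and no two TFs are differentially
#' bound; "TF1>TF2,TF3" when TF1 has a significant event and significantly
#' more reads than both others (with a greater log fold-change vs input);
#' "TF1,TF2>TF3" when TF1 and TF2 both have events, are not differentially
#' bound with respect to each other, and both exceed TF3.  Sites matching no
#' rule are "unclassified"; retained categories must hold at least
#' `min_category` events, smaller ones are folded into "unclassified/minor".
#'
#' @param event_tables Named list (2 or 3 TFs) of event tables from
#'   [call_events()].
#' @param libs_by_tf Named list of replicate [tag_library()] lists, parallel
#'   to `event_tables`.
#' @param control_lib Input control [tag_library()] (or NULL).
#' @param g A [genome()].
#' @param config From [event_config()].
#' @return Object of class `category_assignment`: list with `sites` (chrom,
#'   summit, per-TF significance/q/logFC columns, per-pair `q_diff` columns,
#'   `label_raw`, `label`), `categories` (retained-category summary), `phi`,
#'   `config`.
#' @export
classify_sites <- function(event_tables, libs_by_tf, control_lib, g,
                           config = event_config()) {
  tf_names <- names(event_tables)
  nt <- length(tf_names)
  stopifnot(nt %in% c(2L, 3L), identical(sort(tf_names),
                                         sort(names(libs_by_tf))))
  sites <- site_union(event_tables, config$merge_radius)
  if (nrow(sites) == 0L)
    return(structure(list(sites = sites,
                          categories = data.table::data.table(),
                          phi = NA_real_, config = config),
                     class = "category_assignment"))

  # count matrices and normalization
  libs_flat <- list(); groups <- character()
  for (tf in tf_names) {
    libs_flat <- c(libs_flat, libs_by_tf[[tf]])
    groups <- c(groups, rep(tf, length(libs_by_tf[[tf]])))
  }
  lib_sizes <- vapply(libs_flat, .lib_total, 0)
  counts <- .site_count_matrix(sites, libs_flat, config$window)
  phi <- estimate_dispersion(counts, lib_sizes, groups,
                             default_phi = config$default_phi)

  ref <- mean(lib_sizes)
  # per-TF mean normalized count and logFC vs input
  input_norm <- if (!is.null(control_lib) && control_lib$total > 0) {
    ic <- .site_count_matrix(sites, list(control_lib), config$window)[, 1L]
    ic * ref / control_lib$total
  } else rep(0, nrow(sites))
  pc <- config$pseudocount
  for (tf in tf_names) {
    j <- which(groups == tf)
    norm_mean <- rowMeans(sweep(counts[, j, drop = FALSE], 2L,
                                ref / lib_sizes[j], "*"))
    sites[, (paste0("lfc_", tf)) := log2((norm_mean + pc) / (input_norm + pc))]
    sites[, (paste0("sig_", tf)) :=
            !is.na(get(paste0("q_", tf))) &
            get(paste0("q_", tf)) < config$q_bind]
  }

  # pairwise exact tests, BH per pair family (sites significant in >= 1)
  pairs <- utils::combn(tf_names, 2L, simplify = FALSE)
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    ja <- which(groups == a); jb <- which(groups == b)
    fam <- which(sites[[paste0("sig_", a)]] | sites[[paste0("sig_", b)]])
    qd <- rep(NA_real_, nrow(sites))
    if (length(fam) > 0L) {
      p <- .nb_exact_p_many(counts[fam, ja, drop = FALSE],
                            counts[fam, jb, drop = FALSE],
                            lib_sizes[ja], lib_sizes[jb], phi)
      qd[fam] <- stats::p.adjust(p, method = "BH")
    }
    sites[, (paste0("qdiff_", a, "_", b)) := qd]
  }

  sites[, label_raw := .assign_labels(sites, tf_names, config)]
  tab <- table(sites$label_raw)
  minor <- names(tab)[tab < config$min_category]
  minor <- setdiff(minor, "unclassified")
  sites[, label := ifelse(label_raw %in% c(minor, "unclassified"),
                          "unclassified/minor", label_raw)]
  categories <- data.table::as.data.table(
    table(label = sites$label))[order(-N)]
  data.table::setnames(categories, "N", "n_sites")

  structure(list(sites = sites[], categories = categories[], phi = phi,
                 config = config),
            class = "category_assignment")
}

# closed-vocabulary label assignment
.assign_labels <- function(sites, tf_names, config) {
  qd <- function(a, b) {
    col <- paste0("qdiff_", a, "_", b)
    if (!col %in% names(sites)) col <- paste0("qdiff_", b, "_", a)
    sites[[col]]
  }
  sig <- function(a) sites[[paste0("sig_", a)]]
  lfc <- function(a) sites[[paste0("lfc_", a)]]
  t <- config$q_diff
  n <- nrow(sites)
  # "a significantly greater than b": differential and larger logFC vs input
  gt <- function(a, b) {
    v <- qd(a, b)
    !is.na(v) & v < t & lfc(a) > lfc(b)
  }
  eqv <- function(a, b) {
    v <- qd(a, b)
    !is.na(v) & v > t
  }
  lab <- rep("unclassified", n)
  if (length(tf_names) == 2L) {
    a <- tf_names[1L]; b <- tf_names[2L]
    shared <- sig(a) & sig(b) & eqv(a, b)
    lab[shared] <- paste0(a, "=", b)
    w <- sig(a) & gt(a, b); lab[w & lab == "unclassified"] <- paste0(a, ">", b)
    w <- sig(b) & gt(b, a); lab[w & lab == "unclassified"] <- paste0(b, ">", a)
    return(lab)
  }
  a <- tf_names[1L]; b <- tf_names[2L]; c_ <- tf_names[3L]
  shared <- sig(a) & sig(b) & sig(c_) & eqv(a, b) & eqv(a, c_) & eqv(b, c_)
  lab[shared] <- paste0(a, "=", b, "=", c_)
  singles <- list(c(a, b, c_), c(b, a, c_), c(c_, a, b))
  for (s3 in singles) {
    w <- sig(s3[1L]) & gt(s3[1L], s3[2L]) & gt(s3[1L], s3[3L])
    lab[w & lab == "unclassified"] <-
      paste0(s3[1L], ">", s3[2L], ",", s3[3L])
  }
  duos <- list(c(a, b, c_), c(a, c_, b), c(b, c_, a))
  for (d3 in duos) {
    w <- sig(d3[1L]) & sig(d3[2L]) & eqv(d3[1L], d3[2L]) &
      gt(d3[1L], d3[3L]) & gt(d3[2L], d3[3L])
    lab[w & lab == "unclassified"] <-
      paste0(d3[1L], ",", d3[2L], ">", d3[3L])
  }
  lab
}

#' Pairwise differential binding classification
#'
#' Two-TF convenience wrapper around [classify_sites()]: labels are "A=B",
#' "A>B", "B>A" (with the actual TF names).
#'
#' @inheritParams classify_sites
#' @param events_a,events_b Event tables for the two TFs.
#' @param libs_a,libs_b Replicate library lists.
#' @param names_ab Character vector of length 2 naming the TFs.
#' @return A `category_assignment` (see [classify_sites()]).
#' @export
classify_pairwise <- function(events_a, events_b, libs_a, libs_b,
                              control_lib, g, names_ab = c("A", "B"),
                              config = event_config()) {
  evs <- stats::setNames(list(events_a, events_b), names_ab)
  libs <- stats::setNames(list(libs_a, libs_b), names_ab)
  classify_sites(evs, libs, control_lib, g, config)
}

#' @export
print.category_assignment <- function(x, ...) {
  cat("category_assignment:", nrow(x$sites), "sites, phi =",
      signif(x$phi, 3), "\n")
  print(x$categories)
  invisible(x)
}
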