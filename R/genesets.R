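# Differential-expression gene sets and peak/gene-set association by
# logistic regression with gene-length control.

#' Build gene sets from differential-expression summary tables
#'
#' Rules (three TFs, one baseline):
#' * shared-up: `LFC > lfc_thresh` and `padj < alpha` in every TF-vs-baseline
#'   contrast, and not differentially expressed between TFs
#'   (`|pairwise LFC| <= lfc_thresh`); shared-down analogously with
#'   `LFC < -lfc_thresh`.
#' * TF-specific up: significantly higher in that TF than in both others in
#'   the pairwise contrasts (`LFC > lfc_thresh`, `padj < alpha`); down
#'   analogously.
#' * two-of-three up: both members exceed the third (`LFC > lfc_thresh`,
#'   `padj < alpha`) and the members are not differential with respect to
#'   each other (`|LFC| <= lfc_thresh`); down analogously.
#'
#' Sets of the same direction are disjoint by construction; genes matching no
#' rule are unassigned.  Assignment is deterministic and independent of input
#' row order.
#'
#' @param records data.table with columns `gene`, `contrast`, `lfc`, `padj`.
#'   Contrast labels follow `"<x>_vs_<y>"`; all three TF-vs-baseline and all
#'   three pairwise contrasts must be present (error naming the first
#'   missing one otherwise).
#' @param tf_names Character vector of the three TF names.
#' @param baseline Baseline condition name (default "progenitor").
#' @param lfc_thresh Log2 fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return Named list of character vectors (member gene ids, sorted), with
#'   names like "shared-up", "A-up", "A,B-up", and the corresponding
#'   "-down" sets.
#' @export
build_gene_sets <- function(records, tf_names, baseline = "progenitor",
                            lfc_thresh = 2, alpha = 0.01) {
  stopifnot(length(tf_names) == 3L)
  records <- data.table::as.data.table(records)
  need_base <- paste0(tf_names, "_vs_", baseline)
  prs <- utils::combn(tf_names, 2L, simplify = FALSE)
  need_pair <- vapply(prs, function(p) paste0(p[1L], "_vs_", p[2L]), "")
  have <- unique(records$contrast)
  pair_key <- vapply(prs, function(p) {
    fwd <- paste0(p[1L], "_vs_", p[2L]); rev <- paste0(p[2L], "_vs_", p[1L])
    if (fwd %in% have) fwd else if (rev %in% have) rev else NA_character_
  }, "")
  missing <- c(setdiff(need_base, have), need_pair[is.na(pair_key)])
  if (length(missing) > 0L)
    stop("missing contrast: ", missing[1L])

  genes <- sort(unique(records$gene))
  get_wide <- function(contrast_name, flip = FALSE) {
    r <- records[contrast == contrast_name]
    l <- stats::setNames(rep(NA_real_, length(genes)), genes)
    p <- l
    l[r$gene] <- if (flip) -r$lfc else r$lfc
    p[r$gene] <- r$padj
    list(lfc = l, padj = p)
  }
  base <- lapply(stats::setNames(need_base, tf_names), get_wide)
  # pairwise LFC oriented as tf_i vs tf_j for i<j in tf_names order
  pairw <- list()
  for (k in seq_along(prs)) {
    p <- prs[[k]]
    flip <- !(paste0(p[1L], "_vs_", p[2L]) %in% have)
    pairw[[paste(p, collapse = "|")]] <- get_wide(pair_key[k], flip = flip)
  }
  pw <- function(x, y) {
    key <- paste(c(x, y), collapse = "|")
    if (key %in% names(pairw)) return(pairw[[key]])
    z <- pairw[[paste(c(y, x), collapse = "|")]]
    list(lfc = -z$lfc, padj = z$padj)
  }

  up_sig <- function(w) !is.na(w$lfc) & !is.na(w$padj) &
    w$lfc > lfc_thresh & w$padj < alpha
  dn_sig <- function(w) !is.na(w$lfc) & !is.na(w$padj) &
    w$lfc < -lfc_thresh & w$padj < alpha
  flat <- function(w) !is.na(w$lfc) & abs(w$lfc) <= lfc_thresh

  sets <- list()
  add <- function(label, mask) {
    sets[[label]] <<- genes[which(mask)]
  }
  all_pairs_flat <- flat(pw(tf_names[1L], tf_names[2L])) &
    flat(pw(tf_names[1L], tf_names[3L])) &
    flat(pw(tf_names[2L], tf_names[3L]))
  add("shared-up",
      Reduce(`&`, lapply(base, up_sig)) & all_pairs_flat)
  add("shared-down",
      Reduce(`&`, lapply(base, dn_sig)) & all_pairs_flat)
  for (i in seq_along(tf_names)) {
    x <- tf_names[i]; others <- tf_names[-i]
    add(paste0(x, "-up"),
        up_sig(pw(x, others[1L])) & up_sig(pw(x, others[2L])))
    add(paste0(x, "-down"),
        dn_sig(pw(x, others[1L])) & dn_sig(pw(x, others[2L])))
  }
  for (pr in prs) {
    z <- setdiff(tf_names, pr)
    lab <- paste0(pr[1L], ",", pr[2L])
    add(paste0(lab, "-up"),
        up_sig(pw(pr[1L], z)) & up_sig(pw(pr[2L], z)) & flat(pw(pr[1L], pr[2L])))
    add(paste0(lab, "-down"),
        dn_sig(pw(pr[1L], z)) & dn_sig(pw(pr[2L], z)) & flat(pw(pr[1L], pr[2L])))
  }
  sets
}

#' Assign peaks to the gene with the nearest TSS
#'
#' Distance is `|summit - TSS|`; ties go to the lexicographically smaller
#' gene id.  Peaks on chromosomes without genes are skipped with a warning.
#'
#' @param peaks data.table with `chrom` and `summit` columns.
#' @param gene_models data.table with `gene`, `chrom`, `tss` columns.
#' @return List: `assignment` (data.table `peak` index, `gene`, `distance`)
#'   and `bound_genes` (character vector of genes with >= 1 assigned peak).
#' @export
assign_peaks_to_genes <- function(peaks, gene_models) {
  peaks <- data.table::as.data.table(peaks)
  gm <- data.table::as.data.table(gene_models)
  n <- nrow(peaks)
  gene_out <- rep(NA_character_, n)
  dist_out <- rep(NA_real_, n)
  skipped <- 0L
  for (cn in unique(peaks$chrom)) {
    i <- which(peaks$chrom == cn)
    gsub <- gm[chrom == cn]
    if (nrow(gsub) == 0L) { skipped <- skipped + length(i); next }
    # sort by tss, then gene id so ties resolve lexicographically
    gsub <- gsub[order(tss, gene)]
    j <- findInterval(peaks$summit[i], gsub$tss)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, nrow(gsub))
    dlo <- abs(peaks$summit[i] - gsub$tss[lo])
    dhi <- abs(peaks$summit[i] - gsub$tss[hi])
    # ties: prefer the lexicographically smaller gene id
    pick_lo <- dlo < dhi |
      (dlo == dhi & gsub$gene[lo] <= gsub$gene[hi])
    sel <- ifelse(pick_lo, lo, hi)
    gene_out[i] <- gsub$gene[sel]
    dist_out[i] <- pmin(dlo, dhi)
  }
  if (skipped > 0L)
    warning(skipped, " peak(s) on chromosomes without genes were skipped")
  keep <- !is.na(gene_out)
  list(assignment = data.table::data.table(peak = which(keep),
                                           gene = gene_out[keep],
                                           distance = dist_out[keep]),
       bound_genes = sort(unique(gene_out[keep])))
}

#' Logistic association between peak binding and gene-set membership
#'
#' Fits `logit P(bound) = b0 + b1 * membership + b2 * log10(length)` by
#' iteratively reweighted least squares (convergence tolerance 1e-8) and
#' reports the Wald test for `b1`.  Complete separation is flagged and no
#' p-value is reported.
#'
#' @param bound Logical/0-1 vector: gene has >= 1 assigned peak.
#' @param membership Logical/0-1 vector: gene belongs to the set.
#' @param gene_lengths Positive mappable gene lengths (bp).
#' @return List: `beta` (membership coefficient), `se`, `z`, `p`, `status`
#'   ("ok" or "separation").
#' @export
association_test <- function(bound, membership, gene_lengths) {
  bound <- as.integer(bound); membership <- as.integer(membership)
  stopifnot(length(bound) == length(membership),
            length(bound) == length(gene_lengths), all(gene_lengths > 0))
  if (length(unique(bound)) < 2L) stop("bound indicator has no variation")
  if (sum(membership) < 2L || sum(1 - membership) < 2L)
    stop("need >= 2 genes inside and outside the set")
  df <- data.frame(bound = bound, member = membership,
                   loglen = log10(gene_lengths))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(bound ~ member + loglen, family = stats::binomial(),
               data = df, control = stats::glm.control(epsilon = 1e-8,
                                                       maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)[["member"]]
  se <- sqrt(diag(stats::vcov(fit)))[["member"]]
  if ((sep_warn && abs(b) > 10) || abs(b) > 15 || se > 100) {
    return(list(beta = b, se = se, z = NA_real_, p = NA_real_,
                status = "separation"))
  }
  z <- b / se
  list(beta = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)), status = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; order preserved.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Category-by-gene-set association matrix
#'
#' For every binding category, genes are marked bound by nearest-TSS
#' assignment of that category's peaks; every (category, gene set) pair is
#' tested with [association_test()] and the whole report is BH-adjusted as
#' one family.
#'
#' @param site_table data.table with `chrom`, `summit` and `label` columns
#'   (e.g. `classify_sites()$sites`).
#' @param gene_sets Named list of member-gene vectors
#'   (from [build_gene_sets()]).
#' @param gene_models data.table `gene`, `chrom`, `tss`, `length`.
#' @param categories Category labels to test (default: all labels except
#'   "unclassified/minor").
#' @return data.table: `category`, `gene_set`, `beta`, `se`, `p`, `padj`,
#'   `status`.
#' @export
association_matrix <- function(site_table, gene_sets, gene_models,
                               categories = NULL) {
  site_table <- data.table::as.data.table(site_table)
  gm <- data.table::as.data.table(gene_models)
  if (is.null(categories))
    categories <- setdiff(sort(unique(site_table$label)),
                          "unclassified/minor")
  rows <- list()
  for (cat in categories) {
    peaks <- site_table[label == cat]
    if (nrow(peaks) == 0L) next
    bound_genes <- suppressWarnings(
      assign_peaks_to_genes(peaks, gm)$bound_genes)
    bound <- gm$gene %in% bound_genes
    for (set_name in names(gene_sets)) {
      member <- gm$gene %in% gene_sets[[set_name]]
      res <- if (sum(member) < 2L || sum(!member) < 2L || !any(bound) ||
                 all(bound)) {
        list(beta = NA_real_, se = NA_real_, p = NA_real_, status = "skipped")
      } else association_test(bound, member, gm$length)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        category = cat, gene_set = set_name, beta = res$beta, se = res$se,
        p = res$p, status = res$status)
    }
  }
  out <- data.table::rbindlist(rows)
  out[, padj := NA_real_]
  ok <- !is.na(out$p)
  out$padj[ok] <- bh_adjust(out$p[ok])
  out[]
}
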