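make_records <- function(rows) {
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(gene = r[[1]], contrast = r[[2]],
                           lfc = as.numeric(r[[3]]),
                           padj = as.numeric(r[[4]]))))
}

full_contrasts <- function(gene, base_lfc, base_p, pair_lfc, pair_p) {
  make_records(list(
    list(gene, "A_vs_progenitor", base_lfc[1], base_p[1]),
    list(gene, "B_vs_progenitor", base_lfc[2], base_p[2]),
    list(gene, "C_vs_progenitor", base_lfc[3], base_p[3]),
    list(gene, "A_vs_B", pair_lfc[1], pair_p[1]),
    list(gene, "A_vs_C", pair_lfc[2], pair_p[2]),
    list(gene, "B_vs_C", pair_lfc[3], pair_p[3])))
}

test_that("gene-set rules match their definitions", {
  rec <- rbind(
    # up in all three baselines, flat between TFs -> shared-up
    full_contrasts("g1", c(3, 3, 3), c(0.001, 0.001, 0.001),
                   c(0.5, -0.5, 0.2), c(0.5, 0.5, 0.5)),
    # up only in A, higher than B and C -> A-up
    full_contrasts("g2", c(4, 0, 0), c(1e-5, 0.9, 0.9),
                   c(4, 4, 0), c(1e-5, 1e-5, 0.9)),
    # strong LFC but insignificant padj -> unassigned
    full_contrasts("g3", c(3, 3, 3), c(0.5, 0.5, 0.5),
                   c(0, 0, 0), c(0.9, 0.9, 0.9)),
    # up in A and B over C, flat between A and B -> A,B-up
    full_contrasts("g4", c(3, 3, 0), c(1e-4, 1e-4, 0.9),
                   c(0.3, 3, 3), c(0.8, 1e-4, 1e-4)),
    # down in A relative to both others -> A-down
    full_contrasts("g5", c(0, 3, 3), c(0.9, 1e-4, 1e-4),
                   c(-3, -3, 0.1), c(1e-4, 1e-4, 0.8)))
  sets <- build_gene_sets(rec, c("A", "B", "C"))
  expect_equal(sets[["shared-up"]], "g1")
  expect_equal(sets[["A-up"]], "g2")
  expect_false("g3" %in% unlist(sets))
  expect_equal(sets[["A,B-up"]], "g4")
  expect_equal(sets[["A-down"]], "g5")
  # same-direction sets are disjoint
  up <- sets[grep("-up$", names(sets))]
  expect_equal(anyDuplicated(unlist(up)), 0L)

  # permuting record order never changes assignments
  set.seed(100)
  rec2 <- rec[sample(nrow(rec))]
  expect_identical(build_gene_sets(rec2, c("A", "B", "C")), sets)

  # missing contrast errors by name
  expect_error(build_gene_sets(rec[contrast != "B_vs_C"], c("A", "B", "C")),
               "B_vs_C")
})

test_that("peaks map to nearest TSS with deterministic tie-breaking", {
  gm <- data.table::data.table(
    gene = c("gB", "gA"), chrom = "c1", tss = c(1000L, 2000L),
    length = c(500L, 800L))
  # single gene on chromosome gets everything
  one <- assign_peaks_to_genes(
    data.table::data.table(chrom = "c1", summit = c(10L, 5000L)),
    gm[1])
  expect_equal(one$assignment$gene, c("gB", "gB"))
  # equidistant peak: lexicographically smaller id wins
  tie <- assign_peaks_to_genes(
    data.table::data.table(chrom = "c1", summit = 1500L), gm)
  expect_equal(tie$assignment$gene, "gA")
  # peaks on chromosomes without genes are skipped with a warning
  expect_warning(
    sk <- assign_peaks_to_genes(
      data.table::data.table(chrom = c("c1", "c9"), summit = c(999L, 5L)),
      gm),
    "skipped")
  expect_equal(sk$assignment$gene, "gB")

  # all-pairs brute-force oracle on random peaks/genes
  set.seed(101)
  gm2 <- data.table::data.table(
    gene = sprintf("g%03d", 1:200),
    chrom = sample(c("c1", "c2"), 200L, TRUE),
    tss = sample.int(1e6, 200L), length = 1000L)
  pk <- data.table::data.table(chrom = sample(c("c1", "c2"), 500L, TRUE),
                               summit = sample.int(1e6, 500L))
  got <- assign_peaks_to_genes(pk, gm2)$assignment
  for (i in seq_len(nrow(got))) {
    cand <- gm2[chrom == pk$chrom[got$peak[i]]]
    dmin <- min(abs(cand$tss - pk$summit[got$peak[i]]))
    best <- sort(cand$gene[abs(cand$tss - pk$summit[got$peak[i]]) == dmin])[1]
    expect_equal(got$gene[i], best)
  }
})

test_that("association test recovers planted effects and flags separation", {
  set.seed(102)
  n <- 4000L
  len <- pmax(200L, round(10^rnorm(n, 3.4, 0.35)))
  member <- rbinom(n, 1L, 0.25)
  eta <- -1.2 + log(3) * member + 0.5 * (log10(len) - 3.4)
  bound <- rbinom(n, 1L, plogis(eta))
  res <- association_test(bound, member, len)
  expect_equal(res$status, "ok")
  expect_lt(abs(res$beta - log(3)), 0.3)
  expect_lt(res$p, 1e-6)

  # perfect separation
  sep <- association_test(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0),
                          c(1000, 2000, 1500, 900, 800, 1200))
  expect_equal(sep$status, "separation")
  expect_true(is.na(sep$p))

  expect_error(association_test(rep(1L, 10L), rbinom(10, 1, 0.5),
                                rep(1000, 10)), "variation")
})

test_that("length confounding is absorbed by the length covariate", {
  set.seed(103)
  n <- 6000L
  len <- pmax(200L, round(10^rnorm(n, 3.4, 0.35)))
  # membership correlates with length; binding depends on length only
  member <- rbinom(n, 1L, plogis(2 * (log10(len) - 3.4)))
  bound <- rbinom(n, 1L, plogis(-1 + 1.5 * (log10(len) - 3.4)))
  with_len <- association_test(bound, member, len)$beta
  no_len <- coef(glm(bound ~ member, family = binomial()))[["member"]]
  expect_lt(abs(with_len), abs(no_len))
})

test_that("BH adjustment equals the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  # reference oracle: explicit step-up with monotone enforcement
  step_up <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * n / (n:1)))[ro]
  }
  set.seed(104)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("category-by-set association peaks on the matching diagonal", {
  scen <- small_scenario()
  ec <- small_event_config()
  ev <- lapply(scen$chip, function(l)
    call_events(l, scen$input, scen$genome, ec))
  cls <- classify_sites(ev, scen$chip, scen$input, scen$genome, ec)
  sets <- build_gene_sets(scen$expression$records, c("A", "B", "C"))
  assoc <- association_matrix(cls$sites, sets, scen$expression$genes)
  match_set <- c("A=B=C" = "shared-up", "A>B,C" = "A-up", "B>A,C" = "B-up",
                 "C>A,B" = "C-up", "A,B>C" = "A,B-up", "B,C>A" = "B,C-up")
  for (cat in intersect(names(match_set), unique(assoc$category))) {
    rows <- assoc[category == cat & !is.na(padj)]
    # the matching set attains the minimum adjusted p (ties allowed: a
    # two-of-three up set is extensionally identical to the opposite
    # one-of-three down set, both defined from the same pairwise contrasts)
    expect_lte(rows[gene_set == match_set[cat], padj],
               min(rows$padj) + 1e-12)
    expect_gt(rows[gene_set == match_set[cat], beta], 0)
  }
})
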