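test_that("genome generation is seeded and matches its composition", {
  cfg <- list(n_chrom = 1L, chrom_length = 1e5,
              composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  g1 <- generate_genome(cfg, seed = 3L)
  g2 <- generate_genome(cfg, seed = 3L)
  expect_identical(g1$seq, g2$seq)
  freq <- table(strsplit(g1$seq[[1]], "")[[1]]) / 1e5
  expect_true(all(abs(freq - 0.25) < 0.01))

  cfg$composition <- c(A = 1, C = 0, G = 0, T = 0)
  cfg$chrom_length <- 1e4
  gA <- generate_genome(cfg, seed = 1L)
  expect_equal(gA$seq[[1]], strrep("A", 1e4))

  cfg$composition <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generate_genome(cfg), "composition")
  expect_error(generate_genome(list(n_chrom = 1, chrom_length = 100,
                                    composition = c(0.25, 0.25, 0.25, 0.25))),
               "10 kb")
})

test_that("planted landscape honors configured counts, flags and capacity", {
  cfg <- mini_truth_config(label = c("A=B=C", "B>A,C"),
                           motif = c("pan", "posterior"),
                           n_sites = c(100L, 100L),
                           accessible_fraction = c(1, 0),
                           chrom_length = 1e6)
  g <- generate_genome(cfg$genome, seed = 2L)
  pl <- plant_landscape(g, cfg, seed = 2L)
  tr <- pl$truth
  expect_equal(as.integer(table(tr$sites$category)[c("A=B=C", "B>A,C")]),
               c(100L, 100L))
  expect_true(all(tr$sites[category == "A=B=C", accessible]))
  expect_false(any(tr$sites[category == "B>A,C", accessible]))
  # lambda = affinity * (1 or pioneer_index)
  expect_equal(unique(tr$lambda[tr$sites$category == "A=B=C", "B"]), 1)
  expect_equal(unique(tr$lambda[tr$sites$category == "B>A,C", "B"]), 0.9)
  expect_equal(unique(tr$lambda[tr$sites$category == "B>A,C", "C"]), 0.1)

  # capacity error when sites cannot fit at the spacing
  cfg2 <- mini_truth_config(n_sites = 1000L, chrom_length = 1e6)
  expect_error(plant_landscape(generate_genome(cfg2$genome, 1L), cfg2,
                               seed = 1L),
               "capacity")

  # zero sites: genome unchanged, empty truth
  cfg3 <- mini_truth_config(n_sites = 0L)
  g3 <- generate_genome(cfg3$genome, seed = 4L)
  pl3 <- plant_landscape(g3, cfg3, seed = 4L)
  expect_identical(pl3$genome$seq, g3$seq)
  expect_equal(nrow(pl3$truth$sites), 0L)
})

test_that("truth accessibility flags agree exactly with truth domains", {
  tr <- small_scenario()$truth
  frac_acc <- fraction_in_domains(
    tr$sites[accessible == TRUE, .(chrom, summit = pos)], tr$domains)
  frac_inacc <- fraction_in_domains(
    tr$sites[accessible == FALSE, .(chrom, summit = pos)], tr$domains)
  expect_equal(frac_acc, 1)
  expect_equal(frac_inacc, 0)
})

test_that("planted motif instances score above the calibrated threshold", {
  # exact-consensus planting: every site must carry a hit
  cfg <- mini_truth_config(label = "B>A,C", motif = "posterior",
                           n_sites = 100L, accessible_fraction = 0,
                           chrom_length = 1e6)
  cfg$motifs$posterior <- motif_model("posterior", consensus = "TTTATGG",
                                      fidelity = 1)
  g <- generate_genome(cfg$genome, seed = 5L)
  pl <- plant_landscape(g, cfg, seed = 5L)
  bg <- train_background(pl$genome, order = 2L)
  mm <- cfg$motifs$posterior
  qseq <- sample_sequences(bg, 1000L, 100L, seed = 6L)
  at <- (100L - mm$width) %/% 2L
  qseq <- paste0(substr(qseq, 1L, at), mm$consensus,
                 substr(qseq, at + mm$width + 1L, 100L))
  sm <- calibrate_threshold(score_motif(mm, bg), qseq,
                            sample_sequences(bg, 20000L, 100L, seed = 7L))
  ph <- peaks_with_hits(pl$truth$sites[, .(chrom, summit = pos)],
                        pl$genome, sm, within = 50L)
  expect_true(all(ph$flagged))

  # default-fidelity planting (0.995/position): a small mutation load is
  # expected, but the vast majority of sites remain above threshold
  scen <- small_scenario()
  bg2 <- train_background(scen$genome, order = 2L)
  mm2 <- scen$config$motifs$posterior
  sm2 <- calibrate_threshold(score_motif(mm2, bg2), qseq,
                             sample_sequences(bg2, 20000L, 100L, seed = 8L))
  sites <- scen$truth$sites[motif == "posterior"]
  ph2 <- peaks_with_hits(sites[, .(chrom, summit = pos)], scen$genome, sm2,
                         within = 50L)
  expect_gt(mean(ph2$flagged), 0.9)
})

test_that("ChIP simulation respects occupancy, pioneer dial and bookkeeping", {
  cfg <- mini_truth_config(label = c("open", "closed"),
                           motif = c("pan", "posterior"),
                           n_sites = c(100L, 200L),
                           accessible_fraction = c(1, 0),
                           chrom_length = 2e6)
  g <- generate_genome(cfg$genome, seed = 6L)
  pl <- plant_landscape(g, cfg, seed = 6L)

  # phi = 0: deterministic counts, totals exact
  libs <- simulate_chip(pl$truth, pl$genome, "A", depth = 1e5,
                        n_replicates = 2L, phi = 0, bg_fraction = 0.5,
                        seed = 7L)
  expect_equal(length(libs), 2L)
  mu <- pl$truth$lambda[, "A"] * 5e4 / sum(pl$truth$lambda[, "A"])
  expect_equal(vapply(libs, function(l) l$total, 0),
               rep(sum(round(mu)) + 5e4, 2L))

  # pioneer index scales occupancy at inaccessible sites monotonically
  closed <- pl$truth$sites$category == "closed"
  mean_closed <- function(pi_b) {
    tf2 <- cfg$tf_specs$B
    tf2$pioneer_index <- pi_b
    tr2 <- pl$truth
    tr2$lambda[, "B"] <- tf2$affinity[tr2$sites$motif] *
      ifelse(tr2$sites$accessible, 1, pi_b)
    lib <- simulate_chip(tr2, pl$genome, "B", depth = 2e5,
                         n_replicates = 1L, phi = 0.1, bg_fraction = 0.2,
                         seed = 8L)[[1]]
    mean(.count_sites(lib, tr2$sites[closed]))
  }
  .count_sites <- function(lib, s) {
    vapply(seq_len(nrow(s)), function(i)
      count_in_window(lib, s$chrom[i], s$pos[i] - 100L, s$pos[i] + 100L),
      0L)
  }
  m <- vapply(c(0, 0.25, 0.5, 1), mean_closed, 0)
  expect_true(all(diff(m) > 0))
  # pi = 0 leaves only uniform background at closed sites
  expect_lt(m[1], 0.2 * 2e5 * 200 / 2e6 * 1.5)

  # identical seeds give byte-identical BED output
  l1 <- simulate_chip(pl$truth, pl$genome, "A", depth = 5e4, seed = 9L)[[1]]
  l2 <- simulate_chip(pl$truth, pl$genome, "A", depth = 5e4, seed = 9L)[[1]]
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_tags(l1, p1); write_tags(l2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pioneer ratio at inaccessible sites follows pi within 3 SE", {
  # equal-affinity TF at open and closed sites: the closed/open count ratio
  # equals pi, so comparing pi = 1.0 vs pi = 0.1 must give a 10x contrast
  # (normalizing by the open sites cancels the per-library depth scale)
  cfg <- mini_truth_config(label = c("open", "closed"),
                           motif = c("posterior", "posterior2"),
                           n_sites = c(200L, 200L),
                           accessible_fraction = c(1, 0),
                           chrom_length = 2e6)
  cfg$motifs$posterior2 <- motif_model("posterior2", consensus = "TTTATGA")
  g <- generate_genome(cfg$genome, seed = 10L)
  pl <- plant_landscape(g, cfg, seed = 10L)
  rel_closed <- function(pi_x, seed) {
    tr <- pl$truth
    tr$lambda[, "B"] <- ifelse(tr$sites$accessible, 1, pi_x)
    lib <- simulate_chip(tr, pl$genome, "B", depth = 4e5, n_replicates = 1L,
                         phi = 0.1, bg_fraction = 0.1, seed = seed)[[1]]
    s <- tr$sites
    cnt <- vapply(seq_len(nrow(s)), function(i)
      count_in_window(lib, s$chrom[i], s$pos[i] - 100L, s$pos[i] + 100L), 0L)
    bg <- 0.1 * 4e5 * 200 / 2e6
    closed <- cnt[s$category == "closed"] - bg
    open <- cnt[s$category == "open"] - bg
    list(r = mean(closed) / mean(open),
         se = mean(closed) / mean(open) *
           sqrt(var(closed) / (200 * mean(closed)^2) +
                var(open) / (200 * mean(open)^2)))
  }
  hi <- rel_closed(1.0, 11L)
  lo <- rel_closed(0.1, 12L)
  ratio <- hi$r / lo$r
  se <- ratio * sqrt((hi$se / hi$r)^2 + (lo$se / lo$r)^2)
  expect_lt(abs(ratio - 10), 3 * se)
})

test_that("ATAC simulation: domain enrichment, post-mode null, zero depth", {
  scen <- small_scenario()
  tr <- scen$truth
  lib <- scen$atac_prior[[1]]
  dom <- tr$domains
  dom_len <- sum(dom$end - dom$start)
  genome_len <- sum(as.numeric(scen$genome$lengths))
  n_in <- sum(vapply(seq_len(nrow(dom)), function(i)
    count_in_window(lib, dom$chrom[i], dom$start[i], dom$end[i]), 0L))
  rate_in <- n_in / dom_len
  rate_out <- (lib$total - n_in) / (genome_len - dom_len)
  expect_gt(rate_in / rate_out, 7)
  expect_lt(rate_in / rate_out, 13)

  # post mode with zero opener strength reproduces prior mode
  tfs0 <- lapply(scen$config$tf_specs, function(tf) {
    tf$opener_strength <- 0; tf })
  post0 <- simulate_atac(tr, scen$genome, tfs0, depth = 1e5,
                         n_replicates = 1L, mode = "post", seed = 13L)
  prior <- simulate_atac(tr, scen$genome, NULL, depth = 1e5,
                         n_replicates = 1L, mode = "prior", seed = 13L)
  expect_identical(post0[[1]]$tags, prior[[1]]$tags)

  z <- simulate_atac(tr, scen$genome, NULL, depth = 0, n_replicates = 2L,
                     seed = 14L)
  expect_equal(vapply(z, function(l) l$total, 0), c(0, 0))
})

test_that("expression simulation plants patterns and keeps nulls null", {
  scen <- small_scenario()
  ex <- scen$expression
  # seed determinism
  ex2 <- simulate_expression(scen$truth, scen$genome,
                             n_genes = scen$config$expression$n_genes,
                             effect_lfc = scen$config$expression$effect_lfc,
                             seed = scen$config$seed + 40L)
  expect_identical(ex$records, ex2$records)

  # a gene planted near a shared site satisfies the shared-upregulated rule
  sets <- build_gene_sets(ex$records, c("A", "B", "C"))
  planted_shared <- ex$truth_sets[planted_set == "shared-up", gene]
  expect_gt(length(planted_shared), 5L)
  expect_true(all(planted_shared %in% sets[["shared-up"]]))

  # null genes pass padj < 0.01 at about the uniform rate
  nulls <- ex$truth_sets[is.na(planted_set), gene]
  nr <- ex$records[gene %in% nulls]
  expect_lt(mean(nr$padj < 0.01), 0.02)
})
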