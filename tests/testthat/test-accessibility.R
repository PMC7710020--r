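test_that("domain calling: null, planted block, merge rule", {
  g <- random_genome(1e6, seed = 50L)
  # uniform coverage: no domains
  n_dom <- 0L
  for (s in 1:3) {
    lib <- random_tags(g, 2e4, seed = 50L + s)
    n_dom <- n_dom + nrow(call_domains(list(lib), g))
  }
  expect_equal(n_dom, 0L)

  # one 2 kb block at 10x background: exactly one domain, tight boundaries
  set.seed(54)
  block <- data.table::data.table(
    chrom = "chr1", pos = sample(500000:501999, 400L, TRUE), strand = "+")
  lib <- tag_library(rbind(random_tags(g, 2e4, seed = 55L)$tags, block),
                     genome = g)
  d <- call_domains(list(lib), g, bin = 50L)
  expect_equal(nrow(d), 1L)
  expect_lte(abs(d$start - 500000), 100L)
  expect_lte(abs(d$end - 502000), 100L)

  # two blocks separated by more than the merge gap stay separate
  block2 <- data.table::data.table(
    chrom = "chr1", pos = c(sample(700000:700999, 250L, TRUE),
                            sample(703000:703999, 250L, TRUE)),
    strand = "+")
  lib2 <- tag_library(rbind(random_tags(g, 2e4, seed = 56L)$tags, block2),
                      genome = g)
  d2 <- call_domains(list(lib2), g)
  expect_equal(nrow(d2), 2L)
  expect_equal(nrow(call_domains(list(tag_library(NULL)), g)), 0L)
})

test_that("site densities are per-million normalized window counts", {
  g <- random_genome(1e5, seed = 57L)
  lib <- random_tags(g, 5000L, seed = 58L)
  sites <- data.table::data.table(chrom = "chr1",
                                  summit = as.integer(seq(2000, 98000,
                                                          length.out = 50)))
  sd <- site_density(sites, list(lib), window = 2000L)
  # linear-scan oracle
  oracle <- vapply(sites$summit, function(s)
    sum(lib$tags$pos >= s - 1000 & lib$tags$pos < s + 1000), 0L)
  expect_equal(sd$densities$density, oracle * 1e6 / lib$total)

  # duplicating every tag leaves densities unchanged
  lib2 <- tag_library(rbind(lib$tags, lib$tags))
  sd2 <- site_density(sites, list(lib2), window = 2000L)
  expect_equal(sd2$densities$density, sd$densities$density)

  # empty window: zero density; quartile summary ordered
  far <- data.table::data.table(chrom = "chr1", summit = 1000L)
  lib3 <- tag_library(data.table::data.table(chrom = "chr1", pos = 90000L,
                                             strand = "+"), genome = g)
  expect_equal(site_density(far, list(lib3))$densities$density, 0)
  qs <- sd$summary
  expect_true(qs$min <= qs$q1 && qs$q1 <= qs$median &&
              qs$median <= qs$q3 && qs$q3 <= qs$max)
  expect_equal(qs$n, 50L)
})

test_that("fraction_in_domains uses point membership", {
  dom <- data.table::data.table(chrom = "c1", start = 100L, end = 200L)
  sites <- data.table::data.table(chrom = "c1",
                                  summit = c(99L, 100L, 150L, 199L, 200L))
  expect_equal(fraction_in_domains(sites, dom), 3 / 5)
  expect_equal(fraction_in_domains(sites, dom[0]), 0)
  expect_equal(fraction_in_domains(sites,
    data.table::data.table(chrom = "c1", start = 0L, end = 1000L)), 1)
})

test_that("composite profiles do exact base-overlap bookkeeping", {
  g <- genome(c(c1 = strrep("A", 20000L)))
  set.seed(59)
  lib <- tag_library(data.table::data.table(
    chrom = "c1", pos = sample(0:19999, 2000L, TRUE),
    strand = sample(c("+", "-"), 2000L, TRUE)), genome = g)
  sites <- data.table::data.table(chrom = "c1",
                                  summit = c(5000L, 9000L, 15000L))
  cp <- composite_profile(sites, list(lib), half_window = 1000L,
                          extend = 100L)
  expect_equal(length(cp$density), 2000L)
  expect_true(all(cp$density >= 0))
  # conservation: raw overlap equals brute-force extended-read overlap
  ext <- extend_tags(lib, g, 100L)
  tot <- 0
  for (s in sites$summit) {
    a <- pmax(ext$start, s - 1000L); b <- pmin(ext$end, s + 1000L)
    tot <- tot + sum(pmax(b - a, 0L))
  }
  expect_equal(cp$raw_overlap[1], tot)
  # normalized scale: sum * n_sites/1000 * total/1e6 recovers the raw overlap
  expect_equal(sum(cp$per_replicate[, 1]) * (nrow(sites) / 1000) *
                 (lib$total / 1e6), tot)

  # single + read at offset -10 covers [-10, 89] at 1e6/total * 1000/n
  one <- tag_library(data.table::data.table(chrom = "c1", pos = 4990L,
                                            strand = "+"), genome = g)
  cp1 <- composite_profile(data.table::data.table(chrom = "c1",
                                                  summit = 5000L),
                           list(one), 1000L, 100L)
  on <- which(cp1$density > 0)
  expect_equal(cp1$offsets[range(on)], c(-10L, 89L))
  expect_equal(unique(cp1$density[on]), 1e6 / 1 * 1000 / 1)

  # translation invariance
  g2 <- genome(c(c1 = strrep("A", 26000L)))
  lib2 <- tag_library(data.table::copy(lib$tags)[, pos := pos + 5000L],
                      genome = g2)
  cp2 <- composite_profile(
    data.table::data.table(chrom = "c1", summit = sites$summit + 5000L),
    list(lib2), 1000L, 100L)
  expect_equal(cp2$density, cp$density)

  # zero-tag library gives a zero profile
  cp0 <- composite_profile(sites, list(tag_library(NULL)), 1000L, 100L)
  expect_true(all(cp0$density == 0))
})

test_that("accessibility change is zero for identical conditions", {
  g <- random_genome(1e5, seed = 60L)
  lib <- random_tags(g, 3000L, seed = 61L)
  sites <- data.table::data.table(chrom = "chr1",
                                  summit = c(20000L, 50000L, 80000L),
                                  category = c("x", "x", "y"))
  ch <- accessibility_change(sites, list(lib), list(lib))
  expect_true(all(ch$per_site$delta == 0))
  expect_equal(ch$by_category$mean_delta, c(0, 0))
  expect_error(accessibility_change(sites, list(lib), list(lib), window = 0),
               "window")
})

test_that("planted opener effect separates bound from control sites", {
  scen <- small_scenario()
  tr <- scen$truth
  bs <- tr$sites[category == "B>A,C", .(chrom, summit = pos,
                                        category = "bound")]
  cs <- tr$control_sites[, .(chrom, summit = pos, category = "control")]
  ch <- accessibility_change(rbind(bs, cs), scen$atac_prior, scen$atac_post)
  d <- ch$by_category
  sep <- (d[category == "bound", mean_delta] -
            d[category == "control", mean_delta]) /
    sqrt(d[category == "bound", se_delta]^2 +
           d[category == "control", se_delta]^2)
  expect_gt(sep, 3)
})
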