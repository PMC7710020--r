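test_that("consensus score on a uniform background has its closed form", {
  mm <- motif_model("m", consensus = "TTAATT", fidelity = 0.95)
  sm <- score_motif(mm, rep(0.25, 4), pseudocount = 0)
  sc <- scan_pwm(mm$consensus, sm, both_strands = FALSE)
  expect_equal(sc$score, 6 * log2(4 * 0.95), tolerance = 1e-12)
})

test_that("scanning the reverse complement gives the same best score", {
  g <- random_genome(20000L, seed = 80L)
  bg <- train_background(g, order = 2L)
  sm <- score_motif(default_motif_models()$posterior, bg)
  set.seed(81)
  seqs <- sample_sequences(bg, 20L, 200L)
  rc <- vapply(seqs, function(s) {
    r <- rev(charToRaw(chartr("ACGT", "TGCA", s))); rawToChar(r)
  }, "", USE.NAMES = FALSE)
  expect_equal(scan_max_scores(rc, sm), scan_max_scores(seqs, sm))
})

test_that("window scores match an independent per-position rescorer", {
  g <- random_genome(30000L, seed = 82L)
  bg <- train_background(g, order = 2L)
  for (mm in default_motif_models()[c("anterior", "posterior")]) {
    sm <- score_motif(mm, bg)
    w <- mm$width
    seqs <- sample_sequences(bg, 10L, 300L, seed = 83L)
    for (s in seqs) {
      sc <- scan_pwm(s, sm)
      code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T", "N"))
      nw <- 300L - w + 1L
      brute_f <- vapply(seq_len(nw), function(i)
        sum(sm$lodds[cbind(seq_len(w), code[i:(i + w - 1)])]), 0)
      brute_r <- vapply(seq_len(nw), function(i)
        sum(sm$lodds_rc[cbind(seq_len(w), code[i:(i + w - 1)])]), 0)
      expect_equal(sc[strand == "+"][order(start), score], brute_f,
                   tolerance = 1e-9)
      expect_equal(sc[strand == "-"][order(start), score], brute_r,
                   tolerance = 1e-9)
    }
  }
})

test_that("N bases poison windows and short sequences scan empty", {
  mm <- motif_model("m", consensus = "TTAATT")
  sm <- score_motif(mm, rep(0.25, 4))
  sc <- scan_pwm("TTANTTAATT", sm, both_strands = FALSE)
  expect_equal(sc$score[1:4], rep(-Inf, 4))  # windows touching the N
  expect_gt(sc$score[5], 0)
  expect_equal(nrow(scan_pwm("ACG", sm)), 0L)
})

test_that("FDR calibration admits planted queries and rejects null queries", {
  g <- random_genome(2e5, seed = 84L)
  bg <- train_background(g, order = 2L)
  mm <- default_motif_models()$posterior
  nulls <- sample_sequences(bg, 30000L, 100L, seed = 85L)

  # planted-consensus query: high admission, realized ratio <= target
  qseq <- sample_sequences(bg, 1000L, 100L, seed = 86L)
  at <- (100L - mm$width) %/% 2L
  qseq <- paste0(substr(qseq, 1L, at), mm$consensus,
                 substr(qseq, at + mm$width + 1L, 100L))
  sm <- calibrate_threshold(score_motif(mm, bg), qseq, nulls,
                            fdr_target = 0.1)
  expect_equal(sm$calibration$status, "ok")
  expect_gte(sm$calibration$query_rate, 0.99)
  expect_lte(sm$calibration$realized_ratio, 0.1)

  # raising the target never raises the threshold
  sm2 <- calibrate_threshold(score_motif(mm, bg), qseq, nulls,
                             fdr_target = 0.3)
  expect_lte(sm2$threshold, sm$threshold)

  # query from the null distribution: no discriminative threshold
  qnull <- sample_sequences(bg, 1000L, 100L, seed = 87L)
  smn <- calibrate_threshold(score_motif(mm, bg), qnull, nulls)
  expect_equal(smn$calibration$status, "no_discriminative_threshold")
  expect_true(is.na(smn$threshold))

  expect_error(calibrate_threshold(sm, character(0), nulls), "query")
})

test_that("peak flagging respects the offset window and N genomes", {
  mm <- default_motif_models()$posterior
  gN <- genome(c(c1 = strrep("N", 1000L)))
  gM <- genome(c(c1 = paste0(strrep("A", 300L), mm$consensus,
                             strrep("A", 293L))))
  bgu <- rep(0.25, 4)
  sm <- score_motif(mm, bgu)
  sm$threshold <- 5
  # motif starts at 300: offset +60 from summit 240 -> not flagged;
  # offset +50 from summit 250 -> flagged
  p1 <- peaks_with_hits(data.table::data.table(chrom = "c1", summit = 240L),
                        gM, sm, within = 50L)
  p2 <- peaks_with_hits(data.table::data.table(chrom = "c1", summit = 250L),
                        gM, sm, within = 50L)
  expect_false(p1$flagged); expect_true(p2$flagged)
  expect_equal(p2$hits$offset, 50L)
  # all-N genome: no flags
  pN <- peaks_with_hits(data.table::data.table(chrom = "c1",
                                               summit = c(300L, 700L)),
                        gN, sm, within = 50L)
  expect_false(any(pN$flagged))
  # uncalibrated motif is an error
  sm0 <- score_motif(mm, bgu)
  expect_error(peaks_with_hits(data.table::data.table(chrom = "c1",
                                                      summit = 300L),
                               gM, sm0), "threshold")
})

test_that("over-representation ratio and Fisher p behave as expected", {
  g <- random_genome(1e5, seed = 88L)
  mm <- default_motif_models()$anterior
  sm <- score_motif(mm, rep(0.25, 4))
  sm$threshold <- 100  # nothing can hit: background rate 0
  ov <- overrepresentation(rep(c(TRUE, FALSE), c(5L, 95L)), g, sm,
                           n_background = 200L, seed = 89L)
  expect_equal(ov$rate_background, 0)
  expect_equal(ov$ratio, Inf)

  # hypergeometric enumeration oracle for the 2x2 p-value (30/100 vs 5/100)
  sm$threshold <- -1000  # every window hits
  ovA <- overrepresentation(rep(c(TRUE, FALSE), c(30L, 70L)), g, sm,
                            n_background = 100L, seed = 90L)
  expect_equal(ovA$rate_background, 1)
  tab_p <- fisher.test(matrix(c(30L, 70L, 100L, 0L), 2L))$p.value
  hyper <- function(a, b, c_, d) {
    # two-sided Fisher by enumeration over the a-margin
    n <- a + b; m <- a + c_; N <- a + b + c_ + d
    lo <- max(0L, m - (N - n)); hi <- min(m, n)
    probs <- dhyper(lo:hi, n, N - n, m)
    sum(probs[probs <= dhyper(a, n, N - n, m) * (1 + 1e-7)])
  }
  expect_equal(tab_p, hyper(30L, 70L, 100L, 0L), tolerance = 1e-10)
  expect_equal(ovA$p, tab_p)
  # query rate equal to background rate: ratio 1, p ~ 1
  expect_equal(ovA$ratio, 30 / 100 / 1)
})

test_that("hit-offset histograms conserve counts and center on the truth", {
  hits <- data.table::data.table(offset = rep(0L, 10L))
  h <- hit_position_histogram(hits, half_window = 50L, bin = 10L)
  expect_equal(sum(h$count), 10L)
  expect_equal(h[count > 0, bin_start], 0L)

  set.seed(91)
  hits2 <- data.table::data.table(offset = as.integer(round(rnorm(2000, 0,
                                                                  20))))
  h2 <- hit_position_histogram(hits2, half_window = 250L, bin = 10L)
  expect_equal(sum(h2$count), sum(abs(hits2$offset + 0.5) <= 250))
  mode_bin <- h2$bin_start[which.max(h2$count)]
  expect_lte(abs(mode_bin + 5), 15)  # mode within one bin of zero
})

test_that("MEME minimal format round-trips motif models", {
  mods <- default_motif_models()[c("anterior", "posterior")]
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(mods, path)
  back <- read_meme(path)
  expect_equal(names(back), names(mods))
  for (nm in names(mods))
    expect_equal(back[[nm]]$prob, mods[[nm]]$prob, tolerance = 1e-4)
})
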