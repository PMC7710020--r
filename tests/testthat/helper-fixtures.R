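# Shared fixtures: tiny genomes, tag libraries and reduced scenarios built in
# code at test time.

random_genome <- function(len = 50000L, n_chrom = 1L, seed = 1L,
                          comp = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = comp),
          collapse = ""), character(1L))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome(seqs)
}

random_tags <- function(g, n, seed = 1L, ...) {
  set.seed(seed)
  cn <- sample(g$chroms, n, replace = TRUE, prob = as.numeric(g$lengths))
  tag_library(data.table::data.table(
    chrom = cn,
    pos = as.integer(floor(runif(n) * g$lengths[cn])),
    strand = sample(c("+", "-"), n, replace = TRUE)), genome = g, ...)
}

# a scaled-down scenario shared by unit tests (cached per test run)
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_landscape_config(
        n_chrom = 2L, chrom_length = 1.5e6, sites_per_category = 60L,
        depth = 3e5, seed = 7L)
      cache <<- simulate_scenario(cfg)
    }
    cache
  }
})

small_event_config <- function() event_config(min_category = 40L)

# single-category truth object for targeted generator tests
mini_truth_config <- function(label = "A>B,C", motif = "anterior",
                              n_sites = 1L, accessible_fraction = 1,
                              n_chrom = 1L, chrom_length = 2e5) {
  cfg <- default_landscape_config(n_chrom = n_chrom,
                                  chrom_length = chrom_length)
  cfg$categories <- data.table::data.table(
    label = label, motif = motif, n_sites = as.integer(n_sites),
    accessible_fraction = accessible_fraction)
  cfg$n_decoy_domains <- 0L
  cfg
}

# brute-force single-linkage clustering of points within radius (quadratic)
brute_single_linkage <- function(pos, radius) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= radius && grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}
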