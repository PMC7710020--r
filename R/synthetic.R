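# Synthetic-data generator: genomes, planted binding landscapes with known
# truth, and ChIP/ATAC/expression libraries emulating a multi-TF induction
# study in which factors share motifs but differ in their ability to occupy
# inaccessible chromatin.

#' Construct a transcription-factor specification
#'
#' @param name TF name.
#' @param affinity Named numeric vector: relative occupancy rate per motif
#'   name (>= 0, at least one positive).
#' @param pioneer_index pi in `[0, 1]`: multiplier applied to occupancy at
#'   inaccessible sites (1 = full pioneer, 0 = cannot engage closed chromatin).
#' @param opener_strength >= 0: relative ATAC rate gained at bound sites after
#'   induction (scaled by the site's occupancy).
#' @return Object of class `tf_spec`.
#' @export
tf_spec <- function(name, affinity, pioneer_index = 1, opener_strength = 0) {
  stopifnot(is.numeric(affinity), !is.null(names(affinity)),
            all(affinity >= 0), any(affinity > 0),
            pioneer_index >= 0, pioneer_index <= 1, opener_strength >= 0)
  structure(list(name = name, affinity = affinity,
                 pioneer_index = pioneer_index,
                 opener_strength = opener_strength), class = "tf_spec")
}

#' Default synthetic landscape configuration
#'
#' Three TFs (A, B, C) sharing homeodomain-style motifs but differing in
#' pioneer ability (`pi_A = 0.05`, `pi_B = 0.9`, `pi_C = 0.1`), five planted
#' binding categories of 800 sites each on a 20 Mb / 4 chromosome genome, with
#' the B-preferential category planted entirely in inaccessible chromatin:
#'
#' \tabular{llll}{
#'   label \tab motif \tab accessible fraction \tab expected pattern \cr
#'   A=B=C \tab pan \tab 1.0 \tab bound equally by all three \cr
#'   A>B,C \tab anterior \tab 1.0 \tab A-preferential \cr
#'   B>A,C \tab posterior \tab 0.0 \tab B-preferential via pioneer activity \cr
#'   A,B>C \tab central \tab 1.0 \tab A/B-shared \cr
#'   B,C>A \tab posterior \tab 1.0 \tab posterior-motif shared \cr
#' }
#'
#' @param n_chrom,chrom_length Genome shape (default 4 x 5 Mb).
#' @param sites_per_category Planted sites per category (default 800).
#' @param depth ChIP/ATAC tags per replicate (default 2e6).
#' @param n_replicates Replicates per experiment (default 2).
#' @param phi Negative-binomial dispersion of per-site ChIP counts.
#' @param sigma Fragment-offset spread (bp) around the site point.
#' @param bg_fraction Fraction of ChIP tags that are uniform background.
#' @param seed Scenario seed.
#' @return Nested configuration list understood by [simulate_scenario()].
#' @export
default_landscape_config <- function(n_chrom = 4L, chrom_length = 5e6,
                                     sites_per_category = 800L,
                                     depth = 2e6, n_replicates = 2L,
                                     phi = 0.1, sigma = 35,
                                     bg_fraction = 0.5, seed = 1L) {
  motifs <- default_motif_models()
  tfs <- list(
    A = tf_spec("A",
                affinity = c(anterior = 1, central = 1, pan = 1,
                             posterior = 0.05, hox13 = 0),
                pioneer_index = 0.05, opener_strength = 1),
    B = tf_spec("B",
                affinity = c(anterior = 0.05, central = 1, pan = 1,
                             posterior = 1, hox13 = 0),
                pioneer_index = 0.9, opener_strength = 1),
    C = tf_spec("C",
                affinity = c(anterior = 0.05, central = 0.05, pan = 1,
                             posterior = 1, hox13 = 1),
                pioneer_index = 0.1, opener_strength = 1))
  # Category sizes are balanced so that every TF's summed occupancy is equal:
  # with fixed per-experiment sequencing depth, a TF concentrating the same
  # depth on fewer sites would otherwise show genuinely higher normalized
  # counts at sites it "shares", contradicting the planted labels.  The
  # A-preferential class is enlarged and a C-exclusive class (hox13 motif)
  # added so sum(lambda) is equal across TFs (each TF also has private
  # binding in real data).
  n <- as.integer(sites_per_category)
  categories <- data.table::data.table(
    label = c("A=B=C", "A>B,C", "B>A,C", "A,B>C", "B,C>A", "C>A,B"),
    motif = c("pan", "anterior", "posterior", "central", "posterior",
              "hox13"),
    n_sites = c(n, as.integer(round(1.945 * n)), n, n, n,
                as.integer(round(1.75 * n))),
    accessible_fraction = c(1, 1, 0, 1, 1, 1))
  list(
    genome = list(n_chrom = as.integer(n_chrom),
                  chrom_length = as.numeric(chrom_length),
                  composition = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)),
    motifs = motifs,
    tf_specs = tfs,
    categories = categories,
    site_spacing = 2000L,      # minimum distance between planted site points
    edge_margin = 2500L,
    domain_width = c(600L, 1400L),
    n_decoy_domains = 400L,
    chip = list(depth = depth, n_replicates = as.integer(n_replicates),
                phi = phi, sigma = sigma, bg_fraction = bg_fraction),
    input = list(depth = depth),
    atac = list(depth = depth, n_replicates = as.integer(n_replicates),
                domain_ratio = 10, site_mass = 1000, site_sigma = 300),
    expression = list(n_genes = 3000L, effect_lfc = 4, noise_sd = 0.2,
                      plant_prob = 0.8, max_dist = 10000L),
    seed = as.integer(seed))
}

#' Generate a random genome
#'
#' Chromosome sequences are drawn i.i.d. from the configured base composition
#' (reproducible for a fixed seed).
#'
#' @param config List with `n_chrom`, `chrom_length`, `composition` (length-4
#'   probabilities for A, C, G, T) -- e.g. the `genome` element of
#'   [default_landscape_config()].
#' @param seed RNG seed.
#' @return A [genome()].
#' @export
generate_genome <- function(config, seed = 1L) {
  comp <- config$composition
  if (length(comp) != 4L || any(comp < 0) || abs(sum(comp) - 1) > 1e-9)
    stop("composition must be 4 non-negative probabilities summing to 1")
  if (config$chrom_length < 1e4) stop("chromosome length must be >= 10 kb")
  set.seed(seed)
  bases <- charToRaw("ACGT")
  seqs <- vapply(seq_len(config$n_chrom), function(i) {
    idx <- sample.int(4L, config$chrom_length, replace = TRUE, prob = comp)
    rawToChar(bases[idx])
  }, character(1L))
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  genome(seqs)
}

#' Plant a binding landscape into a genome
#'
#' Places non-overlapping sites on a jittered grid (capacity error when the
#' requested sites do not fit at the configured spacing), embeds a sampled
#' motif instance at each site point, assigns accessibility flags at exactly
#' the configured per-category fractions, builds ground-truth accessible
#' domains around accessible sites plus decoy domains away from all sites, and
#' tabulates each TF's expected occupancy
#' `lambda = affinity[motif] * (1 if accessible else pioneer_index)`.
#'
#' @param g A [genome()].
#' @param config Configuration list (see [default_landscape_config()]).
#' @param tf_specs List of [tf_spec()]; defaults to `config$tf_specs`.
#' @param seed RNG seed.
#' @return List with `genome` (motifs embedded) and `truth`, an object of
#'   class `synthetic_truth`: `sites` (chrom, pos, category, motif,
#'   accessible, motif_strand, instance), `domains` (chrom, start, end, kind),
#'   `lambda` (sites x TFs matrix), `tf_names`, `control_sites` (unbound
#'   points outside all domains), `config`.
#' @export
plant_landscape <- function(g, config, tf_specs = config$tf_specs, seed = 1L) {
  set.seed(seed)
  cats <- data.table::as.data.table(config$categories)
  n_total <- sum(cats$n_sites)
  tf_names <- vapply(tf_specs, `[[`, "", "name")

  empty_truth <- function() structure(list(
    sites = data.table::data.table(chrom = character(), pos = integer(),
                                   category = character(), motif = character(),
                                   accessible = logical(),
                                   motif_strand = character(),
                                   instance = character()),
    domains = data.table::data.table(chrom = character(), start = integer(),
                                     end = integer(), kind = character()),
    lambda = matrix(0, 0L, length(tf_names),
                    dimnames = list(NULL, tf_names)),
    tf_names = tf_names,
    control_sites = data.table::data.table(chrom = character(),
                                           pos = integer()),
    config = config), class = "synthetic_truth")
  if (n_total == 0L)
    return(list(genome = g, truth = empty_truth()))

  spacing <- config$site_spacing
  edge <- config$edge_margin
  lens <- as.numeric(g$lengths)
  # distribute sites across chromosomes proportional to length
  n_per <- floor(n_total * lens / sum(lens))
  rem <- n_total - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L

  site_chrom <- character(0); site_pos <- integer(0)
  mid_chrom <- character(0); mid_pos <- integer(0); mid_half <- numeric(0)
  for (ci in seq_along(g$chroms)) {
    k <- n_per[ci]
    if (k == 0L) next
    span <- lens[ci] - 2 * edge
    slot <- floor(span / k)
    if (slot <= spacing)
      stop("capacity error: cannot place ", k, " sites at spacing ", spacing,
           " on ", g$chroms[ci])
    u <- floor(stats::runif(k) * (slot - spacing))
    p <- as.integer(edge + (seq_len(k) - 1L) * slot + u)
    site_chrom <- c(site_chrom, rep(g$chroms[ci], k))
    site_pos <- c(site_pos, p)
    if (k >= 2L) {
      mids <- as.integer((p[-k] + p[-1L]) / 2)
      halves <- (p[-1L] - p[-k]) / 2
      mid_chrom <- c(mid_chrom, rep(g$chroms[ci], k - 1L))
      mid_pos <- c(mid_pos, mids)
      mid_half <- c(mid_half, halves)
    }
  }

  # shuffle category labels over placed sites; exact per-category counts
  labels <- sample(rep(cats$label, cats$n_sites))
  sites <- data.table::data.table(chrom = site_chrom, pos = site_pos,
                                  category = labels)
  sites[, motif := cats$motif[match(category, cats$label)]]
  # accessibility flags: exact count per category
  sites[, accessible := FALSE]
  for (i in seq_len(nrow(cats))) {
    idx <- which(sites$category == cats$label[i])
    n_acc <- round(cats$accessible_fraction[i] * length(idx))
    if (n_acc > 0L)
      sites$accessible[sample(idx, n_acc)] <- TRUE
  }

  # embed motif instances
  motifs <- config$motifs
  sites[, motif_strand := sample(c("+", "-"), .N, replace = TRUE)]
  sites[, instance := ""]
  for (mname in unique(sites$motif)) {
    mm <- motifs[[mname]]
    if (is.null(mm)) stop("unknown motif model: ", mname)
    idx <- which(sites$motif == mname)
    sites$instance[idx] <- sample_motif_instances(mm, length(idx))
  }
  raws <- lapply(g$seq, charToRaw)
  widths <- vapply(motifs, `[[`, 0L, "width")[sites$motif]
  for (i in seq_len(nrow(sites))) {
    w <- widths[i]
    s0 <- sites$pos[i] - w %/% 2L
    ins <- if (sites$motif_strand[i] == "+") sites$instance[i]
           else .revcomp(sites$instance[i])
    raws[[sites$chrom[i]]][(s0 + 1L):(s0 + w)] <- charToRaw(ins)
  }
  g2 <- genome(vapply(raws, rawToChar, character(1L)))

  # ground-truth domains: one around each accessible site
  wd <- config$domain_width
  acc <- sites[accessible == TRUE]
  dom <- NULL
  if (nrow(acc) > 0L) {
    width <- floor(stats::runif(nrow(acc), wd[1L], wd[2L] + 1))
    center <- acc$pos + floor(stats::runif(nrow(acc), -100, 101))
    dom <- data.table::data.table(
      chrom = acc$chrom,
      start = as.integer(pmax(0, center - width %/% 2L)),
      end = as.integer(pmin(g$lengths[acc$chrom], center + (width - width %/% 2L))),
      kind = "site")
  }
  # decoy domains at inter-site midpoints far enough from both neighbours
  nd <- config$n_decoy_domains
  if (nd > 0L && length(mid_pos) > 0L) {
    safe <- which(mid_half >= spacing * 0.9)  # >= ~1800 bp from either site
    take <- safe[sample.int(length(safe), min(nd, length(safe)))]
    width <- floor(stats::runif(length(take), wd[1L], wd[2L] + 1))
    dom2 <- data.table::data.table(
      chrom = mid_chrom[take],
      start = as.integer(mid_pos[take] - width %/% 2L),
      end = as.integer(mid_pos[take] + (width - width %/% 2L)),
      kind = "decoy")
    dom <- rbind(dom, dom2)
  }
  if (is.null(dom))
    dom <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), kind = character())
  data.table::setorder(dom, chrom, start)
  # by construction domains never overlap; assert the invariant
  if (nrow(dom) > 1L) {
    ov <- dom[, any(start[-1L] < end[-.N]), by = chrom]$V1
    if (any(ov)) stop("internal error: overlapping truth domains")
  }

  # per-TF expected occupancy
  lambda <- vapply(tf_specs, function(tf) {
    aff <- tf$affinity[sites$motif]
    aff[is.na(aff)] <- 0
    unname(aff * ifelse(sites$accessible, 1, tf$pioneer_index))
  }, numeric(nrow(sites)))
  lambda <- matrix(lambda, nrow = nrow(sites),
                   dimnames = list(NULL, tf_names))

  # unbound control points: inter-site midpoints not used by decoy domains,
  # hence outside all domains and >= ~spacing from any planted site
  ctrl <- NULL
  if (length(mid_pos) > 0L) {
    cand <- which(mid_half >= spacing * 0.9)
    cand <- setdiff(cand, if (exists("take", inherits = FALSE)) take
                          else integer(0))
    n_ctrl <- min(length(cand), 800L)
    if (n_ctrl > 0L) {
      pick <- cand[sample.int(length(cand), n_ctrl)]
      ctrl <- data.table::data.table(chrom = mid_chrom[pick],
                                     pos = mid_pos[pick])
    }
  }
  if (is.null(ctrl))
    ctrl <- data.table::data.table(chrom = character(), pos = integer())

  truth <- structure(list(
    sites = sites, domains = dom, lambda = lambda, tf_names = tf_names,
    control_sites = ctrl, config = config), class = "synthetic_truth")
  list(genome = g2, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$sites), "planted sites,",
      nrow(x$domains), "accessible domains,", length(x$tf_names), "TFs\n")
  invisible(x)
}

#' Simulate ChIP-seq tag libraries for one TF
#'
#' Per-site replicate counts are drawn NB(mean `lambda_s * depth_scale`,
#' variance `m + phi m^2`); each signal tag is placed at the site point plus a
#' rounded Normal(0, sigma) offset with a random strand, and
#' `bg_fraction * depth` tags are placed uniformly over the genome.  With
#' `phi = 0` counts are the rounded expected values, so total tag counts are
#' exact (deterministic generator mode used for bookkeeping tests).
#'
#' @param truth A `synthetic_truth` from [plant_landscape()].
#' @param g The planted [genome()].
#' @param tf TF name (column of `truth$lambda`).
#' @param depth Tags per replicate.
#' @param n_replicates Number of replicate libraries.
#' @param phi NB dispersion (variance `m + phi m^2`).
#' @param sigma Fragment-offset spread in bp.
#' @param bg_fraction Fraction of tags placed uniformly.
#' @param seed RNG seed.
#' @return List of [tag_library()] objects (one per replicate).
#' @export
simulate_chip <- function(truth, g, tf, depth = 2e6, n_replicates = 2L,
                          phi = 0.1, sigma = 35, bg_fraction = 0.5,
                          seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), depth > 0, phi >= 0)
  set.seed(seed)
  lam <- truth$lambda[, tf]
  sites <- truth$sites
  n_bg <- round(bg_fraction * depth)
  scale <- if (sum(lam) > 0) (depth - n_bg) / sum(lam) else 0
  mu <- lam * scale
  lapply(seq_len(n_replicates), function(r) {
    counts <- if (phi > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
              else as.integer(round(mu))
    n_sig <- sum(counts)
    sig <- NULL
    if (n_sig > 0L) {
      cn <- rep(sites$chrom, counts)
      p <- rep(sites$pos, counts) +
        as.integer(round(stats::rnorm(n_sig, 0, sigma)))
      p <- pmin(pmax(p, 0L), as.integer(g$lengths[cn]) - 1L)
      sig <- data.table::data.table(
        chrom = cn, pos = p,
        strand = sample(c("+", "-"), n_sig, replace = TRUE))
    }
    bg <- .uniform_tags(g, n_bg)
    tag_library(rbind(sig, bg),
                experiment_id = paste0(tf, "_rep", r),
                condition = tf, replicate_id = paste0("rep", r))
  })
}

#' Simulate an input-control tag library
#'
#' Tags are placed uniformly over the genome.
#'
#' @param g A [genome()].
#' @param depth Number of tags.
#' @param seed RNG seed.
#' @return A [tag_library()].
#' @export
simulate_input <- function(g, depth = 2e6, seed = 1L) {
  set.seed(seed)
  tag_library(.uniform_tags(g, depth), experiment_id = "input",
              condition = "input", replicate_id = "rep1")
}

.uniform_tags <- function(g, n) {
  if (n <= 0L) return(NULL)
  cn <- sample(g$chroms, n, replace = TRUE, prob = as.numeric(g$lengths))
  data.table::data.table(
    chrom = cn,
    pos = as.integer(floor(stats::runif(n) * g$lengths[cn])),
    strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate ATAC-seq tag libraries
#'
#' Tag rate is uniform at a baseline everywhere, elevated `domain_ratio`-fold
#' inside ground-truth accessible domains, and -- in `post` mode -- each site
#' bound by a supplied TF additionally gains mass
#' `opener_strength * occupancy * site_mass` (in bp-equivalents) spread
#' Normal(0, `site_sigma`) around the site point, emulating binding-induced
#' accessibility gain.  Prior and post modes consume randomness identically,
#' so `post` with zero opener strength reproduces `prior` under the same seed.
#'
#' @param truth A `synthetic_truth`.
#' @param g The planted [genome()].
#' @param tf_specs List of bound [tf_spec()]s (`post` mode), or NULL.
#' @param depth Tags per replicate.
#' @param n_replicates Number of replicates.
#' @param mode "prior" (before induction) or "post" (after).
#' @param domain_ratio Inside:outside rate ratio (default 10).
#' @param site_mass bp-equivalents of gained mass per unit occupancy.
#' @param site_sigma Spread of gained tags around the site point.
#' @param seed RNG seed.
#' @return List of [tag_library()] objects.
#' @export
simulate_atac <- function(truth, g, tf_specs = NULL, depth = 2e6,
                          n_replicates = 2L, mode = c("prior", "post"),
                          domain_ratio = 10, site_mass = 1000,
                          site_sigma = 300, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "synthetic_truth"), depth >= 0)
  set.seed(seed)
  dom <- truth$domains
  sites <- truth$sites
  gain <- numeric(nrow(sites))
  if (mode == "post" && !is.null(tf_specs)) {
    for (tf in tf_specs)
      gain <- gain + tf$opener_strength * truth$lambda[, tf$name]
  }
  masses <- c(sum(as.numeric(g$lengths)),            # uniform baseline
              (domain_ratio - 1) * pmax(dom$end - dom$start, 0),
              gain * site_mass)
  lapply(seq_len(n_replicates), function(r) {
    if (depth == 0) return(tag_library(NULL,
        experiment_id = paste0("atac_", mode, "_rep", r),
        condition = paste0("atac_", mode), replicate_id = paste0("rep", r)))
    counts <- as.vector(stats::rmultinom(1L, depth, prob = masses))
    n_dom <- nrow(dom); n_site <- nrow(sites)
    bg <- .uniform_tags(g, counts[1L])
    parts <- list(bg)
    if (n_dom > 0L) {
      cd <- counts[2L:(1L + n_dom)]
      nd <- sum(cd)
      if (nd > 0L) {
        i <- rep(seq_len(n_dom), cd)
        parts <- c(parts, list(data.table::data.table(
          chrom = dom$chrom[i],
          pos = as.integer(dom$start[i] +
            floor(stats::runif(nd) * (dom$end[i] - dom$start[i]))),
          strand = sample(c("+", "-"), nd, replace = TRUE))))
      }
    }
    if (n_site > 0L) {
      cs <- counts[(2L + n_dom):(1L + n_dom + n_site)]
      ns <- sum(cs)
      if (ns > 0L) {
        i <- rep(seq_len(n_site), cs)
        p <- sites$pos[i] + as.integer(round(stats::rnorm(ns, 0, site_sigma)))
        p <- pmin(pmax(p, 0L), as.integer(g$lengths[sites$chrom[i]]) - 1L)
        parts <- c(parts, list(data.table::data.table(
          chrom = sites$chrom[i], pos = p,
          strand = sample(c("+", "-"), ns, replace = TRUE))))
      }
    }
    tag_library(data.table::rbindlist(parts),
                experiment_id = paste0("atac_", mode, "_rep", r),
                condition = paste0("atac_", mode),
                replicate_id = paste0("rep", r))
  })
}

#' Simulate gene models and a differential-expression summary table
#'
#' Genes are placed uniformly on the genome with log-normal mappable lengths.
#' Each gene within `max_dist` of a planted site inherits (with probability
#' `plant_prob`) the expression pattern of its nearest site's category: the
#' matching TF-vs-baseline and pairwise contrasts receive
#' `LFC = effect_lfc + noise` with small adjusted p; all other entries are
#' null (`LFC ~ Normal(0, noise_sd)`, p uniform).
#'
#' @param truth A `synthetic_truth`.
#' @param g The planted [genome()].
#' @param n_genes Number of genes.
#' @param effect_lfc Planted log2 fold change (> 0).
#' @param noise_sd LFC noise standard deviation.
#' @param plant_prob Probability that an eligible gene receives the effect.
#' @param max_dist Maximum site-TSS distance for planting.
#' @param baseline Baseline condition name used in contrast labels.
#' @param seed RNG seed.
#' @return List: `genes` (gene, chrom, strand, tss, length), `records`
#'   (gene, contrast, lfc, padj), `truth_sets` (gene, planted_set).
#' @export
simulate_expression <- function(truth, g, n_genes = 3000L, effect_lfc = 4,
                                noise_sd = 0.2, plant_prob = 0.8,
                                max_dist = 10000L, baseline = "progenitor",
                                seed = 1L) {
  stopifnot(effect_lfc > 0)
  set.seed(seed)
  tfn <- truth$tf_names
  stopifnot(length(tfn) == 3L)
  cn <- sample(g$chroms, n_genes, replace = TRUE, prob = as.numeric(g$lengths))
  genes <- data.table::data.table(
    gene = sprintf("g%05d", seq_len(n_genes)),
    chrom = cn,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = as.integer(floor(stats::runif(n_genes) * g$lengths[cn])),
    length = pmax(200L, as.integer(round(10^stats::rnorm(n_genes, 3.4, 0.35)))))

  # nearest planted site per gene
  genes[, c("category", "distance") := {
    res <- list(rep(NA_character_, .N), rep(NA_real_, .N))
    s <- truth$sites[chrom == .BY$chrom][order(pos)]
    if (nrow(s) > 0L) {
      i <- findInterval(tss, s$pos)
      lo <- pmax(i, 1L); hi <- pmin(i + 1L, nrow(s))
      dlo <- abs(tss - s$pos[lo]); dhi <- abs(tss - s$pos[hi])
      nearest <- ifelse(dlo <= dhi, lo, hi)
      res <- list(s$category[nearest], pmin(dlo, dhi))
    }
    res
  }, by = chrom]

  contrasts <- c(paste0(tfn, "_vs_", baseline),
                 paste0(tfn[1L], "_vs_", tfn[2L]),
                 paste0(tfn[1L], "_vs_", tfn[3L]),
                 paste0(tfn[2L], "_vs_", tfn[3L]))
  # planted LFC pattern per category label over the 6 contrasts
  # (A_vs_base, B_vs_base, C_vs_base, A_vs_B, A_vs_C, B_vs_C)
  e <- effect_lfc
  pat <- list(); set_label <- character()
  addpat <- function(lab, v, set) {
    pat[[lab]] <<- v
    set_label[lab] <<- set
  }
  addpat(paste0(tfn[1L], "=", tfn[2L], "=", tfn[3L]), c(e, e, e, 0, 0, 0),
         "shared-up")
  addpat(paste0(tfn[1L], ">", tfn[2L], ",", tfn[3L]), c(e, 0, 0, e, e, 0),
         paste0(tfn[1L], "-up"))
  addpat(paste0(tfn[2L], ">", tfn[1L], ",", tfn[3L]), c(0, e, 0, -e, 0, e),
         paste0(tfn[2L], "-up"))
  addpat(paste0(tfn[3L], ">", tfn[1L], ",", tfn[2L]), c(0, 0, e, 0, -e, -e),
         paste0(tfn[3L], "-up"))
  addpat(paste0(tfn[1L], ",", tfn[2L], ">", tfn[3L]), c(e, e, 0, 0, e, e),
         paste0(tfn[1L], ",", tfn[2L], "-up"))
  addpat(paste0(tfn[1L], ",", tfn[3L], ">", tfn[2L]), c(e, 0, e, e, 0, -e),
         paste0(tfn[1L], ",", tfn[3L], "-up"))
  addpat(paste0(tfn[2L], ",", tfn[3L], ">", tfn[1L]), c(0, e, e, -e, -e, 0),
         paste0(tfn[2L], ",", tfn[3L], "-up"))

  planted <- !is.na(genes$category) & genes$category %in% names(pat) &
    genes$distance <= max_dist & stats::runif(n_genes) < plant_prob
  truth_sets <- data.table::data.table(
    gene = genes$gene,
    planted_set = ifelse(planted, set_label[genes$category], NA_character_))

  nrec <- n_genes * length(contrasts)
  rec <- data.table::data.table(
    gene = rep(genes$gene, each = length(contrasts)),
    contrast = rep(contrasts, times = n_genes),
    lfc = stats::rnorm(nrec, 0, noise_sd),
    padj = stats::runif(nrec))
  idx_planted <- which(rep(planted, each = length(contrasts)))
  if (length(idx_planted) > 0L) {
    patmat <- do.call(rbind, pat)[genes$category[planted], , drop = FALSE]
    eff <- as.vector(t(patmat))
    sel <- idx_planted[eff != 0]
    rec$lfc[sel] <- rec$lfc[sel] + eff[eff != 0]
    rec$padj[sel] <- 10^-stats::runif(length(sel), 3, 8)
  }
  list(genes = genes[, .(gene, chrom, strand, tss, length)],
       records = rec, truth_sets = truth_sets)
}

#' Simulate a complete study scenario
#'
#' Runs [generate_genome()], [plant_landscape()], [simulate_chip()] for every
#' TF, [simulate_input()], [simulate_atac()] in prior and post modes, and
#' [simulate_expression()], all seeded deterministically from one scenario
#' seed.
#'
#' @param config Scenario configuration (default
#'   [default_landscape_config()]).
#' @param seed Overrides `config$seed` when given.
#' @return List: `genome`, `truth`, `chip` (named list of replicate-library
#'   lists per TF), `input`, `atac_prior`, `atac_post`, `expression`,
#'   `config`.
#' @export
simulate_scenario <- function(config = default_landscape_config(),
                              seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  s <- config$seed
  g0 <- generate_genome(config$genome, seed = s)
  pl <- plant_landscape(g0, config, seed = s + 1L)
  g <- pl$genome; truth <- pl$truth
  ch <- config$chip
  chip <- list()
  for (i in seq_along(config$tf_specs)) {
    tf <- config$tf_specs[[i]]
    chip[[tf$name]] <- simulate_chip(
      truth, g, tf$name, depth = ch$depth, n_replicates = ch$n_replicates,
      phi = ch$phi, sigma = ch$sigma, bg_fraction = ch$bg_fraction,
      seed = s + 10L + i)
  }
  input <- simulate_input(g, depth = config$input$depth, seed = s + 20L)
  at <- config$atac
  atac_prior <- simulate_atac(
    truth, g, NULL, depth = at$depth, n_replicates = at$n_replicates,
    mode = "prior", domain_ratio = at$domain_ratio,
    site_mass = at$site_mass, site_sigma = at$site_sigma, seed = s + 30L)
  atac_post <- simulate_atac(
    truth, g, config$tf_specs, depth = at$depth,
    n_replicates = at$n_replicates, mode = "post",
    domain_ratio = at$domain_ratio, site_mass = at$site_mass,
    site_sigma = at$site_sigma, seed = s + 31L)
  ex <- config$expression
  expression <- simulate_expression(
    truth, g, n_genes = ex$n_genes, effect_lfc = ex$effect_lfc,
    noise_sd = ex$noise_sd, plant_prob = ex$plant_prob,
    max_dist = ex$max_dist, seed = s + 40L)
  list(genome = g, truth = truth, chip = chip, input = input,
       atac_prior = atac_prior, atac_post = atac_post,
       expression = expression, config = config)
}
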