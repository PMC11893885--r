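# Synthetic-data generators. The simulator plants a regulatory landscape on a
# small toy genome (default 2 chromosomes x 10 Mb) with known truth so every
# downstream stage -- bidirectional calling, DE testing, clustering,
# interaction calling, GWAS enrichment, conservation -- can be scored.

#' Simulation configuration
#'
#' Returns the default simulation configuration, with any field overridable
#' through `...`. Defaults emulate the study conditions: three differentiation
#' timepoints (D1/D3/D6) with two replicates of a total-RNA (promoter/CAGE)
#' and a nascent-RNA (enhancer/NET-CAGE) assay, unidirectional high promoter
#' signal vs balanced low bidirectional enhancer signal, four planted temporal
#' expression patterns, capture Hi-C pairs with power-law distance decay plus
#' planted enhancer-promoter contacts absent at negative-control probes,
#' LD-structured variants with planted enhancer enrichment, and conservation
#' elevated in enhancers.
#'
#' @param ... named overrides of any default field
#' @return a named list of class `enhdyn_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genome
    n_chroms = 2L, chrom_length = 1e7,
    # landscape
    n_promoters = 400L, n_enhancers = 300L,
    promoter_width = 300L, enhancer_halfwidth = 300L,
    min_feature_gap = 4000L,
    cluster_props = c(c1 = 0.1, c2 = 0.1, c3 = 0.1, c4 = 0.1, flat = 0.6),
    known_fraction = 0.35,
    # expression
    effect_fold = 4, dispersion = 0.1,
    promoter_mean = 60, enhancer_mean = 30,
    promoter_strandedness = 0.95,
    balance_range = c(0.4, 0.6),
    enhancer_total_scale = 0.25,
    noise_rate = 1e-5,
    pos_sd = 15,
    timepoints = c("D1", "D3", "D6"), n_reps = 2L,
    # capture Hi-C
    n_probe_promoters = 300L, n_probe_enhancers = 150L,
    n_probe_gwas = 50L, n_neg_controls = 200L,
    probe_width = 600L,
    n_planted = 60L, lambda = 8,
    plant_dist = c(25000, 50000),
    hic_bin = 2000L, hic_min_dist = 10000, hic_max_dist = 200000,
    hic_pairs = 190000, hic_decay = 0.15,
    # variants / LD / GWAS
    snp_rate = 1 / 500, af_shape = c(1, 3),
    enh_snp_factor = 3, ld_block = 20000L, ld_scale = 7500,
    ld_max_pair_dist = 5000L, n_gwas_loci = 100L,
    gwas_min_spacing = 100000,
    eqtl_rate = 0.05, eqtl_enh_factor = 2,
    # conservation
    cons_step = 100L, cons_base = 0.2, cons_sd = 0.1, cons_shift = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  check_that(length(unknown) == 0,
             paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  check_that(abs(sum(cfg$cluster_props) - 1) < 1e-8, "cluster_props must sum to 1")
  check_that(all(unlist(cfg[c("n_promoters", "n_enhancers", "n_reps")]) > 0),
             "counts must be positive")
  structure(cfg, class = "enhdyn_config")
}

#' Sample metadata table for a configuration
#'
#' @param config an [sim_config()] list
#' @param assays which assays to include
#' @return tibble with sample_id, timepoint, assay, replicate
#' @export
sim_samples <- function(config, assays = c("total", "nascent")) {
  grid <- expand.grid(replicate = seq_len(config$n_reps),
                      assay = assays,
                      timepoint = config$timepoints,
                      stringsAsFactors = FALSE)
  tibble(
    sample_id = sprintf("%s_%s_r%d", grid$timepoint, grid$assay, grid$replicate),
    timepoint = grid$timepoint, assay = grid$assay, replicate = grid$replicate
  )
}

# cluster multipliers across (D1, D3, D6); fold = extreme-timepoint ratio
cluster_profiles <- function(fold) {
  lo <- 1 / fold
  list(c1 = c(1, lo, lo),    # downregulated from Day 3
       c2 = c(1, 1, lo),     # drastically downregulated on Day 6
       c3 = c(lo, 1, 1),     # upregulated from Day 3
       c4 = c(lo, lo, 1),    # drastically upregulated on Day 6
       flat = c(1, 1, 1))
}

# quota-based assignment of cluster labels (largest remainder)
quota_labels <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  rep(names(props), times = base)
}

# place n non-overlapping slots of `width` with at least `gap` between starts
place_slots <- function(n, chrom_sizes, width, gap) {
  total_needed <- n * (width + gap)
  check_that(total_needed < sum(chrom_sizes$length) * 0.8,
             "genome too small to place requested regions")
  per_chrom <- as.vector(stats::rmultinom(1, n, prob = chrom_sizes$length))
  out <- purrr::map2_dfr(seq_len(nrow(chrom_sizes)), per_chrom, function(i, k) {
    if (k == 0) return(NULL)
    L <- chrom_sizes$length[i]
    slack <- L - k * (width + gap)
    check_that(slack > 0, "genome too small to place requested regions")
    starts <- sort(runif(k, 0, slack)) + (seq_len(k) - 1) * (width + gap) + gap / 2
    tibble(chrom = chrom_sizes$chrom[i], start = floor(starts))
  })
  out$end <- out$start + width
  out
}

#' Generate the planted regulatory landscape
#'
#' Places promoters and (known/novel) enhancers with temporal cluster labels,
#' capture probes (promoter / enhancer / gwas / negative_control classes) and
#' planted enhancer-promoter interactions with their active timepoints.
#'
#' @param config an [sim_config()] list
#' @return list with `chrom_sizes`, `promoters`, `enhancers`, `probes`,
#'   `planted_interactions`, `samples`
#' @export
gen_landscape <- function(config = sim_config()) {
  set.seed(child_seed(config$seed, 1))
  chrom_sizes <- tibble(chrom = sprintf("chr%d", seq_len(config$n_chroms)),
                        length = as.integer(config$chrom_length))

  n_extra <- config$n_probe_gwas + config$n_neg_controls
  n_slots <- config$n_promoters + config$n_enhancers + n_extra
  slots <- place_slots(n_slots, chrom_sizes,
                       width = max(config$promoter_width,
                                   2 * config$enhancer_halfwidth,
                                   config$probe_width),
                       gap = config$min_feature_gap)
  slots <- slots[sample.int(nrow(slots)), ]
  idx <- 0

  take <- function(k) {
    out <- slots[idx + seq_len(k), ]
    idx <<- idx + k
    out
  }

  prom <- take(config$n_promoters)
  promoters <- tibble(
    chrom = prom$chrom,
    start = prom$start,
    end = prom$start + config$promoter_width,
    strand = sample(c("+", "-"), config$n_promoters, replace = TRUE),
    id = sprintf("prom_%04d", seq_len(config$n_promoters)),
    cluster = sample(quota_labels(config$n_promoters, config$cluster_props)),
    base_mean = config$promoter_mean
  )

  enh <- take(config$n_enhancers)
  center <- enh$start + config$enhancer_halfwidth
  enhancers <- tibble(
    chrom = enh$chrom,
    start = center - config$enhancer_halfwidth,
    end = center + config$enhancer_halfwidth,
    strand = "*",
    id = sprintf("enh_%04d", seq_len(config$n_enhancers)),
    center = center,
    cluster = sample(quota_labels(config$n_enhancers, config$cluster_props)),
    base_mean = config$enhancer_mean,
    balance = runif(config$n_enhancers, config$balance_range[1],
                    config$balance_range[2]),
    known = seq_len(config$n_enhancers) %in%
      sample.int(config$n_enhancers, round(config$known_fraction * config$n_enhancers))
  )
  enhancers$novelty <- ifelse(enhancers$known, "known", "novel")

  gw <- take(config$n_probe_gwas)
  gwas_regions <- tibble(
    chrom = gw$chrom, start = gw$start, end = gw$start + config$probe_width,
    strand = "*", id = sprintf("gwasr_%04d", seq_len(config$n_probe_gwas))
  )
  neg <- take(config$n_neg_controls)
  neg_regions <- tibble(
    chrom = neg$chrom, start = neg$start, end = neg$start + config$probe_width,
    strand = "*", id = sprintf("neg_%04d", seq_len(config$n_neg_controls))
  )

  probe_prom <- promoters[sample.int(nrow(promoters),
                                     min(config$n_probe_promoters, nrow(promoters))), ]
  de_enh <- enhancers[enhancers$cluster != "flat", ]
  pool_enh <- if (nrow(de_enh) >= config$n_probe_enhancers) de_enh else enhancers
  probe_enh <- pool_enh[sample.int(nrow(pool_enh),
                                   min(config$n_probe_enhancers, nrow(pool_enh))), ]
  probes <- bind_rows(
    tibble(chrom = probe_prom$chrom, start = probe_prom$start, end = probe_prom$end,
           strand = "*", id = probe_prom$id, class = "promoter"),
    tibble(chrom = probe_enh$chrom, start = probe_enh$start, end = probe_enh$end,
           strand = "*", id = probe_enh$id, class = "enhancer"),
    mutate(gwas_regions, class = "gwas"),
    mutate(neg_regions, class = "negative_control")
  )

  planted <- plant_interactions(probes, promoters, enhancers, config)

  list(chrom_sizes = chrom_sizes, promoters = promoters, enhancers = enhancers,
       probes = probes, planted_interactions = planted,
       samples = sim_samples(config))
}

# choose planted (anchor, other-feature) contacts within the plant distance
plant_interactions <- function(probes, promoters, enhancers, config) {
  if (config$n_planted == 0) {
    return(tibble(anchor_id = character(), other_id = character(),
                  chrom = character(), anchor_mid = integer(),
                  other_mid = integer(), lambda = numeric(),
                  timepoints = list()))
  }
  check_that(config$lambda >= 1, "planted interaction effect lambda must be >= 1")
  targets <- probes[probes$class != "negative_control", ]
  features <- bind_rows(
    promoters[, c("chrom", "start", "end", "id")],
    enhancers[, c("chrom", "start", "end", "id")]
  )
  features$mid <- region_mid(features)
  targets$mid <- region_mid(targets)

  cand <- inner_join(
    mutate(targets[, c("chrom", "id", "mid")], dummy = 1),
    mutate(setNames(features[, c("chrom", "id", "mid")],
                    c("chrom", "other_id", "other_mid")), dummy = 1),
    by = c("chrom", "dummy"), relationship = "many-to-many"
  )
  cand$dist <- abs(cand$other_mid - cand$mid)
  cand <- cand[cand$dist >= config$plant_dist[1] &
                 cand$dist <= config$plant_dist[2] &
                 cand$id != cand$other_id, ]
  cand <- cand[sample.int(nrow(cand)), ]
  cand <- cand[!duplicated(cand$id), ]
  cand <- head(cand, config$n_planted)

  tps <- config$timepoints
  n_active <- sample(c(1, 2, 3), nrow(cand), replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
  tibble(
    anchor_id = cand$id, other_id = cand$other_id, chrom = cand$chrom,
    anchor_mid = cand$mid, other_mid = cand$other_mid,
    lambda = config$lambda,
    timepoints = purrr::map(n_active, function(k) sort(sample(tps, k)))
  )
}

#' Generate stranded CTSS tag tables with planted temporal signal
#'
#' Promoter tags are predominantly (default 95%) on the annotated strand;
#' enhancer tags are split between a minus-strand left flank and a plus-strand
#' right flank with per-locus balance drawn around 50/50. Per-feature counts
#' are negative binomial around cluster-specific temporal means; enhancer
#' signal is strongest in the nascent-RNA assay. Uniform background noise tags
#' are sprinkled genome-wide.
#'
#' @param truth a [gen_landscape()] result
#' @param config the matching [sim_config()]
#' @return tibble of CTSS records (chrom, pos, strand, count, sample_id)
#' @export
gen_ctss <- function(truth, config = sim_config()) {
  set.seed(child_seed(config$seed, 2))
  samples <- truth$samples
  check_that(all(samples$timepoint %in% config$timepoints), "unknown timepoint")
  profs <- cluster_profiles(config$effect_fold)
  tp_index <- match(samples$timepoint, config$timepoints)
  size <- 1 / config$dispersion

  draw_counts <- function(features, assay_scale_fun) {
    cells <- tidyr::crossing(feature_row = seq_len(nrow(features)),
                             sample_row = seq_len(nrow(samples)))
    mult <- vapply(seq_len(nrow(cells)), function(i) {
      f <- cells$feature_row[i]; s <- cells$sample_row[i]
      profs[[features$cluster[f]]][tp_index[s]]
    }, 0)
    mu <- features$base_mean[cells$feature_row] * mult *
      assay_scale_fun(samples$assay[cells$sample_row])
    cells$n <- rnbinom(nrow(cells), mu = mu, size = size)
    cells
  }

  # promoters: expressed in both assays
  prom <- truth$promoters
  tags <- list()
  if (nrow(prom) > 0) {
    cells <- draw_counts(prom, function(a) 1)
    cells <- cells[cells$n > 0, ]
    f <- cells$feature_row[rep(seq_len(nrow(cells)), cells$n)]
    s <- cells$sample_row[rep(seq_len(nrow(cells)), cells$n)]
    summit <- floor((prom$start + prom$end) / 2)
    pos <- round(rnorm(length(f), summit[f], config$pos_sd))
    pos <- pmin(pmax(pos, prom$start[f]), prom$end[f] - 1)
    sense <- runif(length(f)) < config$promoter_strandedness
    strand <- ifelse(sense, prom$strand[f],
                     ifelse(prom$strand[f] == "+", "-", "+"))
    tags$prom <- tibble(chrom = prom$chrom[f], pos = as.integer(pos),
                        strand = strand, sample_id = samples$sample_id[s])
  }

  # enhancers: nascent assay at full level, total assay damped
  enh <- truth$enhancers
  if (nrow(enh) > 0) {
    cells <- draw_counts(enh, function(a) {
      ifelse(a == "nascent", 1, config$enhancer_total_scale)
    })
    cells <- cells[cells$n > 0, ]
    if (nrow(cells) > 0) {
      cells$n_plus <- rbinom(nrow(cells), cells$n, enh$balance[cells$feature_row])
      cells$n_minus <- cells$n - cells$n_plus
      flank_off <- ceiling(config$enhancer_halfwidth * 0.4)
      expand_side <- function(nn, sgn, strand) {
        keep <- nn > 0
        f <- cells$feature_row[keep][rep(seq_len(sum(keep)), nn[keep])]
        s <- cells$sample_row[keep][rep(seq_len(sum(keep)), nn[keep])]
        summit <- enh$center[f] + sgn * flank_off
        pos <- round(rnorm(length(f), summit, config$pos_sd))
        pos <- pmin(pmax(pos, enh$start[f]), enh$end[f] - 1)
        tibble(chrom = enh$chrom[f], pos = as.integer(pos), strand = strand,
               sample_id = samples$sample_id[s])
      }
      tags$enh_plus <- expand_side(cells$n_plus, +1, "+")
      tags$enh_minus <- expand_side(cells$n_minus, -1, "-")
    }
  }

  # uniform background noise
  if (config$noise_rate > 0) {
    genome <- sum(truth$chrom_sizes$length)
    n_noise <- rpois(nrow(samples), config$noise_rate * genome)
    s <- rep(seq_len(nrow(samples)), n_noise)
    if (length(s) > 0) {
      u <- runif(length(s), 0, genome)
      cum <- cumsum(truth$chrom_sizes$length)
      ci <- findInterval(u, c(0, head(cum, -1)), rightmost.closed = FALSE)
      tags$noise <- tibble(
        chrom = truth$chrom_sizes$chrom[ci],
        pos = as.integer(floor(u - c(0, head(cum, -1))[ci])),
        strand = sample(c("+", "-"), length(s), replace = TRUE),
        sample_id = samples$sample_id[s]
      )
    }
  }

  out <- bind_rows(tags)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  count = integer(), sample_id = character()))
  }
  out |>
    count(.data$chrom, .data$pos, .data$strand, .data$sample_id, name = "count") |>
    select("chrom", "pos", "strand", "count", "sample_id") |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$strand)
}

# candidate (anchor, bin) slot table: every fixed-width other-end bin within
# [min_dist, max_dist] of each anchor midpoint, on the anchor's chromosome
hic_slots <- function(probes, chrom_sizes, bin_size, min_dist, max_dist) {
  probes$mid <- region_mid(probes)
  purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    L <- chrom_sizes$length[match(probes$chrom[i], chrom_sizes$chrom)]
    nbin <- floor(L / bin_size)
    mid <- probes$mid[i]
    j <- seq(max(0, floor((mid - max_dist) / bin_size)),
             min(nbin - 1, floor((mid + max_dist) / bin_size)))
    bmid <- (j + 0.5) * bin_size
    d <- abs(bmid - mid)
    keep <- d >= min_dist & d <= max_dist
    tibble(anchor_id = probes$id[i], chrom = probes$chrom[i],
           bin = j[keep], dist = d[keep])
  })
}

#' Generate capture Hi-C valid-pair tables with planted contacts
#'
#' Background supporting-pair counts between an anchor probe and a distal
#' fixed-width bin are Poisson with a power-law distance decay; a planted
#' interaction multiplies the expected count by `lambda` in both replicates at
#' its active timepoints. Negative-control probes receive background only.
#'
#' @param truth a [gen_landscape()] result
#' @param config the matching [sim_config()]
#' @return list with `pairs` (canonicalized valid-pair tibble across all
#'   timepoint x replicate samples), `samples` (their metadata) and
#'   `slot_mu` (per-slot background means, useful for diagnostics)
#' @export
gen_hic <- function(truth, config = sim_config()) {
  set.seed(child_seed(config$seed, 3))
  check_that(config$lambda >= 1, "planted interaction effect lambda must be >= 1")
  probes <- truth$probes
  slots <- hic_slots(probes, truth$chrom_sizes, config$hic_bin,
                     config$hic_min_dist, config$hic_max_dist)
  decay <- (slots$dist / config$hic_min_dist)^(-config$hic_decay)
  C <- config$hic_pairs / sum(decay)
  slots$mu <- C * decay

  # planted slots: (anchor, bin containing the partner midpoint)
  planted <- truth$planted_interactions
  if (nrow(planted) > 0) {
    pl <- tibble(anchor_id = planted$anchor_id,
                 bin = floor(planted$other_mid / config$hic_bin),
                 lambda = planted$lambda,
                 timepoints = planted$timepoints)
    pl <- tidyr::unnest(pl, "timepoints") |> rename(timepoint = "timepoints")
  } else {
    pl <- tibble(anchor_id = character(), bin = integer(),
                 lambda = numeric(), timepoint = character())
  }

  samples <- sim_samples(config, assays = "hic")
  probes$mid <- region_mid(probes)
  pair_list <- purrr::map(seq_len(nrow(samples)), function(si) {
    tp <- samples$timepoint[si]
    mu <- slots$mu
    if (nrow(pl) > 0) {
      key <- paste(slots$anchor_id, slots$bin)
      boosted <- pl[pl$timepoint == tp, ]
      hit <- match(key, paste(boosted$anchor_id, boosted$bin))
      mu <- ifelse(is.na(hit), mu, mu * boosted$lambda[pmax(hit, 1)])
    }
    n <- rpois(length(mu), mu)
    keep <- n > 0
    idx <- rep(which(keep), n[keep])
    pi <- match(slots$anchor_id[idx], probes$id)
    pos1 <- floor(runif(length(idx), probes$start[pi], probes$end[pi]))
    pos2 <- floor(runif(length(idx),
                        slots$bin[idx] * config$hic_bin,
                        (slots$bin[idx] + 1) * config$hic_bin))
    tibble(chrom1 = slots$chrom[idx], pos1 = as.integer(pos1),
           strand1 = sample(c("+", "-"), length(idx), replace = TRUE),
           chrom2 = slots$chrom[idx], pos2 = as.integer(pos2),
           strand2 = sample(c("+", "-"), length(idx), replace = TRUE),
           sample_id = samples$sample_id[si])
  })
  pairs <- canonicalize_pairs(bind_rows(pair_list))
  list(pairs = pairs, samples = samples,
       slot_mu = slots[, c("anchor_id", "chrom", "bin", "dist", "mu")])
}

#' Generate variants, LD pairs, GWAS and eQTL SNP lists
#'
#' SNP density inside enhancers is `enh_snp_factor` times the background
#' density; LD r-squared decays exponentially with distance within blocks;
#' allele frequencies are Beta-distributed; GWAS index SNPs are drawn with
#' weight favouring enhancer SNPs by the same factor; eQTL flags are elevated
#' inside enhancers.
#'
#' @param truth a [gen_landscape()] result
#' @param config the matching [sim_config()]
#' @return list with `variants`, `ld`, `gwas` (index snp ids), `eqtl` (snp ids)
#' @export
gen_variants <- function(truth, config = sim_config()) {
  set.seed(child_seed(config$seed, 4))
  check_that(config$enh_snp_factor >= 0, "enrichment factor must be >= 0")
  genome <- sum(truth$chrom_sizes$length)
  cum <- cumsum(truth$chrom_sizes$length)
  off <- c(0, head(cum, -1))

  n_base <- rpois(1, config$snp_rate * genome)
  u <- runif(n_base, 0, genome)
  ci <- findInterval(u, off, rightmost.closed = FALSE)
  base <- tibble(chrom = truth$chrom_sizes$chrom[ci],
                 pos = as.integer(floor(u - off[ci])))

  extra <- NULL
  enh <- truth$enhancers
  if (config$enh_snp_factor > 1 && nrow(enh) > 0) {
    widths <- enh$end - enh$start
    n_extra <- rpois(1, (config$enh_snp_factor - 1) * config$snp_rate * sum(widths))
    e <- sample.int(nrow(enh), n_extra, replace = TRUE, prob = widths)
    extra <- tibble(chrom = enh$chrom[e],
                    pos = as.integer(floor(runif(n_extra, enh$start[e], enh$end[e]))))
  }

  v <- bind_rows(base, extra) |> distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
  bases <- c("A", "C", "G", "T")
  v$ref <- sample(bases, nrow(v), replace = TRUE)
  v$alt <- vapply(v$ref, function(r) sample(setdiff(bases, r), 1), "")
  v$af <- rbeta(nrow(v), config$af_shape[1], config$af_shape[2])
  v$snp_id <- sprintf("rs%07d", seq_len(nrow(v)))
  v <- select(v, "snp_id", "chrom", "pos", "ref", "alt", "af")

  in_enh <- character(0)
  if (nrow(enh) > 0) {
    in_enh <- overlaps_any(
      tibble(chrom = v$chrom, start = v$pos, end = v$pos + 1L, id = v$snp_id),
      enh)
  }
  v$in_enhancer <- v$snp_id %in% in_enh

  # LD: within-block pairs up to ld_max_pair_dist, r2 decaying with distance
  ld <- NULL
  if (config$ld_block > 1 && nrow(v) > 1) {
    v$block <- paste(v$chrom, floor(v$pos / config$ld_block))
    pieces <- list()
    for (k in seq_len(50)) {
      a <- v[seq_len(nrow(v) - k), ]
      b <- v[-seq_len(k), ]
      ok <- a$block == b$block & (b$pos - a$pos) <= config$ld_max_pair_dist
      if (!any(ok)) break
      pieces[[k]] <- tibble(snp_a = a$snp_id[ok], snp_b = b$snp_id[ok],
                            distance = b$pos[ok] - a$pos[ok])
    }
    ld <- bind_rows(pieces)
    if (!is.null(ld) && nrow(ld) > 0) {
      ld$r2 <- exp(-ld$distance / config$ld_scale)
    }
    v$block <- NULL
  }
  if (is.null(ld) || nrow(ld) == 0) {
    ld <- tibble(snp_a = character(), snp_b = character(),
                 distance = integer(), r2 = numeric())
  }

  # GWAS index SNPs, weighted at the locus level (index or any LD proxy in an
  # enhancer), spaced apart; locus-level weighting makes the planted
  # enrichment factor apply to the quantity the permutation test measures
  lh <- if (nrow(enh) > 0) {
    locus_hits(v, ld, enh)
  } else setNames(rep(FALSE, nrow(v)), v$snp_id)
  w <- ifelse(lh[v$snp_id], config$enh_snp_factor, 1)
  ord <- sample.int(nrow(v), prob = w)
  gwas <- character(0)
  last_pos <- list()
  for (i in ord) {
    ch <- v$chrom[i]; p <- v$pos[i]
    near <- last_pos[[ch]]
    if (is.null(near) || all(abs(near - p) >= config$gwas_min_spacing)) {
      gwas <- c(gwas, v$snp_id[i])
      last_pos[[ch]] <- c(near, p)
      if (length(gwas) >= config$n_gwas_loci) break
    }
  }

  p_eqtl <- ifelse(v$in_enhancer,
                   pmin(1, config$eqtl_rate * config$eqtl_enh_factor),
                   config$eqtl_rate)
  eqtl <- v$snp_id[runif(nrow(v)) < p_eqtl]

  list(variants = v, ld = ld, gwas = gwas, eqtl = eqtl)
}

#' Generate a conservation score track (bedGraph-style tiles)
#'
#' Per-tile scores are Gaussian around `cons_base`, shifted up by `cons_shift`
#' inside enhancers, and clipped to `[0, 1]`.
#'
#' @param truth a [gen_landscape()] result
#' @param config the matching [sim_config()]
#' @return tibble with chrom, start, end, score
#' @export
gen_conservation <- function(truth, config = sim_config()) {
  set.seed(child_seed(config$seed, 5))
  check_that(config$cons_base >= 0 && config$cons_base <= 1,
             "cons_base must lie in [0, 1]")
  step <- config$cons_step
  track <- purrr::map_dfr(seq_len(nrow(truth$chrom_sizes)), function(i) {
    L <- truth$chrom_sizes$length[i]
    starts <- seq(0, L - step, by = step)
    tibble(chrom = truth$chrom_sizes$chrom[i], start = as.integer(starts),
           end = as.integer(starts + step))
  })
  track$id <- sprintf("tile_%08d", seq_len(nrow(track)))
  track$score <- rnorm(nrow(track), config$cons_base, config$cons_sd)
  if (nrow(truth$enhancers) > 0 && config$cons_shift != 0) {
    hit <- overlaps_any(track, truth$enhancers)
    track$score[track$id %in% hit] <- track$score[track$id %in% hit] + config$cons_shift
  }
  track$score <- pmin(1, pmax(0, track$score))
  track$id <- NULL
  track
}

#' Run every generator and return all pipeline inputs
#'
#' @param config an [sim_config()] list
#' @return list with `config`, `truth`, `ctss`, `hic`, `variants`,
#'   `conservation`
#' @export
simulate_study <- function(config = sim_config()) {
  truth <- gen_landscape(config)
  list(config = config,
       truth = truth,
       ctss = gen_ctss(truth, config),
       hic = gen_hic(truth, config),
       variants = gen_variants(truth, config),
       conservation = gen_conservation(truth, config))
}

#' Load a simulation configuration from a YAML file
#'
#' Fields in the file override [sim_config()] defaults.
#'
#' @param path YAML file path
#' @return an `enhdyn_config` list
#' @export
sim_config_from_yaml <- function(path) {
  check_that(file.exists(path), paste("no such file:", path))
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write all generated inputs and truth tables to a directory
#'
#' Materializes a [simulate_study()] result as the plain-text files the
#' pipeline consumes — per-sample CTSS and valid-pair TSVs, BED catalogs
#' (promoters, enhancers, probes), variant/LD TSVs, GWAS and eQTL SNP lists,
#' the conservation bedGraph, a chrom-sizes table — plus `truth/` TSVs
#' (cluster labels, novelty flags, planted interactions) sufficient to score
#' every downstream stage. Returns the file manifest.
#'
#' @param sim a [simulate_study()] result
#' @param outdir output directory (created if needed)
#' @return invisibly, a character vector of written paths
#' @export
write_study <- function(sim, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(0)
  keep <- function(p) {
    paths <<- c(paths, p)
    p
  }
  truth <- sim$truth
  readr::write_tsv(truth$chrom_sizes,
                   keep(file.path(outdir, "chrom_sizes.tsv")),
                   col_names = FALSE)
  write_bed(truth$promoters, keep(file.path(outdir, "promoters.bed")))
  write_bed(truth$enhancers[, c("chrom", "start", "end", "strand", "id")],
            keep(file.path(outdir, "enhancers.bed")))
  write_bed(truth$probes[, c("chrom", "start", "end", "strand", "id")],
            keep(file.path(outdir, "probes.bed")))
  readr::write_tsv(truth$probes[, c("id", "class")],
                   keep(file.path(outdir, "probe_classes.tsv")))
  for (s in unique(sim$ctss$sample_id)) {
    write_ctss(sim$ctss[sim$ctss$sample_id == s, ],
               keep(file.path(outdir, paste0("ctss_", s, ".tsv"))))
  }
  for (s in unique(sim$hic$pairs$sample_id)) {
    write_pairs(sim$hic$pairs[sim$hic$pairs$sample_id == s, ],
                keep(file.path(outdir, paste0("pairs_", s, ".tsv"))))
  }
  write_variants(sim$variants$variants,
                 keep(file.path(outdir, "variants.tsv")))
  write_ld(sim$variants$ld, keep(file.path(outdir, "ld.tsv")))
  writeLines(sim$variants$gwas, keep(file.path(outdir, "gwas_snps.txt")))
  writeLines(sim$variants$eqtl, keep(file.path(outdir, "eqtl_snps.txt")))
  write_bedgraph(sim$conservation,
                 keep(file.path(outdir, "conservation.bedgraph")))
  readr::write_tsv(truth$promoters[, c("id", "cluster")],
                   keep(file.path(outdir, "truth", "promoter_clusters.tsv")))
  readr::write_tsv(truth$enhancers[, c("id", "cluster", "novelty", "balance")],
                   keep(file.path(outdir, "truth", "enhancer_truth.tsv")))
  pl <- truth$planted_interactions
  pl$timepoints <- vapply(pl$timepoints, paste, "", collapse = ",")
  readr::write_tsv(pl,
                   keep(file.path(outdir, "truth", "planted_interactions.tsv")))
  readr::write_tsv(truth$samples, keep(file.path(outdir, "samples.tsv")))
  invisible(paths)
}
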