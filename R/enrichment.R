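# GWAS-variant enrichment with LD expansion and matched-control permutations,
# and characterization of regulatory regions: conservation, SNP density,
# nucleotide diversity (pi = 2*AF*(1-AF)), eQTL overlap, and length-matched
# random region sampling.

#' Expand GWAS index SNPs to LD loci
#'
#' A proxy is included iff its r-squared with the index SNP is at least
#' `r2_threshold` and its distance at most `window`. Loci sharing proxies are
#' merged into one locus (union of proxies, indexed by the first index SNP).
#'
#' @param gwas_snps character vector of index SNP ids
#' @param ld LD pair tibble (snp_a, snp_b, r2, distance); treated as symmetric
#' @param r2_threshold minimum r-squared (default 0.7)
#' @param window maximum distance in bp (default 1 Mb)
#' @return tibble with locus (index snp id), snp_id (proxy, includes index)
#' @export
ld_expand <- function(gwas_snps, ld, r2_threshold = 0.7, window = 1e6) {
  check_that(r2_threshold >= 0 && r2_threshold <= 1,
             "r2_threshold must lie in [0, 1]")
  sym <- bind_rows(
    ld[, c("snp_a", "snp_b", "r2", "distance")],
    setNames(ld[, c("snp_b", "snp_a", "r2", "distance")],
             c("snp_a", "snp_b", "r2", "distance"))
  )
  sym <- sym[sym$r2 >= r2_threshold & sym$distance <= window &
               sym$snp_a %in% gwas_snps, ]
  adj <- split(sym$snp_b, factor(sym$snp_a, levels = gwas_snps))
  prox <- lapply(setNames(gwas_snps, gwas_snps), function(s) {
    unique(c(s, adj[[s]]))
  })
  # merge loci sharing proxies: connected components over shared-proxy edges
  long <- tibble(locus = rep(gwas_snps, lengths(prox)),
                 snp_id = unlist(prox, use.names = FALSE))
  # chain edges between loci sharing a proxy are enough for the components
  edges <- long |>
    group_by(.data$snp_id) |>
    mutate(prev = lag(.data$locus)) |>
    ungroup() |>
    filter(!is.na(.data$prev), .data$prev != .data$locus) |>
    distinct(.data$prev, .data$locus)
  comp_of <- setNames(seq_along(gwas_snps), gwas_snps)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = gwas_snps))
    comp_of <- igraph::components(g)$membership
  }
  # representative index snp per component: the first in input order
  rep_of <- tapply(gwas_snps, comp_of[gwas_snps], function(x) x[1])
  long$locus <- as.character(rep_of[as.character(comp_of[long$locus])])
  distinct(long, .data$locus, .data$snp_id)
}

# covariate bins for control matching
matching_bins <- function(variants, ld, gene_regions, r2_threshold = 0.7,
                          window = 1e6) {
  v <- variants
  maf <- pmin(v$af, 1 - v$af)
  maf_bin <- as.integer(cut(maf, breaks = quantile(maf, probs = seq(0, 1, 0.1)),
                            include.lowest = TRUE))
  sym <- bind_rows(ld[, c("snp_a", "snp_b", "r2", "distance")],
                   setNames(ld[, c("snp_b", "snp_a", "r2", "distance")],
                            c("snp_a", "snp_b", "r2", "distance")))
  sym <- sym[sym$r2 >= r2_threshold & sym$distance <= window, ]
  np <- table(factor(sym$snp_a, levels = v$snp_id))
  proxy_bin <- cut(as.integer(np), breaks = c(-1, 0, 2, 5, Inf),
                   labels = c("0", "1-2", "3-5", "6+"))
  dist_bin <- rep("na", nrow(v))
  if (!is.null(gene_regions) && nrow(gene_regions) > 0) {
    near <- nearest_promoter(
      tibble(chrom = v$chrom, start = v$pos, end = v$pos + 1L, id = v$snp_id),
      gene_regions)
    d <- near$distance[match(v$snp_id, near$enhancer_id)]
    qs <- quantile(d, probs = c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE)
    dist_bin <- as.character(cut(d, breaks = unique(qs), include.lowest = TRUE))
    dist_bin[is.na(dist_bin)] <- "na"
  }
  tibble(snp_id = v$snp_id,
         maf_bin = maf_bin,
         proxy_bin = as.character(proxy_bin),
         dist_bin = dist_bin)
}

#' Matched control SNPs for each GWAS index SNP
#'
#' Controls are drawn from the variant pool within the same covariate bin
#' (MAF decile, LD-proxy-count bin, distance-to-nearest-gene tertile),
#' excluding the index SNP and its proxies. When a bin holds fewer than
#' `min_neighbors` controls the matching is widened (covariates dropped one
#' at a time) with a warning.
#'
#' @param index_snps character vector of index SNP ids
#' @param variants variant tibble (snp_id, chrom, pos, af)
#' @param ld LD pair tibble
#' @param gene_regions region tibble used for the distance covariate
#' @param min_neighbors minimum controls per index SNP (default 500)
#' @param r2_threshold,window LD expansion parameters for proxy exclusion
#' @return named list: for each index snp, a character vector of control ids
#' @export
match_controls <- function(index_snps, variants, ld, gene_regions = NULL,
                           min_neighbors = 500, r2_threshold = 0.7,
                           window = 1e6) {
  check_that(nrow(variants) >= min_neighbors,
             "variant pool smaller than min_neighbors")
  bins <- matching_bins(variants, ld, gene_regions, r2_threshold, window)
  expanded <- ld_expand(index_snps, ld, r2_threshold, window)
  widened <- 0
  out <- lapply(setNames(index_snps, index_snps), function(s) {
    b <- bins[bins$snp_id == s, ]
    excl <- c(s, expanded$snp_id[expanded$locus == s])
    lvls <- list(
      c("maf_bin", "proxy_bin", "dist_bin"),
      c("maf_bin", "proxy_bin"),
      c("maf_bin"),
      character(0)
    )
    for (use in lvls) {
      cand <- bins
      for (cv in use) cand <- cand[cand[[cv]] == b[[cv]][1], ]
      cand <- cand$snp_id[!cand$snp_id %in% excl]
      if (length(cand) >= min_neighbors) {
        if (length(use) < 3) widened <<- widened + 1
        return(cand)
      }
    }
    widened <<- widened + 1
    setdiff(bins$snp_id, excl)
  })
  if (widened > 0) {
    warn(sprintf("matching bins widened for %d of %d index SNPs",
                 widened, length(index_snps)))
  }
  out
}

#' Locus-level region-hit indicator for every SNP in a pool
#'
#' For each SNP, `TRUE` iff the SNP itself or any of its LD proxies
#' (r-squared >= `r2_threshold` within `window`) falls inside the regions.
#'
#' @param variants variant tibble (snp_id, chrom, pos)
#' @param ld LD pair tibble
#' @param regions region tibble
#' @param r2_threshold,window LD expansion parameters
#' @return named logical vector over `variants$snp_id`
#' @export
locus_hits <- function(variants, ld, regions, r2_threshold = 0.7, window = 1e6) {
  regions <- as_regions(regions, prefix = "reg")
  snp_regions <- tibble(chrom = variants$chrom, start = variants$pos,
                        end = variants$pos + 1L, id = variants$snp_id)
  in_region <- variants$snp_id %in% overlaps_any(snp_regions, regions)
  names(in_region) <- variants$snp_id
  sym <- bind_rows(ld[, c("snp_a", "snp_b", "r2", "distance")],
                   setNames(ld[, c("snp_b", "snp_a", "r2", "distance")],
                            c("snp_a", "snp_b", "r2", "distance")))
  sym <- sym[sym$r2 >= r2_threshold & sym$distance <= window, ]
  out <- in_region
  if (nrow(sym) > 0) {
    proxy_hit <- tapply(in_region[sym$snp_b], sym$snp_a, any)
    idx <- match(names(proxy_hit), names(out))
    out[idx] <- out[idx] | proxy_hit
  }
  out
}

#' Permutation test of GWAS-locus enrichment in regions
#'
#' `observed` is the number of loci with at least one proxy SNP inside the
#' regions. Each permutation replaces every index SNP with a random matched
#' control, expands it through LD identically, and recounts.
#' `p = (#permutations >= observed + 1) / (n + 1)`; `expected` is the
#' permutation mean and `fold = observed / expected`.
#'
#' @param loci [ld_expand()] tibble for the index SNPs
#' @param regions region tibble tested for enrichment
#' @param controls [match_controls()] list
#' @param variants variant tibble (positions for the whole pool)
#' @param ld LD pair tibble (for control expansion)
#' @param n_permutations number of permutations (default 1000)
#' @param seed RNG seed
#' @param r2_threshold,window LD expansion parameters
#' @param locus_hit optional precomputed [locus_hits()] vector for the pool
#'   (recomputed when `NULL`)
#' @return object of class `enhdyn_enrichment`
#' @export
enrichment_test <- function(loci, regions, controls, variants, ld,
                            n_permutations = 1000, seed = 1,
                            r2_threshold = 0.7, window = 1e6,
                            locus_hit = NULL) {
  check_that(n_permutations > 0, "n_permutations must be positive")
  if (n_permutations < 100) warn("fewer than 100 permutations: p is coarse")
  set.seed(seed)
  if (is.null(locus_hit)) {
    locus_hit <- locus_hits(variants, ld, regions, r2_threshold, window)
  }
  locus_hit_by_snp <- locus_hit

  # observed and permuted counts use the same locus-level hit definition so
  # that the permutation null is exchangeable with the observed statistic
  index_snps <- unique(loci$locus)
  observed <- sum(locus_hit_by_snp[index_snps], na.rm = TRUE)

  perm <- vapply(seq_len(n_permutations), function(i) {
    picks <- vapply(index_snps, function(s) {
      pool <- controls[[s]]
      pool[sample.int(length(pool), 1)]
    }, "")
    sum(locus_hit_by_snp[picks])
  }, 0)

  expected <- mean(perm)
  p <- (sum(perm >= observed) + 1) / (n_permutations + 1)
  fold <- if (expected > 0) observed / expected else NA_real_
  structure(list(observed = observed, expected = expected, fold = fold,
                 p = p, n_permutations = n_permutations,
                 n_loci = length(index_snps), perm = perm),
            class = "enhdyn_enrichment")
}

#' @export
print.enhdyn_enrichment <- function(x, ...) {
  cat(sprintf(
    "GWAS enrichment: observed %d / %d loci, expected %.2f, fold %.2f, p = %.4g (%d permutations)\n",
    x$observed, x$n_loci, x$expected, x$fold, x$p, x$n_permutations))
  invisible(x)
}

#' @export
tidy.enhdyn_enrichment <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected, fold = x$fold,
         p = x$p, n_loci = x$n_loci, n_permutations = x$n_permutations)
}

#' @export
glance.enhdyn_enrichment <- function(x, ...) tidy(x)

#' Sample random regions matched on length distribution
#'
#' Produces a region set whose multiset of lengths equals the template's
#' exactly; placements are uniform over the genome, rejected when they
#' overlap an excluded region (telomere/centromere stand-ins, probes, ...).
#'
#' @param template region tibble whose lengths are copied
#' @param chrom_sizes tibble with chrom, length
#' @param excluded optional region tibble placements must avoid
#' @param seed RNG seed
#' @param max_retry placement attempts per region (default 1000)
#' @return region tibble of matched random regions
#' @export
sample_matched_regions <- function(template, chrom_sizes, excluded = NULL,
                                   seed = 1, max_retry = 1000) {
  set.seed(seed)
  lens <- sample(template$end - template$start)
  excl_gr <- NULL
  if (!is.null(excluded) && nrow(excluded) > 0) {
    excl_gr <- GenomicRanges::reduce(regions_to_gr(as_regions(excluded, "excl")),
                                     ignore.strand = TRUE)
  }
  out <- purrr::map_dfr(seq_along(lens), function(i) {
    w <- lens[i]
    for (try in seq_len(max_retry)) {
      ci <- sample.int(nrow(chrom_sizes), 1, prob = chrom_sizes$length)
      L <- chrom_sizes$length[ci]
      if (L <= w) next
      s <- floor(runif(1, 0, L - w))
      if (!is.null(excl_gr)) {
        cand <- GenomicRanges::GRanges(chrom_sizes$chrom[ci],
                                       IRanges::IRanges(s + 1, s + w))
        hit <- suppressWarnings(GenomicRanges::findOverlaps(cand, excl_gr))
        if (length(hit) > 0) next
      }
      return(tibble(chrom = chrom_sizes$chrom[ci], start = as.integer(s),
                    end = as.integer(s + w), strand = "*",
                    id = sprintf("rand_%05d", i)))
    }
    abort("could not place a matched region after max_retry attempts")
  })
  as_regions(out)
}

#' Per-region mean conservation and group comparison
#'
#' Base-weighted mean of the score track over each region, for the test set
#' and each comparison set, with two-sided Wilcoxon rank-sum tests of the
#' test set against every other set.
#'
#' @param region_sets named list of region tibbles; the first is the test set
#' @param track score tibble (chrom, start, end, score)
#' @return list with `means` (per-region tibble: set, id, mean_score) and
#'   `tests` (tibble: set, p, median_test, median_other)
#' @export
conservation_compare <- function(region_sets, track) {
  check_that(nrow(track) > 0, "empty score track")
  track_regions <- tibble(chrom = track$chrom, start = track$start,
                          end = track$end,
                          id = as.character(seq_len(nrow(track))))
  means <- purrr::imap_dfr(region_sets, function(regs, nm) {
    regs <- as_regions(regs, prefix = nm)
    ov <- overlap_pairs(regs, track_regions)
    if (nrow(ov) == 0) {
      return(tibble(set = nm, id = regs$id, mean_score = NA_real_))
    }
    ov$score <- track$score[as.integer(ov$b_id)]
    agg <- ov |>
      group_by(.data$a_id) |>
      summarise(mean_score = sum(.data$score * .data$overlap_bp) /
                  sum(.data$overlap_bp), .groups = "drop")
    tibble(set = nm, id = regs$id,
           mean_score = agg$mean_score[match(regs$id, agg$a_id)])
  })
  test_set <- names(region_sets)[1]
  x <- means$mean_score[means$set == test_set]
  tests <- purrr::map_dfr(setdiff(names(region_sets), test_set), function(nm) {
    y <- means$mean_score[means$set == nm]
    wt <- suppressWarnings(wilcox.test(x, y))
    pv <- wt$p.value
    if (!is.finite(pv)) pv <- 1  # fully tied groups carry no evidence
    tibble(set = nm, p = pv,
           median_test = median(x, na.rm = TRUE),
           median_other = median(y, na.rm = TRUE))
  })
  list(means = means, tests = tests)
}

#' Per-region SNP count and nucleotide diversity
#'
#' Per-SNP nucleotide diversity is `pi = 2 * AF * (1 - AF)`; each region's
#' `mean_pi` averages over its SNPs (0 when it has none). `log_mean_pi` is
#' log10 of `mean_pi` plus the smallest non-zero regional mean (the standard
#' offset to avoid log of zero).
#'
#' @param regions region tibble
#' @param variants variant tibble with af
#' @return tibble with id, n_snps, mean_pi, log_mean_pi
#' @export
nucleotide_diversity <- function(regions, variants) {
  check_that(all(variants$af >= 0 & variants$af <= 1),
             "allele frequencies must lie in [0, 1]")
  regions <- as_regions(regions)
  snp_regions <- tibble(chrom = variants$chrom, start = variants$pos,
                        end = variants$pos + 1L, id = variants$snp_id)
  ov <- overlap_pairs(snp_regions, regions)
  pi_snp <- 2 * variants$af * (1 - variants$af)
  names(pi_snp) <- variants$snp_id
  agg <- ov |>
    group_by(.data$b_id) |>
    summarise(n_snps = n(), mean_pi = mean(pi_snp[.data$a_id]),
              .groups = "drop")
  out <- tibble(id = regions$id) |>
    left_join(agg, by = c(id = "b_id")) |>
    mutate(n_snps = ifelse(is.na(.data$n_snps), 0L, .data$n_snps),
           mean_pi = ifelse(is.na(.data$mean_pi), 0, .data$mean_pi))
  nz <- out$mean_pi[out$mean_pi > 0]
  offset <- if (length(nz)) min(nz) else 1e-6
  out$log_mean_pi <- log10(out$mean_pi + offset)
  out
}

#' eQTL enrichment of region SNPs against a comparison SNP set
#'
#' 2x2 Fisher's exact test of eQTL membership among SNPs inside the test
#' regions vs SNPs inside the comparison (random) regions; `fold` is the
#' ratio of eQTL proportions.
#'
#' @param region_snps SNP ids inside the test regions
#' @param eqtl_snps SNP ids flagged as eQTLs
#' @param random_snps SNP ids inside the comparison regions
#' @return tibble with fold, p and the 2x2 counts
#' @export
eqtl_enrichment <- function(region_snps, eqtl_snps, random_snps) {
  check_that(length(random_snps) > 0, "empty random SNP set")
  a <- sum(region_snps %in% eqtl_snps)
  b <- length(region_snps) - a
  c <- sum(random_snps %in% eqtl_snps)
  d <- length(random_snps) - c
  ft <- fisher.test(matrix(c(a, b, c, d), 2))
  fold <- if (c > 0) (a / (a + b)) / (c / (c + d)) else NA_real_
  tibble(fold = fold, p = ft$p.value, eqtl_in_regions = a,
         n_region_snps = a + b, eqtl_in_random = c, n_random_snps = c + d)
}
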