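# Capture Hi-C interaction calling against an empirical negative-control
# background, per-timepoint interaction networks, and per-node interactome
# change statistics (Jaccard index and overlap coefficient).

#' Bin valid pairs into anchored supporting-pair counts
#'
#' A pair supports (anchor, bin) iff one end falls inside the anchor's probe
#' region and the other end in the fixed-width other-end bin. Pairs with both
#' ends in probes are counted once per anchor. Trans-chromosomal pairs and
#' pairs with anchor-to-bin midpoint distance outside
#' `[min_distance, max_distance]` are dropped; the short-range exclusion
#' removes the proximity-ligation regime where the empirical background is
#' uninformative.
#'
#' @param pairs canonicalized valid-pair tibble with sample_id
#' @param probes region tibble with a `class` column
#'   (promoter/enhancer/gwas/negative_control)
#' @param samples tibble mapping sample_id to timepoint and replicate
#' @param bin_size other-end bin width in bp (default 2000)
#' @param max_distance maximum anchor-bin distance (default 2 Mb)
#' @param min_distance minimum anchor-bin distance (default 10 kb)
#' @return tibble with anchor_id, anchor_class, chrom, bin, dist, timepoint,
#'   replicate, support
#' @export
bin_pairs <- function(pairs, probes, samples, bin_size = 2000,
                      max_distance = 2e6, min_distance = 1e4) {
  check_that(bin_size > 0, "bin_size must be positive")
  probes <- as_regions(probes, prefix = "probe")
  check_that("class" %in% names(probes), "probes need a class column")
  amid <- region_mid(probes)
  cis <- pairs[pairs$chrom1 == pairs$chrom2, ]
  if (nrow(cis) == 0) {
    return(tibble(anchor_id = character(), anchor_class = character(),
                  chrom = character(), bin = integer(), dist = numeric(),
                  timepoint = character(), replicate = integer(),
                  support = integer()))
  }

  end_support <- function(pos_anchor, pos_other) {
    ends <- tibble(chrom = cis$chrom1, start = pos_anchor,
                   end = pos_anchor + 1L, id = as.character(seq_len(nrow(cis))))
    ov <- overlap_pairs(ends, probes)
    if (nrow(ov) == 0) return(NULL)
    i <- as.integer(ov$a_id)
    pr <- match(ov$b_id, probes$id)
    bin <- floor(pos_other[i] / bin_size)
    d <- abs((bin + 0.5) * bin_size - amid[pr])
    keep <- d >= min_distance & d <= max_distance
    tibble(anchor_id = probes$id[pr[keep]],
           anchor_class = probes$class[pr[keep]],
           chrom = cis$chrom1[i[keep]], bin = bin[keep], dist = d[keep],
           sample_id = cis$sample_id[i[keep]])
  }

  sup <- bind_rows(end_support(cis$pos1, cis$pos2),
                   end_support(cis$pos2, cis$pos1))
  if (is.null(sup) || nrow(sup) == 0) {
    return(tibble(anchor_id = character(), anchor_class = character(),
                  chrom = character(), bin = integer(), dist = numeric(),
                  timepoint = character(), replicate = integer(),
                  support = integer()))
  }
  sup |>
    count(.data$anchor_id, .data$anchor_class, .data$chrom, .data$bin,
          .data$dist, .data$sample_id, name = "support") |>
    left_join(samples[, c("sample_id", "timepoint", "replicate")],
              by = "sample_id") |>
    select("anchor_id", "anchor_class", "chrom", "bin", "dist",
           "timepoint", "replicate", "support")
}

# log-spaced distance-bin edges
distance_bin_edges <- function(min_distance, max_distance, n_bins) {
  exp(seq(log(min_distance), log(max_distance), length.out = n_bins + 1))
}

#' Fit the empirical interaction background from negative-control probes
#'
#' For each log-spaced distance bin, stores the empirical multiset of
#' supporting-pair values over all (negative-control anchor, other-end bin,
#' replicate) slots -- including the zero-support slots, whose number is
#' derived from the probe geometry. The upper-tail probability of a support
#' value k >= 1 is `p(k) = (#values >= k + 1) / (N + 1)`; the +1 pseudocount
#' keeps p strictly positive with a finite control sample. Distance bins with
#' fewer than `min_obs` nonzero-capable slots are merged upward.
#'
#' @param support one timepoint's [bin_pairs()] table (all anchors; only
#'   negative_control rows are used)
#' @param probes probe region tibble with class column
#' @param chrom_sizes tibble with chrom, length
#' @param bin_size,min_distance,max_distance binning geometry (must match
#'   [bin_pairs()])
#' @param n_distance_bins number of log-spaced distance bins (default 20)
#' @param min_obs minimum negative-control slots per distance bin before
#'   merging upward (default 50)
#' @param n_reps number of replicates contributing values per slot
#' @return object of class `enhdyn_background`
#' @export
fit_background <- function(support, probes, chrom_sizes, bin_size = 2000,
                           min_distance = 1e4, max_distance = 2e6,
                           n_distance_bins = 20, min_obs = 50, n_reps = 2) {
  neg <- probes[probes$class == "negative_control", ]
  check_that(nrow(neg) > 0, "no negative-control probes: cannot fit background")
  edges <- distance_bin_edges(min_distance, max_distance, n_distance_bins)
  slots <- hic_slots(as_regions(neg), chrom_sizes, bin_size,
                     min_distance, max_distance)
  slot_bin <- findInterval(slots$dist, edges, rightmost.closed = TRUE,
                           all.inside = TRUE)
  N_slots <- tabulate(slot_bin, nbins = n_distance_bins)

  # merge sparse bins upward
  merge_map <- seq_len(n_distance_bins)
  i <- 1
  while (i < n_distance_bins) {
    if (N_slots[i] < min_obs) {
      merge_map[merge_map == i] <- i + 1
      N_slots[i + 1] <- N_slots[i + 1] + N_slots[i]
      N_slots[i] <- 0
    }
    i <- i + 1
  }

  negsup <- support[support$anchor_class == "negative_control" &
                      support$support > 0, ]
  nb <- findInterval(negsup$dist, edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nb <- merge_map[nb]
  values <- lapply(seq_len(n_distance_bins), function(b) {
    sort(negsup$support[nb == b])
  })
  structure(list(edges = edges, merge_map = merge_map,
                 N = N_slots * n_reps, values = values,
                 n_reps = n_reps),
            class = "enhdyn_background")
}

#' Empirical upper-tail probability with a +1 pseudocount
#'
#' `p(k) = (#values >= k + 1) / (N + 1)` over a multiset of `N` background
#' values; `p(0) = 1`. The pseudocount keeps p strictly positive with a
#' finite background sample.
#'
#' @param values sorted or unsorted numeric background values
#' @param k support value(s) to score
#' @param n_total total multiset size `N` (defaults to `length(values)`;
#'   pass the full slot count when `values` omits zeros)
#' @return numeric vector of tail probabilities
#' @export
empirical_tail_p <- function(values, k, n_total = length(values)) {
  v <- sort(values)
  vapply(k, function(ki) {
    if (ki <= 0) return(1)
    n_ge <- length(v) - findInterval(ki - 1e-9, v)
    (n_ge + 1) / (n_total + 1)
  }, 0)
}

#' Empirical upper-tail probability of a support value
#'
#' @param bg an [fit_background()] model
#' @param dist anchor-bin distance(s)
#' @param k support value(s)
#' @return numeric vector of tail probabilities
#' @export
background_p <- function(bg, dist, k) {
  b <- findInterval(dist, bg$edges, rightmost.closed = TRUE, all.inside = TRUE)
  b <- bg$merge_map[b]
  vapply(seq_along(k), function(i) {
    empirical_tail_p(bg$values[[b[i]]], k[i], n_total = bg$N[b[i]])
  }, 0)
}

#' Call significant interactions against the empirical background
#'
#' Per timepoint: slots whose supporting pairs reach `min_support` in every
#' replicate are the candidates; each candidate replicate gets an empirical
#' p-value from the negative-control background at its distance, Bonferroni
#' corrected by m = number of candidate slots at that timepoint. An
#' interaction passes (`pass_both`) iff support >= `min_support` and
#' Bonferroni p <= `alpha` in both replicates; `pass_any` (at least one
#' replicate) is used for network construction. Candidates whose other-end
#' bin overlaps a blacklist region are removed.
#'
#' @param support [bin_pairs()] table for all timepoints
#' @param probes probe region tibble with class column
#' @param chrom_sizes tibble with chrom, length
#' @param bin_size,min_distance,max_distance geometry matching [bin_pairs()]
#' @param min_support minimum supporting pairs per replicate (default 5)
#' @param alpha Bonferroni-adjusted p cutoff (default 0.1)
#' @param n_distance_bins background distance bins (default 20)
#' @param blacklist optional region tibble; calls in these regions are dropped
#' @return object of class `enhdyn_calls`: tibble of candidates with
#'   per-replicate support/p/pass columns plus `pass_both`/`pass_any`;
#'   attribute `m` gives the per-timepoint multiplicity
#' @export
call_interactions <- function(support, probes, chrom_sizes, bin_size = 2000,
                              min_distance = 1e4, max_distance = 2e6,
                              min_support = 5, alpha = 0.1,
                              n_distance_bins = 20, blacklist = NULL) {
  check_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  reps <- sort(unique(support$replicate))
  n_reps <- length(reps)
  tps <- unique(support$timepoint)
  m_by_tp <- setNames(numeric(length(tps)), tps)

  out <- purrr::map_dfr(tps, function(tp) {
    sup_tp <- support[support$timepoint == tp, ]
    # complete replicate columns with zeros
    wide <- sup_tp |>
      select("anchor_id", "anchor_class", "chrom", "bin", "dist",
             "replicate", "support") |>
      tidyr::pivot_wider(names_from = "replicate", values_from = "support",
                         names_prefix = "support_r", values_fill = 0L)
    sup_cols <- paste0("support_r", reps)
    for (cc in setdiff(sup_cols, names(wide))) wide[[cc]] <- 0L
    smat <- as.matrix(wide[, sup_cols])
    cand <- wide[rowSums(smat >= min_support) == n_reps, ]
    if (nrow(cand) == 0) return(NULL)

    if (!is.null(blacklist) && nrow(blacklist) > 0) {
      bin_regions <- tibble(chrom = cand$chrom,
                            start = as.integer(cand$bin * bin_size),
                            end = as.integer((cand$bin + 1) * bin_size),
                            id = as.character(seq_len(nrow(cand))))
      bad <- overlaps_any(bin_regions, as_regions(blacklist, prefix = "bl"))
      cand <- cand[!as.character(seq_len(nrow(cand))) %in% bad, ]
      if (nrow(cand) == 0) return(NULL)
    }

    m <- nrow(cand)
    m_by_tp[tp] <<- m
    bg <- fit_background(sup_tp, probes, chrom_sizes, bin_size,
                         min_distance, max_distance, n_distance_bins,
                         n_reps = n_reps)
    pass <- matrix(FALSE, nrow(cand), n_reps)
    for (r in seq_len(n_reps)) {
      k <- cand[[paste0("support_r", reps[r])]]
      p <- background_p(bg, cand$dist, k)
      pb <- pmin(1, p * m)
      cand[[paste0("p_r", reps[r])]] <- p
      cand[[paste0("p_bonf_r", reps[r])]] <- pb
      pass[, r] <- k >= min_support & pb <= alpha
      cand[[paste0("pass_r", reps[r])]] <- pass[, r]
    }
    cand$pass_both <- rowSums(pass) == n_reps
    cand$pass_any <- rowSums(pass) >= 1
    cand$timepoint <- tp
    cand$bin_start <- as.integer(cand$bin * bin_size)
    cand$bin_end <- as.integer((cand$bin + 1) * bin_size)
    cand
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(anchor_id = character(), anchor_class = character(),
                  chrom = character(), bin = integer(), dist = numeric(),
                  timepoint = character(), pass_both = logical(),
                  pass_any = logical())
  }
  attr(out, "m") <- m_by_tp
  attr(out, "min_support") <- min_support
  attr(out, "alpha") <- alpha
  class(out) <- c("enhdyn_calls", class(out))
  out
}

#' Two-sample proportion test of interaction frequency, targets vs controls
#'
#' Compares hits/candidates between targeted probes and negative controls
#' with the chi-squared test for equality of proportions with continuity
#' correction. `fold` is the ratio of the two proportions.
#'
#' @param hits_target,n_target hits and candidate slots for targets
#' @param hits_neg,n_neg hits and candidate slots for negative controls
#' @return tibble with fold, p, and the four counts
#' @export
enrichment_vs_negative <- function(hits_target, n_target, hits_neg, n_neg) {
  check_that(n_neg > 0, "zero negative-control candidates")
  check_that(n_target > 0, "zero target candidates")
  if (hits_target == 0 && hits_neg == 0) {
    warn("no hits in either group; fold undefined")
    return(tibble(fold = NA_real_, p = NA_real_, hits_target, n_target,
                  hits_neg, n_neg))
  }
  pt <- suppressWarnings(prop.test(c(hits_target, hits_neg), c(n_target, n_neg),
                                   correct = TRUE))
  fold <- (hits_target / n_target) / (hits_neg / n_neg)
  tibble(fold = fold, p = pt$p.value, hits_target, n_target, hits_neg, n_neg)
}

#' Summary statistics of significant interactions
#'
#' @param calls an [call_interactions()] result
#' @return list with `mean_distance`, `frac_over_100kb`, `by_class` tibble,
#'   `n_interactions`
#' @export
interaction_stats <- function(calls) {
  sig <- calls[calls$pass_both, ]
  if (nrow(sig) == 0) {
    return(list(mean_distance = NA_real_, frac_over_100kb = NA_real_,
                by_class = tibble(anchor_class = character(), n = integer()),
                n_interactions = 0L))
  }
  list(mean_distance = mean(abs(sig$dist)),
       frac_over_100kb = mean(abs(sig$dist) > 1e5),
       by_class = count(as_tibble(sig), .data$anchor_class),
       n_interactions = nrow(sig))
}

#' Fraction of promoter interactions involving the nearest gene
#'
#' For each significant promoter-anchored interaction, maps the distal end to
#' its nearest promoter (by midpoint) and asks whether that nearest promoter
#' is the anchored one.
#'
#' @param calls an [call_interactions()] result
#' @param promoters promoter region tibble
#' @param bin_size other-end bin width used in calling
#' @return list with `fraction`, `n_nearest`, `n_total`
#' @export
nearest_gene_fraction <- function(calls, promoters, bin_size = 2000) {
  sig <- calls[calls$pass_both & calls$anchor_class == "promoter", ]
  if (nrow(sig) == 0) return(list(fraction = NA_real_, n_nearest = 0L, n_total = 0L))
  other <- tibble(chrom = sig$chrom,
                  start = as.integer(sig$bin * bin_size),
                  end = as.integer((sig$bin + 1) * bin_size),
                  id = sprintf("oe_%06d", seq_len(nrow(sig))))
  near <- nearest_promoter(other, promoters)
  hit <- near$promoter_id[match(other$id, near$enhancer_id)] == sig$anchor_id
  list(fraction = mean(hit, na.rm = TRUE),
       n_nearest = sum(hit, na.rm = TRUE), n_total = nrow(sig))
}

#' Build the interaction network for one timepoint
#'
#' Each interacting promoter or enhancer is a node; two nodes are connected
#' if they had a significant interaction in at least one replicate
#' (`pass_any`). Other-end bins are mapped to overlapping features; bins with
#' no feature become distal-bin nodes. The network is undirected with no
#' self-loops or duplicate edges.
#'
#' @param calls an [call_interactions()] result
#' @param timepoint which timepoint's network to build
#' @param features region tibble of promoters and enhancers (for mapping
#'   other-end bins to feature nodes)
#' @param bin_size other-end bin width used in calling
#' @return list of class `enhdyn_network`: `timepoint`, `nodes`, `edges`
#'   tibble, `graph` (igraph), `neighbors` named list
#' @export
build_network <- function(calls, timepoint, features = NULL, bin_size = 2000) {
  sel <- calls[calls$pass_any & calls$timepoint == timepoint, ]
  if (nrow(sel) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(timepoint = timepoint, nodes = character(),
                          edges = tibble(from = character(), to = character()),
                          graph = g, neighbors = list()),
                     class = "enhdyn_network"))
  }
  other_node <- sprintf("bin_%s_%d", sel$chrom, sel$bin)
  if (!is.null(features) && nrow(features) > 0) {
    bins <- tibble(chrom = sel$chrom, start = as.integer(sel$bin * bin_size),
                   end = as.integer((sel$bin + 1) * bin_size),
                   id = as.character(seq_len(nrow(sel))))
    ov <- overlap_pairs(bins, as_regions(features))
    # when several features overlap a bin keep the largest overlap
    ov <- ov |> arrange(dplyr::desc(.data$overlap_bp)) |>
      distinct(.data$a_id, .keep_all = TRUE)
    mapped <- ov$b_id[match(as.character(seq_len(nrow(sel))), ov$a_id)]
    other_node <- ifelse(is.na(mapped), other_node, mapped)
  }
  edges <- tibble(from = sel$anchor_id, to = other_node) |>
    filter(.data$from != .data$to) |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    distinct(.data$a, .data$b) |>
    rename(from = "a", to = "b")
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  nb <- lapply(setNames(nodes, nodes), function(x) {
    unique(c(edges$to[edges$from == x], edges$from[edges$to == x]))
  })
  structure(list(timepoint = timepoint, nodes = nodes, edges = edges,
                 graph = g, neighbors = nb),
            class = "enhdyn_network")
}

#' Per-node Jaccard index and overlap coefficient between two networks
#'
#' For node x with neighbor sets A and B in the two networks:
#' `JI = |A intersect B| / |A union B|` and
#' `OCE = |A intersect B| / min(|A|, |B|)`. A node absent from a network has
#' an empty neighbor set; when the smaller neighbor set is empty the OCE is
#' defined as 1 (the degenerate case: a node that loses its single contact
#' has JI 0 but OCE 1), and JI is 1 when both sets are empty.
#'
#' @param net_a,net_b [build_network()] results
#' @param nodes nodes to evaluate (default: union of both node sets)
#' @return tibble with node, n_a, n_b, n_common, ji, oce
#' @export
node_dynamics <- function(net_a, net_b, nodes = NULL) {
  if (is.null(nodes)) nodes <- union(net_a$nodes, net_b$nodes)
  n_a <- n_b <- n_common <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    A <- net_a$neighbors[[nodes[i]]] %||% character(0)
    B <- net_b$neighbors[[nodes[i]]] %||% character(0)
    n_a[i] <- length(A)
    n_b[i] <- length(B)
    n_common[i] <- length(intersect(A, B))
  }
  n_union <- n_a + n_b - n_common
  ji <- ifelse(n_union == 0, 1, n_common / n_union)
  oce <- ifelse(pmin(n_a, n_b) == 0, 1, n_common / pmin(n_a, n_b))
  tibble(node = nodes, n_a = n_a, n_b = n_b, n_common = n_common,
         ji = ji, oce = oce)
}

#' Compare interactome change between DE and non-DE nodes
#'
#' Two-sided Wilcoxon rank-sum tests on per-node OCE and JI between
#' differentially expressed and non-differentially expressed nodes.
#'
#' @param dynamics a [node_dynamics()] tibble
#' @param de_status tibble with node, is_de
#' @return tibble with metric, statistic, p, n_de, n_non_de,
#'   median_de, median_non_de
#' @export
compare_de_dynamics <- function(dynamics, de_status) {
  d <- inner_join(dynamics, de_status, by = "node")
  check_that(sum(d$is_de) >= 2 && sum(!d$is_de) >= 2,
             "need at least two nodes per group")
  purrr::map_dfr(c("oce", "ji"), function(metric) {
    x <- d[[metric]][d$is_de]
    y <- d[[metric]][!d$is_de]
    wt <- suppressWarnings(wilcox.test(x, y))
    tibble(metric = metric, statistic = unname(wt$statistic), p = wt$p.value,
           n_de = length(x), n_non_de = length(y),
           median_de = median(x), median_non_de = median(y))
  })
}

#' Correlation of interacting-pair expression by interaction timepoint
#'
#' For interactions observed at exactly one timepoint, computes the
#' correlation between the anchored feature's and the partner feature's
#' expression at every expression timepoint. The resulting matrix (interaction
#' timepoint x expression timepoint) is expected to peak on the diagonal when
#' contacts and transcription are coupled.
#'
#' @param pair_activity tibble with columns a_id, b_id, timepoint (the single
#'   timepoint at which the pair interacts)
#' @param expr_a,expr_b feature x timepoint expression matrices (replicates
#'   already averaged) for the a-side and b-side features
#' @param method "pearson" (default) or "spearman"
#' @return numeric matrix, rows = interaction timepoints, cols = expression
#'   timepoints; cells with fewer than 3 pairs are NA
#' @export
dynamic_expression_correlation <- function(pair_activity, expr_a, expr_b,
                                           method = "pearson") {
  tps <- colnames(expr_a)
  out <- matrix(NA_real_, length(tps), length(tps),
                dimnames = list(interaction = tps, expression = tps))
  for (ti in tps) {
    sel <- pair_activity[pair_activity$timepoint == ti, ]
    sel <- sel[sel$a_id %in% rownames(expr_a) & sel$b_id %in% rownames(expr_b), ]
    if (nrow(sel) < 3) next
    for (te in tps) {
      out[ti, te] <- suppressWarnings(
        cor(expr_a[sel$a_id, te], expr_b[sel$b_id, te], method = method))
    }
  }
  out
}

# regions where at least k of the peak sets co-occur
composite_peaks <- function(peak_sets, k) {
  all_regions <- bind_rows(lapply(peak_sets, as_regions))
  chroms <- unique(all_regions$chrom)
  seqlens <- vapply(chroms, function(ch) {
    max(all_regions$end[all_regions$chrom == ch])
  }, 0)
  grl <- lapply(peak_sets, function(x) {
    gr <- GenomicRanges::reduce(regions_to_gr(as_regions(x)),
                                ignore.strand = TRUE)
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqinfo(gr) <- GenomeInfoDb::Seqinfo(chroms, unname(seqlens))
    gr
  })
  cov <- Reduce(`+`, lapply(grl, GenomicRanges::coverage))
  gr <- GenomicRanges::GRanges(IRanges::slice(cov, lower = k, rangesOnly = TRUE))
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), id = character()))
  }
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = "*",
         id = sprintf("comp%d_%05d", k, seq_along(gr)))
}

#' Peak-set enrichment of distal interacting regions
#'
#' For each peak set (plus composite sets where >= 2, >= 3 or all sets
#' co-occur), reports the percentage of distal regions overlapping the set,
#' the fold enrichment relative to a background universe of candidate distal
#' bins, the base-pair Jaccard index between the sets, and Fisher's exact p
#' on the 2x2 region-overlap table.
#'
#' @param distal region tibble of distal (non-targeted) interacting regions
#' @param peak_sets named list of peak region tibbles
#' @param universe region tibble of all candidate distal bins
#' @param composites add composite co-occurrence sets (default TRUE)
#' @return tibble with set, pct_overlap, fold, jaccard_bp, p
#' @export
distal_peak_enrichment <- function(distal, peak_sets, universe,
                                   composites = TRUE) {
  distal <- as_regions(distal, prefix = "distal")
  universe <- as_regions(universe, prefix = "univ")
  sets <- peak_sets
  if (composites && length(peak_sets) >= 2) {
    for (k in 2:length(peak_sets)) {
      sets[[paste0("composite", k)]] <- composite_peaks(peak_sets, k)
    }
  }
  purrr::map_dfr(names(sets), function(nm) {
    ps <- as_regions(sets[[nm]], prefix = nm)
    if (nrow(ps) == 0) {
      return(tibble(set = nm, pct_overlap = NA_real_, fold = NA_real_,
                    jaccard_bp = NA_real_, p = NA_real_))
    }
    hit_d <- length(overlaps_any(distal, ps))
    hit_u <- length(overlaps_any(universe, ps))
    frac_d <- hit_d / nrow(distal)
    frac_u <- hit_u / nrow(universe)
    fold <- if (frac_u > 0) frac_d / frac_u else NA_real_
    # bp Jaccard between the distal set and the peak set
    g1 <- GenomicRanges::reduce(regions_to_gr(distal), ignore.strand = TRUE)
    g2 <- GenomicRanges::reduce(regions_to_gr(ps), ignore.strand = TRUE)
    inter <- sum(IRanges::width(suppressWarnings(
      GenomicRanges::intersect(g1, g2, ignore.strand = TRUE))))
    uni <- sum(IRanges::width(suppressWarnings(
      GenomicRanges::union(g1, g2, ignore.strand = TRUE))))
    jac <- if (uni > 0) inter / uni else NA_real_
    ft <- fisher.test(matrix(c(hit_d, nrow(distal) - hit_d,
                               hit_u, nrow(universe) - hit_u), 2))
    tibble(set = nm, pct_overlap = 100 * frac_d, fold = fold,
           jaccard_bp = jac, p = ft$p.value)
  })
}
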