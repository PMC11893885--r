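# Interaction binning, empirical background, calling, networks, JI/OCE.

make_samples <- function() {
  tibble::tibble(sample_id = c("D1_r1", "D1_r2"), timepoint = "D1",
                 assay = "hic", replicate = c(1L, 2L))
}

test_that("pair binning counts support and drops trans/out-of-range pairs", {
  probes <- regions_tbl("chr1", 10000, 11000, id = "P")
  probes$class <- "promoter"
  mk_pair <- function(p2, chrom2 = "chr1", n = 1, sample = "D1_r1") {
    tibble::tibble(chrom1 = "chr1", pos1 = rep(10500L, n), strand1 = "+",
                   chrom2 = chrom2, pos2 = rep(as.integer(p2), n),
                   strand2 = "-", sample_id = sample)
  }
  pairs <- dplyr::bind_rows(
    mk_pair(41000, n = 7),              # 7 identical pairs -> support 7
    mk_pair(41000, chrom2 = "chr2"),    # trans -> dropped
    mk_pair(3e6)                        # beyond max distance -> dropped
  )
  sup <- bin_pairs(pairs, probes, make_samples(), bin_size = 2000,
                   max_distance = 2e6, min_distance = 1e4)
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$support, 7L)
  expect_equal(sup$bin, 20L)
  expect_error(bin_pairs(pairs, probes, make_samples(), bin_size = 0),
               "positive")
})

test_that("empirical tail probability matches the worked examples", {
  expect_equal(empirical_tail_p(c(0, 0, 1, 1, 2, 6), 6), 2 / 7,
               tolerance = 1e-12)
  expect_equal(empirical_tail_p(rep(0, 9), 1), 1 / 10)
  expect_equal(empirical_tail_p(c(0, 0, 1), 0), 1)
  # zeros may be passed implicitly through n_total
  expect_equal(empirical_tail_p(c(1, 1, 2, 6), 6, n_total = 6), 2 / 7)
})

test_that("caller enforces support and Bonferroni thresholds in both reps", {
  set.seed(31)
  chrom_sizes <- tibble::tibble(chrom = "chr1", length = 2e6L)
  # anchors: 1 target + 30 negative controls
  starts <- seq(2e4, 2e6 - 2e4, length.out = 31)
  probes <- regions_tbl("chr1", starts, starts + 1000,
                        id = c("T", sprintf("N%02d", 1:30)))
  probes$class <- c("promoter", rep("negative_control", 30))

  # craft a support table: background support 0/1 everywhere, strong signal
  # at one (T, bin) slot in both replicates
  target_bin <- floor((starts[1] + 60500) / 2000)
  sup <- tibble::tibble(
    anchor_id = "T", anchor_class = "promoter", chrom = "chr1",
    bin = as.integer(target_bin),
    dist = abs((target_bin + 0.5) * 2000 - (starts[1] + 500)),
    timepoint = "D1", replicate = c(1L, 2L), support = c(12L, 9L))
  calls <- call_interactions(sup, probes, chrom_sizes,
                             max_distance = 2e5)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$pass_both)
  expect_equal(unname(attr(calls, "m")["D1"]), 1)

  # support (4, 9): fails the min-support rule in one replicate
  sup2 <- sup
  sup2$support <- c(4L, 9L)
  calls2 <- call_interactions(sup2, probes, chrom_sizes, max_distance = 2e5)
  expect_equal(sum(calls2$pass_both), 0L)

  # Bonferroni arithmetic: p_bonf = min(1, p * m)
  expect_equal(min(1, 1e-6 * 1000), 1e-3)  # passes alpha = 0.1
  expect_true(all(calls$p_bonf_r1 == pmin(1, calls$p_r1 * 1)))

  expect_error(call_interactions(sup, probes, chrom_sizes, alpha = 0),
               "alpha")
  # blacklist removes the call
  bl <- regions_tbl("chr1", target_bin * 2000, (target_bin + 1) * 2000,
                    id = "bl1")
  calls_bl <- call_interactions(sup, probes, chrom_sizes, max_distance = 2e5,
                                blacklist = bl)
  expect_equal(nrow(as.data.frame(calls_bl)), 0L)
})

test_that("caller never passes support below the minimum", {
  cfg <- tiny_config(lambda = 8, n_planted = 5L)
  truth <- gen_landscape(cfg)
  hic <- gen_hic(truth, cfg)
  sup <- bin_pairs(hic$pairs, truth$probes, hic$samples,
                   bin_size = cfg$hic_bin, max_distance = cfg$hic_max_dist,
                   min_distance = cfg$hic_min_dist)
  calls <- call_interactions(sup, truth$probes, truth$chrom_sizes,
                             bin_size = cfg$hic_bin,
                             min_distance = cfg$hic_min_dist,
                             max_distance = cfg$hic_max_dist)
  sig <- calls[calls$pass_both, ]
  expect_true(all(sig$support_r1 >= 5 & sig$support_r2 >= 5))
})

test_that("proportion-equality enrichment matches the chi-squared oracle", {
  res <- enrichment_vs_negative(30, 1000, 10, 1000)
  expect_equal(res$fold, 3)
  oracle <- prop.test(c(30, 10), c(1000, 1000), correct = TRUE)
  expect_equal(res$p, oracle$p.value)

  same <- enrichment_vs_negative(50, 1000, 50, 1000)
  expect_equal(same$fold, 1)
  expect_gt(same$p, 0.9)

  expect_warning(zero <- enrichment_vs_negative(0, 100, 0, 100), "undefined")
  expect_true(is.na(zero$fold))
  expect_error(enrichment_vs_negative(1, 10, 1, 0), "negative-control")
})

test_that("interaction summary statistics follow the arithmetic", {
  calls <- tibble::tibble(
    anchor_id = c("a", "b"), anchor_class = c("promoter", "enhancer"),
    chrom = "chr1", bin = c(1L, 2L), dist = c(5e4, 1.5e5),
    timepoint = "D1", pass_both = TRUE, pass_any = TRUE)
  st <- interaction_stats(calls)
  expect_equal(st$mean_distance, 1e5)
  expect_equal(st$frac_over_100kb, 0.5)
  expect_equal(st$n_interactions, 2L)

  short <- calls
  short$dist <- c(1e4, 1e4)
  expect_equal(interaction_stats(short)$frac_over_100kb, 0)
  expect_equal(interaction_stats(calls[calls$dist > 1e5, ])$mean_distance, 1.5e5)
  empty <- interaction_stats(calls[0, ])
  expect_true(is.na(empty$mean_distance))
})

test_that("nearest-gene fraction counts anchored-promoter contacts", {
  prom <- regions_tbl("chr1", c(1e4, 1e5, 2e5, 3e5, 4e5),
                      c(1e4 + 200, 1e5 + 200, 2e5 + 200, 3e5 + 200, 4e5 + 200),
                      id = paste0("p", 1:5))
  # 4 promoter calls; only the first lands nearest to its own anchor
  calls <- tibble::tibble(
    anchor_id = c("p1", "p1", "p1", "p1"), anchor_class = "promoter",
    chrom = "chr1",
    bin = as.integer(c(9, 55, 105, 155)),   # bins of 2000 bp
    dist = 1, timepoint = "D1", pass_both = TRUE, pass_any = TRUE)
  out <- nearest_gene_fraction(calls, prom, bin_size = 2000)
  expect_equal(out$fraction, 0.25)
  expect_equal(out$n_total, 4L)

  none <- nearest_gene_fraction(calls[0, ], prom)
  expect_true(is.na(none$fraction))
})

test_that("network edges require one passing replicate and deduplicate", {
  calls <- tibble::tibble(
    anchor_id = c("A", "A", "B"), anchor_class = "promoter", chrom = "chr1",
    bin = c(10L, 10L, 99L), dist = 1,
    timepoint = "D1",
    pass_r1 = c(TRUE, TRUE, FALSE), pass_r2 = c(FALSE, TRUE, FALSE),
    pass_both = c(FALSE, TRUE, FALSE), pass_any = c(TRUE, TRUE, FALSE))
  feats <- regions_tbl("chr1", 20000, 22000, id = "E")
  net <- build_network(calls, "D1", feats, bin_size = 2000)
  expect_equal(nrow(net$edges), 1L)  # duplicate (A, bin10) edges collapse
  expect_setequal(net$nodes, c("A", "E"))
  expect_equal(net$neighbors[["A"]], "E")

  empty <- build_network(calls[0, ], "D1", feats)
  expect_equal(length(empty$nodes), 0L)
})

test_that("JI and OCE match the set-arithmetic examples", {
  mknet <- function(edges) {
    nodes <- sort(unique(unlist(edges)))
    e <- tibble::tibble(from = vapply(edges, `[`, "", 1),
                        to = vapply(edges, `[`, "", 2))
    nb <- lapply(setNames(nodes, nodes), function(x)
      unique(c(e$to[e$from == x], e$from[e$to == x])))
    structure(list(timepoint = "t", nodes = nodes, edges = e,
                   neighbors = nb), class = "enhdyn_network")
  }
  # one neighbor then zero: JI = 0, OCE = 1 (degenerate case)
  netA <- mknet(list(c("x", "a")))
  netB <- mknet(list(c("y", "z")))
  d <- node_dynamics(netA, netB, nodes = "x")
  expect_equal(d$ji, 0)
  expect_equal(d$oce, 1)

  # identical neighbor sets
  d2 <- node_dynamics(netA, netA, nodes = "x")
  expect_equal(d2$ji, 1)
  expect_equal(d2$oce, 1)

  # A = {a,b,c}, B = {b,c,d}
  nA <- mknet(list(c("x", "a"), c("x", "b"), c("x", "c")))
  nB <- mknet(list(c("x", "b"), c("x", "c"), c("x", "d")))
  d3 <- node_dynamics(nA, nB, nodes = "x")
  expect_equal(d3$ji, 0.5)
  expect_equal(d3$oce, 2 / 3)

  # symmetry in network order
  d3r <- node_dynamics(nB, nA, nodes = "x")
  expect_equal(d3$ji, d3r$ji)
  expect_equal(d3$oce, d3r$oce)
})

test_that("OCE >= JI and both lie in [0,1] over random neighbor sets", {
  set.seed(17)
  pool <- paste0("n", 1:30)
  for (i in 1:200) {
    A <- sample(pool, sample(0:10, 1))
    B <- sample(pool, sample(0:10, 1))
    netA <- structure(list(nodes = "x", neighbors = list(x = A)),
                      class = "enhdyn_network")
    netB <- structure(list(nodes = "x", neighbors = list(x = B)),
                      class = "enhdyn_network")
    d <- node_dynamics(netA, netB, nodes = "x")
    expect_gte(d$oce, d$ji)
    expect_true(d$ji >= 0 && d$ji <= 1 && d$oce >= 0 && d$oce <= 1)
  }
})

test_that("DE vs non-DE dynamics contrast behaves at the extremes", {
  dyn <- tibble::tibble(node = paste0("n", 1:100),
                        ji = c(rep(0, 50), rep(1, 50)),
                        oce = c(rep(0, 50), rep(1, 50)))
  de <- tibble::tibble(node = dyn$node, is_de = c(rep(TRUE, 50), rep(FALSE, 50)))
  out <- compare_de_dynamics(dyn, de)
  expect_lt(out$p[out$metric == "oce"], 1e-4)
  expect_error(compare_de_dynamics(dyn[1:2, ],
                                   tibble::tibble(node = dyn$node[1:2],
                                                  is_de = c(TRUE, FALSE))),
               "two nodes")
})

test_that("dynamic expression correlation peaks at the active timepoint", {
  tps <- c("D1", "D3", "D6")
  # identical promoter/enhancer profiles -> all correlations 1
  set.seed(2)
  e <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("f", 1:20), tps))
  pa <- tibble::tibble(a_id = rownames(e)[1:10], b_id = rownames(e)[1:10],
                       timepoint = rep(tps, length.out = 10))
  m <- dynamic_expression_correlation(pa, e, e)
  expect_true(all(abs(m[!is.na(m)] - 1) < 1e-12))

  # coupled only at the interaction timepoint -> diagonal strictly largest
  set.seed(4)
  n <- 60
  pe <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("p", 1:n), tps))
  ee <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("e", 1:n), tps))
  act <- rep(tps, each = n / 3)
  for (i in seq_len(n)) ee[i, act[i]] <- pe[i, act[i]] + rnorm(1, sd = 0.2)
  pa2 <- tibble::tibble(a_id = rownames(pe), b_id = rownames(ee),
                        timepoint = act)
  m2 <- dynamic_expression_correlation(pa2, pe, ee)
  for (t in tps) expect_equal(names(which.max(m2[t, ])), t)

  # fewer than 3 pairs in a cell -> NA row
  m3 <- dynamic_expression_correlation(pa2[1:2, ], pe, ee)
  expect_true(all(is.na(m3["D3", ])))
})

test_that("distal peak enrichment handles saturating and disjoint sets", {
  univ <- regions_tbl("chr1", seq(0, 19000, 1000), seq(500, 19500, 1000),
                      id = sprintf("u%02d", 1:20))
  distal <- univ[1:10, ]
  whole <- regions_tbl("chr1", 0, 2e4, id = "w")
  out <- distal_peak_enrichment(distal, list(whole = whole), univ,
                                composites = FALSE)
  expect_equal(out$pct_overlap, 100)
  expect_equal(out$fold, 1)

  off <- regions_tbl("chr2", 0, 1e4, id = "o")
  out2 <- distal_peak_enrichment(distal, list(off = off), univ,
                                 composites = FALSE)
  expect_equal(out2$pct_overlap, 0)

  # composite regions: co-occurrence of >= 2 sets
  p1 <- regions_tbl("chr1", 0, 5000, id = "a")
  p2 <- regions_tbl("chr1", 4000, 9000, id = "b")
  comp <- enhdyn:::composite_peaks(list(x = p1, y = p2), 2)
  expect_equal(comp$start, 4000L)
  expect_equal(comp$end, 5000L)
})
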