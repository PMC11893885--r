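# Quantification, normalization, DE testing, temporal clustering.

test_that("strand-specific tag counting follows the overlap rule", {
  regions <- regions_tbl("chr1", 100, 200, strand = "+", id = "P1")
  ctss <- dplyr::bind_rows(ctss_tbl("chr1", 150, "+", 3),
                           ctss_tbl("chr1", 160, "-", 5))
  expect_equal(unname(count_tags(ctss, regions, TRUE)[1, 1]), 3)
  # unstranded enhancer sums both strands
  enh <- regions_tbl("chr1", 100, 200, strand = "*", id = "E1")
  expect_equal(unname(count_tags(ctss, enh, FALSE)[1, 1]), 8)
  # boundary: position `end` is excluded (half-open)
  edge <- ctss_tbl("chr1", c(100, 200), "+", c(1, 1))
  expect_equal(unname(count_tags(edge, regions, TRUE)[1, 1]), 1)
  # tags outside the region -> zero
  away <- ctss_tbl("chr1", 500, "+", 9)
  expect_equal(unname(count_tags(away, regions, TRUE)[1, 1]), 0)
})

test_that("CPM normalization matches hand arithmetic and sums to 1e6", {
  counts <- matrix(c(75, 25), 2, 1, dimnames = list(c("a", "b"), "s1"))
  e <- cpm_normalize(counts, prior = 0.25)
  expect_equal(e$cpm["a", 1], 75.25 / 100.5 * 1e6, tolerance = 1e-10)
  expect_equal(e$cpm["b", 1], 25.25 / 100.5 * 1e6, tolerance = 1e-10)
  expect_equal(unname(colSums(e$cpm)), 1e6, tolerance = 1e-6)

  zeros <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1"))
  ez <- cpm_normalize(zeros, prior = 0.25)
  expect_equal(unname(ez$cpm[, 1]), c(5e5, 5e5))
  expect_error(cpm_normalize(zeros, prior = 0), "zero")

  set.seed(3)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  expect_equal(unname(colSums(cpm_normalize(m)$cpm)), rep(1e6, 6),
               tolerance = 1e-6)
})

test_that("expression filtering uses a strict threshold", {
  m <- matrix(c(-2.4, -3, -2, -2, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("low", "edge", "high"), c("s1", "s2")))
  expect_setequal(filter_expressed(m, -2.5), c("low", "edge", "high"))
  expect_setequal(filter_expressed(m, -2), "high")   # strict >: edge dropped
  expect_setequal(filter_expressed(m, -10), rownames(m))
  expect_error(filter_expressed(m, -2, min_samples = 5), "min_samples")
})

test_that("de_test handles degenerate input and planted effects", {
  group <- rep(c("D1", "D3", "D6"), each = 2)
  flat <- matrix(5L, 10, 6, dimnames = list(paste0("f", 1:10), NULL))
  de <- de_test(flat, group)
  expect_equal(de$table$statistic, rep(0, 10))
  expect_equal(de$table$p, rep(1, 10))

  expect_error(de_test(flat, rep("D1", 6)), "two groups")
  expect_error(de_test(flat[, 1:4], group), "match")

  # strong planted effects (balanced directions) among null features
  set.seed(8)
  mu <- matrix(100, 300, 6)
  mu[1:15, ] <- rep(c(50, 50, 200, 200, 800, 800), each = 15)
  mu[16:30, ] <- rep(c(800, 800, 200, 200, 50, 50), each = 15)
  counts <- matrix(rnbinom(300 * 6, mu = as.vector(mu), size = 10), 300, 6,
                   dimnames = list(paste0("f", 1:300), NULL))
  de2 <- de_test(counts, group)
  expect_gt(mean(de2$table$is_de[1:30]), 0.8)
  expect_lt(mean(de2$table$is_de[-(1:30)]), 0.05)

  # tidy/glance round out the broom interface
  expect_s3_class(generics::tidy(de2), "tbl_df")
  expect_equal(generics::glance(de2)$n_features, 300L)
})

test_that("de_test agrees with edgeR on ranking planted effects", {
  set.seed(9)
  group <- rep(c("D1", "D3", "D6"), each = 2)
  mu <- matrix(80, 200, 6)
  mu[1:20, ] <- rep(c(40, 40, 160, 160, 640, 640), each = 20)
  counts <- matrix(rnbinom(200 * 6, mu = as.vector(mu), size = 10), 200, 6,
                   dimnames = list(paste0("f", 1:200), NULL))
  mine <- de_test(counts, group)$table
  y <- edgeR::DGEList(counts, group = group)
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  ref <- edgeR::topTags(edgeR::glmQLFTest(fit, coef = 2:3), n = Inf,
                        sort.by = "none")$table
  # independent implementations rank the same features on top
  expect_gt(cor(rank(mine$p), rank(ref$PValue), method = "spearman"), 0.8)
})

test_that("temporal clustering recovers archetypes and is deterministic", {
  set.seed(5)
  tp <- rep(c("D1", "D3", "D6"), each = 2)
  arch <- rbind(c1 = c(1, 0, 0), c2 = c(1, 1, 0), c3 = c(0, 1, 1),
                c4 = c(0, 0, 1))
  m <- arch[rep(1:4, each = 50), rep(1:3, each = 2)] * 4 +
    matrix(rnorm(200 * 6, sd = 0.05), 200, 6)
  rownames(m) <- paste0("f", 1:200)
  cl <- cluster_temporal(m, tp, seed = 1)
  truthcl <- rep(1:4, each = 50)
  expect_equal(adjusted_rand(cl$cluster, truthcl), 1)
  # relabeling maps clusters onto the temporal semantics deterministically
  expect_equal(cl$cluster, truthcl)

  cl2 <- cluster_temporal(m, tp, seed = 1)
  expect_identical(cl, cl2)

  # constant rows are excluded with a warning
  m2 <- rbind(m, const = rep(1, 6))
  expect_warning(cl3 <- cluster_temporal(m2, tp, seed = 1), "constant")
  expect_false("const" %in% cl3$feature)

  expect_error(cluster_temporal(m[1:3, ], tp, k = 4), "fewer")
})

test_that("nearest promoter uses midpoint distance with tie rules", {
  prom <- regions_tbl("chr1", c(900, 8900), c(1100, 9100),
                      id = c("p1", "p2"))
  enh <- regions_tbl("chr1", 3900, 4100, id = "e1")
  got <- nearest_promoter(enh, prom)
  expect_equal(got$promoter_id, "p1")
  expect_equal(got$distance, 3000)

  # equidistant promoters: lower start coordinate wins
  prom2 <- regions_tbl("chr1", c(1900, 5900), c(2100, 6100),
                       id = c("lo", "hi"))
  tie <- nearest_promoter(regions_tbl("chr1", 3900, 4100, id = "e"), prom2)
  expect_equal(tie$promoter_id, "lo")

  # single promoter genome: everything maps to it
  one <- nearest_promoter(
    regions_tbl("chr1", c(100, 5e5), c(200, 5e5 + 100), id = c("a", "b")),
    prom[1, ])
  expect_equal(one$promoter_id, c("p1", "p1"))

  # chromosome without promoters is flagged missing
  miss <- nearest_promoter(regions_tbl("chrX", 10, 20, id = "x"), prom)
  expect_true(is.na(miss$promoter_id))
})

test_that("cluster overlap matrix matches a hand tally", {
  enh_cl <- tibble::tibble(feature = paste0("e", 1:10),
                           cluster = c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4))
  near <- tibble::tibble(enhancer_id = paste0("e", 1:10),
                         promoter_id = paste0("p", 1:10), distance = 1)
  prom_cl <- tibble::tibble(feature = paste0("p", 1:10),
                            cluster = c(1, 1, 2, NA, 2, 2, 3, 1, 4, 4))
  prom_cl <- prom_cl[!is.na(prom_cl$cluster), ]
  m <- cluster_overlap_matrix(enh_cl, prom_cl, near)
  expect_equal(m[1, ], c(2, 1, 0, 0) / 4, ignore_attr = TRUE)  # p4 not DE
  expect_equal(m[2, ], c(0, 2, 0, 0) / 2, ignore_attr = TRUE)
  expect_equal(m[3, ], c(1, 0, 1, 0) / 2, ignore_attr = TRUE)
  expect_equal(m[4, ], c(0, 0, 0, 2) / 2, ignore_attr = TRUE)
  expect_true(all(rowSums(m) <= 1))

  # all nearest promoters share the enhancer cluster -> identity diagonal
  prom_same <- tibble::tibble(feature = paste0("p", 1:10),
                              cluster = enh_cl$cluster)
  mi <- cluster_overlap_matrix(enh_cl, prom_same, near)
  expect_equal(diag(mi), rep(1, 4))
  # non-DE nearest promoters only -> all zeros
  m0 <- cluster_overlap_matrix(enh_cl, prom_cl[0, ], near)
  expect_true(all(m0 == 0))
})
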