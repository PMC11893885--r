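# Synthetic-data generators: determinism, planted structure, error handling.

test_that("landscape generation is deterministic and quota-exact", {
  cfg <- tiny_config()
  t1 <- gen_landscape(cfg)
  t2 <- gen_landscape(cfg)
  expect_identical(t1$promoters, t2$promoters)
  expect_identical(t1$planted_interactions$anchor_id,
                   t2$planted_interactions$anchor_id)

  # quota-based cluster assignment: exact counts
  cfg4 <- tiny_config(n_promoters = 400L, chrom_length = 8e6,
                      cluster_props = c(c1 = .25, c2 = .25, c3 = .25, c4 = .25,
                                        flat = 0))
  t4 <- gen_landscape(cfg4)
  expect_equal(unname(table(t4$promoters$cluster)[c("c1", "c2", "c3", "c4")]),
               rep(100L, 4), ignore_attr = TRUE)

  # promoters and enhancers never overlap
  expect_equal(nrow(overlap_pairs(t1$promoters, t1$enhancers)), 0L)

  # genome too small
  expect_error(gen_landscape(sim_config(n_chroms = 1L, chrom_length = 1e4)),
               "too small")
})

test_that("no enhancers means no enhancer-involved planted interactions", {
  cfg <- tiny_config(n_enhancers = 1L, n_probe_enhancers = 1L, n_planted = 0L)
  t <- gen_landscape(cfg)
  expect_equal(nrow(t$planted_interactions), 0L)
})

test_that("CTSS signal has the planted strand structure", {
  cfg <- tiny_config()
  truth <- gen_landscape(cfg)
  ctss <- gen_ctss(truth, cfg)

  # promoter tags: >= 90% on the annotated strand
  prom <- truth$promoters
  ov <- overlap_pairs(
    regions_tbl(ctss$chrom, ctss$pos, ctss$pos + 1L,
                id = as.character(seq_len(nrow(ctss)))), prom)
  ti <- as.integer(ov$a_id)
  sense <- ctss$strand[ti] == prom$strand[match(ov$b_id, prom$id)]
  frac_sense <- sum(ctss$count[ti][sense]) / sum(ctss$count[ti])
  expect_gte(frac_sense, 0.9)

  # enhancer tags split between strands within binomial 99% bounds per locus
  enh <- truth$enhancers
  ove <- overlap_pairs(
    regions_tbl(ctss$chrom, ctss$pos, ctss$pos + 1L,
                id = as.character(seq_len(nrow(ctss)))), enh)
  te <- as.integer(ove$a_id)
  by_enh <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(id = ove$b_id,
                                   plus = (ctss$strand[te] == "+") * ctss$count[te],
                                   count = ctss$count[te]), id),
    plus = sum(plus), total = sum(count))
  by_enh <- by_enh[by_enh$total >= 100, ]
  bal <- enh$balance[match(by_enh$id, enh$id)]
  lo <- qbinom(0.005, by_enh$total, bal)
  hi <- qbinom(0.995, by_enh$total, bal)
  expect_gte(mean(by_enh$plus >= lo & by_enh$plus <= hi), 0.95)

  # no features, no noise -> empty CTSS
  cfg0 <- tiny_config(noise_rate = 0, promoter_mean = 0, enhancer_mean = 0,
                      n_planted = 0L)
  truth0 <- gen_landscape(cfg0)
  expect_equal(nrow(gen_ctss(truth0, cfg0)), 0L)
})

test_that("Hi-C generator scales with depth and rejects bad effect sizes", {
  cfg <- tiny_config()
  truth <- gen_landscape(cfg)
  expect_error(gen_hic(truth, tiny_config(lambda = 0.5)), "lambda")

  h1 <- gen_hic(truth, cfg)
  cfg2 <- tiny_config(hic_pairs = cfg$hic_pairs * 2, seed = 5L)
  h2 <- gen_hic(truth, cfg2)
  n_samp <- nrow(h1$samples)
  r <- (nrow(h2$pairs) / n_samp) / (nrow(h1$pairs) / n_samp)
  expect_gt(r, 1.9)  # doubling pairs doubles expected support (Poisson error)
  expect_lt(r, 2.1)

  # pairs parse through the io round-trip
  path <- withr::local_tempfile()
  sub <- h1$pairs[h1$pairs$sample_id == h1$samples$sample_id[1], ]
  write_pairs(sub, path)
  back <- read_pairs(path, h1$samples$sample_id[1])
  expect_equal(nrow(back), nrow(sub))
  expect_equal(back$pos1, sub$pos1)
})

test_that("negative-control probes carry background only", {
  cfg <- tiny_config(n_planted = 5L)
  truth <- gen_landscape(cfg)
  neg_ids <- truth$probes$id[truth$probes$class == "negative_control"]
  expect_false(any(truth$planted_interactions$anchor_id %in% neg_ids))
})

test_that("variant generator plants density and AF structure", {
  cfg <- tiny_config()
  truth <- gen_landscape(cfg)
  expect_error(gen_variants(truth, tiny_config(enh_snp_factor = -1)),
               "factor")
  vr <- gen_variants(truth, cfg)
  expect_true(all(vr$variants$af >= 0 & vr$variants$af <= 1))
  expect_true(all(vr$ld$r2 >= 0 & vr$ld$r2 <= 1))

  # enrichment_factor = 1: enhancer SNP density ~ background (binomial CI)
  cfg1 <- tiny_config(enh_snp_factor = 1)
  v1 <- gen_variants(truth, cfg1)
  enh_bp <- sum(truth$enhancers$end - truth$enhancers$start)
  genome_bp <- sum(truth$chrom_sizes$length)
  n_in <- sum(v1$variants$in_enhancer)
  ci <- qbinom(c(0.005, 0.995), nrow(v1$variants), enh_bp / genome_bp)
  expect_gte(n_in, ci[1])
  expect_lte(n_in, ci[2])

  # LD block size 1 -> no LD pairs
  v0 <- gen_variants(truth, tiny_config(ld_block = 1L))
  expect_equal(nrow(v0$ld), 0L)
})

test_that("study writer emits parseable files plus truth tables", {
  cfg <- tiny_config()
  sim <- simulate_study(cfg)
  d <- withr::local_tempdir()
  paths <- write_study(sim, d)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(d, "truth", "enhancer_truth.tsv")))

  v <- read_variants(file.path(d, "variants.tsv"))
  expect_identical(v$snp_id, sim$variants$variants$snp_id)
  expect_equal(v$af, sim$variants$variants$af, tolerance = 1e-12)
  ld <- read_ld(file.path(d, "ld.tsv"))
  expect_equal(nrow(ld), nrow(sim$variants$ld))
  s1 <- sim$ctss$sample_id[1]
  ct <- read_ctss(file.path(d, paste0("ctss_", s1, ".tsv")), s1)
  expect_equal(sum(ct$count), sum(sim$ctss$count[sim$ctss$sample_id == s1]))
  bg <- read_bedgraph(file.path(d, "conservation.bedgraph"))
  expect_equal(nrow(bg), nrow(sim$conservation))

  # YAML config overrides defaults
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9L, n_promoters = 50L), yml)
  c2 <- sim_config_from_yaml(yml)
  expect_equal(c2$seed, 9L)
  expect_equal(c2$n_promoters, 50L)
  expect_equal(c2$n_enhancers, sim_config()$n_enhancers)
})

test_that("conservation track is clipped and shifted in enhancers", {
  cfg <- tiny_config()
  truth <- gen_landscape(cfg)
  expect_error(gen_conservation(truth, tiny_config(cons_base = 1.5)),
               "cons_base")
  tr <- gen_conservation(truth, cfg)
  expect_true(all(tr$score >= 0 & tr$score <= 1))

  cc <- conservation_compare(list(enh = truth$enhancers,
                                  rest = truth$promoters), tr)
  m_enh <- mean(cc$means$mean_score[cc$means$set == "enh"], na.rm = TRUE)
  m_bg <- mean(cc$means$mean_score[cc$means$set == "rest"], na.rm = TRUE)
  expect_equal(m_enh, cfg$cons_base + cfg$cons_shift, tolerance = 0.1)
  expect_equal(m_bg, cfg$cons_base, tolerance = 0.1)

  # shift 0: means equal within sampling error (t-test not significant)
  cfg0 <- tiny_config(cons_shift = 0)
  tr0 <- gen_conservation(truth, cfg0)
  cc0 <- conservation_compare(list(enh = truth$enhancers,
                                   rest = truth$promoters), tr0)
  tt <- t.test(cc0$means$mean_score[cc0$means$set == "enh"],
               cc0$means$mean_score[cc0$means$set == "rest"])
  expect_gt(tt$p.value, 0.001)
})
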