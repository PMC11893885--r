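# Headline summary arithmetic, qPCR relative quantification, and the
# end-to-end pipeline on synthetic inputs.

#' Summarize the enhancer universe
#'
#' @param known_set_sizes named integer vector of known enhancer catalog sizes
#' @param loci called loci with novelty labels ([classify_novelty()])
#' @param retained_ids ids of loci retained after expression filtering
#'   (default: all loci)
#' @return tibble with the counts and percentages: n_loci, n_known,
#'   pct_known (1 dp), n_retained, n_novel_retained, pct_novel_retained
#'   (1 dp), universe_total
#' @export
summarize_universe <- function(known_set_sizes, loci,
                               retained_ids = loci$id) {
  n_loci <- nrow(loci)
  n_known <- sum(loci$novelty == "known")
  retained <- loci[loci$id %in% retained_ids, ]
  n_retained <- nrow(retained)
  n_novel_retained <- sum(retained$novelty == "novel")
  tibble(
    n_loci = n_loci,
    n_known = n_known,
    pct_known = pct(n_known, n_loci, 1),
    n_retained = n_retained,
    n_novel_retained = n_novel_retained,
    pct_novel_retained = pct(n_novel_retained, n_retained, 1),
    universe_total = combine_universe(known_set_sizes, loci)
  )
}

#' Summarize interaction involvement
#'
#' @param n_interactions_de,n_interactions interactions involving a DE
#'   feature / all interactions
#' @param n_de_enh_interacting,n_de_enh DE enhancers with >= 1 interaction /
#'   all DE enhancers
#' @param n_gwas_interacting,n_gwas GWAS anchors with >= 1 interaction / all
#'   GWAS anchors
#' @return tibble of counts and percentages (integer rounding for the
#'   interaction and GWAS shares, 1 decimal for the DE-enhancer share)
#' @export
summarize_interactions <- function(n_interactions_de, n_interactions,
                                   n_de_enh_interacting, n_de_enh,
                                   n_gwas_interacting, n_gwas) {
  tibble(
    n_interactions_de = n_interactions_de,
    n_interactions = n_interactions,
    pct_interactions_de = pct(n_interactions_de, n_interactions, 0),
    n_de_enh_interacting = n_de_enh_interacting,
    n_de_enh = n_de_enh,
    pct_de_enh_interacting = pct(n_de_enh_interacting, n_de_enh, 1),
    n_gwas_interacting = n_gwas_interacting,
    n_gwas = n_gwas,
    pct_gwas_interacting = pct(n_gwas_interacting, n_gwas, 0)
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and
#' `fold = 2^-ddCt`. Per-replicate folds (against the control's mean dCt)
#' give the SEM.
#'
#' @param qpcr tibble with condition, target_ct, reference_ct, replicate
#' @param control name of the control condition
#' @return tibble with condition, ddct, fold, fold_sem, n
#' @export
fold_change_ddct <- function(qpcr, control) {
  check_that(control %in% qpcr$condition, "missing control condition")
  check_that(all(qpcr$target_ct > 0) && all(qpcr$reference_ct > 0),
             "Ct values must be positive")
  qpcr <- mutate(qpcr, dct = .data$target_ct - .data$reference_ct)
  ctrl_mean <- mean(qpcr$dct[qpcr$condition == control])
  qpcr |>
    group_by(.data$condition) |>
    summarise(
      ddct = mean(.data$dct) - ctrl_mean,
      fold = 2^(-(mean(.data$dct) - ctrl_mean)),
      fold_sem = stats::sd(2^(-(.data$dct - ctrl_mean))) / sqrt(n()),
      n = n(), .groups = "drop")
}

#' One-way ANOVA with Dunnett's multiple comparisons on qPCR dCt values
#'
#' @param qpcr tibble with condition, target_ct, reference_ct, replicate
#' @param control name of the control condition
#' @return tibble with comparison, estimate, p (Dunnett-adjusted)
#' @export
qpcr_anova_dunnett <- function(qpcr, control) {
  check_that(control %in% qpcr$condition, "missing control condition")
  d <- mutate(qpcr, dct = .data$target_ct - .data$reference_ct,
              condition = stats::relevel(factor(.data$condition), ref = control))
  fit <- aov(dct ~ condition, data = d)
  dn <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(dn)
  tibble(comparison = names(sm$test$coefficients),
         estimate = unname(sm$test$coefficients),
         p = unname(sm$test$pvalues))
}

# average expression per timepoint (replicates averaged) for given features
expr_by_timepoint <- function(log2_cpm, samples, timepoints) {
  sapply(timepoints, function(tp) {
    cols <- samples$sample_id[samples$timepoint == tp]
    cols <- intersect(cols, colnames(log2_cpm))
    rowMeans(log2_cpm[, cols, drop = FALSE])
  })
}

#' Run the full pipeline on synthetic inputs
#'
#' Generates a landscape with planted truth, calls bidirectional enhancers
#' from the pooled nascent-RNA CTSS signal, quantifies and tests temporal
#' differential expression for promoters (total RNA) and enhancers (nascent
#' RNA), clusters temporal profiles, calls capture Hi-C interactions against
#' the negative-control background, computes interactome dynamics (JI/OCE)
#' and their DE contrast, runs the GWAS matched-control permutation
#' enrichment, characterizes novel enhancers (conservation, SNP density,
#' nucleotide diversity, eQTL overlap) against length-matched random regions,
#' and assembles a run report whose percentages are recomputable from the
#' integer counts stored beside them.
#'
#' @param config an [sim_config()] list
#' @param n_permutations permutations for the GWAS test (default 500)
#' @return object of class `enhdyn_run`: all stage outputs plus `report`
#' @export
run_pipeline <- function(config = sim_config(), n_permutations = 500) {
  sim <- simulate_study(config)
  truth <- sim$truth
  samples <- truth$samples

  # --- enhancer calling from pooled nascent CTSS ---------------------------
  nascent_ids <- samples$sample_id[samples$assay == "nascent"]
  ctss_nascent <- sim$ctss[sim$ctss$sample_id %in% nascent_ids, ]
  clusters <- cluster_ctss(ctss_nascent)
  loci <- call_bidirectional(clusters, promoter_mask = truth$promoters)
  loci <- classify_novelty(loci, list(known = truth$enhancers[truth$enhancers$known, ]))

  # --- expression ----------------------------------------------------------
  total_ids <- samples$sample_id[samples$assay == "total"]
  prom_counts <- count_tags(sim$ctss[sim$ctss$sample_id %in% total_ids, ],
                            truth$promoters, strand_specific = TRUE)
  enh_counts <- count_tags(ctss_nascent, truth$enhancers, strand_specific = FALSE)
  prom_expr <- cpm_normalize(prom_counts)
  enh_expr <- cpm_normalize(enh_counts)
  prom_keep <- filter_expressed(prom_expr, -2)
  enh_keep <- filter_expressed(enh_expr, -2.5)

  tp_of <- function(ids) samples$timepoint[match(ids, samples$sample_id)]
  prom_de <- de_test(prom_counts[prom_keep, , drop = FALSE],
                     tp_of(colnames(prom_counts)))
  enh_de <- de_test(enh_counts[enh_keep, , drop = FALSE],
                    tp_of(colnames(enh_counts)))

  prom_de_ids <- prom_de$table$feature[prom_de$table$is_de]
  enh_de_ids <- enh_de$table$feature[enh_de$table$is_de]
  prom_clusters <- if (length(prom_de_ids) >= 4) {
    cluster_temporal(prom_expr$log2_cpm[prom_de_ids, , drop = FALSE],
                     tp_of(colnames(prom_counts)), seed = config$seed)
  } else tibble(feature = character(), cluster = integer())
  enh_clusters <- if (length(enh_de_ids) >= 4) {
    cluster_temporal(enh_expr$log2_cpm[enh_de_ids, , drop = FALSE],
                     tp_of(colnames(enh_counts)), seed = config$seed)
  } else tibble(feature = character(), cluster = integer())

  nearest <- nearest_promoter(truth$enhancers, truth$promoters)
  overlap_mat <- cluster_overlap_matrix(enh_clusters, prom_clusters, nearest)

  # --- interactions --------------------------------------------------------
  support <- bin_pairs(sim$hic$pairs, truth$probes, sim$hic$samples,
                       bin_size = config$hic_bin,
                       max_distance = config$hic_max_dist,
                       min_distance = config$hic_min_dist)
  calls <- call_interactions(support, truth$probes, truth$chrom_sizes,
                             bin_size = config$hic_bin,
                             min_distance = config$hic_min_dist,
                             max_distance = config$hic_max_dist)
  stats_int <- interaction_stats(calls)
  nearest_gene <- nearest_gene_fraction(calls, truth$promoters,
                                        bin_size = config$hic_bin)

  features <- bind_rows(
    truth$promoters[, c("chrom", "start", "end", "strand", "id")],
    truth$enhancers[, c("chrom", "start", "end", "strand", "id")]
  )
  tps <- config$timepoints
  nets <- lapply(setNames(tps, tps), function(tp) {
    build_network(calls, tp, features, bin_size = config$hic_bin)
  })
  dyn <- purrr::map_dfr(utils::combn(tps, 2, simplify = FALSE), function(pr) {
    d <- node_dynamics(nets[[pr[1]]], nets[[pr[2]]])
    d$pair <- paste(pr[2], "vs", pr[1])
    d
  })
  de_ids <- c(prom_de_ids, enh_de_ids)
  de_status <- tibble(node = unique(dyn$node),
                      is_de = unique(dyn$node) %in% de_ids)
  de_dyn <- tryCatch(compare_de_dynamics(dyn, de_status), error = function(e) NULL)

  # --- GWAS enrichment -----------------------------------------------------
  vr <- sim$variants
  loci_ld <- ld_expand(vr$gwas, vr$ld)
  controls <- match_controls(unique(loci_ld$locus), vr$variants, vr$ld,
                             truth$promoters,
                             min_neighbors = min(500, nrow(vr$variants) - 50))
  gwas_enr <- enrichment_test(loci_ld, truth$enhancers, controls, vr$variants,
                              vr$ld, n_permutations = n_permutations,
                              seed = config$seed)

  # --- novel-enhancer characterization ------------------------------------
  novel_enh <- truth$enhancers[!truth$enhancers$known, ]
  excl <- bind_rows(truth$promoters[, c("chrom", "start", "end")],
                    truth$enhancers[, c("chrom", "start", "end")])
  excl$strand <- "*"
  excl$id <- sprintf("excl_%05d", seq_len(nrow(excl)))
  rand_regions <- sample_matched_regions(novel_enh, truth$chrom_sizes,
                                         excluded = excl, seed = config$seed)
  cons <- conservation_compare(
    list(novel_enhancers = novel_enh, random = rand_regions),
    sim$conservation)
  pi_enh <- nucleotide_diversity(novel_enh, vr$variants)
  pi_rand <- nucleotide_diversity(rand_regions, vr$variants)
  snp_regions <- tibble(chrom = vr$variants$chrom, start = vr$variants$pos,
                        end = vr$variants$pos + 1L, id = vr$variants$snp_id)
  snps_in_enh <- overlaps_any(snp_regions, novel_enh)
  snps_in_rand <- overlaps_any(snp_regions, rand_regions)
  eqtl <- eqtl_enrichment(snps_in_enh, vr$eqtl, snps_in_rand)

  # --- report --------------------------------------------------------------
  n_known_catalog <- sum(truth$enhancers$known)
  universe <- summarize_universe(c(known = n_known_catalog), loci,
                                 retained_ids = loci$id)
  sig <- calls[calls$pass_both, ]
  de_anchor <- sig$anchor_id %in% de_ids
  gwas_anchors <- unique(truth$probes$id[truth$probes$class == "gwas"])
  enh_probe_ids <- truth$probes$id[truth$probes$class == "enhancer"]
  de_enh_probes <- intersect(enh_probe_ids, enh_de_ids)
  interactions_sum <- summarize_interactions(
    n_interactions_de = sum(de_anchor),
    n_interactions = nrow(sig),
    n_de_enh_interacting = length(intersect(de_enh_probes, sig$anchor_id)),
    n_de_enh = length(de_enh_probes),
    n_gwas_interacting = length(intersect(gwas_anchors, sig$anchor_id)),
    n_gwas = length(gwas_anchors)
  )

  report <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[order(names(config))]),
    counts = list(
      n_promoters = nrow(truth$promoters),
      n_enhancers = nrow(truth$enhancers),
      n_bidirectional_loci = nrow(loci),
      n_promoters_expressed = length(prom_keep),
      n_enhancers_expressed = length(enh_keep),
      n_de_promoters = length(prom_de_ids),
      n_de_enhancers = length(enh_de_ids),
      n_interactions = stats_int$n_interactions,
      n_gwas_loci = gwas_enr$n_loci
    ),
    universe = universe,
    interactions = interactions_sum,
    mean_interaction_distance = stats_int$mean_distance,
    frac_over_100kb = stats_int$frac_over_100kb,
    nearest_gene_fraction = nearest_gene$fraction,
    gwas = tidy(gwas_enr)
  )

  structure(list(
    config = config, sim = sim, loci = loci,
    prom_counts = prom_counts, enh_counts = enh_counts,
    prom_expr = prom_expr, enh_expr = enh_expr,
    prom_de = prom_de, enh_de = enh_de,
    prom_clusters = prom_clusters, enh_clusters = enh_clusters,
    cluster_overlap = overlap_mat,
    support = support, calls = calls, networks = nets,
    dynamics = dyn, de_dynamics = de_dyn,
    gwas_enrichment = gwas_enr, conservation = cons,
    pi_enhancers = pi_enh, pi_random = pi_rand, eqtl = eqtl,
    report = report
  ), class = "enhdyn_run")
}

#' @export
print.enhdyn_run <- function(x, ...) {
  r <- x$report
  cat("enhdyn synthetic pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  bidirectional loci: %d (%.1f%% known)\n",
              r$universe$n_loci, r$universe$pct_known))
  cat(sprintf("  DE promoters/enhancers: %d / %d\n",
              r$counts$n_de_promoters, r$counts$n_de_enhancers))
  cat(sprintf("  significant interactions: %d (mean distance %.1f kb)\n",
              r$counts$n_interactions, r$mean_interaction_distance / 1e3))
  cat(sprintf("  GWAS enrichment fold %.2f (p = %.3g)\n",
              r$gwas$fold, r$gwas$p))
  invisible(x)
}
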