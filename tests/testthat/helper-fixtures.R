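# Small fixture builders shared across tests. Everything is generated in
# code; no stored data files.

regions_tbl <- function(chrom, start, end, strand = "*", id = NULL) {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end), strand = rep_len(strand, n),
    id = id %||% sprintf("r%02d", seq_len(n))
  )
}

ctss_tbl <- function(chrom, pos, strand, count, sample_id = "s1") {
  n <- length(pos)
  tibble::tibble(chrom = rep_len(chrom, n), pos = as.integer(pos),
                 strand = rep_len(strand, n), count = as.integer(count),
                 sample_id = rep_len(sample_id, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-base overlap oracle for two catalogs
bruteforce_overlaps <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      bases_a <- seq(a$start[i], a$end[i] - 1)
      bases_b <- seq(b$start[j], b$end[j] - 1)
      ov <- length(intersect(bases_a, bases_b))
      if (ov >= min_bp) {
        out[[length(out) + 1]] <- tibble::tibble(
          a_id = a$id[i], b_id = b$id[j], overlap_bp = ov)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(a_id = character(), b_id = character(),
                          overlap_bp = integer()))
  }
  dplyr::bind_rows(out)
}

# small config for fast simulator unit tests
tiny_config <- function(...) {
  sim_config(
    n_chroms = 1L, chrom_length = 2e6,
    n_promoters = 30L, n_enhancers = 20L,
    n_probe_promoters = 20L, n_probe_enhancers = 10L,
    n_probe_gwas = 5L, n_neg_controls = 30L,
    n_planted = 5L, plant_dist = c(25000, 40000),
    hic_pairs = 20000, hic_max_dist = 1e5,
    n_gwas_loci = 10L, snp_rate = 1 / 1000,
    ...
  )
}

# adjusted Rand index (independent implementation for cluster scoring)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  (a - expected) / ((b + c) / 2 - expected)
}
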