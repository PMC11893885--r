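# Bidirectional enhancer calling from stranded CTSS signal. A putative
# enhancer is a divergent pair of transcribed tag clusters (minus-strand
# cluster to the left, plus-strand cluster to the right) with balanced output:
# directionality D = (F - R) / (F + R) close to zero, where F and R are the
# plus- and minus-flank tag totals.

#' Cluster CTSS tags into strand-specific tag clusters
#'
#' Single-linkage clustering: consecutive same-strand tags at most `max_gap`
#' bp apart share a cluster; clusters with total tag count below `min_count`
#' are dropped. Tags are pooled across samples before clustering.
#'
#' @param ctss CTSS tibble (chrom, pos, strand, count; sample_id ignored)
#' @param max_gap maximum gap in bp between tags of one cluster (default 20)
#' @param min_count minimum total tag count to keep a cluster (default 2)
#' @return tibble with chrom, start, end, strand, id, total_count, summit_pos
#' @export
cluster_ctss <- function(ctss, max_gap = 20, min_count = 2) {
  check_that(max_gap >= 0, "max_gap must be non-negative")
  pooled <- ctss |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  if (nrow(pooled) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), id = character(),
                  total_count = integer(), summit_pos = integer()))
  }
  pooled <- pooled |>
    group_by(.data$chrom, .data$strand) |>
    mutate(gap = as.numeric(.data$pos) - lag(as.numeric(.data$pos), default = -Inf),
           cl = cumsum(.data$gap > max_gap)) |>
    ungroup()
  clusters <- pooled |>
    group_by(.data$chrom, .data$strand, .data$cl) |>
    summarise(start = min(.data$pos),
              end = max(.data$pos) + 1L,
              total_count = sum(.data$count),
              summit_pos = .data$pos[which.max(.data$count)],
              .groups = "drop") |>
    filter(.data$total_count >= min_count) |>
    arrange(.data$chrom, .data$start)
  clusters$id <- sprintf("tc_%06d", seq_len(nrow(clusters)))
  select(clusters, "chrom", "start", "end", "strand", "id",
         "total_count", "summit_pos")
}

#' Call bidirectionally transcribed loci from stranded tag clusters
#'
#' Pairs each minus-strand cluster with a plus-strand cluster in divergent
#' orientation (minus cluster left of plus cluster) whose inner edges are at
#' most `pairing_window` bp apart; when several plus clusters qualify the
#' nearest is kept. The locus spans both flanks, its midpoint is the middle of
#' the inner gap, `minus_count` (R) and `plus_count` (F) are the flank totals
#' and `directionality` D = (F - R) / (F + R). Only loci with |D| strictly
#' below `directionality_threshold` are emitted; loci overlapping the padded
#' promoter mask are discarded; overlapping loci are merged keeping the more
#' balanced one (smaller |D|).
#'
#' @param clusters output of [cluster_ctss()]
#' @param pairing_window maximum inner-edge gap in bp (default 400)
#' @param directionality_threshold |D| must be strictly below this (default 0.8)
#' @param promoter_mask optional region tibble of promoters to exclude
#' @param promoter_pad padding added to each side of the mask (default 500)
#' @return tibble of loci: chrom, start, end, strand ("*"), id, midpoint,
#'   minus_count, plus_count, directionality
#' @export
call_bidirectional <- function(clusters, pairing_window = 400,
                               directionality_threshold = 0.8,
                               promoter_mask = NULL, promoter_pad = 500) {
  check_that(pairing_window > 0, "pairing_window must be positive")
  minus <- clusters[clusters$strand == "-", ]
  plus <- clusters[clusters$strand == "+", ]
  if (nrow(minus) == 0 || nrow(plus) == 0) {
    return(empty_loci())
  }
  # for each minus cluster, nearest plus cluster starting at/after its end
  cand <- inner_join(
    tibble(chrom = minus$chrom, m_start = minus$start, m_end = minus$end,
           R = minus$total_count, key = minus$chrom),
    tibble(p_start = plus$start, p_end = plus$end, F = plus$total_count,
           key = plus$chrom),
    by = "key", relationship = "many-to-many"
  ) |>
    mutate(gap = .data$p_start - .data$m_end) |>
    filter(.data$gap >= 0, .data$gap <= pairing_window) |>
    group_by(.data$chrom, .data$m_start, .data$m_end, .data$R) |>
    slice(which.min(.data$gap)) |>
    ungroup()
  if (nrow(cand) == 0) return(empty_loci())

  loci <- tibble(
    chrom = cand$chrom,
    start = cand$m_start,
    end = cand$p_end,
    strand = "*",
    midpoint = as.integer(floor((cand$m_end + cand$p_start) / 2)),
    minus_count = cand$R,
    plus_count = cand$F,
    directionality = (cand$F - cand$R) / (cand$F + cand$R)
  )
  loci <- loci[abs(loci$directionality) < directionality_threshold, ]
  if (nrow(loci) == 0) return(empty_loci())
  loci$id <- sprintf("bid_%05d", seq_len(nrow(loci)))

  if (!is.null(promoter_mask) && nrow(promoter_mask) > 0) {
    mask <- as_regions(promoter_mask)
    mask$start <- pmax(0, mask$start - promoter_pad)
    mask$end <- mask$end + promoter_pad
    mask$id <- sprintf("mask_%06d", seq_len(nrow(mask)))
    drop <- overlaps_any(loci, mask)
    loci <- loci[!loci$id %in% drop, ]
  }
  if (nrow(loci) == 0) return(empty_loci())

  # merge overlapping loci keeping the most balanced (smallest |D|)
  loci <- arrange(loci, abs(.data$directionality))
  keep <- rep(TRUE, nrow(loci))
  gr <- regions_to_gr(loci)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
  for (k in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[k]; j <- S4Vectors::subjectHits(hits)[k]
    if (keep[i]) keep[j] <- FALSE
  }
  loci <- loci[keep, ]
  loci <- arrange(loci, .data$chrom, .data$start)
  loci$id <- sprintf("bid_%05d", seq_len(nrow(loci)))
  select(loci, "chrom", "start", "end", "strand", "id", "midpoint",
         "minus_count", "plus_count", "directionality")
}

empty_loci <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), id = character(), midpoint = integer(),
         minus_count = integer(), plus_count = integer(),
         directionality = numeric())
}

#' Classify called loci as known or novel against known enhancer catalogs
#'
#' A locus is `known` iff it overlaps (>= `min_bp` bp) any region in any of
#' the supplied known sets; per-set overlap counts are attached as an
#' attribute `set_counts`.
#'
#' @param loci locus tibble from [call_bidirectional()]
#' @param known_sets named list of region tibbles
#' @param min_bp minimum overlap (default 1)
#' @return `loci` with a `novelty` column (`"known"`/`"novel"`)
#' @export
classify_novelty <- function(loci, known_sets, min_bp = 1) {
  if (nrow(loci) == 0) {
    loci$novelty <- character(0)
    attr(loci, "set_counts") <- setNames(integer(length(known_sets)),
                                         names(known_sets))
    return(loci)
  }
  known_ids <- character(0)
  set_counts <- integer(0)
  for (nm in names(known_sets)) {
    ids <- overlaps_any(loci, as_regions(known_sets[[nm]], prefix = nm),
                        min_bp = min_bp)
    set_counts[nm] <- length(ids)
    known_ids <- union(known_ids, ids)
  }
  loci$novelty <- ifelse(loci$id %in% known_ids, "known", "novel")
  attr(loci, "set_counts") <- set_counts
  loci
}

#' Total size of the combined transcribed-enhancer universe
#'
#' Sum of the known catalog sizes plus the number of novel loci.
#'
#' @param known_set_sizes integer vector of known catalog sizes
#' @param loci locus tibble with a `novelty` column
#' @return integer total
#' @export
combine_universe <- function(known_set_sizes, loci) {
  check_that("novelty" %in% names(loci), "loci must carry novelty labels")
  sum(known_set_sizes) + sum(loci$novelty == "novel")
}
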