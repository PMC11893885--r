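# Genomic-region tibbles and readers/writers for the plain-text formats the
# pipeline touches. All coordinates are 0-based half-open (BED convention)
# everywhere inside the package; CTSS positions can be shifted on read for
# 1-based dialects.

#' Validate and normalize a region tibble
#'
#' A region tibble has columns `chrom` (character), `start`, `end` (0-based,
#' half-open), `strand` (`"+"`, `"-"` or `"*"` for unstranded) and `id`
#' (unique within the catalog). Missing `strand`/`id` columns are filled in.
#'
#' @param x data frame with at least `chrom`, `start`, `end`
#' @param prefix id prefix used when auto-generating ids
#' @return a validated region tibble
#' @export
as_regions <- function(x, prefix = "region") {
  x <- as_tibble(x)
  check_that(all(c("chrom", "start", "end") %in% names(x)),
             "regions need chrom, start, end columns")
  if (!"strand" %in% names(x)) x$strand <- "*"
  if (!"id" %in% names(x) || any(is.na(x$id))) {
    x$id <- sprintf("%s_%05d", prefix, seq_len(nrow(x)))
  }
  x$chrom <- as.character(x$chrom)
  x$strand <- as.character(x$strand)
  check_that(all(nzchar(x$chrom)), "chrom must be non-empty")
  check_that(all(x$strand %in% c("+", "-", "*")),
             "strand must be one of '+', '-', '*'")
  check_that(all(x$start >= 0) && all(x$start < x$end),
             "regions must satisfy 0 <= start < end")
  check_that(!anyDuplicated(x$id), "region ids must be unique within a catalog")
  select(x, "chrom", "start", "end", "strand", "id", dplyr::everything())
}

# region tibble -> GRanges (1-based closed internally)
regions_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == "*", "*", x$strand)
  )
}

region_mid <- function(x) floor((x$start + x$end) / 2)

#' Read a BED3/BED6 file into a region tibble
#'
#' @param path file path
#' @param zero_based ignored for BED (always 0-based); present for symmetry
#' @return region tibble
#' @export
read_bed <- function(path, zero_based = TRUE) {
  check_that(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_regions(tibble(chrom = character(), start = integer(),
                             end = integer(), strand = character(),
                             id = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) abort(sprintf("malformed BED line %d: fewer than 3 columns", bad[1]))
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort(sprintf("malformed BED line %d: non-integer coordinates", bad[1]))
  bad <- which(start >= end)
  if (length(bad)) abort(sprintf("malformed BED line %d: start >= end", bad[1]))
  x <- tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = start,
    end = end,
    id = ifelse(nf >= 4, vapply(fields, function(f) f[4] %||% NA_character_, ""),
                NA_character_),
    strand = ifelse(nf >= 6, vapply(fields, function(f) f[6] %||% "*", ""), "*")
  )
  x$strand[!x$strand %in% c("+", "-")] <- "*"
  if (any(is.na(x$id))) x$id[is.na(x$id)] <- sprintf("bed_%05d", which(is.na(x$id)))
  as_regions(x, prefix = "bed")
}

#' Write a region tibble as BED6
#'
#' @param x region tibble
#' @param path output path
#' @param extra optional character vector of extra column names to append
#' @return invisibly, `path`
#' @export
write_bed <- function(x, path, extra = character()) {
  x <- as_regions(x)
  out <- data.frame(x$chrom, x$start, x$end, x$id, 0L, x$strand)
  for (col in extra) out[[col]] <- x[[col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a CTSS table (chrom, pos, strand, count)
#'
#' The CAGE-community 4-column TSV of per-base, per-strand tag counts.
#'
#' @param path file path
#' @param sample_id sample label attached to every record
#' @param one_based set `TRUE` if the file uses 1-based positions; they are
#'   converted to the package's 0-based convention on read
#' @return tibble with chrom, pos, strand, count, sample_id
#' @export
read_ctss <- function(path, sample_id, one_based = FALSE) {
  x <- readr::read_tsv(path, col_names = c("chrom", "pos", "strand", "count"),
                       col_types = "cici", progress = FALSE)
  check_that(all(x$strand %in% c("+", "-")), "CTSS strand must be '+' or '-'")
  check_that(all(x$count >= 0), "CTSS counts must be non-negative")
  if (one_based) x$pos <- x$pos - 1L
  x$sample_id <- sample_id
  as_tibble(x)
}

#' Write a CTSS table
#'
#' @param x CTSS tibble (chrom, pos, strand, count)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ctss <- function(x, path) {
  check_that(all(x$count >= 0), "CTSS counts must be non-negative")
  readr::write_tsv(x[, c("chrom", "pos", "strand", "count")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a Hi-C valid-pair table
#'
#' Six tab-separated columns: chrom1, pos1, strand1, chrom2, pos2, strand2.
#' Ends are canonicalized so that (chrom1, pos1) <= (chrom2, pos2).
#'
#' @param path file path
#' @param sample_id sample label
#' @return tibble of canonicalized pairs
#' @export
read_pairs <- function(path, sample_id) {
  x <- suppressWarnings(
    readr::read_tsv(path,
                    col_names = c("chrom1", "pos1", "strand1",
                                  "chrom2", "pos2", "strand2"),
                    col_types = "ciccic", progress = FALSE))
  if (nrow(x) == 0) {
    x$sample_id <- character()
    return(as_tibble(x))
  }
  check_that(ncol(x) == 6 && !anyNA(x),
             "valid pairs need 6 columns per line")
  check_that(all(c(x$strand1, x$strand2) %in% c("+", "-")),
             "unknown strand symbol in pairs file")
  x$sample_id <- sample_id
  canonicalize_pairs(as_tibble(x))
}

#' @rdname read_pairs
#' @param x pair tibble
#' @export
canonicalize_pairs <- function(x) {
  if (nrow(x) == 0) return(x)
  flip <- (x$chrom2 < x$chrom1) | (x$chrom2 == x$chrom1 & x$pos2 < x$pos1)
  out <- x
  out[flip, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
    x[flip, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
  out
}

#' Write a valid-pair table
#' @param x canonicalized pair tibble
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pairs <- function(x, path) {
  readr::write_tsv(x[, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a chrom-sizes table (chrom, length)
#' @param path file path
#' @return tibble with chrom, length
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"), col_types = "ci",
                  progress = FALSE)
}

#' Read a bedGraph score track
#' @param path file path
#' @return tibble with chrom, start, end, score (0-based half-open)
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                  col_types = "ciid", comment = "track", progress = FALSE)
}

#' Write a bedGraph score track
#' @param x tibble with chrom, start, end, score
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "score")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a variant table (chrom, pos, ref, alt, af)
#' @param path file path
#' @return tibble with snp_id, chrom, pos, ref, alt, af
#' @export
read_variants <- function(path) {
  x <- readr::read_tsv(path, col_names = c("snp_id", "chrom", "pos", "ref", "alt", "af"),
                       col_types = "cciccd", progress = FALSE)
  check_that(all(x$af >= 0 & x$af <= 1), "allele frequencies must lie in [0, 1]")
  as_tibble(x)
}

#' Read an LD pair table (snp_a, snp_b, r2, distance)
#' @param path file path
#' @return tibble with snp_a, snp_b, r2, distance
#' @export
read_ld <- function(path) {
  x <- readr::read_tsv(path, col_names = c("snp_a", "snp_b", "r2", "distance"),
                       col_types = "ccdi", progress = FALSE)
  check_that(all(x$r2 >= 0 & x$r2 <= 1), "r2 must lie in [0, 1]")
  check_that(all(x$distance >= 0), "LD distances must be non-negative")
  as_tibble(x)
}

#' Write an LD pair table
#' @param x LD tibble
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ld <- function(x, path) {
  readr::write_tsv(x[, c("snp_a", "snp_b", "r2", "distance")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a variant table (snp_id, chrom, pos, ref, alt, af)
#' @param x variant tibble
#' @param path output path
#' @return invisibly, `path`
#' @export
write_variants <- function(x, path) {
  readr::write_tsv(x[, c("snp_id", "chrom", "pos", "ref", "alt", "af")], path,
                   col_names = FALSE)
  invisible(path)
}

#' All pairwise overlaps between two region catalogs
#'
#' Half-open interval semantics: `[0,10)` and `[10,20)` do not overlap.
#' Delegates the interval search to IRanges.
#'
#' @param a,b region tibbles
#' @param min_bp minimum overlap in base pairs to report (default 1)
#' @return tibble with a_id, b_id, overlap_bp
#' @export
overlap_pairs <- function(a, b, min_bp = 1) {
  a <- as_regions(a, prefix = "a")
  b <- as_regions(b, prefix = "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_id = character(), b_id = character(), overlap_bp = integer()))
  }
  gra <- regions_to_gr(a)
  grb <- regions_to_gr(b)
  # catalogs on disjoint chromosome sets legitimately share no overlaps;
  # suppress the seqlevel-mismatch warning that case triggers
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, minoverlap = min_bp,
                                ignore.strand = TRUE))
  ov <- IRanges::pintersect(
    IRanges::ranges(gra)[S4Vectors::queryHits(hits)],
    IRanges::ranges(grb)[S4Vectors::subjectHits(hits)]
  )
  tibble(
    a_id = a$id[S4Vectors::queryHits(hits)],
    b_id = b$id[S4Vectors::subjectHits(hits)],
    overlap_bp = IRanges::width(ov)
  )
}

# ids of `a` regions overlapping any `b` region by >= min_bp
overlaps_any <- function(a, b, min_bp = 1) {
  unique(overlap_pairs(a, b, min_bp = min_bp)$a_id)
}
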