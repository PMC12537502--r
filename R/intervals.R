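# Interval algebra on 0-based half-open data frames (chrom, start, end),
# backed by IRanges. GRanges is 1-based inclusive, so conversion adds 1 to
# start on the way in and subtracts it on the way out.

#' Convert a 0-based half-open interval data frame to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). Additional columns are carried as metadata.
#' @return A [GenomicRanges::GRanges] object (1-based inclusive).
#' @keywords internal
#' @export
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand",
                                "seqnames", "ranges", "width", "element",
                                "seqlevels", "seqlengths", "isCircular"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, extra, drop = FALSE])
  }
  gr
}

#' Convert GRanges back to a 0-based half-open data frame
#' @param gr A GRanges object.
#' @return data.frame with `chrom`, `start`, `end` plus metadata columns.
#' @keywords internal
#' @export
as_bed_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Which intervals in `a` overlap any interval in `b`?
#'
#' Overlap means at least one shared base under the half-open convention.
#'
#' @param a,b interval data frames (`chrom`, `start`, `end`).
#' @return logical vector along rows of `a`.
#' @export
iv_overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  suppressWarnings(IRanges::overlapsAny(as_granges0(a), as_granges0(b)))
}

#' Overlap pairs between two interval sets
#' @inheritParams iv_overlaps_any
#' @return data.frame with columns `query`, `subject` (row indices).
#' @export
iv_overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b)))
  data.frame(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Distance to the nearest interval in `b` for each interval in `a`
#'
#' Gap distance in bp: 0 when the intervals overlap or abut is 1? Under the
#' half-open convention, intervals `[0,500)` and `[2500,4000)` are separated
#' by a gap of 2000 bp. Returns NA when `b` has no interval on the chromosome.
#'
#' @inheritParams iv_overlaps_any
#' @return list with `distance` (integer, NA if no same-chrom interval) and
#'   `nearest` (row index into `b`, NA if none).
#' @export
iv_nearest <- function(a, b) {
  n <- nrow(a)
  out <- list(distance = rep(NA_integer_, n), nearest = rep(NA_integer_, n))
  if (n == 0 || nrow(b) == 0) return(out)
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  # disjoint seqlevels (e.g. a chromosome absent from b) are expected and
  # reported as NA, not worth a warning
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(ga, gb))
  qi <- S4Vectors::queryHits(hits)
  out$distance[qi] <- as.integer(S4Vectors::mcols(hits)$distance)
  out$nearest[qi] <- S4Vectors::subjectHits(hits)
  out
}

#' Merge overlapping or nearby intervals
#' @param df interval data frame.
#' @param gap merge intervals separated by less than `gap` bp (default 0:
#'   only overlapping/abutting intervals merge).
#' @return merged interval data frame.
#' @export
iv_merge <- function(df, gap = 0L) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  gr <- as_granges0(df)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  as_bed_df(red)
}

#' Subtract interval set `b` from `a`
#' @inheritParams iv_overlaps_any
#' @return interval data frame covering `a` minus `b`.
#' @export
iv_setdiff <- function(a, b) {
  ga <- GenomicRanges::reduce(as_granges0(a))
  if (nrow(b) == 0) return(as_bed_df(ga))
  gb <- GenomicRanges::reduce(as_granges0(b))
  as_bed_df(GenomicRanges::setdiff(ga, gb))
}

#' Total bases of `a` covered by intervals in `b`, per row of `a`
#' @inheritParams iv_overlaps_any
#' @return integer vector of covered base counts along rows of `a`.
#' @export
iv_covered_bases <- function(a, b) {
  n <- nrow(a)
  if (n == 0) return(integer(0))
  out <- integer(n)
  if (nrow(b) == 0) return(out)
  ga <- as_granges0(a)
  gb <- GenomicRanges::reduce(as_granges0(b))
  h <- GenomicRanges::findOverlaps(ga, gb)
  if (length(h) == 0) return(out)
  qi <- S4Vectors::queryHits(h)
  ov <- GenomicRanges::pintersect(ga[qi], gb[S4Vectors::subjectHits(h)])
  w <- GenomicRanges::width(ov)
  agg <- tapply(w, qi, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Count points falling inside each interval
#'
#' @param iv interval data frame.
#' @param points data.frame with `chrom`, `pos` (0-based single base).
#' @return integer count per row of `iv`; a point on the start boundary
#'   counts, a point at `end` does not (half-open).
#' @export
iv_count_points <- function(iv, points) {
  n <- nrow(iv)
  if (n == 0) return(integer(0))
  out <- integer(n)
  if (nrow(points) == 0) return(out)
  gp <- GenomicRanges::GRanges(as.character(points$chrom),
                               IRanges::IRanges(points$pos + 1L, width = 1L))
  h <- GenomicRanges::findOverlaps(as_granges0(iv), gp)
  tab <- table(S4Vectors::queryHits(h))
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}
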