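# Per-cell-type pseudobulk ACR calling. Candidate peaks come from a Poisson
# threshold on the piled-up Tn5 signal; the defining computation is the
# empirical permutation FDR that follows, plus the nucleosome/fragment-size
# filters and 500 bp summit-window refinement.

#' Default ACR-calling parameters
#'
#' @param extsize pileup extension per insertion (bp).
#' @param shift pileup shift per insertion (bp).
#' @param fdr empirical permutation FDR cutoff.
#' @param n_perm_sets permutation sets per cell type.
#' @param window final ACR width (bp, even).
#' @param nuc_overlap_max maximum fraction of a peak coverable by nucleosome
#'   calls.
#' @param frag_size_max maximum mean fragment size (bp) of reads in a peak.
#' @param candidate_p Poisson tail probability for candidate calling.
#' @return list of parameters.
#' @export
acr_params <- function(extsize = 150L, shift = -75L, fdr = 0.05,
                       n_perm_sets = 1L, window = 500L,
                       nuc_overlap_max = 0.5, frag_size_max = 150,
                       candidate_p = 1e-5) {
  stopifnot(window %% 2L == 0L, fdr > 0, fdr < 1, n_perm_sets >= 1)
  list(extsize = extsize, shift = shift, fdr = fdr,
       n_perm_sets = n_perm_sets, window = window,
       nuc_overlap_max = nuc_overlap_max, frag_size_max = frag_size_max,
       candidate_p = candidate_p)
}

#' Pile up Tn5 insertions into a per-base coverage track
#'
#' Each insertion contributes an `extsize` bp interval placed at
#' `pos + shift` (default: shift -75, extend 150, i.e. a 150 bp window
#' centred on the insertion site), clipped to the chromosome.
#'
#' @param insertions data frame with `chrom`, `pos`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param extsize,shift pileup parameters (defaults 150 / -75).
#' @return named list of integer coverage vectors, one per chromosome.
#' @export
pseudobulk_pileup <- function(insertions, chrom_sizes, extsize = 150L,
                              shift = -75L) {
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    pos <- insertions$pos[insertions$chrom == ch]
    delta <- integer(len + 1L)
    if (length(pos)) {
      s <- pmax(0L, pos + shift)
      e <- pmin(len, pos + shift + extsize)
      ts <- tabulate(s + 1L, nbins = len + 1L)
      te <- tabulate(e + 1L, nbins = len + 1L)
      delta <- ts - te
    }
    cumsum(delta)[seq_len(len)]
  })
  names(out) <- names(chrom_sizes)
  out
}

#' Call candidate peaks from a coverage track
#'
#' Candidates are maximal runs of bases whose coverage exceeds the upper
#' `candidate_p` quantile of Poisson(lambda * extsize), where lambda is the
#' genome-wide insertion rate per bp. Runs closer than `merge_gap` bp are
#' merged; the summit is the leftmost coverage maximum.
#'
#' @param coverage output of [pseudobulk_pileup()].
#' @param candidate_p Poisson tail probability (default 1e-5).
#' @param extsize pileup extension used to build `coverage`.
#' @param merge_gap merge distance in bp (default 150).
#' @return data.frame with chrom, start, end, summit, summit_cov.
#' @export
call_candidate_peaks <- function(coverage, candidate_p = 1e-5,
                                 extsize = 150L, merge_gap = 150L) {
  total_mass <- sum(vapply(coverage, function(v) sum(as.numeric(v)), 0))
  L <- sum(vapply(coverage, length, 0L))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      summit_cov = integer(0))
  if (total_mass == 0) return(empty)
  lambda_cov <- total_mass / L   # expected coverage per base
  thr <- qpois(candidate_p, lambda_cov, lower.tail = FALSE)
  rows <- list()
  for (ch in names(coverage)) {
    v <- coverage[[ch]]
    above <- v > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
    # merge runs separated by < merge_gap
    if (nrow(runs) > 1) {
      keep_start <- runs$start[1]
      merged <- list()
      cur_s <- runs$start[1]; cur_e <- runs$end[1]
      for (k in 2:nrow(runs)) {
        if (runs$start[k] - cur_e < merge_gap) {
          cur_e <- runs$end[k]
        } else {
          merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
          cur_s <- runs$start[k]; cur_e <- runs$end[k]
        }
      }
      merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
      m <- do.call(rbind, merged)
      runs <- data.frame(start = m[, 1], end = m[, 2])
    }
    idx <- seq_len(nrow(runs))
    summit <- vapply(idx, function(k) {
      seg <- v[(runs$start[k] + 1L):runs$end[k]]
      runs$start[k] + which.max(seg) - 1L
    }, 0L)
    rows[[ch]] <- data.frame(chrom = ch, start = runs$start, end = runs$end,
                             summit = as.integer(summit),
                             summit_cov = v[summit + 1L],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute the empirical FDR density threshold from real and permuted sets
#'
#' For each candidate threshold t (the observed real densities),
#' FDR(t) = #\{permuted >= t\} / #\{real >= t\}; the returned threshold is
#' the minimum real density at which the FDR stays below `fdr`.
#'
#' @param real_density numeric vector of candidate-peak Tn5 densities.
#' @param perm_density numeric vector of permuted-interval densities (pooled
#'   over permutation sets; counts are averaged per set via `n_sets`).
#' @param fdr FDR cutoff (default 0.05).
#' @param n_sets number of permutation sets pooled into `perm_density`.
#' @return list with `threshold` (Inf when no threshold attains the FDR) and
#'   `keep` (logical along `real_density`).
#' @export
empirical_fdr_threshold <- function(real_density, perm_density, fdr = 0.05,
                                    n_sets = 1L) {
  cand <- sort(unique(real_density))
  thr <- Inf
  for (t in cand) {
    n_real <- sum(real_density >= t)
    n_perm <- sum(perm_density >= t) / n_sets
    if (n_real > 0 && n_perm / n_real < fdr) {
      thr <- t
      break
    }
  }
  list(threshold = thr, keep = real_density >= thr)
}

#' Place length-matched random intervals in mappable, non-exonic space
#'
#' @param widths integer vector of interval widths to place.
#' @param space interval data frame of allowed space.
#' @return data.frame of placed intervals (uniform over allowed positions;
#'   overlaps among placed intervals are permitted).
#' @keywords internal
sample_intervals_in_space <- function(widths, space) {
  if (nrow(space) == 0) stop("insufficient mappable space for permutation")
  seg_len <- space$end - space$start
  out <- data.frame(chrom = character(length(widths)),
                    start = integer(length(widths)),
                    end = integer(length(widths)), stringsAsFactors = FALSE)
  for (i in seq_along(widths)) {
    w <- widths[i]
    fits <- seg_len >= w
    if (!any(fits)) stop("no mappable segment fits width ", w)
    wts <- pmax(seg_len - w + 1L, 0L) * fits
    seg <- sample.int(nrow(space), 1L, prob = wts)
    off <- sample.int(seg_len[seg] - w + 1L, 1L) - 1L
    out$chrom[i] <- space$chrom[seg]
    out$start[i] <- space$start[seg] + off
    out$end[i] <- out$start[i] + w
  }
  out
}

#' Permutation-based empirical FDR filter for candidate peaks
#'
#' For every candidate peak an equal number of random intervals of the same
#' widths is placed uniformly in mappable, non-exonic space. Tn5 densities
#' (insertions per bp) are computed for both sets and candidates are
#' retained above the minimum density at which the empirical FDR stays
#' below `params$fdr`.
#'
#' @param candidates candidate peaks from [call_candidate_peaks()].
#' @param insertions insertion table (chrom, pos).
#' @param genome list with `mappable` and `exons` interval data frames.
#' @param params [acr_params()].
#' @param seed integer seed for interval placement.
#' @return list with `peaks` (retained candidates, with `density`),
#'   `threshold`, `real_density`, `perm_density`.
#' @export
permutation_fdr_filter <- function(candidates, insertions, genome, params =
                                     acr_params(), seed = 1L) {
  set.seed(seed)
  if (nrow(candidates) == 0) {
    return(list(peaks = candidates, threshold = Inf,
                real_density = numeric(0), perm_density = numeric(0)))
  }
  space <- iv_setdiff(genome$mappable, genome$exons)
  pts <- data.frame(chrom = insertions$chrom, pos = insertions$pos)
  widths <- candidates$end - candidates$start
  real_density <- iv_count_points(candidates, pts) / widths
  perm_density <- numeric(0)
  for (s in seq_len(params$n_perm_sets)) {
    perm <- sample_intervals_in_space(widths, space)
    perm_density <- c(perm_density,
                      iv_count_points(perm, pts) / widths)
  }
  res <- empirical_fdr_threshold(real_density, perm_density,
                                 fdr = params$fdr,
                                 n_sets = params$n_perm_sets)
  if (!is.finite(res$threshold)) {
    warning("no density threshold attains the requested FDR; ",
            "returning empty peak set")
  }
  peaks <- candidates[res$keep, , drop = FALSE]
  peaks$density <- real_density[res$keep]
  rownames(peaks) <- NULL
  list(peaks = peaks, threshold = res$threshold,
       real_density = real_density, perm_density = perm_density)
}

#' Apply nucleosome and fragment-size filters, then fix 500 bp windows
#'
#' Drops peaks with more than `nuc_overlap_max` of their span covered by
#' nucleosome calls, and peaks whose overlapping insertions have mean
#' fragment size above `frag_size_max` bp. Survivors are resized to
#' `window` bp centred on the summit (clipped at chromosome bounds and
#' flagged).
#'
#' @param peaks retained peaks (with `summit`).
#' @param nucleosomes interval data frame of nucleosome calls.
#' @param insertions insertion table with `frag_size`.
#' @param chrom_sizes named chromosome lengths.
#' @param params [acr_params()].
#' @return data.frame of 500 bp ACR windows with `summit`, `clipped`.
#' @export
refine_and_filter <- function(peaks, nucleosomes, insertions, chrom_sizes,
                              params = acr_params()) {
  if (nrow(peaks) == 0) return(cbind(peaks, clipped = logical(0)))
  span <- peaks$end - peaks$start
  nuc_frac <- iv_covered_bases(peaks, nucleosomes) / span
  gp <- iv_overlap_pairs(peaks, data.frame(chrom = insertions$chrom,
                                           start = insertions$pos,
                                           end = insertions$pos + 1L))
  mean_fs <- rep(NA_real_, nrow(peaks))
  if (nrow(gp)) {
    agg <- tapply(insertions$frag_size[gp$subject], gp$query, mean)
    mean_fs[as.integer(names(agg))] <- agg
  }
  keep <- nuc_frac <= params$nuc_overlap_max &
    (is.na(mean_fs) | mean_fs <= params$frag_size_max)
  out <- peaks[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$clipped <- logical(0)
    return(out)
  }
  half <- params$window %/% 2L
  len <- chrom_sizes[out$chrom]
  s <- out$summit - half
  e <- out$summit + half
  clipped <- s < 0 | e > len
  s2 <- pmax(0L, s)
  e2 <- pmin(as.integer(len), e)
  # keep the full window width where clipping occurred, sliding it inward
  s2 <- ifelse(e2 - s2 < params$window, pmax(0L, e2 - params$window), s2)
  e2 <- ifelse(e2 - s2 < params$window,
               pmin(as.integer(len), s2 + params$window), e2)
  out$start <- as.integer(s2)
  out$end <- as.integer(e2)
  out$clipped <- clipped
  rownames(out) <- NULL
  out
}

#' Merge per-cell-type ACR windows into an atlas
#'
#' Overlapping windows from different cell types are unified, re-centred on
#' the summit of the pooled coverage, and re-emitted as `window` bp
#' intervals.
#'
#' @param acr_list list of per-cell-type ACR data frames.
#' @param insertions pooled insertion table (all cell types).
#' @param chrom_sizes named chromosome lengths.
#' @param params [acr_params()].
#' @return data.frame of atlas ACRs (acr_id, chrom, start, end, summit).
#' @export
merge_acrs <- function(acr_list, insertions, chrom_sizes,
                       params = acr_params()) {
  allp <- do.call(rbind, lapply(acr_list, function(d)
    d[, c("chrom", "start", "end")]))
  if (is.null(allp) || nrow(allp) == 0) {
    return(data.frame(acr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0)))
  }
  merged <- iv_merge(allp)
  cov <- pseudobulk_pileup(insertions, chrom_sizes,
                           extsize = params$extsize, shift = params$shift)
  summit <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    v <- cov[[merged$chrom[i]]][(merged$start[i] + 1L):merged$end[i]]
    summit[i] <- merged$start[i] + which.max(v) - 1L
  }
  half <- params$window %/% 2L
  len <- chrom_sizes[merged$chrom]
  s <- pmax(0L, summit - half)
  e <- pmin(as.integer(len), summit + half)
  s <- ifelse(e - s < params$window, pmax(0L, e - params$window), s)
  out <- data.frame(acr_id = sprintf("ACR%05d", seq_len(nrow(merged))),
                    chrom = merged$chrom, start = as.integer(s),
                    end = as.integer(s + params$window),
                    summit = summit, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

#' Build the sparse peak-by-cell insertion count matrix
#'
#' @param acrs atlas ACRs (non-overlapping).
#' @param insertions insertion table with `barcode`.
#' @param cells cell table; only barcodes present here become columns.
#' @return list with `matrix` (sparse ACR x barcode counts) and
#'   `n_skipped` (insertions whose barcode was not in `cells`).
#' @export
build_peak_matrix <- function(acrs, insertions, cells) {
  j <- match(insertions$barcode, cells$barcode)
  n_skipped <- sum(is.na(j))
  keep <- !is.na(j)
  pairs <- iv_overlap_pairs(acrs,
                            data.frame(chrom = insertions$chrom[keep],
                                       start = insertions$pos[keep],
                                       end = insertions$pos[keep] + 1L))
  jj <- j[keep][pairs$subject]
  m <- Matrix::sparseMatrix(i = pairs$query, j = jj, x = 1,
                            dims = c(nrow(acrs), nrow(cells)),
                            dimnames = list(acrs$acr_id, cells$barcode))
  list(matrix = m, n_skipped = n_skipped)
}

#' Full per-cell-type ACR calling pipeline
#'
#' Runs pileup, Poisson candidate calling, the permutation FDR filter and
#' the nucleosome/fragment filters per cell type, merges the per-type peak
#' pools into 500 bp summit-centred atlas ACRs, and builds the
#' peak-by-cell count matrix.
#'
#' @param insertions insertion table with `chrom`, `pos`, `barcode`,
#'   `frag_size`, `cell_type`.
#' @param cells QC-passing cell table.
#' @param genome list with `chrom_sizes`, `mappable`, `exons`.
#' @param nucleosomes nucleosome-call intervals (may be empty).
#' @param params [acr_params()].
#' @param seed integer seed (one derived seed per cell type).
#' @return list with `acrs`, `per_celltype` (peak data frames),
#'   `matrix` (sparse ACR x barcode), `celltype_counts` (ACR x cell type).
#' @export
call_acrs <- function(insertions, cells, genome, nucleosomes = NULL,
                      params = acr_params(), seed = 1L) {
  if (is.null(nucleosomes)) {
    nucleosomes <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))
  }
  insertions <- insertions[insertions$barcode %in% cells$barcode, ]
  types <- sort(unique(cells$cell_type))
  per_type <- list()
  for (k in seq_along(types)) {
    ty <- types[k]
    ins_t <- insertions[insertions$cell_type == ty, ]
    cov <- pseudobulk_pileup(ins_t, genome$chrom_sizes,
                             extsize = params$extsize, shift = params$shift)
    cand <- call_candidate_peaks(cov, candidate_p = params$candidate_p,
                                 extsize = params$extsize)
    fdr_res <- permutation_fdr_filter(cand, ins_t, genome, params,
                                      seed = seed + k)
    per_type[[ty]] <- refine_and_filter(fdr_res$peaks, nucleosomes, ins_t,
                                        genome$chrom_sizes, params)
  }
  acrs <- merge_acrs(per_type, insertions, genome$chrom_sizes, params)
  pm <- build_peak_matrix(acrs, insertions, cells)
  ct_counts <- celltype_counts(pm$matrix, cells)
  list(acrs = acrs, per_celltype = per_type, matrix = pm$matrix,
       celltype_counts = ct_counts)
}

#' Collapse a peak-by-cell matrix to peak-by-cell-type pseudobulk counts
#' @param m sparse ACR x barcode matrix.
#' @param cells cell table with `barcode`, `cell_type` matching columns.
#' @return dense ACR x cell-type count matrix.
#' @export
celltype_counts <- function(m, cells) {
  types <- sort(unique(cells$cell_type))
  ind <- Matrix::sparseMatrix(
    i = seq_len(nrow(cells)),
    j = match(cells$cell_type, types),
    x = 1, dims = c(nrow(cells), length(types)),
    dimnames = list(cells$barcode, types))
  as.matrix(m %*% ind[colnames(m), , drop = FALSE])
}
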