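# H3K27me3-associated ACR classification, candidate-silencer gene linkage
# with expression contrasts, and broad methylation region (BMR) calling.

#' Accessibility-call parameters
#' @param cov_thresh strict lower bound on the per-million-scaled maximum
#'   coverage within the peak (default 2).
#' @param min_tn5 minimum Tn5 integration sites per peak (default 20,
#'   inclusive: "fewer than 20" are dropped).
#' @param cpm_thresh strict lower bound on quantile-normalized CPM
#'   (default 2).
#' @param flank H3K27me3 association flank in bp (default 500).
#' @return parameter list.
#' @export
access_params <- function(cov_thresh = 2, min_tn5 = 20L, cpm_thresh = 2,
                          flank = 500L) {
  list(cov_thresh = cov_thresh, min_tn5 = min_tn5, cpm_thresh = cpm_thresh,
       flank = flank)
}

#' Maximum per-base coverage within each ACR, per cell type
#'
#' @param acrs ACR intervals.
#' @param insertions insertion table with `cell_type`.
#' @param chrom_sizes named chromosome lengths.
#' @param extsize,shift pileup parameters.
#' @return ACR x cell-type matrix of raw maximum coverage.
#' @export
acr_max_coverage <- function(acrs, insertions, chrom_sizes, extsize = 150L,
                             shift = -75L) {
  types <- sort(unique(insertions$cell_type))
  out <- matrix(0, nrow(acrs), length(types),
                dimnames = list(acrs$acr_id, types))
  for (ty in types) {
    cov <- pseudobulk_pileup(insertions[insertions$cell_type == ty, ],
                             chrom_sizes, extsize = extsize, shift = shift)
    for (i in seq_len(nrow(acrs))) {
      v <- cov[[acrs$chrom[i]]][(acrs$start[i] + 1L):acrs$end[i]]
      out[i, ty] <- max(v)
    }
  }
  out
}

#' Binary accessibility calls per (ACR, cell type)
#'
#' An ACR is accessible in a cell type when all three criteria hold: the
#' maximum per-base coverage within the peak, scaled per million insertions
#' of that cell type, exceeds `cov_thresh`; the peak has at least `min_tn5`
#' integration sites; and the quantile-normalized CPM exceeds `cpm_thresh`.
#' CPM uses edgeR and quantile normalization uses limma's column-quantile
#' averaging.
#'
#' @param counts ACR x cell-type Tn5 count matrix.
#' @param max_cov ACR x cell-type raw maximum-coverage matrix (same dims).
#' @param lib_sizes per-cell-type total insertion counts (defaults to
#'   column sums of `counts`).
#' @param params [access_params()].
#' @return logical ACR x cell-type matrix.
#' @export
accessible_call_matrix <- function(counts, max_cov, lib_sizes = NULL,
                                   params = access_params()) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == dim(max_cov)))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  zero <- lib_sizes == 0
  if (any(zero)) {
    warning("cell type(s) with zero depth: ",
            paste(colnames(counts)[zero], collapse = ", "))
    lib_sizes[zero] <- 1
  }
  norm_cov <- sweep(max_cov, 2, lib_sizes / 1e6, "/")
  cpm <- edgeR::cpm(counts, lib.size = lib_sizes)
  qn <- limma::normalizeQuantiles(cpm)
  acc <- norm_cov > params$cov_thresh &
    counts >= params$min_tn5 &
    qn > params$cpm_thresh
  if (any(zero)) acc[, zero] <- FALSE
  dimnames(acc) <- dimnames(counts)
  acc
}

#' Classify ACRs by H3K27me3 association and accessibility breadth
#'
#' H3K27me3 status is `associated` when the ACR overlaps a domain or lies
#' within `flank` bp of one. Breadth from the accessibility-call matrix
#' with n cell types: `broad` when accessible in at least n-1 (n < 10) or
#' n-2 (n >= 10) cell types; `cell-type-specific` when accessible in fewer
#' than 3 (n < 10) or fewer than 4 (n >= 10); otherwise `intermediate`.
#'
#' @param acrs ACR intervals with `acr_id`.
#' @param accessible logical ACR x cell-type matrix.
#' @param domains H3K27me3 domain intervals.
#' @param params [access_params()].
#' @return data.frame: acr_id, h3k27me3_status, n_accessible, breadth,
#'   candidate_silencer (associated AND broad).
#' @export
classify_h3k27me3_acrs <- function(acrs, accessible, domains,
                                   params = access_params()) {
  n <- ncol(accessible)
  broad_min <- if (n < 10) n - 1L else n - 2L
  spec_max <- if (n < 10) 3L else 4L
  nd <- iv_nearest(acrs, domains)
  assoc <- !is.na(nd$distance) & nd$distance <= params$flank
  nacc <- rowSums(accessible)
  breadth <- ifelse(nacc >= broad_min, "broad",
                    ifelse(nacc < spec_max, "cell-type-specific",
                           "intermediate"))
  data.frame(acr_id = acrs$acr_id,
             h3k27me3_status = ifelse(assoc, "associated", "absent"),
             n_accessible = nacc, breadth = breadth,
             candidate_silencer = assoc & breadth == "broad",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Link candidate-silencer ACRs to genes and contrast expression
#'
#' A gene is linked to a broad ACR when the ACR sits upstream of the TSS
#' with a gap (TSS to the ACR's nearest edge, strand-aware) between 500
#' and 5000 bp inclusive and, for H3K27me3-associated links, the H3K27me3
#' domain covers more than 50% of the gene body. Per cell type a paired one-sided Wilcoxon signed-rank
#' test compares expression of genes linked to H3K27me3-associated broad
#' ACRs against an equal-count accessibility-matched sample of genes linked
#' to H3K27me3-absent broad ACRs (alternative: silencer-linked genes are
#' lower).
#'
#' @param annot output of [classify_h3k27me3_acrs()].
#' @param acrs ACR intervals (same order as `annot`).
#' @param genes gene models.
#' @param domains H3K27me3 domains.
#' @param expr gene x cell-type expression (or accessibility) matrix.
#' @param min_upstream,max_upstream link window bounds in bp.
#' @param body_cover_min minimum H3K27me3 gene-body cover for silencer
#'   links (default 0.5, strict).
#' @param seed integer seed for control matching.
#' @return list with `links` (acr_id, gene_id, h3k27me3_status, distance)
#'   and `tests` (cell_type, n_pairs, p).
#' @export
link_and_compare_expression <- function(annot, acrs, genes, domains, expr,
                                        min_upstream = 500L,
                                        max_upstream = 5000L,
                                        body_cover_min = 0.5, seed = 1L) {
  set.seed(seed)
  broad <- annot$breadth == "broad"
  # coarse candidate windows spanning the whole upstream reach, then the
  # exact TSS-to-ACR gap condition
  plus <- genes$strand == "+"
  win <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, pmax(0L, genes$start - max_upstream - 600L),
                   genes$end),
    end = ifelse(plus, genes$start,
                 genes$end + max_upstream + 600L),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  cover <- iv_covered_bases(genes, domains) / (genes$end - genes$start)
  pairs <- iv_overlap_pairs(acrs, win)
  pairs <- pairs[broad[pairs$query], , drop = FALSE]
  gap <- ifelse(plus[pairs$subject],
                genes$start[pairs$subject] - acrs$end[pairs$query],
                acrs$start[pairs$query] - genes$end[pairs$subject])
  pairs <- pairs[gap >= min_upstream & gap <= max_upstream, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(links = data.frame(), tests = data.frame()))
  }
  status <- annot$h3k27me3_status[pairs$query]
  gene_ok <- status == "absent" | cover[pairs$subject] > body_cover_min
  pairs <- pairs[gene_ok, , drop = FALSE]
  status <- annot$h3k27me3_status[pairs$query]
  links <- data.frame(acr_id = annot$acr_id[pairs$query],
                      gene_id = genes$gene_id[pairs$subject],
                      h3k27me3_status = status, stringsAsFactors = FALSE)
  links <- unique(links)

  sil_genes <- unique(links$gene_id[links$h3k27me3_status == "associated"])
  ctl_genes <- setdiff(unique(links$gene_id[links$h3k27me3_status ==
                                              "absent"]), sil_genes)
  tests <- data.frame(cell_type = character(0), n_pairs = integer(0),
                      p = numeric(0))
  if (length(sil_genes) >= 6 && length(ctl_genes) >= 6) {
    n_pair <- min(length(sil_genes), length(ctl_genes))
    # match controls by rank of mean expression so the contrast is not
    # driven by baseline accessibility differences
    mean_sil <- rowMeans(expr[sil_genes, , drop = FALSE])
    mean_ctl <- rowMeans(expr[ctl_genes, , drop = FALSE])
    sil_use <- sil_genes[order(mean_sil)][seq_len(n_pair)]
    ctl_use <- ctl_genes[order(mean_ctl)][seq_len(n_pair)]
    for (ct in colnames(expr)) {
      x <- expr[sil_use, ct]
      y <- expr[ctl_use, ct]
      p <- tryCatch(wilcox.test(x, y, paired = TRUE,
                                alternative = "less")$p.value,
                    error = function(e) NA_real_)
      tests <- rbind(tests, data.frame(cell_type = ct, n_pairs = n_pair,
                                       p = p))
    }
  } else {
    message("fewer than 6 linked genes in a group; expression test skipped")
  }
  list(links = links, tests = tests)
}

#' Call broad methylation regions (BMRs)
#'
#' A BMR is a maximal run of at least `min_windows` consecutive tiling
#' windows whose methylation level strictly exceeds the genome-wide mean.
#' Runs are emitted as merged intervals.
#'
#' @param windows data.frame with chrom, start, end, level; windows must
#'   tile each chromosome without overlap (consecutive = abutting).
#' @param min_windows minimum run length (default 3).
#' @return interval data frame of BMRs.
#' @export
call_bmrs <- function(windows, min_windows = 3L) {
  gm <- mean(windows$level)
  windows <- windows[order(windows$chrom, windows$start), ]
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    above <- w$level > gm
    # breaks in tiling also break runs
    contig <- c(TRUE, w$start[-1] == w$end[-nrow(w)])
    run_id <- cumsum(!above | !contig)
    for (rid in unique(run_id[above])) {
      idx <- which(run_id == rid & above)
      if (length(idx) >= min_windows) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = w$start[idx[1]], end = w$end[idx[length(idx)]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
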