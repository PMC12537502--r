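# Gene accessibility scores, per-cell-type marker genes, and cell-cycle
# stage assignment.

#' Binary gene accessibility score matrix
#'
#' Counts Tn5 insertions over each gene body plus a 500 bp upstream
#' extension (strand-aware, clipped at chromosome bounds), normalizes by
#' log counts-per-ten-thousand, and sets every positive normalized value to
#' 1. Because of the final binarization the result is identical for any
#' monotone positive normalization; the normalization step is kept visible
#' in the intermediate return value.
#'
#' @param insertions insertion table (chrom, pos, barcode).
#' @param genes gene models with strand.
#' @param cells cell table defining the columns.
#' @param upstream upstream extension in bp (default 500).
#' @return list with `score` (sparse binary gene x cell), `counts`
#'   (sparse raw counts).
#' @export
gene_score_matrix <- function(insertions, genes, cells, upstream = 500L) {
  ext <- genes
  plus <- genes$strand == "+"
  ext$start <- ifelse(plus, pmax(0L, genes$start - upstream), genes$start)
  ext$end <- ifelse(plus, genes$end, genes$end + upstream)
  j <- match(insertions$barcode, cells$barcode)
  keep <- !is.na(j)
  pairs <- iv_overlap_pairs(ext,
                            data.frame(chrom = insertions$chrom[keep],
                                       start = insertions$pos[keep],
                                       end = insertions$pos[keep] + 1L))
  counts <- Matrix::sparseMatrix(i = pairs$query, j = j[keep][pairs$subject],
                                 x = 1,
                                 dims = c(nrow(genes), nrow(cells)),
                                 dimnames = list(genes$gene_id,
                                                 cells$barcode))
  depth <- Matrix::colSums(counts)
  depth[depth == 0] <- 1
  norm <- counts
  norm@x <- log1p(norm@x / rep.int(depth, diff(norm@p))[seq_along(norm@x)] *
                    1e4)
  score <- norm
  score@x <- as.numeric(score@x > 0)
  list(score = Matrix::drop0(score), counts = counts)
}

#' Per-cell-type marker genes by one-vs-rest differential accessibility
#'
#' Pseudobulk gene counts per cell type are tested one-vs-rest with edgeR's
#' exact negative-binomial test (common dispersion across the pseudobulk
#' columns, library-size normalized). Markers satisfy FDR < `fdr_cut` and
#' log2 fold-change > 0.
#'
#' @param counts gene x cell-type pseudobulk count matrix (>= 2 columns).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return data.frame (gene, cell_type, log2FC, p, FDR) of markers.
#' @export
marker_genes <- function(counts, fdr_cut = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 cell types")
  zero_ct <- colSums(counts) == 0
  if (any(zero_ct)) {
    warning("cell type(s) with zero total counts excluded: ",
            paste(colnames(counts)[zero_ct], collapse = ", "))
    counts <- counts[, !zero_ct, drop = FALSE]
  }
  out <- list()
  for (ty in colnames(counts)) {
    group <- factor(ifelse(colnames(counts) == ty, "focal", "rest"),
                    levels = c("rest", "focal"))
    dge <- edgeR::DGEList(counts = counts, group = group)
    dge <- edgeR::calcNormFactors(dge)
    dge <- edgeR::estimateCommonDisp(dge)
    et <- edgeR::exactTest(dge, pair = c("rest", "focal"))
    tab <- et$table
    fdr <- p.adjust(tab$PValue, method = "BH")
    sel <- fdr < fdr_cut & tab$logFC > 0
    if (any(sel)) {
      out[[ty]] <- data.frame(gene = rownames(tab)[sel], cell_type = ty,
                              log2FC = tab$logFC[sel], p = tab$PValue[sel],
                              FDR = fdr[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), cell_type = character(0),
                      log2FC = numeric(0), p = numeric(0), FDR = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign cell-cycle stages from marker-gene accessibility
#'
#' For each stage the per-cell score is the sum of that stage's marker gene
#' scores. A permutation null draws equally sized random marker sets from
#' the full marker list excluding the focal stage's genes; the stage score
#' is z-scored against the permutation mean/SD and converted to a
#' probability with the standard normal CDF. Each cell is assigned the
#' stage with the highest probability.
#'
#' @param score gene x cell score matrix (e.g. from [gene_score_matrix()]).
#' @param stage_markers data.frame with `gene`, `stage` (the canonical
#'   asset has 55 genes across stages; any replaceable set works).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame per cell: barcode, assigned stage, per-stage
#'   probability columns, `low_confidence` flag.
#' @export
cell_cycle_assign <- function(score, stage_markers, n_perm = 1000L,
                              seed = 1L) {
  set.seed(seed)
  stage_markers <- stage_markers[stage_markers$gene %in% rownames(score), ]
  stages <- sort(unique(stage_markers$stage))
  n_cell <- ncol(score)
  probs <- matrix(NA_real_, n_cell, length(stages),
                  dimnames = list(colnames(score), stages))
  for (s in stages) {
    genes_s <- stage_markers$gene[stage_markers$stage == s]
    pool <- stage_markers$gene[stage_markers$stage != s]
    obs <- Matrix::colSums(score[genes_s, , drop = FALSE])
    perm <- matrix(0, n_perm, n_cell)
    for (b in seq_len(n_perm)) {
      g <- sample(pool, length(genes_s), replace = length(pool) <
                    length(genes_s))
      perm[b, ] <- Matrix::colSums(score[g, , drop = FALSE])
    }
    mu <- colMeans(perm)
    sdv <- apply(perm, 2, sd)
    z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
    probs[, s] <- pnorm(z)
  }
  assigned <- stages[max.col(probs, ties.method = "first")]
  low_conf <- apply(probs, 1, max) < 0.6
  out <- data.frame(barcode = colnames(score), stage = assigned,
                    low_confidence = low_conf, stringsAsFactors = FALSE,
                    row.names = NULL)
  cbind(out, as.data.frame(probs, row.names = NULL))
}
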