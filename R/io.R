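# Readers/writers for the plain-text formats the pipeline consumes and emits.
# Everything is converted to the package-wide 0-based half-open convention on
# read; GFF3 (1-based inclusive) is shifted.

#' Read a fragments file (10x-style TSV)
#'
#' Columns: chrom, start, end, barcode, count. `start`/`end` are the 0-based
#' half-open fragment coordinates after Tn5 shifting; `count` is the number
#' of identical fragment events.
#'
#' @param path path to a (optionally gzipped) tab-separated file.
#' @return data.table with those five columns.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "barcode", "count"))
  if (any(dt$end <= dt$start)) stop("malformed fragments: end <= start at line ",
                                    which(dt$end <= dt$start)[1])
  dt
}

#' Write a fragments file
#' @param frags data.frame/data.table with chrom, start, end, barcode, count.
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  data.table::fwrite(frags[, c("chrom", "start", "end", "barcode", "count")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Expand fragments into single-base Tn5 insertion records
#'
#' Each fragment contributes two insertion events: one at `start` and one at
#' `end - 1` (the two Tn5 integration sites), each replicated `count` times.
#'
#' @param frags fragments table from [read_fragments()].
#' @return data.table with `chrom`, `pos`, `barcode`, `frag_size`.
#' @export
fragments_to_insertions <- function(frags) {
  frags <- data.table::as.data.table(frags)
  idx <- rep(seq_len(nrow(frags)), frags$count)
  f <- frags[idx]
  size <- f$end - f$start
  data.table::data.table(
    chrom = rep(f$chrom, 2L),
    pos = c(f$start, f$end - 1L),
    barcode = rep(f$barcode, 2L),
    frag_size = rep(size, 2L)
  )
}

#' Read a BED3/BED6 file into a 0-based half-open data frame
#' @param path BED path.
#' @return data.frame with chrom, start, end (+ name, score, strand if BED6).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  as.data.frame(dt)
}

#' Write intervals as BED
#' @param df interval data frame; extra columns name/score/strand are kept.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  # BED columns are positional: emit up to the first absent optional column
  opt <- c("name", "score", "strand")
  n_opt <- match(FALSE, opt %in% names(df), nomatch = 4L) - 1L
  keep <- c("chrom", "start", "end", opt[seq_len(n_opt)])
  data.table::fwrite(df[, keep, drop = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of paired intervals (e.g. Hi-C loops)
#' @param path BEDPE path; columns chrom1,start1,end1,chrom2,start2,end2[,name,score].
#' @return data.frame of the paired intervals.
#' @export
read_bedpe <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score")
  data.table::setnames(dt, nm[seq_len(min(ncol(dt), 8L))])
  as.data.frame(dt)
}

#' Read gene models from GFF3
#'
#' Keeps features of type `gene`; 1-based inclusive GFF coordinates are
#' converted to 0-based half-open (`start - 1`, `end`).
#'
#' @param path GFF3 path.
#' @return data.frame with chrom, start, end, strand, gene_id.
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) stop("malformed GFF3 line ", bad[1])
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  data.frame(
    chrom = m[, 1],
    start = as.integer(m[, 4]) - 1L,
    end = as.integer(m[, 5]),
    strand = m[, 7],
    gene_id = ids,
    stringsAsFactors = FALSE
  )
}

#' Write gene models as GFF3
#' @param genes data.frame with chrom, start, end (0-based half-open), strand, gene_id.
#' @param path output path.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- sprintf("%s\tchromatlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a bedGraph coverage/level track
#' @param path bedGraph path.
#' @return data.frame with chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  as.data.frame(dt)
}

#' Write a bedGraph track
#' @param df data.frame with chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  data.table::fwrite(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read motif position frequency matrices in JASPAR text format
#'
#' Parses the `>ID name` header followed by four `A/C/G/T [ counts ]` rows.
#' Counts are converted to column-normalized probabilities with a pseudocount.
#'
#' @param path JASPAR PFM text file.
#' @param pseudocount added to every count before normalization (default 0.8,
#'   split evenly across the four bases).
#' @return list of motif models (see [motif_pwm()]).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    hdr <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]]
    rows <- lines[(i + 1):(i + 4)]
    nums <- lapply(rows, function(r) {
      r <- gsub("^[ACGT]\\s*\\[?|\\]$", "", r)
      as.numeric(strsplit(trimws(gsub("\\]", "", r)), "\\s+")[[1]])
    })
    if (length(unique(lengths(nums))) != 1L) stop("ragged PFM at record ", hdr[1])
    counts <- do.call(rbind, nums)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[hdr[1]]] <- motif_pwm(id = hdr[1],
                               name = if (length(hdr) > 1) hdr[2] else hdr[1],
                               counts = counts, pseudocount = pseudocount)
  }
  out
}

#' Write a sparse count matrix as triplet + dimension name TSVs
#'
#' Emits `<prefix>.mtx.tsv` (row, col, value; 1-based indices),
#' `<prefix>.rows.tsv` and `<prefix>.cols.tsv`.
#'
#' @param m a sparse [Matrix::Matrix] with dimnames.
#' @param prefix output path prefix.
#' @export
write_sparse_triplet <- function(m, prefix) {
  tm <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  data.table::fwrite(data.table::data.table(row = tm@i + 1L, col = tm@j + 1L,
                                            value = tm@x),
                     paste0(prefix, ".mtx.tsv"), sep = "\t")
  writeLines(rownames(m), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(m), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' Read a sparse matrix written by [write_sparse_triplet()]
#' @param prefix path prefix used at write time.
#' @return sparse dgCMatrix with dimnames.
#' @export
read_sparse_triplet <- function(prefix) {
  tr <- data.table::fread(paste0(prefix, ".mtx.tsv"))
  rn <- readLines(paste0(prefix, ".rows.tsv"))
  cn <- readLines(paste0(prefix, ".cols.tsv"))
  Matrix::sparseMatrix(i = tr$row, j = tr$col, x = tr$value,
                       dims = c(length(rn), length(cn)),
                       dimnames = list(rn, cn))
}

#' Read syntenic block definitions
#'
#' TSV columns: block_id, chromA, startA, endA, chromB, startB, endB,
#' orientation (`same`/`inverted`); coordinates 0-based half-open.
#'
#' @param path blocks TSV.
#' @return data.frame of blocks.
#' @export
read_blocks <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("block_id", "chromA", "startA", "endA", "chromB", "startB", "endB",
            "orientation")
  if (!all(need %in% names(dt))) stop("blocks TSV missing columns")
  as.data.frame(dt)
}
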