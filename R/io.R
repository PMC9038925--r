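#' Read and write the pipeline's plain-text formats
#'
#' Peaks travel as BED3+name (0-based half-open, tab-separated, no header);
#' matrices as TSV with a feature-id first column and sample ids in the
#' header; gene annotations as a GTF-like TSV. Writers emit full numeric
#' precision so a write/read round trip is lossless to numerical accuracy.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param peaks a `peak_set`.
#' @export
write_bed <- function(peaks, path) {
  data.table::fwrite(
    data.table::data.table(chrom = peaks$chrom, start = peaks$start,
                           end = peaks$end, name = peaks$peak_id),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED needs at least 3 columns")
  ids <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL
  peak_set(dt[[1]], dt[[2]], dt[[3]], ids)
}

#' @rdname io
#' @param mat numeric matrix with row and column names.
#' @param id_col name of the feature-id column in the file.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  dt <- data.table::data.table(id = rownames(mat))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- ids
  mat
}

#' @rdname io
#' @param genes a `gene_annotation`.
#' @export
write_genes_tsv <- function(genes, path) {
  data.table::fwrite(data.table::as.data.table(unclass(genes)[c(
    "gene_id", "chrom", "strand", "tss", "tts")]), path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @export
read_genes_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  gene_annotation(dt$gene_id, dt$chrom, dt$strand, dt$tss,
                  tts = if ("tts" %in% names(dt)) dt$tts else NULL)
}

#' @rdname io
#' @param config a list (e.g. a `cohort_config`).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
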