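SUBGENOMES <- c("A", "C", "D")

TF_FAMILIES <- c("MYB", "WRKY", "bHLH", "AP2", "ERF", "NAC", "MADS",
                 "Dof", "bZIP", "HSF")

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prop <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Expression set constructor
#'
#' Bundles a counts matrix, its sample design and gene lengths; FPKM is
#' derived immediately with [compute_fpkm()].
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns; dimnames required.
#' @param design data.frame with columns `sample_id`, `tissue`,
#'   `timepoint`, `replicate`; one row per counts column.
#' @param gene_lengths named numeric vector of exonic lengths in bp.
#' @return An object of class `expr_set` with elements `counts`, `fpkm`,
#'   `design`, `gene_lengths`.
#' @export
expr_set <- function(counts, design, gene_lengths) {
  stop_if(!is.matrix(counts), "counts must be a matrix")
  stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
          "counts must carry gene and sample names")
  stop_if(any(counts < 0) || any(counts != floor(counts)),
          "counts must be non-negative integers")
  stop_if(!all(c("sample_id", "tissue", "timepoint", "replicate") %in%
                 names(design)), "design lacks required columns")
  stop_if(!identical(colnames(counts), as.character(design$sample_id)),
          "design rows must match counts columns (same order)")
  stop_if(anyDuplicated(design[c("tissue", "timepoint", "replicate")]) > 0,
          "(tissue, timepoint, replicate) must be unique")
  gene_lengths <- gene_lengths[rownames(counts)]
  stop_if(anyNA(gene_lengths), "gene_lengths missing for some genes")
  structure(
    list(counts = counts,
         fpkm = compute_fpkm(counts, gene_lengths),
         design = design,
         gene_lengths = gene_lengths),
    class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d genes x %d samples (%s tissues, %s timepoints)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$tissue)),
              length(unique(x$design$timepoint))))
  invisible(x)
}

#' Select sample ids from a design
#'
#' @param design a sample design data.frame.
#' @param tissue optional tissue label.
#' @param salt_only if `TRUE`, keep timepoints > 0 only.
#' @param timepoint optional single timepoint (hours).
#' @return character vector of sample ids.
#' @export
select_samples <- function(design, tissue = NULL, salt_only = FALSE,
                           timepoint = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(tissue)) {
    stop_if(!tissue %in% design$tissue, "unknown tissue: ", tissue)
    keep <- keep & design$tissue == tissue
  }
  if (!is.null(timepoint)) {
    stop_if(!timepoint %in% design$timepoint,
            "unknown timepoint: ", timepoint)
    keep <- keep & design$timepoint == timepoint
  }
  if (salt_only) keep <- keep & design$timepoint > 0
  design$sample_id[keep]
}
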