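#' FPKM from raw counts
#'
#' `fpkm[g,s] = counts[g,s] / (length_kb[g] * libsize[s] / 1e6)` with the
#' library size taken as the column sum of counts.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param gene_lengths exonic lengths in bp (named or in row order).
#' @return numeric matrix of the same shape.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  stop_if(!is.matrix(counts), "counts must be a matrix")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  stop_if(length(gene_lengths) != nrow(counts),
          "one gene length per counts row required")
  stop_if(any(gene_lengths <= 0), "gene lengths must be positive")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0] %||% which(libsize == 0)
    stop("zero library size for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts / outer(gene_lengths / 1000, libsize / 1e6)
}

#' DEG-calling thresholds
#'
#' @param fc_min minimum |log2 fold change| (boundary inclusive).
#' @param fpkm_min expression floor; the larger of the two group means
#'   must exceed it.
#' @param epsilon pseudocount (FPKM units) added to both group means in
#'   the fold-change ratio.
#' @param test if `TRUE`, additionally require BH-adjusted Welch-t
#'   p < `alpha` (test on log2(FPKM + 1)).
#' @param alpha significance level used in test mode.
#' @return list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(fc_min = 1, fpkm_min = 0.5, epsilon = 0.01,
                           test = FALSE, alpha = 0.05) {
  stop_if(fc_min < 0 || fpkm_min < 0 || epsilon < 0,
          "thresholds must be non-negative")
  structure(list(fc_min = fc_min, fpkm_min = fpkm_min, epsilon = epsilon,
                 test = test, alpha = alpha), class = "deg_thresholds")
}

welch_p <- function(x_mat, y_mat) {
  # row-wise Welch t-test p-values; NA when both groups are constant
  nx <- ncol(x_mat); ny <- ncol(y_mat)
  mx <- rowMeans(x_mat); my <- rowMeans(y_mat)
  vx <- apply(x_mat, 1, stats::var); vy <- apply(y_mat, 1, stats::var)
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[se2 == 0] <- NA_real_
  p
}

#' Call DEGs for one tissue/timepoint contrast against the 0-h control
#'
#' `log2fc = log2((mean FPKM_t + eps) / (mean FPKM_0 + eps))`; the
#' expression filter requires `max(mean_t, mean_0) > fpkm_min`. In test
#' mode a Welch t-test on log2(FPKM + 1) with BH adjustment across genes
#' must additionally reach `alpha`.
#'
#' @param expr an [expr_set()].
#' @param tissue,timepoint the treated cell; `timepoint` must be > 0.
#' @param thresholds a [deg_thresholds()].
#' @return data.frame with one row per gene: gene_id, tissue, timepoint,
#'   log2fc, mean_fpkm_treated, mean_fpkm_control, p, padj, is_deg.
#' @export
call_degs <- function(expr, tissue, timepoint,
                      thresholds = deg_thresholds()) {
  stop_if(!inherits(expr, "expr_set"), "expr must be an expr_set")
  stop_if(timepoint == 0, "timepoint must be a salt timepoint (> 0)")
  treated <- select_samples(expr$design, tissue = tissue,
                            timepoint = timepoint)
  control <- select_samples(expr$design, tissue = tissue, timepoint = 0)
  stop_if(length(treated) < 1 || length(control) < 1,
          "both contrast cells need at least one replicate")
  ft <- expr$fpkm[, treated, drop = FALSE]
  f0 <- expr$fpkm[, control, drop = FALSE]
  mt <- rowMeans(ft); m0 <- rowMeans(f0)
  eps <- thresholds$epsilon
  log2fc <- log2((mt + eps) / (m0 + eps))
  expressed <- pmax(mt, m0) > thresholds$fpkm_min
  p <- padj <- rep(NA_real_, nrow(expr$fpkm))
  is_deg <- abs(log2fc) >= thresholds$fc_min & expressed
  if (thresholds$test) {
    p <- welch_p(log2(ft + 1), log2(f0 + 1))
    padj <- stats::p.adjust(p, method = "BH")
    is_deg <- is_deg & !is.na(padj) & padj < thresholds$alpha
  }
  data.frame(gene_id = rownames(expr$fpkm), tissue = tissue,
             timepoint = timepoint, log2fc = log2fc,
             mean_fpkm_treated = mt, mean_fpkm_control = m0,
             p = p, padj = padj, is_deg = is_deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call DEGs for every tissue x salt-timepoint contrast
#'
#' @inheritParams call_degs
#' @return row-bound data.frame of [call_degs()] results.
#' @export
call_degs_all <- function(expr, thresholds = deg_thresholds()) {
  tissues <- unique(expr$design$tissue)
  tps <- setdiff(sort(unique(expr$design$timepoint)), 0)
  do.call(rbind, lapply(tissues, function(ti)
    do.call(rbind, lapply(tps, function(tp)
      call_degs(expr, ti, tp, thresholds)))))
}

#' DEG counts per contrast and per-tissue unions
#'
#' @param degs a combined DEG table from [call_degs_all()].
#' @return list: `per_contrast` (tissue, timepoint, n_deg),
#'   `per_tissue` (tissue, n_union), `tissue_unions` (named list of gene
#'   ids DEG at >= 1 timepoint in that tissue), `grand_union`.
#' @export
deg_counts <- function(degs) {
  hits <- degs[degs$is_deg, , drop = FALSE]
  per_contrast <- stats::aggregate(is_deg ~ tissue + timepoint, degs, sum)
  names(per_contrast)[3] <- "n_deg"
  per_contrast <- per_contrast[order(per_contrast$tissue,
                                     per_contrast$timepoint), ]
  rownames(per_contrast) <- NULL
  tissues <- unique(degs$tissue)
  unions <- lapply(stats::setNames(tissues, tissues), function(ti)
    sort(unique(hits$gene_id[hits$tissue == ti])))
  per_tissue <- data.frame(tissue = tissues,
                           n_union = vapply(unions, length, 0L),
                           row.names = NULL, stringsAsFactors = FALSE)
  list(per_contrast = per_contrast, per_tissue = per_tissue,
       tissue_unions = unions,
       grand_union = sort(unique(hits$gene_id)))
}

#' Core DEGs and exclusive membership regions across tissues
#'
#' The core set is the intersection of the per-tissue DEG unions; the
#' `2^k - 1` exclusive membership regions (UpSet-style) partition the
#' grand union.
#'
#' @param unions named list (>= 2 entries) of per-tissue gene-id vectors.
#' @return list: `core` (gene ids), `regions` (region label, n),
#'   `grand_union`.
#' @export
core_degs <- function(unions) {
  stop_if(length(unions) < 2, "need unions for at least 2 tissues")
  stop_if(is.null(names(unions)), "unions must be named by tissue")
  all_genes <- sort(unique(unlist(unions)))
  memb <- vapply(unions, function(u) all_genes %in% u,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(unions)))
  key <- apply(memb, 1, function(r) paste(names(unions)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(unions), function(k)
    utils::combn(names(unions), k, paste, collapse = "&",
                 simplify = FALSE)), use.names = FALSE)
  n <- vapply(combos, function(cb) sum(key == cb), 0L)
  core <- all_genes[rowSums(memb) == length(unions)]
  list(core = core,
       regions = data.frame(region = combos, n = n,
                            stringsAsFactors = FALSE),
       grand_union = all_genes)
}

#' Fraction of a gene subset that is salt-responsive
#'
#' @param gene_subset non-empty character vector of gene ids.
#' @param deg_union character vector of responsive gene ids.
#' @return proportion in \[0, 1\].
#' @export
responsive_fraction <- function(gene_subset, deg_union) {
  gene_subset <- unique(gene_subset)
  stop_if(length(gene_subset) == 0, "gene subset is empty")
  length(intersect(gene_subset, deg_union)) / length(gene_subset)
}

#' Responsive fractions per TF family (and optionally per tissue)
#'
#' @param catalog gene catalog with a `tf_family` column.
#' @param deg_union grand DEG union (gene ids).
#' @param tissue_unions optional named list of per-tissue unions; adds a
#'   row per family x tissue.
#' @return data.frame: family, tissue ("all" for the union), n_family,
#'   n_responsive, fraction.
#' @export
tf_responsive_summary <- function(catalog, deg_union,
                                  tissue_unions = NULL) {
  tf <- catalog[!is.na(catalog$tf_family), ]
  stop_if(nrow(tf) == 0, "catalog carries no TF-family labels")
  fams <- sort(unique(tf$tf_family))
  one <- function(union, label) {
    do.call(rbind, lapply(fams, function(fm) {
      genes <- tf$gene_id[tf$tf_family == fm]
      data.frame(family = fm, tissue = label,
                 n_family = length(genes),
                 n_responsive = length(intersect(genes, union)),
                 fraction = responsive_fraction(genes, union),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one(deg_union, "all")
  for (ti in names(tissue_unions))
    out <- rbind(out, one(tissue_unions[[ti]], ti))
  out
}
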