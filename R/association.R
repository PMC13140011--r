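#' Genotype panel constructor
#'
#' @param geno accessions x markers dosage matrix (0/1/2 copies of the
#'   alternate allele; NA for missing), dimnames required.
#' @param markers data.frame: marker_id, chromosome, position (1-based),
#'   ref, alt, type (SNP/InDel); positions strictly increasing within a
#'   chromosome.
#' @return object of class `genotype_panel` with per-marker `maf` and
#'   `missing_rate`.
#' @export
genotype_panel <- function(geno, markers) {
  stop_if(!is.matrix(geno), "geno must be a matrix")
  stop_if(is.null(rownames(geno)) || is.null(colnames(geno)),
          "geno needs accession and marker names")
  stop_if(!identical(colnames(geno), markers$marker_id),
          "marker table must match geno columns (same order)")
  stop_if(!all(geno %in% c(0, 1, 2, NA)), "dosages must be 0/1/2/NA")
  for (ch in unique(markers$chromosome)) {
    p <- markers$position[markers$chromosome == ch]
    stop_if(is.unsorted(p, strictly = TRUE),
            "positions must be strictly increasing within chromosome ", ch)
  }
  p_alt <- colMeans(geno, na.rm = TRUE) / 2
  structure(list(geno = geno, markers = markers,
                 accessions = rownames(geno),
                 maf = pmin(p_alt, 1 - p_alt),
                 missing_rate = colMeans(is.na(geno))),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d accessions x %d markers (%d InDel)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$markers$type == "InDel")))
  invisible(x)
}

#' Marker quality control
#'
#' Retains markers with minor-allele frequency >= `maf_min` (boundary
#' inclusive) and missing rate <= `miss_max`.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min MAF floor (default 0.05).
#' @param miss_max missing-rate ceiling (default 0.1).
#' @return list: `panel` (filtered), `report` (n_input, n_dropped_maf,
#'   n_dropped_missing, n_retained).
#' @export
qc_markers <- function(panel, maf_min = 0.05, miss_max = 0.1) {
  stop_if(ncol(panel$geno) == 0, "empty panel")
  fail_maf <- panel$maf < maf_min | is.na(panel$maf)
  fail_miss <- panel$missing_rate > miss_max
  keep <- !fail_maf & !fail_miss
  stop_if(!any(keep & panel$maf > 0),
          "no polymorphic markers survive QC")
  filtered <- genotype_panel(panel$geno[, keep, drop = FALSE],
                             panel$markers[keep, , drop = FALSE])
  list(panel = filtered,
       report = data.frame(n_input = ncol(panel$geno),
                           n_dropped_maf = sum(fail_maf),
                           n_dropped_missing = sum(fail_miss),
                           n_retained = sum(keep)))
}

#' Principal-component covariates from the dosage matrix
#'
#' Missing dosages are mean-imputed per marker, markers standardized
#' (zero-variance markers dropped) and the top-k PCs returned.
#'
#' @param panel a [genotype_panel()].
#' @param k number of components (default 3).
#' @return accessions x k matrix of PC scores.
#' @export
pca_covariates <- function(panel, k = 3) {
  n <- nrow(panel$geno)
  stop_if(k >= n, "k must be smaller than the number of accessions")
  g <- panel$geno
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  sd_ <- apply(g, 2, stats::sd)
  g <- scale(g[, sd_ > 0, drop = FALSE])
  pc <- stats::prcomp(g, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- panel$accessions
  scores
}

#' Per-marker association scan with PC covariates
#'
#' Least-squares fit of `phenotype ~ intercept + covariates + dosage`
#' per marker (accessions with a missing dosage dropped for that
#' marker), Wald test on the dosage coefficient.
#'
#' @param panel a QC-filtered [genotype_panel()].
#' @param phenotype data.frame (accession_id, germination_rate) or a
#'   named numeric vector.
#' @param covariates optional accessions x k matrix
#'   ([pca_covariates()]).
#' @param threshold genome-wide significance threshold recorded in the
#'   output (default 1e-4).
#' @return data.frame: marker_id, chromosome, position, beta, se, p,
#'   n_used, threshold, significant.
#' @export
assoc_scan <- function(panel, phenotype, covariates = NULL,
                       threshold = 1e-4) {
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype[[2]], phenotype[[1]])
  y <- phenotype[panel$accessions]
  stop_if(anyNA(y), "phenotype missing for some accessions")
  stop_if(stats::sd(y) == 0, "constant phenotype")
  X0 <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariates))
    X0 <- cbind(X0, covariates[panel$accessions, , drop = FALSE])
  res <- lapply(seq_len(ncol(panel$geno)), function(j) {
    d <- panel$geno[, j]
    ok <- !is.na(d)
    if (stats::sd(d[ok]) == 0)
      return(c(beta = NA_real_, se = NA_real_, p = NA_real_,
               n = sum(ok)))
    fit <- if (ncol(X0) > 1) {
      stats::lm(y[ok] ~ X0[ok, -1, drop = FALSE] + d[ok])
    } else {
      stats::lm(y[ok] ~ d[ok])
    }
    cf <- summary(fit)$coefficients
    row <- cf[nrow(cf), ]
    c(beta = unname(row[1]), se = unname(row[2]),
      p = unname(row[4]), n = sum(ok))
  })
  res <- do.call(rbind, res)
  data.frame(marker_id = panel$markers$marker_id,
             chromosome = panel$markers$chromosome,
             position = panel$markers$position,
             beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
             n_used = res[, "n"], threshold = threshold,
             significant = !is.na(res[, "p"]) & res[, "p"] < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise LD r-squared
#'
#' Composite LD: squared Pearson correlation of dosage vectors,
#' pairwise-complete over missing genotypes. Monomorphic markers yield
#' NA rows/columns.
#'
#' @param panel a [genotype_panel()].
#' @param marker_ids markers to include (>= 2); default all.
#' @return symmetric matrix of r-squared values in \[0, 1\] with unit
#'   diagonal.
#' @export
ld_r2 <- function(panel, marker_ids = NULL) {
  if (is.null(marker_ids)) marker_ids <- panel$markers$marker_id
  stop_if(length(marker_ids) < 2, "need at least 2 markers")
  stop_if(!all(marker_ids %in% colnames(panel$geno)),
          "unknown marker id(s)")
  g <- panel$geno[, marker_ids, drop = FALSE]
  suppressWarnings(r <- stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Two-group haplotype comparison at a focal InDel
#'
#' Accessions homozygous for the insertion-carrying (longer) allele form
#' Hap1, homozygotes for the deletion allele Hap2; heterozygous or
#' missing accessions are excluded. Germination rates are compared with
#' a Student's (pooled-variance) t-test by default.
#'
#' @param panel a [genotype_panel()].
#' @param focal_marker marker id of the focal InDel.
#' @param phenotype as in [assoc_scan()].
#' @param welch use the Welch variant instead of the pooled test.
#' @return list of class `haplotype_comparison`: `groups` (per-accession
#'   haplotype labels), `n`, `means`, `t`, `df`, `p`.
#' @export
haplotype_compare <- function(panel, focal_marker, phenotype,
                              welch = FALSE) {
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype[[2]], phenotype[[1]])
  j <- match(focal_marker, panel$markers$marker_id)
  stop_if(is.na(j), "unknown focal marker: ", focal_marker)
  ref <- panel$markers$ref[j]; alt <- panel$markers$alt[j]
  # Hap1 = the insertion-carrying (longer) allele
  hap1_is_ref <- nchar(ref) >= nchar(alt)
  d <- panel$geno[, j]
  hap1 <- if (hap1_is_ref) d == 0 else d == 2
  hap2 <- if (hap1_is_ref) d == 2 else d == 0
  groups <- rep(NA_character_, length(d))
  groups[which(hap1)] <- "Hap1"
  groups[which(hap2)] <- "Hap2"
  names(groups) <- panel$accessions
  y1 <- phenotype[names(groups)[groups == "Hap1" & !is.na(groups)]]
  y2 <- phenotype[names(groups)[groups == "Hap2" & !is.na(groups)]]
  stop_if(length(y1) < 2 || length(y2) < 2,
          "need >= 2 genotyped accessions per haplotype group")
  tt <- stats::t.test(y1, y2, var.equal = !welch)
  structure(list(groups = groups,
                 n = c(Hap1 = length(y1), Hap2 = length(y2)),
                 means = c(Hap1 = mean(y1), Hap2 = mean(y2)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "haplotype_comparison")
}

#' @export
print.haplotype_comparison <- function(x, ...) {
  cat(sprintf(
    "<haplotype_comparison> Hap1 n=%d mean=%.2f | Hap2 n=%d mean=%.2f | t=%.3f p=%.3g\n",
    x$n["Hap1"], x$means["Hap1"], x$n["Hap2"], x$means["Hap2"],
    x$t, x$p))
  invisible(x)
}
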