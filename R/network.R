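#' Build the co-expression input matrix
#'
#' Restricts the expression set to the salt-responsive gene union,
#' applies the network expression floor (max FPKM > `fpkm_min`),
#' transforms to log2(FPKM + 1) and drops zero-variance genes.
#'
#' @param expr an [expr_set()].
#' @param deg_union gene ids to keep (the DEG union).
#' @param fpkm_min network expression floor (default 0.2).
#' @return genes x samples numeric matrix; the number of zero-variance
#'   genes dropped is attached as attribute `n_zero_variance`.
#' @export
network_input <- function(expr, deg_union, fpkm_min = 0.2) {
  stop_if(ncol(expr$fpkm) < 3, "need at least 3 samples")
  genes <- intersect(rownames(expr$fpkm), deg_union)
  stop_if(length(genes) == 0, "no DEG-union genes in expression matrix")
  f <- expr$fpkm[genes, , drop = FALSE]
  f <- f[apply(f, 1, max) > fpkm_min, , drop = FALSE]
  x <- log2(f + 1)
  v <- apply(x, 1, stats::var)
  n_zero <- sum(v == 0)
  if (n_zero > 0)
    message(n_zero, " zero-variance gene(s) dropped from network input")
  x <- x[v > 0, , drop = FALSE]
  attr(x, "n_zero_variance") <- n_zero
  x
}

#' Signed adjacency from expression
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2) ^ beta` with unit diagonal.
#'
#' @param expr_matrix genes x samples matrix (e.g. [network_input()]).
#' @param beta soft-threshold power (>= 1).
#' @return symmetric adjacency matrix in \[0, 1\].
#' @export
signed_adjacency <- function(expr_matrix, beta) {
  stop_if(beta < 1, "beta must be >= 1")
  v <- apply(expr_matrix, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s) produce undefined correlations: ",
         paste(rownames(expr_matrix)[v == 0], collapse = ", "),
         call. = FALSE)
  r <- stats::cor(t(expr_matrix))
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

scale_free_r2 <- function(k, n_bins = 10) {
  # signed scale-free fit: R^2 of log10(freq) ~ log10(mean k), negated
  # when the slope is positive
  k <- k[k > 0]
  if (length(unique(k)) < 2) stop("degenerate fit: all connectivities equal",
                                  call. = FALSE)
  br <- seq(min(log10(k)), max(log10(k)), length.out = n_bins + 1)
  bin <- cut(log10(k), breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  if (!is.na(slope) && slope > 0) r2 <- -r2
  c(r2 = r2, slope = unname(slope))
}

#' Soft-threshold scan for scale-free topology
#'
#' For each candidate power, computes signed adjacency connectivities,
#' bins log10(k) into 10 equal-width bins and regresses log10(frequency)
#' on log10(mean bin k); the fit index is negated when the slope is
#' positive. The chosen power is the smallest with fit >= `r2_target`,
#' falling back (with a warning) to the argmax when none reaches it.
#'
#' @param expr_matrix genes x samples matrix.
#' @param betas candidate integer powers (default 1:30).
#' @param r2_target scale-free fit target (default 0.85).
#' @return list of class `soft_threshold_scan`: `scan` (beta, r2,
#'   mean_k), `beta` (chosen power), `r2_target`.
#' @export
select_soft_threshold <- function(expr_matrix, betas = 1:30,
                                  r2_target = 0.85) {
  stop_if(any(betas < 1 | betas > 30), "powers must lie in [1, 30]")
  if (nrow(expr_matrix) < 50)
    warning("fewer than 50 genes: scale-free fit will be unstable")
  r <- stats::cor(t(expr_matrix))
  s <- (1 + r) / 2
  diag(s) <- 0
  rows <- lapply(betas, function(b) {
    k <- rowSums(s^b)
    fit <- scale_free_r2(k)
    data.frame(beta = b, r2 = fit[["r2"]], mean_k = mean(k))
  })
  scan <- do.call(rbind, rows)
  hit <- which(!is.na(scan$r2) & scan$r2 >= r2_target)
  if (length(hit) > 0) {
    beta <- scan$beta[hit[1]]
  } else {
    beta <- scan$beta[which.max(scan$r2)]
    warning("no power reached the scale-free fit target ", r2_target,
            "; using argmax power ", beta)
  }
  structure(list(scan = scan, beta = beta, r2_target = r2_target),
            class = "soft_threshold_scan")
}

#' Topological overlap from a signed adjacency
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over u != i, j and `k_i = sum_u a_iu` over
#' u != i; unit diagonal.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return TOM similarity matrix in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  stop_if(!isSymmetric(unname(adjacency), tol = 1e-10),
          "adjacency must be symmetric")
  stop_if(any(adjacency < 0 | adjacency > 1), "adjacency must be in [0,1]")
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black",
  "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

module_labels_from_sizes <- function(cluster_ids, min_size) {
  sizes <- sort(table(cluster_ids), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_size]
  pal <- c(MODULE_COLORS,
           sprintf("module%d", seq_len(max(0, length(keep) -
                                             length(MODULE_COLORS)))))
  lab <- rep("grey", length(cluster_ids))
  for (i in seq_along(keep))
    lab[cluster_ids == keep[i]] <- pal[i]
  names(lab) <- names(cluster_ids)
  lab
}

#' Detect preliminary modules on the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at the
#' height given by `quantile(merge heights, cut_height_quantile)`;
#' clusters smaller than `min_size` are assigned the reserved `grey`
#' label and surviving modules are named by descending size.
#'
#' @param diss_tom dissimilarity matrix (1 - TOM).
#' @param min_size minimum module size (default 30).
#' @param cut_height_quantile quantile of dendrogram merge heights used
#'   as the static cut (default 0.99).
#' @return named character vector of module labels per gene.
#' @export
detect_modules <- function(diss_tom, min_size = 30,
                           cut_height_quantile = 0.99) {
  stop_if(min_size < 2, "min_size must be >= 2")
  tree <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- stats::quantile(tree$height, cut_height_quantile, names = FALSE)
  cl <- stats::cutree(tree, h = h)
  module_labels_from_sizes(cl, min_size)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression (unit norm over samples), sign-oriented to
#' correlate positively with the module's mean expression profile. A
#' single-gene module returns that gene's standardized profile with a
#' warning.
#'
#' @param expr_matrix genes x samples matrix.
#' @param labels named module labels ([detect_modules()]); `grey` is
#'   skipped.
#' @return modules x samples matrix with attribute `var_explained`.
#' @export
module_eigengene <- function(expr_matrix, labels) {
  mods <- setdiff(unique(labels), "grey")
  stop_if(length(mods) == 0, "no non-grey modules")
  me <- matrix(NA_real_, length(mods), ncol(expr_matrix),
               dimnames = list(mods, colnames(expr_matrix)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    x <- expr_matrix[names(labels)[labels == m], , drop = FALSE]
    xs <- t(scale(t(x)))
    if (nrow(x) == 1) {
      warning("module ", m, " has a single gene; using its profile")
      v <- xs[1, ] / sqrt(sum(xs[1, ]^2))
      ve[m] <- 1
    } else {
      sv <- svd(xs)
      v <- sv$v[, 1]
      ve[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(v, colMeans(xs)) < 0) v <- -v
    me[m, ] <- v
  }
  attr(me, "var_explained") <- ve
  me
}

#' Merge similar modules by eigengene correlation
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor` falls below `merge_cut`, recomputing
#' eigengenes after each merge, until no pair qualifies.
#'
#' @param expr_matrix genes x samples matrix.
#' @param labels initial module labels ([detect_modules()]).
#' @param merge_cut eigengene dissimilarity cut height (default 0.25).
#' @return list of class `module_set`: `labels`, `eigengenes`,
#'   `var_explained`, `me_cor`, `me_adjacency` (signed (1+cor)/2),
#'   `merge_history`, `params`.
#' @export
merge_modules <- function(expr_matrix, labels, merge_cut = 0.25) {
  history <- data.frame(from = character(0), into = character(0),
                        dissimilarity = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2 || merge_cut <= 0) break
    me <- module_eigengene(expr_matrix, labels)
    diss <- 1 - stats::cor(t(me))
    diag(diss) <- Inf
    ij <- arrayInd(which.min(diss), dim(diss))
    if (diss[ij] >= merge_cut) break
    m1 <- rownames(diss)[ij[1]]; m2 <- colnames(diss)[ij[2]]
    sizes <- table(labels)
    from <- if (sizes[m1] < sizes[m2]) m1 else m2
    into <- if (from == m1) m2 else m1
    labels[labels == from] <- into
    history <- rbind(history,
                     data.frame(from = from, into = into,
                                dissimilarity = diss[ij],
                                stringsAsFactors = FALSE))
  }
  me <- module_eigengene(expr_matrix, labels)
  me_cor <- if (nrow(me) > 1) stats::cor(t(me)) else
    matrix(1, 1, 1, dimnames = list(rownames(me), rownames(me)))
  structure(
    list(labels = labels, eigengenes = me,
         var_explained = attr(me, "var_explained"),
         me_cor = me_cor, me_adjacency = (1 + me_cor) / 2,
         merge_history = history,
         params = list(merge_cut = merge_cut)),
    class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("<module_set> %d modules (+grey) over %d genes\n",
              length(setdiff(names(sizes), "grey")), length(x$labels)))
  print(sizes)
  invisible(x)
}

#' Run the full network stage
#'
#' Convenience wrapper: soft-threshold selection (unless `beta` given),
#' signed adjacency, TOM, static-cut module detection and eigengene
#' merging.
#'
#' @param expr_matrix genes x samples matrix from [network_input()].
#' @param beta fixed power, or `NULL` to scan.
#' @param r2_target,min_size,cut_height_quantile,merge_cut stage
#'   parameters.
#' @return `module_set` with the scan and TOM attached (`scan`, `tom`).
#' @export
build_network <- function(expr_matrix, beta = NULL, r2_target = 0.85,
                          min_size = 30, cut_height_quantile = 0.99,
                          merge_cut = 0.25) {
  scan <- NULL
  if (is.null(beta)) {
    scan <- select_soft_threshold(expr_matrix, r2_target = r2_target)
    beta <- scan$beta
  }
  adj <- signed_adjacency(expr_matrix, beta)
  tom <- tom_similarity(adj)
  labels <- detect_modules(1 - tom, min_size, cut_height_quantile)
  ms <- merge_modules(expr_matrix, labels, merge_cut)
  ms$params <- c(ms$params,
                 list(beta = beta, min_size = min_size,
                      cut_height_quantile = cut_height_quantile))
  ms$scan <- scan
  ms$tom <- tom
  ms
}

#' Tissue over-representation per module
#'
#' One-sided hypergeometric test of each tissue's DEG set in each
#' module, BH-adjusted over all module x tissue cells; `q < 0.05` flags
#' tissue-dominant modules.
#'
#' @param module_set a `module_set` (or named label vector).
#' @param tissue_deg_sets named list of per-tissue DEG gene-id vectors.
#' @param background background gene ids (default: all network genes).
#' @return data.frame: module, tissue, module_size, tissue_size,
#'   overlap, p, q, flagged.
#' @export
module_tissue_enrichment <- function(module_set, tissue_deg_sets,
                                     background = NULL) {
  labels <- if (inherits(module_set, "module_set")) module_set$labels
            else module_set
  if (is.null(background)) background <- names(labels)
  mods <- setdiff(unique(labels), "grey")
  out <- do.call(rbind, lapply(mods, function(m) {
    mg <- intersect(names(labels)[labels == m], background)
    do.call(rbind, lapply(names(tissue_deg_sets), function(ti) {
      tg <- intersect(tissue_deg_sets[[ti]], background)
      ov <- length(intersect(mg, tg))
      p <- stats::phyper(ov - 1, length(tg),
                         length(background) - length(tg), length(mg),
                         lower.tail = FALSE)
      data.frame(module = m, tissue = ti, module_size = length(mg),
                 tissue_size = length(tg), overlap = ov, p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$q < 0.05
  out
}

#' Extract a seed-gene subnetwork from one module
#'
#' Edges connect seed genes to their module co-members (seeds included)
#' when |Pearson correlation| >= `weight_min`; the signed-TOM weight for
#' the module submatrix is exported alongside.
#'
#' @param expr_matrix genes x samples matrix.
#' @param module_set a `module_set`.
#' @param seed_genes gene ids; must all belong to one module.
#' @param weight_min minimum |correlation| for an edge.
#' @param catalog optional catalog; adds `source_tf`/`target_tf`
#'   TF-family annotation columns.
#' @return data.frame edge list: source, target, pearson, tom (+ TF
#'   columns).
#' @export
extract_subnetwork <- function(expr_matrix, module_set, seed_genes,
                               weight_min = 0.3, catalog = NULL) {
  labels <- module_set$labels
  missing <- setdiff(seed_genes, names(labels))
  stop_if(length(missing) > 0, "seed gene(s) outside the network: ",
          paste(missing, collapse = ", "))
  mods <- unique(labels[seed_genes])
  stop_if(length(mods) != 1, "seed genes span multiple modules: ",
          paste(mods, collapse = ", "))
  members <- names(labels)[labels == mods]
  x <- expr_matrix[members, , drop = FALSE]
  r <- stats::cor(t(x))
  beta <- module_set$params$beta %||% 10
  tom <- tom_similarity(((1 + r) / 2)^beta * (1 - diag(nrow(r))) +
                          diag(nrow(r)))
  idx <- which(upper.tri(r) & (abs(r) >= weight_min), arr.ind = TRUE)
  keep <- members[idx[, 1]] %in% seed_genes |
    members[idx[, 2]] %in% seed_genes
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(source = members[idx[, 1]],
                    target = members[idx[, 2]],
                    pearson = r[idx], tom = tom[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    fam <- stats::setNames(catalog$tf_family, catalog$gene_id)
    out$source_tf <- fam[out$source]
    out$target_tf <- fam[out$target]
  }
  out
}
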