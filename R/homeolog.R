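#' Classify homeolog groups by subgenome copy pattern
#'
#' Categories follow the allohexaploid copy-pattern vocabulary: `triad`
#' (A:C:D = 1:1:1), `dyad_AC`/`dyad_AD`/`dyad_CD` (n:n:0 with n >= 1 in
#' each present subgenome, the third absent — unequal copy numbers such
#' as 1 A + 2 D still count as a dyad), `singleton_A/C/D` (exactly one
#' copy in exactly one subgenome), and `other` for everything else.
#'
#' @param homeologs data.frame (group_id, gene_id).
#' @param catalog gene catalog with `gene_id` and `subgenome`.
#' @return list: `groups` (group_id, n_A, n_C, n_D, n_genes, category),
#'   `members` (homeologs joined with subgenome and category),
#'   `category_counts` (category, n_groups, n_genes).
#' @export
classify_groups <- function(homeologs, catalog) {
  stop_if(anyDuplicated(homeologs$gene_id) > 0,
          "gene(s) assigned to more than one homeolog group: ",
          paste(unique(homeologs$gene_id[duplicated(homeologs$gene_id)]),
                collapse = ", "))
  idx <- match(homeologs$gene_id, catalog$gene_id)
  stop_if(anyNA(idx), "homeolog member gene(s) absent from catalog")
  sub <- catalog$subgenome[idx]
  bad <- setdiff(unique(sub), SUBGENOMES)
  stop_if(length(bad) > 0, "unknown subgenome label(s): ",
          paste(bad, collapse = ", "))

  tab <- table(homeologs$group_id, factor(sub, levels = SUBGENOMES))
  counts <- as.data.frame.matrix(tab)
  groups <- data.frame(group_id = rownames(counts),
                       n_A = counts$A, n_C = counts$C, n_D = counts$D,
                       row.names = NULL, stringsAsFactors = FALSE)
  groups$n_genes <- groups$n_A + groups$n_C + groups$n_D
  groups$category <- apply(groups[, c("n_A", "n_C", "n_D")], 1,
                           copy_pattern_category)
  members <- data.frame(homeologs, subgenome = sub,
                        category = groups$category[
                          match(homeologs$group_id, groups$group_id)],
                        stringsAsFactors = FALSE)
  agg_g <- stats::aggregate(group_id ~ category, groups, length)
  agg_n <- stats::aggregate(n_genes ~ category, groups, sum)
  category_counts <- merge(agg_g, agg_n)
  names(category_counts)[2] <- "n_groups"
  list(groups = groups, members = members,
       category_counts = category_counts)
}

copy_pattern_category <- function(n) {
  a <- n[1]; c_ <- n[2]; d <- n[3]
  if (a == 1 && c_ == 1 && d == 1) return("triad")
  present <- c(a, c_, d) >= 1
  if (sum(c(a, c_, d)) == 1)
    return(paste0("singleton_", SUBGENOMES[present]))
  if (sum(present) == 2)
    return(paste0("dyad_", paste(SUBGENOMES[present], collapse = "")))
  "other"
}

#' Per-triad subgenome expression fractions
#'
#' For each triad, `e_X` is the mean FPKM of its subgenome-X copy over
#' the selected samples and `fX = e_X / (e_A + e_C + e_D)`. Triads whose
#' summed mean FPKM falls below `floor` are flagged unexpressed (their
#' fractions are NA).
#'
#' @param expr an [expr_set()].
#' @param groups result of [classify_groups()].
#' @param samples sample ids defining the context (see
#'   [select_samples()]); default: all salt-treated samples.
#' @param group_ids optional explicit triad ids; a non-triad id is an
#'   error. Default: all triads.
#' @param floor summed mean-FPKM floor below which a triad counts as
#'   unexpressed.
#' @return data.frame: group_id, eA, eC, eD, fA, fC, fD, total,
#'   unexpressed.
#' @export
ternary_fractions <- function(expr, groups, samples = NULL,
                              group_ids = NULL, floor = 0.5) {
  if (is.null(samples))
    samples <- select_samples(expr$design, salt_only = TRUE)
  stop_if(length(samples) < 1, "selector resolves to zero samples")
  triads <- groups$groups[groups$groups$category == "triad", ]
  if (!is.null(group_ids)) {
    check_triads_only(groups, group_ids)
    triads <- triads[triads$group_id %in% group_ids, ]
  }
  memb <- groups$members[groups$members$group_id %in% triads$group_id, ]
  stop_if(nrow(triads) == 0, "no triad groups supplied")
  mean_f <- rowMeans(expr$fpkm[memb$gene_id, samples, drop = FALSE])
  e <- matrix(NA_real_, nrow(triads), 3,
              dimnames = list(triads$group_id, SUBGENOMES))
  e[cbind(match(memb$group_id, triads$group_id),
          match(memb$subgenome, SUBGENOMES))] <- mean_f
  total <- rowSums(e)
  fr <- e / total
  unexpressed <- total < floor
  fr[unexpressed, ] <- NA_real_
  data.frame(group_id = triads$group_id,
             eA = e[, 1], eC = e[, 2], eD = e[, 3],
             fA = fr[, 1], fC = fr[, 2], fD = fr[, 3],
             total = total, unexpressed = unexpressed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict a fractions/bias call to specific triads
#' @noRd
check_triads_only <- function(groups, group_ids) {
  cat_ <- groups$groups$category[match(group_ids, groups$groups$group_id)]
  bad <- group_ids[is.na(cat_) | cat_ != "triad"]
  stop_if(length(bad) > 0, "non-triad group id(s): ",
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Ternary bias label from subgenome fractions
#'
#' A triad is `balanced` when the Euclidean distance from `(fA, fC, fD)`
#' to the centroid `(1/3, 1/3, 1/3)` is at most `balanced_radius`;
#' otherwise it is labeled by the subgenome with the largest fraction
#' (ties broken in the fixed order A < C < D, with a message). Rows with
#' NA fractions (unexpressed triads) get label `unexpressed`.
#'
#' @param fractions data.frame with columns fA, fC, fD (e.g. from
#'   [ternary_fractions()]) or a numeric vector of length 3.
#' @param balanced_radius radius of the central balanced region in
#'   fraction space (max possible distance is sqrt(2/3)).
#' @return the input data.frame with `distance_to_balanced` and `label`
#'   appended (or, for a vector input, a one-row data.frame).
#' @export
classify_bias <- function(fractions, balanced_radius = 0.2) {
  if (is.numeric(fractions) && is.null(dim(fractions))) {
    stop_if(length(fractions) != 3, "need exactly three fractions")
    fractions <- data.frame(fA = fractions[1], fC = fractions[2],
                            fD = fractions[3])
  }
  f <- as.matrix(fractions[, c("fA", "fC", "fD")])
  ok <- !apply(f, 1, anyNA)
  stop_if(any(f[ok, ] < 0), "negative fraction")
  stop_if(any(abs(rowSums(f[ok, , drop = FALSE]) - 1) > 1e-9),
          "fractions must sum to 1")
  d <- sqrt(rowSums((f - 1 / 3)^2))
  label <- rep("unexpressed", nrow(f))
  top <- apply(f, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1)
      message("fraction tie broken in favour of subgenome ",
              SUBGENOMES[w[1]])
    w[1]
  })
  dominant <- paste0(SUBGENOMES, "-dominant")[top]
  label[ok] <- ifelse(d[ok] <= balanced_radius, "balanced", dominant[ok])
  out <- as.data.frame(fractions)
  out$distance_to_balanced <- d
  out$label <- label
  out
}

#' Dominance count tables across tissues
#'
#' Runs the ternary classification per tissue (salt samples only by
#' default) and tabulates labels: over all expressed triads, restricted
#' to triads with at least one DEG member, and restricted to TF triads
#' split by family.
#'
#' @param expr an [expr_set()].
#' @param groups result of [classify_groups()].
#' @param catalog gene catalog (for TF families).
#' @param deg_union gene ids of salt-responsive genes (optional).
#' @param balanced_radius,floor passed to the classifiers.
#' @param salt_only use salt-treated samples only (default TRUE).
#' @return list: `bias` (per-tissue classified fractions), `all`
#'   (tissue x label counts), `deg` (same, DEG triads), `tf` (family x
#'   label counts, pooled over tissues).
#' @export
dominance_summary <- function(expr, groups, catalog, deg_union = NULL,
                              balanced_radius = 0.2, floor = 0.5,
                              salt_only = TRUE) {
  tissues <- unique(expr$design$tissue)
  bias <- do.call(rbind, lapply(tissues, function(ti) {
    s <- select_samples(expr$design, tissue = ti, salt_only = salt_only)
    fr <- ternary_fractions(expr, groups, samples = s, floor = floor)
    cbind(tissue = ti, classify_bias(fr, balanced_radius))
  }))
  tab <- function(b) {
    b <- b[b$label != "unexpressed", ]
    as.data.frame(table(tissue = b$tissue, label = b$label),
                  stringsAsFactors = FALSE)
  }
  memb <- groups$members
  deg_triads <- if (is.null(deg_union)) character(0) else
    unique(memb$group_id[memb$gene_id %in% deg_union &
                           memb$category == "triad"])
  tf_map <- catalog[!is.na(catalog$tf_family), c("gene_id", "tf_family")]
  tf_memb <- merge(memb[memb$category == "triad", ], tf_map)
  tf_bias <- merge(bias[bias$label != "unexpressed", ],
                   unique(tf_memb[, c("group_id", "tf_family")]))
  tf_tab <- if (nrow(tf_bias) == 0) {
    data.frame(tf_family = character(0), label = character(0),
               Freq = integer(0))
  } else {
    as.data.frame(table(tf_family = tf_bias$tf_family,
                        label = tf_bias$label), stringsAsFactors = FALSE)
  }
  list(bias = bias,
       all = tab(bias),
       deg = tab(bias[bias$group_id %in% deg_triads, ]),
       tf = tf_tab)
}
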