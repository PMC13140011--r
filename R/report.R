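#' Pipeline configuration
#'
#' Bundles the simulation settings and every stage threshold with its
#' documented default.
#'
#' @param sim a [sim_config()] used when `simulate = TRUE` in
#'   [run_all()].
#' @param deg a [deg_thresholds()].
#' @param network_fpkm_min network input expression floor.
#' @param beta fixed soft-threshold power, or `NULL` to scan.
#' @param r2_target scale-free fit target.
#' @param min_module_size,merge_cut,cut_height_quantile module stage
#'   parameters.
#' @param balanced_radius,bias_floor ternary-bias parameters.
#' @param maf_min,miss_max,n_pcs,gwas_threshold association parameters.
#' @param candidate_window_bp window around significant markers for
#'   candidate genes.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            deg = deg_thresholds(),
                            network_fpkm_min = 0.2,
                            beta = NULL, r2_target = 0.85,
                            min_module_size = 30, merge_cut = 0.25,
                            cut_height_quantile = 0.99,
                            balanced_radius = 0.2, bias_floor = 0.5,
                            maf_min = 0.05, miss_max = 0.1, n_pcs = 3,
                            gwas_threshold = 1e-4,
                            candidate_window_bp = 5e4,
                            seed = 1L) {
  stop_if(!is_prop(maf_min) || maf_min > 0.5, "maf_min outside [0, 0.5]")
  stop_if(!is_prop(miss_max), "miss_max outside [0, 1]")
  stop_if(merge_cut < 0 || merge_cut > 1, "merge_cut outside [0, 1]")
  stop_if(balanced_radius < 0 || balanced_radius > sqrt(2 / 3),
          "balanced_radius outside [0, sqrt(2/3)]")
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, deg = deg,
                 network_fpkm_min = network_fpkm_min, beta = beta,
                 r2_target = r2_target,
                 min_module_size = min_module_size,
                 merge_cut = merge_cut,
                 cut_height_quantile = cut_height_quantile,
                 balanced_radius = balanced_radius,
                 bias_floor = bias_floor, maf_min = maf_min,
                 miss_max = miss_max, n_pcs = n_pcs,
                 gwas_threshold = gwas_threshold,
                 candidate_window_bp = candidate_window_bp,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Candidate genes around significant markers
#'
#' Genes on the same chromosome within `window_bp` of any marker below
#' the significance threshold, with the triage flags applied in
#' sequence: expressed (FPKM above floor in >= 1 sample), DEG, homeolog
#' category, module membership and TF family, plus the combined
#' subgenome-divergent-SRTF flag.
#'
#' @param assoc result of [assoc_scan()].
#' @param catalog gene catalog with `chromosome` and `start`.
#' @param expr optional [expr_set()] (for the expressed flag).
#' @param deg_union,groups,module_labels optional annotation sources.
#' @param window_bp window each side of a significant marker.
#' @param expressed_floor FPKM floor for the expressed flag.
#' @return data.frame, one row per candidate gene; empty (with a
#'   warning) when no marker is significant.
#' @export
candidate_genes <- function(assoc, catalog, expr = NULL,
                            deg_union = NULL, groups = NULL,
                            module_labels = NULL, window_bp = 5e4,
                            expressed_floor = 0.5) {
  sig <- assoc[assoc$significant, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), chromosome = character(0),
                      start = integer(0), nearest_marker = character(0),
                      distance_bp = integer(0), expressed = logical(0),
                      is_deg = logical(0), category = character(0),
                      module = character(0), tf_family = character(0),
                      divergent_srtf = logical(0))
  if (nrow(sig) == 0) {
    warning("no markers below the significance threshold")
    return(empty)
  }
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    m <- sig[sig$chromosome == catalog$chromosome[i], , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    dist <- abs(m$position - catalog$start[i])
    if (min(dist) > window_bp) return(NULL)
    data.frame(gene_id = catalog$gene_id[i],
               chromosome = catalog$chromosome[i],
               start = catalog$start[i],
               nearest_marker = m$marker_id[which.min(dist)],
               distance_bp = min(dist), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no genes within the window of significant markers")
    return(empty)
  }
  out$expressed <- if (!is.null(expr)) {
    apply(expr$fpkm[out$gene_id, , drop = FALSE], 1,
          function(r) any(r > expressed_floor))
  } else NA
  out$is_deg <- if (!is.null(deg_union)) out$gene_id %in% deg_union
                else NA
  out$category <- if (!is.null(groups)) {
    groups$members$category[match(out$gene_id,
                                  groups$members$gene_id)]
  } else NA_character_
  out$module <- if (!is.null(module_labels))
    unname(module_labels[out$gene_id]) else NA_character_
  out$tf_family <- catalog$tf_family[match(out$gene_id,
                                           catalog$gene_id)]
  # subgenome-divergent SRTF: a responsive TF gene whose homeolog group
  # is not a complete triad
  deg_ok <- if (is.null(deg_union)) TRUE else
    !is.na(out$is_deg) & out$is_deg
  out$divergent_srtf <- !is.na(out$tf_family) & deg_ok &
    !is.na(out$category) & out$category != "triad"
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on simulated inputs
#'
#' Executes simulate, expression, homeolog, network, association and
#' reporting in order and writes every table to `out_dir` (when given).
#' Identical config + seed yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the TSV bundle.
#' @param simulate generate inputs with the bundled generator (the only
#'   mode currently wired; supplied-data runs use the stage functions
#'   directly).
#' @return a `summary_bundle` list with every stage output.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL,
                    simulate = TRUE) {
  stop_if(!simulate, "run_all currently drives the bundled simulator; ",
          "use the stage functions directly for external data")
  stage <- "simulate"
  bundle <- tryCatch({
    sim <- simulate_all(config$sim)

    stage <- "expression"
    degs <- call_degs_all(sim$expr, config$deg)
    counts <- deg_counts(degs)
    core <- core_degs(counts$tissue_unions)
    tf_summary <- tf_responsive_summary(sim$catalog, counts$grand_union,
                                        counts$tissue_unions)

    stage <- "homeolog"
    groups <- classify_groups(sim$homeologs, sim$catalog)
    dominance <- dominance_summary(sim$expr, groups, sim$catalog,
                                   deg_union = counts$grand_union,
                                   balanced_radius =
                                     config$balanced_radius,
                                   floor = config$bias_floor)

    stage <- "network"
    net_x <- network_input(sim$expr, counts$grand_union,
                           config$network_fpkm_min)
    modules <- build_network(net_x, beta = config$beta,
                             r2_target = config$r2_target,
                             min_size = config$min_module_size,
                             cut_height_quantile =
                               config$cut_height_quantile,
                             merge_cut = config$merge_cut)
    enrichment <- module_tissue_enrichment(modules,
                                           counts$tissue_unions)

    stage <- "association"
    qc <- qc_markers(sim$panel, config$maf_min, config$miss_max)
    pcs <- pca_covariates(qc$panel, config$n_pcs)
    assoc <- assoc_scan(qc$panel, sim$phenotype, pcs,
                        config$gwas_threshold)
    top <- assoc$marker_id[which.min(assoc$p)]
    focal <- if (sim$truth$causal_marker %in%
                   qc$panel$markers$marker_id)
      sim$truth$causal_marker else top
    hap <- haplotype_compare(qc$panel, focal, sim$phenotype)
    ld <- ld_r2(qc$panel,
                qc$panel$markers$marker_id[
                  order(abs(qc$panel$markers$position -
                              assoc$position[match(top,
                                                   assoc$marker_id)]))[
                                                     seq_len(min(25,
                                                       ncol(qc$panel$geno)))]])

    stage <- "report"
    candidates <- candidate_genes(assoc, sim$catalog, sim$expr,
                                  counts$grand_union, groups,
                                  modules$labels,
                                  config$candidate_window_bp)
    module_census <- as.data.frame(
      sort(table(module = modules$labels), decreasing = TRUE),
      stringsAsFactors = FALSE)
    names(module_census) <- c("module", "n_genes")

    structure(
      list(config = config, sim = sim, degs = degs,
           deg_counts = counts, core = core, tf_summary = tf_summary,
           groups = groups, dominance = dominance, modules = modules,
           enrichment = enrichment, qc_report = qc$report,
           assoc = assoc, haplotype = hap, ld = ld,
           candidates = candidates, module_census = module_census),
      class = "summary_bundle")
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.null(out_dir)) write_summary_bundle(bundle, out_dir)
  bundle
}

#' Write the summary bundle as TSV tables
#'
#' @param bundle a `summary_bundle` from [run_all()].
#' @param out_dir output directory (created if absent).
#' @return invisible vector of files written.
#' @export
write_summary_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tabs <- list(
    deg_records.tsv = bundle$degs,
    deg_counts_per_contrast.tsv = bundle$deg_counts$per_contrast,
    deg_counts_per_tissue.tsv = bundle$deg_counts$per_tissue,
    core_regions.tsv = bundle$core$regions,
    tf_summary.tsv = bundle$tf_summary,
    homeolog_groups.tsv = bundle$groups$groups,
    homeolog_category_counts.tsv = bundle$groups$category_counts,
    triad_bias.tsv = bundle$dominance$bias,
    dominance_all.tsv = bundle$dominance$all,
    dominance_deg.tsv = bundle$dominance$deg,
    dominance_tf.tsv = bundle$dominance$tf,
    module_assignment.tsv = data.frame(
      gene_id = names(bundle$modules$labels),
      module = unname(bundle$modules$labels),
      stringsAsFactors = FALSE),
    module_census.tsv = bundle$module_census,
    module_eigengenes.tsv = data.frame(
      module = rownames(bundle$modules$eigengenes),
      bundle$modules$eigengenes, check.names = FALSE),
    module_enrichment.tsv = bundle$enrichment,
    qc_report.tsv = bundle$qc_report,
    association.tsv = bundle$assoc,
    candidates.tsv = bundle$candidates)
  for (f in names(tabs)) write_tsv(tabs[[f]], p(f))
  scan <- bundle$modules$scan
  if (!is.null(scan)) write_tsv(scan$scan, p("soft_threshold_scan.tsv"))
  invisible(names(tabs))
}

#' Cross-table consistency checks on a summary bundle
#'
#' Recounts every summary table from the underlying per-gene tables and
#' reports violations: per-contrast and per-tissue DEG counts, UpSet
#' region partition, homeolog category sums, the 3 x triads = triad
#' genes identity, and the bias-label partition of expressed triads.
#'
#' @param bundle a `summary_bundle`.
#' @return list: `pass` (logical), `violations` (character).
#' @export
reconcile <- function(bundle) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)

  hits <- bundle$degs[bundle$degs$is_deg, ]
  pc <- stats::aggregate(is_deg ~ tissue + timepoint, bundle$degs, sum)
  m <- merge(pc, bundle$deg_counts$per_contrast,
             by = c("tissue", "timepoint"))
  if (any(m$is_deg != m$n_deg))
    note("deg_counts_per_contrast: counts do not match DEG records")
  for (ti in bundle$deg_counts$per_tissue$tissue) {
    n <- length(unique(hits$gene_id[hits$tissue == ti]))
    if (n != bundle$deg_counts$per_tissue$n_union[
      bundle$deg_counts$per_tissue$tissue == ti])
      note(paste0("deg_counts_per_tissue: union mismatch for ", ti))
  }
  if (sum(bundle$core$regions$n) !=
        length(bundle$core$grand_union))
    note("core_regions: regions do not partition the grand union")

  g <- bundle$groups
  if (sum(g$category_counts$n_groups) != nrow(g$groups))
    note("homeolog_category_counts: group counts do not sum")
  tri <- g$groups[g$groups$category == "triad", ]
  if (sum(tri$n_genes) != 3 * nrow(tri))
    note("triad identity violated: genes != 3 x groups")
  bad_cat <- setdiff(g$groups$category,
                     c("triad", "dyad_AC", "dyad_AD", "dyad_CD",
                       "singleton_A", "singleton_C", "singleton_D",
                       "other"))
  if (length(bad_cat) > 0)
    note(paste0("unknown homeolog category: ",
                paste(bad_cat, collapse = ", ")))

  b <- bundle$dominance$bias
  ok_lab <- c("A-dominant", "C-dominant", "D-dominant", "balanced",
              "unexpressed")
  if (!all(b$label %in% ok_lab))
    note("triad_bias: label outside the closed vocabulary")
  expr_b <- b[b$label != "unexpressed", ]
  tab <- as.data.frame(table(tissue = expr_b$tissue,
                             label = expr_b$label),
                       stringsAsFactors = FALSE)
  m2 <- merge(tab, bundle$dominance$all, by = c("tissue", "label"),
              all = TRUE)
  m2[is.na(m2)] <- 0
  if (any(m2$Freq.x != m2$Freq.y))
    note("dominance_all: counts do not match bias records")

  census <- table(bundle$modules$labels)
  for (i in seq_len(nrow(bundle$module_census))) {
    mod <- bundle$module_census$module[i]
    if (census[mod] != bundle$module_census$n_genes[i])
      note(paste0("module_census: size mismatch for ", mod))
  }
  list(pass = length(v) == 0, violations = v)
}
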