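#' Simulation configuration
#'
#' Defines the synthetic study: an allohexaploid gene catalog with
#' triad/dyad/singleton homeolog structure, a negative-binomial expression
#' experiment over 3 tissues x 5 timepoints x 3 replicates, planted
#' subgenome-dominance fractions and co-expression modules, and a
#' genotyped germination-rate panel with one causal promoter InDel.
#'
#' @param n_triads number of 1:1:1 homeolog groups.
#' @param n_dyads_per_pattern dyad groups per pattern (AC, AD, CD).
#' @param n_singletons_per_subgenome single-copy groups per subgenome.
#' @param tissues,timepoints_h,replicates the sample design; timepoints
#'   must include 0 h (the unstressed control).
#' @param nb_dispersion shared negative-binomial dispersion (1/size);
#'   values below 1e-6 switch to the deterministic zero-noise mode in
#'   which counts equal rounded means.
#' @param baseline_log_mean natural-log baseline of the per-gene mean count.
#' @param de_fraction fraction of genes that are salt-responsive.
#' @param de_log2fc_magnitude |log2 fold change| planted on DE genes at
#'   salt timepoints (sign random per gene).
#' @param dominance_mix proportions of triads planted as A-dominant,
#'   C-dominant, D-dominant and balanced (must sum to 1).
#' @param dominance_strength expression fraction given to the dominant
#'   homeolog of a dominant triad (the other two split the remainder).
#' @param n_modules,module_size_range,module_snr planted co-expression
#'   modules: count, size range, and amplitude (log-scale SD units) of the
#'   shared latent profile.
#' @param tf_fraction fraction of genes carrying a TF-family label.
#' @param n_accessions,n_markers association panel dimensions.
#' @param causal_effect germination-rate change (percentage points) per
#'   copy of the insertion (Hap1) allele.
#' @param pheno_intercept,pheno_sd phenotype baseline and residual SD.
#' @param maf_range range the per-marker minor-allele frequency is drawn
#'   from; must lie in (0, 0.5].
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed fixing all outputs bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_triads = 200,
                       n_dyads_per_pattern = 20,
                       n_singletons_per_subgenome = 20,
                       tissues = c("Seed", "Leaf", "Root"),
                       timepoints_h = c(0, 6, 12, 24, 48),
                       replicates = 3,
                       nb_dispersion = 0.15,
                       baseline_log_mean = 4,
                       de_fraction = 0.3,
                       de_log2fc_magnitude = 2,
                       dominance_mix = c(A = 0.2, C = 0.35, D = 0.25,
                                         balanced = 0.2),
                       dominance_strength = 0.7,
                       n_modules = 5,
                       module_size_range = c(30, 80),
                       module_snr = 1,
                       tf_fraction = 0.08,
                       n_accessions = 225,
                       n_markers = 500,
                       causal_effect = 12,
                       pheno_intercept = 55,
                       pheno_sd = 6,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_triads = n_triads,
              n_dyads_per_pattern = n_dyads_per_pattern,
              n_singletons_per_subgenome = n_singletons_per_subgenome,
              tissues = tissues, timepoints_h = timepoints_h,
              replicates = replicates, nb_dispersion = nb_dispersion,
              baseline_log_mean = baseline_log_mean,
              de_fraction = de_fraction,
              de_log2fc_magnitude = de_log2fc_magnitude,
              dominance_mix = dominance_mix,
              dominance_strength = dominance_strength,
              n_modules = n_modules,
              module_size_range = module_size_range,
              module_snr = module_snr, tf_fraction = tf_fraction,
              n_accessions = n_accessions, n_markers = n_markers,
              causal_effect = causal_effect,
              pheno_intercept = pheno_intercept, pheno_sd = pheno_sd,
              maf_range = maf_range, missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_triads", "n_dyads_per_pattern",
              "n_singletons_per_subgenome", "replicates", "n_modules",
              "n_accessions", "n_markers"))
    stop_if(!is_count(cfg[[f]]), f, " must be a non-negative integer")
  stop_if(!0 %in% cfg$timepoints_h,
          "timepoints_h must include 0 (the control)")
  stop_if(!is_prop(cfg$de_fraction), "de_fraction must be in [0,1]")
  stop_if(!is_prop(cfg$tf_fraction), "tf_fraction must be in [0,1]")
  stop_if(!is_prop(cfg$missing_rate), "missing_rate must be in [0,1]")
  stop_if(length(cfg$dominance_mix) != 4 ||
            any(cfg$dominance_mix < 0) ||
            abs(sum(cfg$dominance_mix) - 1) > 1e-8,
          "dominance_mix must be 4 non-negative proportions summing to 1")
  stop_if(cfg$nb_dispersion <= 0, "nb_dispersion must be positive")
  stop_if(cfg$de_log2fc_magnitude <= 0,
          "de_log2fc_magnitude must be positive")
  stop_if(cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
            cfg$maf_range[1] > cfg$maf_range[2],
          "maf_range must lie within (0, 0.5]")
  invisible(cfg)
}

new_gene_id <- function(chrom, idx) sprintf("OT%s%05d", chrom, idx)

#' Simulate the gene catalog and homeolog map
#'
#' Genes are laid out on 7 chromosomes per subgenome with uniform start
#' coordinates and exonic lengths in \[300, 10000\] bp. Triads carry one
#' copy per subgenome; dyads one copy in each of two subgenomes;
#' singletons a single copy. A `tf_fraction` of genes receives a family
#' label from the ten salt-responsive TF families.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (gene_id, subgenome, chromosome, start,
#'   length_bp, tf_family) and `homeologs` (group_id, gene_id).
#' @export
simulate_catalog <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nt <- config$n_triads
  nd <- config$n_dyads_per_pattern
  ns <- config$n_singletons_per_subgenome
  sub <- c(rep(c("A", "C", "D"), nt),
           rep(c("A", "C"), nd), rep(c("A", "D"), nd),
           rep(c("C", "D"), nd),
           rep("A", ns), rep("C", ns), rep("D", ns))
  sizes <- c(rep(3L, nt), rep(2L, 3L * nd), rep(1L, 3L * ns))
  group <- rep(seq_along(sizes), times = sizes)
  stop_if(length(sub) == 0, "configuration requests zero genes")
  n <- length(sub)
  chrom_num <- sample(1:7, n, replace = TRUE)
  chromosome <- paste0(chrom_num, sub)
  catalog <- data.frame(
    gene_id = new_gene_id(chromosome, seq_len(n)),
    subgenome = sub,
    chromosome = chromosome,
    start = sample.int(7e8, n, replace = TRUE),
    length_bp = round(stats::runif(n, 300, 10000)),
    tf_family = NA_character_,
    stringsAsFactors = FALSE)
  n_tf <- round(config$tf_fraction * n)
  if (n_tf > 0) {
    idx <- sample.int(n, n_tf)
    catalog$tf_family[idx] <- sample(TF_FAMILIES, n_tf, replace = TRUE)
  }
  homeologs <- data.frame(group_id = sprintf("HG%05d", group),
                          gene_id = catalog$gene_id,
                          stringsAsFactors = FALSE)
  list(catalog = catalog, homeologs = homeologs)
}

sim_design <- function(config) {
  d <- expand.grid(replicate = seq_len(config$replicates),
                   timepoint = config$timepoints_h,
                   tissue = config$tissues,
                   stringsAsFactors = FALSE)
  d <- d[, c("tissue", "timepoint", "replicate")]
  d$sample_id <- sprintf("%s_T%02d_R%d", d$tissue, d$timepoint, d$replicate)
  d[, c("sample_id", "tissue", "timepoint", "replicate")]
}

#' Simulate the expression experiment
#'
#' Counts are negative-binomial with mean
#' `mu = baseline x length factor x subgenome-fraction factor x DE factor
#' x module factor`: DE genes have their salt timepoints multiplied by
#' `2^(+/- de_log2fc_magnitude)`, triad copies are multiplied by three
#' times their planted subgenome fraction, and module member genes share a
#' latent per-sample log-scale profile scaled by `module_snr`. Dispersion
#' below 1e-6 yields the deterministic mode (counts = round(mu)).
#'
#' @param catalog,homeologs as returned by [simulate_catalog()].
#' @param config a [sim_config()].
#' @return list with `expr` (an [expr_set()]) and `truth` (ground-truth
#'   tables: `genes`, `contrasts`, `triads`).
#' @export
simulate_expression <- function(catalog, homeologs, config) {
  validate_sim_config(config)
  stop_if(nrow(catalog) == 0, "catalog is empty")
  stop_if(config$nb_dispersion <= 0, "nb_dispersion must be positive")
  set.seed(config$seed + 1L)
  design <- sim_design(config)
  n_g <- nrow(catalog)
  n_s <- nrow(design)

  # baseline on the natural-log scale; the lognormal gene effect is
  # shared within a homeolog group so planted fractions are the only
  # systematic within-triad imbalance
  grp <- homeologs$group_id[match(catalog$gene_id, homeologs$gene_id)]
  grp_ids <- unique(grp)
  grp_eff <- stats::setNames(stats::rnorm(length(grp_ids), 0, 0.5),
                             grp_ids)
  gene_eff <- unname(grp_eff[grp])
  gene_eff[is.na(gene_eff)] <- 0
  log_mu <- matrix(config$baseline_log_mean + gene_eff +
                     log(catalog$length_bp / 2000),
                   n_g, n_s)
  rownames(log_mu) <- catalog$gene_id
  colnames(log_mu) <- design$sample_id

  # planted differential expression at salt timepoints
  is_de <- stats::runif(n_g) < config$de_fraction
  lfc <- ifelse(is_de,
                sample(c(-1, 1), n_g, replace = TRUE) *
                  config$de_log2fc_magnitude,
                0)
  salt <- design$timepoint > 0
  log_mu[, salt] <- log_mu[, salt] + lfc * log(2)

  # planted triad dominance: copy mean x 3 x fraction
  grp_sub <- stats::aggregate(
    subgenome ~ group_id,
    merge(homeologs, catalog[, c("gene_id", "subgenome")]),
    function(x) paste(sort(x), collapse = ""))
  triad_ids <- grp_sub$group_id[grp_sub$subgenome == "ACD"]
  labels <- c("A", "C", "D", "balanced")
  triad_truth <- NULL
  if (length(triad_ids) > 0) {
    lab <- sample(labels, length(triad_ids), replace = TRUE,
                  prob = config$dominance_mix)
    fr <- matrix(1 / 3, length(triad_ids), 3,
                 dimnames = list(triad_ids, SUBGENOMES))
    s <- config$dominance_strength
    for (k in 1:3) {
      sel <- lab == SUBGENOMES[k]
      fr[sel, ] <- (1 - s) / 2
      fr[sel, k] <- s
    }
    triad_truth <- data.frame(group_id = triad_ids, label = lab,
                              fA = fr[, 1], fC = fr[, 2], fD = fr[, 3],
                              row.names = NULL, stringsAsFactors = FALSE)
    memb <- merge(homeologs[homeologs$group_id %in% triad_ids, ],
                  catalog[, c("gene_id", "subgenome")])
    fac <- 3 * fr[cbind(match(memb$group_id, triad_ids),
                        match(memb$subgenome, SUBGENOMES))]
    log_mu[memb$gene_id, ] <- log_mu[memb$gene_id, ] + log(fac)
  }

  # planted co-expression modules: shared latent per-sample profile
  module <- rep("none", n_g)
  if (config$n_modules > 0) {
    sizes <- round(stats::runif(config$n_modules,
                                config$module_size_range[1],
                                config$module_size_range[2]))
    sizes <- pmin(sizes, n_g)
    avail <- sample.int(n_g)
    pos <- 0
    for (m in seq_len(config$n_modules)) {
      if (pos + sizes[m] > n_g) break
      idx <- avail[(pos + 1):(pos + sizes[m])]
      pos <- pos + sizes[m]
      module[idx] <- sprintf("sim%02d", m)
      profile <- stats::rnorm(n_s)
      log_mu[idx, ] <- log_mu[idx, ] +
        config$module_snr * matrix(profile, length(idx), n_s, byrow = TRUE)
    }
  }

  mu <- exp(log_mu)
  if (config$nb_dispersion < 1e-6) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     n_g, n_s)
  }
  dimnames(counts) <- dimnames(mu)
  storage.mode(counts) <- "integer"
  lengths <- stats::setNames(catalog$length_bp, catalog$gene_id)

  contrasts <- expand.grid(tissue = config$tissues,
                           timepoint = setdiff(config$timepoints_h, 0),
                           stringsAsFactors = FALSE)
  truth_contrasts <- do.call(rbind, lapply(seq_len(nrow(contrasts)),
    function(i) data.frame(gene_id = catalog$gene_id,
                           tissue = contrasts$tissue[i],
                           timepoint = contrasts$timepoint[i],
                           true_log2fc = lfc,
                           stringsAsFactors = FALSE)))

  list(expr = expr_set(counts, design, lengths),
       truth = list(genes = data.frame(gene_id = catalog$gene_id,
                                       is_de = is_de, true_log2fc = lfc,
                                       module = module,
                                       stringsAsFactors = FALSE),
                    contrasts = truth_contrasts,
                    triads = triad_truth))
}

#' Simulate the genotyped association panel
#'
#' Biallelic markers in Hardy-Weinberg proportions on chromosome 4D, one
#' designated causal 3-bp promoter InDel (REF `TCACTC` = insertion/Hap1
#' allele, ALT `TCC` = deletion/Hap2 allele) placed 1,419 bp upstream of
#' a planted causal D-subgenome gene. Germination rate = intercept +
#' `causal_effect` x (copies of the Hap1 allele) + Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param catalog optional gene catalog used to anchor the causal marker
#'   next to a real catalog gene on chromosome 4D.
#' @return list with `panel` (a `genotype_panel`), `phenotype`
#'   (accession_id, germination_rate) and `truth` (causal marker/gene ids
#'   and effect).
#' @export
simulate_population <- function(config, catalog = NULL) {
  validate_sim_config(config)
  stop_if(config$n_markers < 1, "n_markers must be >= 1")
  set.seed(config$seed + 2L)
  n <- config$n_accessions
  m <- config$n_markers
  accessions <- sprintf("ACC%03d", seq_len(n))

  causal_gene <- NA_character_
  causal_gene_start <- 4.5e8
  if (!is.null(catalog)) {
    cand <- catalog[catalog$chromosome == "4D", ]
    if (nrow(cand) > 0) {
      wrky <- cand[!is.na(cand$tf_family) & cand$tf_family == "WRKY", ]
      pick <- if (nrow(wrky) > 0) wrky[1, ] else cand[1, ]
      causal_gene <- pick$gene_id
      causal_gene_start <- pick$start
    }
  }
  causal_pos <- max(2.5e6 + 1, round(causal_gene_start - 1419))
  span <- 5e6
  offs <- sample.int(span + 1, min(m - 1 + 50, span)) - 1 - span / 2
  pos <- sort(unique(c(causal_pos, causal_pos + offs)))
  pos <- pos[pos > 0]
  stop_if(length(pos) < m, "marker span too small for n_markers")
  keep <- sort(c(which(pos == causal_pos),
                 setdiff(seq_along(pos), which(pos == causal_pos))[
                   seq_len(m - 1)]))
  pos <- pos[keep]
  causal_idx <- which(pos == causal_pos)

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  maf[causal_idx] <- stats::runif(1, 0.25, 0.35)
  geno <- matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m)

  marker_id <- sprintf("SNP_%06d", pos)
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  type <- rep("SNP", m)
  marker_id[causal_idx] <- sprintf("InDel_%d", pos[causal_idx])
  ref[causal_idx] <- "TCACTC"
  alt[causal_idx] <- "TCC"
  type[causal_idx] <- "InDel"

  # phenotype from the causal genotype before masking
  hap1_copies <- 2 - geno[, causal_idx]
  phenotype <- data.frame(
    accession_id = accessions,
    germination_rate = config$pheno_intercept +
      config$causal_effect * hap1_copies +
      stats::rnorm(n, 0, config$pheno_sd),
    stringsAsFactors = FALSE)

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    geno[miss] <- NA_integer_
  }
  dimnames(geno) <- list(accessions, marker_id)

  markers <- data.frame(marker_id = marker_id, chromosome = "4D",
                        position = pos, ref = ref, alt = alt, type = type,
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, markers)
  list(panel = panel, phenotype = phenotype,
       truth = list(causal_marker = marker_id[causal_idx],
                    causal_gene = causal_gene,
                    causal_effect = config$causal_effect))
}

#' Run the full generator
#'
#' @param config a [sim_config()].
#' @return list with `catalog`, `homeologs`, `expr`, `panel`,
#'   `phenotype`, and `truth` (expression + population ground truth).
#' @export
simulate_all <- function(config = sim_config()) {
  cat_hm <- simulate_catalog(config)
  ex <- simulate_expression(cat_hm$catalog, cat_hm$homeologs, config)
  pop <- simulate_population(config, cat_hm$catalog)
  list(catalog = cat_hm$catalog, homeologs = cat_hm$homeologs,
       expr = ex$expr, panel = pop$panel, phenotype = pop$phenotype,
       truth = c(ex$truth, pop["truth"][[1]]))
}
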