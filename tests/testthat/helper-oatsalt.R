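# Shared fixtures and independent oracles, built in code.

# Small simulation configs keep the default suite fast.
tiny_config <- function(...) {
  sim_config(n_triads = 30, n_dyads_per_pattern = 3,
             n_singletons_per_subgenome = 3, n_modules = 2,
             module_size_range = c(8, 12), n_accessions = 60,
             n_markers = 40, ...)
}

# Expression set with exactly controlled FPKM values: all genes 1000 bp,
# a filler gene pads every library to `libsize`, so FPKM of the real
# genes equals counts / (libsize / 1e6).
make_fpkm_expr <- function(fpkm, design, libsize = 1e8) {
  counts <- round(fpkm * libsize / 1e6)
  filler <- libsize - colSums(counts)
  stopifnot(all(filler >= 0))
  counts <- rbind(counts, filler = filler)
  rownames(counts) <- c(rownames(fpkm), "filler")
  colnames(counts) <- design$sample_id
  lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  expr_set(counts, design, lengths)
}

two_cell_design <- function(n_rep = 1, tissue = "Root") {
  data.frame(
    sample_id = c(sprintf("%s_T00_R%d", tissue, seq_len(n_rep)),
                  sprintf("%s_T24_R%d", tissue, seq_len(n_rep))),
    tissue = tissue,
    timepoint = rep(c(0, 24), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
}

# Triple-loop TOM oracle, independent of the matrix-algebra path.
tom_oracle <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

random_adjacency <- function(n) {
  r <- matrix(stats::runif(n * n), n, n)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  a
}

# Hypergeometric over-representation by explicit subset enumeration.
hyper_enum_oracle <- function(n_bg, n_set, n_module, overlap) {
  sets <- utils::combn(n_bg, n_module)
  hits <- apply(sets, 2, function(s) sum(s <= n_set) >= overlap)
  mean(hits)
}

# Pooled-variance two-sample t closed form.
pooled_t_oracle <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  sp2 <- ((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
    (n1 + n2 - 2)
  t_ <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_, p = 2 * stats::pt(abs(t_), n1 + n2 - 2,
                                 lower.tail = FALSE))
}

# Hand-built genotype panel; dimnames are always standardized.
make_panel <- function(geno, positions = NULL, ref = NULL, alt = NULL,
                       type = NULL) {
  m <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(type)) type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                                    "SNP", "InDel")
  rownames(geno) <- sprintf("ACC%03d", seq_len(nrow(geno)))
  colnames(geno) <- sprintf("M%03d", seq_len(m))
  genotype_panel(geno,
                 data.frame(marker_id = colnames(geno),
                            chromosome = "4D", position = positions,
                            ref = ref, alt = alt, type = type,
                            stringsAsFactors = FALSE))
}

# Block-structured expression for network tests. Within a block the
# gene-to-profile correlation decays geometrically from w[1] (hubs) to
# w[2] (periphery); optional uncorrelated background genes give the
# network the low-connectivity tail a scale-free fit needs.
make_block_expr <- function(n_blocks, block_size, n_samples,
                            w = c(0.95, 0.4), background = 0,
                            seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    profile <- as.vector(scale(stats::rnorm(n_samples)))
    wi <- w[1] * (w[2] / w[1])^(seq(0, 1, length.out = block_size))
    t(sapply(wi, function(v)
      v * profile + sqrt(1 - v^2) * stats::rnorm(n_samples)))
  }))
  if (background > 0)
    x <- rbind(x, matrix(stats::rnorm(background * n_samples),
                         background, n_samples))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  attr(x, "block") <- c(rep(seq_len(n_blocks), each = block_size),
                        rep(0L, background))
  x
}
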