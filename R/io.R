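write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

dosage_to_gt <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1]
  gt[is.na(d)] <- "./."
  gt
}

#' Write a genotype panel as a minimal VCF v4.2
#'
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT=GT columns only.
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=oatsalt",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", panel$accessions), collapse = "\t")),
    con)
  m <- panel$markers
  gt <- apply(panel$geno, 2, dosage_to_gt)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(m$chromosome[i], m$position[i], m$marker_id[i], m$ref[i],
            m$alt[i], ".", "PASS", paste0("TYPE=", m$type[i]), "GT",
            gt[, i]), collapse = "\t"), "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a minimal GT-only VCF into a genotype panel
#'
#' @param path VCF path (parsed with vcfR).
#' @return a [genotype_panel()].
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, ncol(gt), nrow(gt),
                   dimnames = list(colnames(gt), fix$ID))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  for (i in seq_len(nrow(gt)))
    dosage[, i] <- unname(map[gt[i, ]])
  info <- v@fix[, "INFO"]
  type <- ifelse(grepl("^TYPE=", info), sub("^TYPE=", "", info),
                 ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1,
                        "SNP", "InDel"))
  markers <- data.frame(marker_id = fix$ID, chromosome = fix$CHROM,
                        position = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, type = type,
                        stringsAsFactors = FALSE)
  genotype_panel(dosage, markers)
}

#' Write all simulated objects as a plain-text fixture bundle
#'
#' Writes catalog/homeolog/design/counts/phenotype TSVs, a minimal VCF
#' and the ground-truth tables; refuses to clobber existing files unless
#' `overwrite = TRUE`.
#'
#' @param sim result of [simulate_all()].
#' @param directory output directory (created if absent).
#' @param overwrite allow replacing existing files.
#' @return manifest data.frame (file, rows), also written as
#'   `manifest.tsv`.
#' @export
write_fixture_bundle <- function(sim, directory, overwrite = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- c("catalog.tsv", "homeologs.tsv", "design.tsv", "counts.tsv",
             "phenotype.tsv", "genotypes.vcf", "truth_genes.tsv",
             "truth_triads.tsv", "truth_population.tsv", "manifest.tsv")
  existing <- files[file.exists(file.path(directory, files))]
  stop_if(length(existing) > 0 && !overwrite,
          "refusing to overwrite: ", paste(existing, collapse = ", "))
  p <- function(f) file.path(directory, f)
  counts_df <- data.frame(gene_id = rownames(sim$expr$counts),
                          sim$expr$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  truth_pop <- data.frame(causal_marker = sim$truth$causal_marker,
                          causal_gene = sim$truth$causal_gene,
                          causal_effect = sim$truth$causal_effect,
                          stringsAsFactors = FALSE)
  write_tsv(sim$catalog, p("catalog.tsv"))
  write_tsv(sim$homeologs, p("homeologs.tsv"))
  write_tsv(sim$expr$design, p("design.tsv"))
  write_tsv(counts_df, p("counts.tsv"))
  write_tsv(sim$phenotype, p("phenotype.tsv"))
  write_vcf(sim$panel, p("genotypes.vcf"))
  write_tsv(sim$truth$genes, p("truth_genes.tsv"))
  if (!is.null(sim$truth$triads))
    write_tsv(sim$truth$triads, p("truth_triads.tsv"))
  write_tsv(truth_pop, p("truth_population.tsv"))
  made <- files[file.exists(file.path(directory, files))]
  made <- setdiff(made, "manifest.tsv")
  manifest <- data.frame(
    file = made,
    rows = vapply(made, function(f) {
      if (grepl("\\.vcf$", f))
        sum(!startsWith(readLines(p(f)), "#"))
      else length(readLines(p(f))) - 1L
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(manifest, p("manifest.tsv"))
  manifest
}

#' Re-read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param directory bundle directory.
#' @return list with `catalog`, `homeologs`, `expr`, `panel`,
#'   `phenotype` (ground-truth tables under `truth`).
#' @export
read_fixture_bundle <- function(directory) {
  p <- function(f) file.path(directory, f)
  catalog <- read_tsv(p("catalog.tsv"))
  homeologs <- read_tsv(p("homeologs.tsv"))
  design <- read_tsv(p("design.tsv"))
  counts_df <- read_tsv(p("counts.tsv"))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  lengths <- stats::setNames(catalog$length_bp, catalog$gene_id)
  truth <- list(genes = read_tsv(p("truth_genes.tsv")),
                population = read_tsv(p("truth_population.tsv")))
  if (file.exists(p("truth_triads.tsv")))
    truth$triads <- read_tsv(p("truth_triads.tsv"))
  list(catalog = catalog, homeologs = homeologs,
       expr = expr_set(counts, design, lengths),
       panel = read_vcf_panel(p("genotypes.vcf")),
       phenotype = read_tsv(p("phenotype.tsv")),
       truth = truth)
}
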