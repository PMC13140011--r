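test_that("FPKM follows its definition and conserves library mass", {
  counts <- matrix(c(10, 0), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  counts["g2", 1] <- 1e6 - 10  # pad the library to exactly 1e6
  f <- compute_fpkm(counts, c(g1 = 1000, g2 = 1000))
  expect_equal(f["g1", 1], 10)
  expect_equal(compute_fpkm(matrix(c(0, 5), 2, 1,
                                   dimnames = list(c("a", "b"), "s")),
                            c(a = 500, b = 2000))["a", 1], 0)

  set.seed(1)
  cm <- matrix(rpois(300, 40), 50, 6,
               dimnames = list(sprintf("g%02d", 1:50),
                               sprintf("s%d", 1:6)))
  len <- stats::setNames(round(runif(50, 300, 5000)), rownames(cm))
  fm <- compute_fpkm(cm, len)
  # inverting the definition recovers the counts to machine precision
  back <- fm * outer(len / 1000, colSums(cm) / 1e6)
  expect_equal(back, cm, tolerance = 1e-12)

  cm0 <- cm; cm0[, 2] <- 0
  expect_error(compute_fpkm(cm0, len), "s2")
  expect_error(compute_fpkm(cm, stats::setNames(rep(0, 50),
                                                rownames(cm))),
               "positive")
})

test_that("DEG calling applies the fold-change and FPKM filters", {
  design <- two_cell_design()
  fpkm <- rbind(boundary = c(1, 2),      # log2fc exactly 1 at eps = 0
                low = c(0.1, 0.4),       # fails the FPKM > 0.5 floor
                flat = c(8, 8),          # no change
                up = c(2, 50))
  colnames(fpkm) <- design$sample_id
  expr <- make_fpkm_expr(fpkm, design)
  th0 <- deg_thresholds(epsilon = 0)
  deg <- call_degs(expr, "Root", 24, th0)
  rec <- function(g) deg[deg$gene_id == g, ]
  expect_equal(rec("boundary")$log2fc, 1)
  expect_true(rec("boundary")$is_deg)  # boundary inclusive (>= 1)
  expect_false(rec("low")$is_deg)
  expect_equal(rec("low")$log2fc, 2)
  expect_false(rec("flat")$is_deg)
  expect_true(rec("up")$is_deg)

  # identical treated/control profiles: all fold changes zero
  fpkm_id <- matrix(c(3, 3, 7, 7), 2, 2, byrow = TRUE,
                    dimnames = list(c("g1", "g2"), NULL))
  expr_id <- make_fpkm_expr(fpkm_id, design)
  deg_id <- call_degs(expr_id, "Root", 24, th0)
  expect_true(all(deg_id$log2fc == 0))
  expect_false(any(deg_id$is_deg))

  expect_error(call_degs(expr, "Shoot", 24), "tissue")
  expect_error(call_degs(expr, "Root", 0), "salt timepoint")
})

test_that("DEG calling is invariant to column order and library scale", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_all(cfg)
  deg1 <- call_degs(sim$expr, "Root", 24)

  perm <- sample(ncol(sim$expr$counts))
  expr_p <- expr_set(sim$expr$counts[, perm],
                     sim$expr$design[perm, ], sim$expr$gene_lengths)
  deg2 <- call_degs(expr_p, "Root", 24)
  expect_equal(deg1, deg2)

  expr_s <- expr_set(sim$expr$counts * 3L, sim$expr$design,
                     sim$expr$gene_lengths)
  deg3 <- call_degs(expr_s, "Root", 24)
  expect_equal(deg1$is_deg, deg3$is_deg)
  expect_equal(deg1$log2fc, deg3$log2fc, tolerance = 1e-12)
})

test_that("per-tissue unions and UpSet regions partition correctly", {
  mk <- function(gene, tissue, tp, deg = TRUE)
    data.frame(gene_id = gene, tissue = tissue, timepoint = tp,
               log2fc = 2, mean_fpkm_treated = 4, mean_fpkm_control = 1,
               p = NA_real_, padj = NA_real_, is_deg = deg)
  # disjoint single-gene sets at 4 timepoints -> union of 4
  d1 <- do.call(rbind, Map(mk, sprintf("g%d", 1:4), "Root",
                           c(6, 12, 24, 48)))
  expect_equal(deg_counts(d1)$per_tissue$n_union, 4)
  # one gene DEG at all timepoints -> union of 1
  d2 <- do.call(rbind, Map(mk, "g1", "Root", c(6, 12, 24, 48)))
  expect_equal(deg_counts(d2)$per_tissue$n_union, 1)

  un <- list(Seed = c("a", "b"), Leaf = c("b", "c"), Root = "b")
  core <- core_degs(un)
  expect_equal(core$core, "b")
  reg <- stats::setNames(core$regions$n, core$regions$region)
  expect_equal(unname(reg["Seed"]), 1)        # a
  expect_equal(unname(reg["Leaf"]), 1)        # c
  expect_equal(unname(reg["Seed&Leaf&Root"]), 1)  # b
  expect_equal(sum(core$regions$n), length(core$grand_union))

  # identical unions: core = union, only the triple region populated
  un2 <- list(Seed = c("x", "y"), Leaf = c("x", "y"),
              Root = c("x", "y"))
  core2 <- core_degs(un2)
  expect_equal(core2$core, c("x", "y"))
  expect_equal(sum(core2$regions$n[core2$regions$region !=
                                     "Seed&Leaf&Root"]), 0)

  # random sets: exclusive regions always partition the grand union
  set.seed(7)
  for (i in 1:20) {
    pool <- sprintf("g%03d", 1:60)
    un3 <- list(Seed = sample(pool, 25), Leaf = sample(pool, 25),
                Root = sample(pool, 25))
    c3 <- core_degs(un3)
    expect_equal(sum(c3$regions$n), length(c3$grand_union))
  }
})

test_that("responsive fractions match direct division", {
  subset42 <- sprintf("tf%02d", 1:52)
  union42 <- c(subset42[1:42], "other1")
  expect_equal(round(100 * responsive_fraction(subset42, union42), 2),
               80.77)
  expect_equal(responsive_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(responsive_fraction(c("a", "b"), c("x")), 0)
  expect_error(responsive_fraction(character(0), "a"), "empty")
})

test_that("threshold-only calling recovers planted DE flags at zero noise", {
  cfg <- sim_config(n_triads = 60, n_dyads_per_pattern = 5,
                    n_singletons_per_subgenome = 5, n_modules = 0,
                    de_fraction = 0.25, nb_dispersion = 1e-8,
                    seed = 13)
  sim <- simulate_all(cfg)
  degs <- call_degs_all(sim$expr)
  union <- deg_counts(degs)$grand_union
  planted <- sim$truth$genes$gene_id[sim$truth$genes$is_de]
  expect_setequal(union, planted)
})

test_that("test-mode false-positive rate stays calibrated on null splits", {
  cfg <- sim_config(n_triads = 80, n_dyads_per_pattern = 0,
                    n_singletons_per_subgenome = 0, replicates = 6,
                    timepoints_h = c(0, 6), n_modules = 0,
                    de_fraction = 0, seed = 17)
  sim <- simulate_all(cfg)
  d <- sim$expr$design[sim$expr$design$timepoint == 0, ]
  d$timepoint <- ifelse(d$replicate <= 3, 0, 6)  # split-replicate null
  d$replicate <- (d$replicate - 1) %% 3 + 1
  expr0 <- expr_set(sim$expr$counts[, d$sample_id], d,
                    sim$expr$gene_lengths)
  degs <- call_degs_all(expr0, deg_thresholds(test = TRUE, fc_min = 0,
                                              fpkm_min = 0))
  expect_gte(nrow(degs), 200)
  expect_lte(mean(degs$is_deg), 0.07)
})
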