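test_that("signed adjacency matches its closed form", {
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  m <- rbind(g1 = x, g2 = x, g3 = -x, g4 = y)
  colnames(m) <- sprintf("s%d", 1:4)
  a <- signed_adjacency(m, 10)
  expect_equal(a["g1", "g2"], 1)            # cor +1
  expect_equal(a["g1", "g3"], 0)            # cor -1
  expect_equal(a["g1", "g4"], 0.5^10)       # cor 0
  expect_true(all(a >= 0 & a <= 1))
  expect_true(isSymmetric(a))

  m_const <- rbind(m, g5 = rep(2, 4))
  expect_error(signed_adjacency(m_const, 2), "g5")
})

test_that("TOM equals the triple-loop oracle", {
  ones <- matrix(1, 3, 3)
  expect_equal(tom_similarity(ones), ones)  # (1+1)/(2+1-1) = 1

  zero <- diag(3)
  t0 <- tom_similarity(zero)
  expect_equal(t0[upper.tri(t0)], rep(0, 3))

  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    a <- random_adjacency(n)
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
  }

  bad <- random_adjacency(4); bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold scan finds scale-free fits on block models", {
  # 20 modules of 50 genes (hubs to periphery) over uncorrelated
  # background genes: a power <= 30 reaches the 0.8 fit index
  x <- make_block_expr(20, 50, 60, w = c(0.99, 0.2), background = 500,
                       seed = 41)
  scan <- select_soft_threshold(x, betas = c(1:16, 20, 25, 30),
                                r2_target = 0.8)
  expect_gte(max(scan$scan$r2, na.rm = TRUE), 0.8)
  expect_true(scan$beta %in% 1:30)
  expect_gte(scan$scan$r2[scan$scan$beta == scan$beta], 0.8)

  xs <- make_block_expr(4, 12, 20, w = c(0.95, 0.5), background = 30,
                        seed = 42)
  # unreachable target falls back to the argmax with a warning
  expect_warning(scan2 <- select_soft_threshold(xs, betas = 1:10,
                                                r2_target = 1.01),
                 "argmax")
  expect_equal(scan2$beta,
               scan2$scan$beta[which.max(scan2$scan$r2)])
  # permuting gene order leaves the scan unchanged
  perm <- sample(nrow(xs))
  scan3 <- suppressWarnings(select_soft_threshold(xs[perm, ],
                                                  betas = 1:10))
  expect_equal(scan3$scan,
               suppressWarnings(select_soft_threshold(xs,
                                                      betas = 1:10))$scan)
})

test_that("module detection separates clean blocks and respects min size", {
  # two perfectly separated blocks: within-cor 1, between-cor 0
  p1 <- c(1, -1, 1, -1, 1, -1); p2 <- c(1, 1, -1, -1, 1, 1)
  x <- rbind(a1 = p1, a2 = 2 * p1, a3 = p1 + 3,
             b1 = p2, b2 = 5 * p2, b3 = p2 - 1)
  colnames(x) <- sprintf("s%d", 1:6)
  tom <- tom_similarity(signed_adjacency(x, 6))
  lab <- detect_modules(1 - tom, min_size = 2,
                        cut_height_quantile = 0.5)
  expect_equal(length(setdiff(unique(lab), "grey")), 2)
  expect_false("grey" %in% lab)
  expect_equal(length(unique(lab[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(lab[c("b1", "b2", "b3")])), 1)

  lab_all_grey <- detect_modules(1 - tom, min_size = 10)
  expect_true(all(lab_all_grey == "grey"))
  expect_error(detect_modules(1 - tom, min_size = 1), "min_size")
})

test_that("eigengenes are oriented unit-norm first PCs", {
  set.seed(43)
  profile <- stats::rnorm(12)
  x_same <- t(replicate(5, 2 * profile + 7))
  rownames(x_same) <- sprintf("g%d", 1:5)
  colnames(x_same) <- sprintf("s%d", 1:12)
  lab <- stats::setNames(rep("blue", 5), rownames(x_same))
  me <- module_eigengene(x_same, lab)
  expect_equal(attr(me, "var_explained")[["blue"]], 1)
  expect_equal(sum(me["blue", ]^2), 1)
  expect_gt(abs(cor(me["blue", ], profile)), 1 - 1e-12)
  expect_gt(cor(me["blue", ], profile), 0)  # orientation

  # flipping all genes flips the module mean, so the oriented
  # eigengene flips deterministically with it (no SVD sign ambiguity)
  me_flip <- module_eigengene(-x_same, lab)
  expect_equal(me_flip["blue", ], -me["blue", ], tolerance = 1e-12)

  # random module: explained variance matches an SVD oracle
  xr <- matrix(stats::rnorm(8 * 12), 8, 12,
               dimnames = list(sprintf("g%d", 1:8),
                               sprintf("s%d", 1:12)))
  labr <- stats::setNames(rep("red", 8), rownames(xr))
  mer <- module_eigengene(xr, labr)
  d2 <- svd(t(scale(t(xr))))$d^2
  expect_equal(attr(mer, "var_explained")[["red"]], d2[1] / sum(d2))
})

test_that("eigengene merging applies the 0.25 dissimilarity cut", {
  set.seed(47)
  n_s <- 40
  p1 <- as.vector(scale(stats::rnorm(n_s)))
  q <- as.vector(scale(stats::resid(stats::lm(stats::rnorm(n_s) ~ p1))))
  mk_mod <- function(profile, nm, n = 6)
    `rownames<-`(t(replicate(n, profile)),
                 sprintf("%s%d", nm, seq_len(n)))
  close_to <- function(r) r * p1 + sqrt(1 - r^2) * q  # cor exactly r

  x_close <- rbind(mk_mod(p1, "a"), mk_mod(close_to(0.9), "b"))
  colnames(x_close) <- sprintf("s%d", seq_len(n_s))
  lab <- stats::setNames(rep(c("m1", "m2"), each = 6),
                         rownames(x_close))
  ms <- merge_modules(x_close, lab, merge_cut = 0.25)
  expect_equal(length(setdiff(unique(ms$labels), "grey")), 1)
  expect_equal(nrow(ms$merge_history), 1)

  x_far <- rbind(mk_mod(p1, "a"), mk_mod(close_to(0.5), "b"))
  colnames(x_far) <- colnames(x_close)
  ms2 <- merge_modules(x_far, lab, merge_cut = 0.25)
  expect_equal(length(setdiff(unique(ms2$labels), "grey")), 2)

  # merge_cut 0 is a no-op; merging never increases module count and is
  # idempotent at a fixed cut
  ms0 <- merge_modules(x_close, lab, merge_cut = 0)
  expect_equal(ms0$labels, lab)
  ms_again <- merge_modules(x_close, ms$labels, merge_cut = 0.25)
  expect_equal(ms_again$labels, ms$labels)
})

test_that("tissue enrichment matches enumeration and flags structure", {
  # module identical to one tissue's DEG set, tissues disjoint
  bg <- sprintf("g%02d", 1:30)
  lab <- stats::setNames(rep("grey", 30), bg)
  lab[1:8] <- "turquoise"
  sets <- list(Seed = bg[1:8], Leaf = bg[9:16], Root = bg[17:24])
  e <- module_tissue_enrichment(lab, sets)
  e_seed <- e[e$module == "turquoise" & e$tissue == "Seed", ]
  # minimum achievable p for these margins: all 8 draws inside the set
  expect_equal(e_seed$p, 1 / choose(30, 8), tolerance = 1e-12)
  expect_true(e_seed$flagged)
  expect_equal(e_seed$p, min(e$p[e$module == "turquoise"]))

  # hypergeometric p equals brute-force enumeration on a 20-gene toy
  bg20 <- sprintf("t%02d", 1:20)
  lab20 <- stats::setNames(rep("grey", 20), bg20)
  lab20[c(1:3, 10:11)] <- "blue"   # module size 5
  set20 <- list(Seed = bg20[1:7])  # overlap 3
  e20 <- module_tissue_enrichment(lab20, set20)
  expect_equal(e20$p, hyper_enum_oracle(20, 7, 5, 3),
               tolerance = 1e-12)
})

test_that("subnetwork export matches recomputed correlations", {
  x <- make_block_expr(2, 8, 20, w = c(0.95, 0.7), seed = 51)
  ms <- merge_modules(
    x, stats::setNames(rep(c("yellow", "green"), each = 8),
                       rownames(x)), merge_cut = 0)
  ms$params$beta <- 6
  seeds <- rownames(x)[1:2]
  edges <- extract_subnetwork(x, ms, seeds, weight_min = 0.3)
  expect_true(all(edges$source %in% seeds | edges$target %in% seeds))
  expect_true(all(abs(edges$pearson) >= 0.3))
  for (k in seq_len(min(nrow(edges), 10)))
    expect_equal(edges$pearson[k],
                 cor(x[edges$source[k], ], x[edges$target[k], ]),
                 tolerance = 1e-12)

  # weight_min 1 keeps only perfectly correlated pairs
  x_dup <- rbind(x, dup1 = x[1, ])
  ms_dup <- merge_modules(
    x_dup, stats::setNames(rep(c("yellow", "green", "yellow"),
                               c(8, 8, 1)), rownames(x_dup)),
    merge_cut = 0)
  e1 <- extract_subnetwork(x_dup, ms_dup, rownames(x)[1],
                           weight_min = 1 - 1e-12)
  expect_true(all(sort(c(e1$source, e1$target)) %in%
                    c(rownames(x)[1], "dup1")))

  expect_error(extract_subnetwork(x, ms, "nope", weight_min = 0),
               "nope")
  expect_error(extract_subnetwork(x, ms, rownames(x)[c(1, 9)]),
               "multiple")
})

test_that("planted modules are recovered with high ARI", {
  cfg <- sim_config(n_triads = 150, n_modules = 5, module_snr = 1,
                    de_fraction = 0.3, seed = 11)
  sim <- simulate_all(cfg)
  x <- suppressMessages(network_input(sim$expr,
                                      rownames(sim$expr$fpkm), 0.2))
  ms <- suppressWarnings(build_network(x, min_size = 20))
  truth <- sim$truth$genes$module[match(names(ms$labels),
                                        sim$truth$genes$gene_id)]
  keep <- truth != "none"
  expect_gte(module_ari(ms$labels[keep], truth[keep]), 0.8)
})

test_that("network input applies the FPKM floor and drops constants", {
  design <- two_cell_design(n_rep = 2)
  fpkm <- rbind(low = c(0.05, 0.1, 0.08, 0.06),
                ok = c(1, 2, 3, 4),
                flat = c(2, 2, 2, 2))
  colnames(fpkm) <- design$sample_id
  expr <- make_fpkm_expr(fpkm, design)
  x <- suppressMessages(network_input(expr, c("low", "ok", "flat")))
  expect_equal(rownames(x), "ok")
  expect_equal(attr(x, "n_zero_variance"), 1)
  expect_equal(x["ok", ], log2(expr$fpkm["ok", ] + 1))
})
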