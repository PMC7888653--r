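test_that("phase 1 flags control-dominant species and spares the rest", {
  tt <- tiny_taxa()
  flagged <- phase1_negative_control_filter(tt)
  expect_identical(flagged, "Ralstonia contamA")
  # a species absent from every control is never flagged
  expect_false("Lactobacillus cleanA" %in% flagged)
  # a table without controls skips the phase with a warning
  no_neg <- taxa_table(tt$counts[, 3:4], c(FALSE, FALSE),
                       c("cancer", "control"))
  expect_warning(out <- phase1_negative_control_filter(no_neg),
                 "no negative controls")
  expect_length(out, 0)
})

test_that("phase 1 recovers planted contaminants with few innocents", {
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sim <- simulate_taxa_table(simulation_design(seed = 400 + s))
    flagged <- phase1_negative_control_filter(sim$table)
    truth <- sim$truth$contaminants
    expect_true(all(truth %in% flagged))
    innocents <- setdiff(flagged, truth)
    expect_lte(length(innocents),
               0.05 * (nrow(sim$table$counts) - length(truth)))
  }
})

test_that("phase 2 uses strict > 0.30 on Spearman over true samples", {
  # indicator with a strictly monotone follower (rho = 1) and an
  # anti-monotone species (rho = -1)
  counts <- rbind(
    "Ralstonia ind" = c(5, 10, 20, 40, 80, 160, 100, 100),
    "Delftia follow" = c(7, 13, 22, 41, 90, 170, 1, 1),
    "Lactobacillus anti" = c(160, 80, 40, 20, 10, 5, 1, 1),
    "Prevotella flat" = c(30, 30, 30, 30, 30, 30, 1, 1))
  tt <- taxa_table(counts,
                   c(rep(FALSE, 6), TRUE, TRUE),
                   c(rep(c("cancer", "control"), 3), NA, NA))
  flagged <- phase2_indicator_correlation(tt, "Ralstonia ind")
  expect_true("Delftia follow" %in% flagged)
  expect_false("Lactobacillus anti" %in% flagged)
  # constant species: undefined correlation is never flagged
  expect_false("Prevotella flat" %in% flagged)
  expect_error(phase2_indicator_correlation(tt, "Missing species"),
               "not in table")
})

test_that("phase 2 matches a direct rank-formula Spearman oracle", {
  set.seed(5)
  counts <- matrix(rpois(6 * 6, 40) + 1, 6, 6,
                   dimnames = list(paste("Genus sp", 1:6),
                                   paste0("S", 1:6)))
  tt <- taxa_table(counts, rep(FALSE, 6), rep(c("cancer", "control"), 3))
  ind <- "Genus sp 1"
  rel <- sweep(counts, 2, colSums(counts), "/")
  for (sp in rownames(counts)[-1]) {
    # Spearman as Pearson on mid-ranks, written out
    rx <- rank(rel[ind, ])
    ry <- rank(rel[sp, ])
    rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    in_flagged <- sp %in% phase2_indicator_correlation(tt, ind,
                                                       cutoff = 0.30)
    expect_identical(in_flagged, rho_hand > 0.30)
  }
})

test_that("phase 3 is an exact genus-membership filter", {
  tt <- tiny_taxa()
  expect_identical(phase3_genus_blacklist(tt, "Ralstonia"),
                   "Ralstonia contamA")
  expect_length(phase3_genus_blacklist(tt, character(0)), 0)
  # oracle: independent string-match over a mixed table
  sim <- simulate_taxa_table(simulation_design(seed = 77))
  bl <- default_contaminant_genera()
  flagged <- phase3_genus_blacklist(sim$table, bl)
  oracle <- rownames(sim$table$counts)[
    sub(" .*", "", rownames(sim$table$counts)) %in% bl]
  expect_setequal(flagged, oracle)
})

test_that("contaminant removal unions the phases and keeps all samples", {
  sim <- simulate_taxa_table(simulation_design(seed = 21))
  out <- remove_contaminants(sim$table, sim$truth$indicators)
  rep <- out$report
  expect_setequal(rep$removed,
                  Reduce(union, list(rep$phase1_flagged, rep$phase2_flagged,
                                     rep$phase3_flagged,
                                     sim$truth$indicators)))
  expect_equal(ncol(out$table$counts), ncol(sim$table$counts))
  expect_equal(nrow(rep$evidence), nrow(sim$table$counts))
})

test_that("rarefaction hits the exact depth and drops shallow samples", {
  counts <- cbind(deep = c(1500, 1200, 0), exact = c(2000, 600, 100),
                  shallow = c(500, 400, 99))
  rownames(counts) <- paste("Genus sp", 1:3)
  tt <- taxa_table(counts, rep(FALSE, 3), rep("control", 3))
  out <- rarefy_table(tt, depth = 2700, seed = 4)
  expect_identical(out$dropped, "shallow")
  expect_true(all(colSums(out$table$counts) == 2700))
  expect_true(all(out$table$counts <= counts[, c("deep", "exact")]))
  # a sample at exactly the depth is kept unchanged
  expect_identical(unname(out$table$counts[, "exact"]),
                   as.integer(counts[, "exact"]))
  expect_error(rarefy_table(taxa_table(
    matrix(5, 1, 1, dimnames = list("Genus sp", "s")), FALSE, "control"),
    depth = 2700), "below rarefaction depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- matrix(c(6000, 3000, 1000), 3, 1,
                   dimnames = list(paste("Genus sp", 1:3), "s1"))
  tt <- taxa_table(counts, FALSE, "control")
  draws <- vapply(1:300, function(s) {
    rarefy_table(tt, depth = 1000, seed = s)$table$counts[, 1]
  }, numeric(3))
  expected <- 1000 * counts[, 1] / sum(counts[, 1])
  for (i in 1:3) {
    se <- sd(draws[i, ]) / sqrt(ncol(draws))
    expect_lt(abs(mean(draws[i, ]) - expected[i]), 3 * se + 1e-9)
  }
})

test_that("Bray-Curtis matches hand values and metric axioms", {
  m <- rbind(a = c(2, 0), b = c(1, 1), c = c(2, 0), d = c(0, 5))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)     # 1 - 2*1/4
  expect_equal(d["a", "c"], 0)       # identical columns
  expect_equal(d["a", "d"], 1)       # disjoint support
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_warning(bray_curtis(rbind(z1 = c(0, 0), z2 = c(0, 0))),
                 "all-zero")
})

test_that("unweighted UniFrac matches hand cases and a brute-force walk", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  m <- rbind(s1 = c(A = 1, B = 0), s2 = c(A = 0, B = 1),
             s3 = c(A = 5, B = 0))
  d <- suppressWarnings(unweighted_unifrac(m, tr2))
  expect_equal(d["s1", "s2"], 1.0)   # each sample a distinct tip
  expect_equal(d["s1", "s3"], 0)     # identical presence sets
  # 4-tip tree with internal structure: compare to explicit branch walk
  tr4 <- ape::read.tree(text = "((A:0.5,B:1.5):0.7,(C:0.9,D:0.3):1.1);")
  comm <- rbind(x = c(A = 3, B = 1, C = 0, D = 0),
                y = c(A = 0, B = 2, C = 4, D = 0),
                z = c(A = 1, B = 0, C = 1, D = 1))
  d4 <- unweighted_unifrac(comm, tr4)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    tips_a <- colnames(comm)[comm[pair[1], ] > 0]
    tips_b <- colnames(comm)[comm[pair[2], ] > 0]
    expect_equal(d4[pair[1], pair[2]],
                 brute_unifrac_pair(tr4, tips_a, tips_b),
                 tolerance = 1e-9)
  }
  expect_error(unweighted_unifrac(
    rbind(s = c(A = 1, Z = 1)), tr2), "missing from tree: Z")
})

test_that("PCoA recovers geometry from distances", {
  # degenerate all-zero matrix
  z <- pcoa_ordination(matrix(0, 3, 3))
  expect_true(all(z$coordinates == 0))

  # three equidistant points: two equal positive eigenvalues, pairwise
  # coordinate distances equal to 1
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa_ordination(d3)
  ev <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  cd <- as.matrix(dist(p3$coordinates))
  expect_equal(cd[upper.tri(cd)], rep(1, 3), tolerance = 1e-9)

  # planted 2-D configuration comes back up to rotation/reflection
  set.seed(9)
  pts <- matrix(rnorm(12), 6, 2)
  rec <- pcoa_ordination(as.matrix(dist(pts)))$coordinates[, 1:2]
  pro <- vegan::procrustes(pts, rec, symmetric = TRUE)
  expect_lt(pro$ss, 1e-8)
})

test_that("differential abundance reports group percents and exact U", {
  # constant columns keep relative abundances tied for "Genus even"
  counts <- rbind(
    "Genus cancOnly" = c(50, 50, 50, 0, 0, 0, 0),
    "Genus filler"   = c(100, 100, 100, 150, 150, 150, 150),
    "Genus even"     = c(100, 100, 100, 100, 100, 100, 100),
    "Genus absent"   = c(0, 0, 0, 0, 0, 0, 0))
  tt <- taxa_table(counts, rep(FALSE, 7),
                   c(rep("cancer", 3), rep("control", 4)))
  da <- differential_abundance(tt)
  expect_false("Genus absent" %in% da$species)
  row1 <- da[da$species == "Genus cancOnly", ]
  expect_lt(row1$p_value, 0.05)
  expect_equal(row1$mean_percent_control, 0)
  expect_equal(row1$prevalence_control, 0)
  expect_equal(da[da$species == "Genus even", "p_value"], 1)

  # U equals brute-force pair counting on a 5v5 table
  set.seed(2)
  counts5 <- matrix(rpois(10 * 2, 30), 2, 10,
                    dimnames = list(c("Genus a", "Genus b"), NULL))
  colnames(counts5) <- paste0("S", 1:10)
  tt5 <- taxa_table(counts5, rep(FALSE, 10),
                    rep(c("cancer", "control"), each = 5))
  da5 <- differential_abundance(tt5)
  rel <- sweep(counts5, 2, colSums(counts5), "/") * 100
  for (sp in rownames(counts5)) {
    expect_equal(da5[da5$species == sp, "U"],
                 brute_u(rel[sp, 1:5], rel[sp, 6:10]))
  }
})

test_that("whole-profile clustering fails to separate while planted species differ", {
  sim <- simulate_taxa_table(simulation_design(seed = 31))
  cleaned <- remove_contaminants(sim$table, sim$truth$indicators)
  rar <- rarefy_table(cleaned$table, depth = 2700, seed = 31)
  keep <- !rar$table$is_negative_control
  tt <- taxa_table(rar$table$counts[, keep, drop = FALSE],
                   rep(FALSE, sum(keep)), rar$table$labels[keep])
  sep <- cluster_separation(tt)
  # below the conventional 0.25 threshold for even "weak" structure
  expect_lt(abs(sep$silhouette), 0.25)
  da <- differential_abundance(tt)
  planted <- da[da$species %in% sim$truth$differential, ]
  expect_true(any(planted$p_value < 0.05))
})
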