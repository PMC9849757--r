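small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_per_group = 5, n_taxa_bacteria = 50, n_taxa_fungi = 30,
                   depth = 15000,
                   blocks_bacteria = list(
                     list(size = 5, rho = 0.95, treatment = "grazed")),
                   blocks_fungi = list(), seed = seed, ...)
}

test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(n_per_group = 2), "n_per_group")
  expect_error(synthetic_config(blocks_bacteria = list(
    list(size = 400, rho = 0.9, treatment = "grazed"))), "blocks_bacteria")
  expect_error(synthetic_config(blocks_fungi = list(
    list(size = 5, rho = 1.2, treatment = "grazed"))), "blocks_fungi")
  expect_error(synthetic_config(blocks_fungi = list(
    list(size = 5, rho = 0.9, treatment = "mowed"))), "treatment")
  expect_error(synthetic_config(effect_table = list(mult = c(XX = 2))),
               "effect_table")
  expect_error(synthetic_config(occupancy_drop = c(grazed = 1, ungrazed = 0)),
               "occupancy_drop")
})

test_that("generation is bit-identical under a fixed seed and config", {
  a <- generate_otu_tables(small_cfg(7))
  b <- generate_otu_tables(small_cfg(7))
  expect_identical(a, b)
  expect_identical(generate_soil_functions(small_cfg(7)),
                   generate_soil_functions(small_cfg(7)))
  c2 <- generate_otu_tables(small_cfg(8))
  expect_false(identical(a$bacteria, c2$bacteria))
})

test_that("tables are valid compositional counts with labelled samples", {
  out <- generate_otu_tables(small_cfg(3))
  expect_true(all(out$bacteria >= 0) && all(out$fungi >= 0))
  expect_true(all(out$bacteria == round(out$bacteria)))
  expect_equal(dim(out$bacteria), c(50, 10))
  expect_equal(dim(out$fungi), c(30, 10))
  expect_identical(out$metadata$treatment, rep(c("grazed", "ungrazed"), each = 5))
  expect_identical(colnames(out$bacteria), out$metadata$sample_id)
  # truth marks exactly the planted block
  tr <- out$truth$bacteria
  expect_equal(sum(tr$block == 1), 5)
  expect_true(all(tr$treatment[tr$block == 1] == "grazed"))
})

test_that("planted blocks reach their correlation target on average", {
  cfg <- synthetic_config(n_per_group = 10, n_taxa_bacteria = 60,
                          n_taxa_fungi = 30, depth = 20000,
                          blocks_bacteria = list(
                            list(size = 5, rho = 0.95, treatment = "grazed")),
                          blocks_fungi = list(), seed = 21)
  out <- generate_otu_tables(cfg)
  grazed <- out$bacteria[, out$metadata$treatment == "grazed"]
  rel <- sweep(grazed, 2, colSums(grazed), "/")
  block_taxa <- out$truth$bacteria$taxon[out$truth$bacteria$block == 1]
  r <- cor(t(rel[block_taxa, ]))
  expect_gte(mean(r[upper.tri(r)]), 0.8)
})

test_that("blockless noise produces no excess of strong correlations", {
  # null reference: per-taxon sample shuffles of the same tables (this
  # preserves the skewed marginals, for which the normal-theory tail rate
  # is too small at n = 10); a many-taxa, even-composition configuration
  # keeps closure dependence negligible
  obs <- 0; perm <- 0; pairs <- 0
  set.seed(999)
  for (s in 1:20) {
    cfg <- synthetic_config(n_per_group = 5, n_taxa_bacteria = 150,
                            n_taxa_fungi = 30, depth = 30000,
                            blocks_bacteria = list(), blocks_fungi = list(),
                            comp_shift = 0, mu_sd = 0.5,
                            occupancy_drop = c(grazed = 0, ungrazed = 0),
                            seed = 100 + s)
    tab <- generate_otu_tables(cfg)$bacteria
    tab <- tab[apply(tab, 1, var) > 0, ]
    rel <- sweep(tab, 2, colSums(tab), "/")
    r <- cor(t(rel))
    obs <- obs + sum(abs(r[upper.tri(r)]) > 0.8)
    pairs <- pairs + sum(upper.tri(r))
    for (k in 1:2) {
      rp <- t(apply(rel, 1, sample))
      r2 <- cor(t(rp))
      perm <- perm + sum(abs(r2[upper.tri(r2)]) > 0.8)
    }
  }
  alpha_perm <- perm / (2 * pairs)
  expect_lte(obs, qbinom(0.999, pairs, alpha_perm))
})

test_that("soil effects converge to the printed ratios at large n", {
  cfg <- synthetic_config(n_per_group = 50, seed = 5)
  soil <- generate_soil_functions(cfg)
  grazed <- soil[1:50, ]; ungrazed <- soil[51:100, ]
  ratio <- mean(grazed[, "SH"]) / mean(ungrazed[, "SH"])
  expect_lt(abs(ratio - 7.5) / 7.5, 0.2)
  expect_lt(abs(mean(grazed[, "AP"]) / mean(ungrazed[, "AP"]) - 0.27), 0.1)
  expect_lt(abs(mean(grazed[, "pH"]) - mean(ungrazed[, "pH"]) - 0.5), 0.15)
  expect_true(all(soil[, setdiff(colnames(soil), "vector_angle")] > 0))
  expect_true(all(soil[, "vector_angle"] >= 0 & soil[, "vector_angle"] <= 90))
})

test_that("a null effect table keeps the type-I error near nominal", {
  null_eff <- list(mult = numeric(0), add = numeric(0))
  pvals <- unlist(lapply(1:200, function(s) {
    cfg <- synthetic_config(n_per_group = 5, effect_table = null_eff,
                            seed = 5000 + s)
    soil <- generate_soil_functions(cfg)
    g <- factor(rep(c("g", "u"), each = 5))
    vapply(colnames(soil), function(v)
      stats::kruskal.test(soil[, v], g)$p.value, numeric(1))
  }))
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("an empty effect table equals explicit no-effect generation", {
  cfg1 <- synthetic_config(n_per_group = 4,
                           effect_table = list(mult = numeric(0),
                                               add = numeric(0)), seed = 77)
  cfg2 <- synthetic_config(n_per_group = 4, effect_table = list(), seed = 77)
  m1 <- generate_soil_functions(cfg1)
  m2 <- generate_soil_functions(cfg2)
  attr(m1, "effects") <- attr(m2, "effects") <- NULL
  expect_identical(m1, m2)
})

test_that("enzyme-derived limitation mode stays internally consistent", {
  cfg <- synthetic_config(n_per_group = 6, limitation = "enzymes", seed = 9)
  soil <- generate_soil_functions(cfg)
  vl <- vector_limitation(soil[, "BGC"], soil[, "NAG"], soil[, "LAP"],
                          soil[, "ACP"], trans = "ln")
  expect_equal(unname(soil[, "C_limitation"]), vl$length, tolerance = 1e-12)
  expect_equal(unname(soil[, "vector_angle"]), vl$angle, tolerance = 1e-12)
})

test_that("planted soil effects are detected downstream at n = 10", {
  detected <- vapply(1:25, function(s) {
    soil <- generate_soil_functions(synthetic_config(n_per_group = 10,
                                                     seed = 300 + s))
    g <- factor(rep(c("g", "u"), each = 10))
    all(vapply(c("SH", "pH", "WC", "AP"), function(v)
      stats::kruskal.test(soil[, v], g)$p.value < 0.05, logical(1)))
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})
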