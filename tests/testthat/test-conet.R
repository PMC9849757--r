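make_table <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("taxon filter keeps exactly the taxa meeting both thresholds", {
  tab <- make_table(list(
    t1 = c(5, 5, 5, 5, 5, 5),     # prevalence 1
    t2 = c(9, 0, 0, 0, 0, 0),     # prevalence 1/6
    t3 = c(1, 1, 1, 0, 0, 0),     # prevalence 1/2
    t4 = c(0, 0, 2, 2, 0, 0),     # prevalence 1/3
    t5 = c(100, 100, 100, 100, 100, 100)))
  expect_identical(filter_taxa(tab, 0, 0), tab)
  expect_false("t2" %in% rownames(filter_taxa(tab, 0.5, 0)))
  expect_identical(rownames(filter_taxa(tab, 0.5, 0)), c("t1", "t3", "t5"))
  # mean relative abundance cut: t5 dominates every sample
  kept <- filter_taxa(tab, 0, 0.5)
  expect_identical(rownames(kept), "t5")
  expect_error(filter_taxa(tab, 1, 0.99), "every taxon")
})

test_that("pairwise correlations match the textbook formula", {
  tab <- make_table(list(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                         c = c(4, 3, 2, 1), d = c(1, 3, 2, 5)))
  ce <- correlation_edges(tab, transform = identity)
  expect_equal(ce$r["a", "b"], 1)
  expect_equal(ce$r["a", "c"], -1)
  oracle <- pearson_brute(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(ce$r["a", "d"], oracle$r, tolerance = 1e-12)
  expect_equal(ce$p["a", "d"], oracle$p, tolerance = 1e-12)
  expect_true(isSymmetric(ce$r))
  expect_equal(unname(diag(ce$r)), rep(1, 4))
  expect_error(correlation_edges(tab[, 1:2]), "3 samples")
})

test_that("zero-variance taxa are excluded with a warning", {
  tab <- make_table(list(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5)))
  expect_warning(ce <- correlation_edges(tab, transform = identity),
                 "zero-variance")
  expect_identical(rownames(ce$r), "a")
  expect_identical(attr(ce, "excluded"), "b")
})

test_that("BH adjustment equals the step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("network edges obey both strict thresholds and keep signs", {
  base <- c(1, 5, 2, 8, 3, 9, 4, 7, 6, 10)
  tab <- make_table(list(
    b1 = base, b2 = 2 * base, b3 = 3 * base,      # exact block, r = 1
    n1 = c(5, 5, 1, 5, 5, 5, 5, 2, 5, 5),
    n2 = c(2, 2, 2, 9, 2, 2, 1, 2, 2, 2),
    n3 = c(7, 1, 7, 7, 7, 3, 7, 7, 7, 7)))
  net <- build_network(tab, r_min = 0.8, q_max = 0.01, transform = identity)
  got <- sort(apply(net$edges[, c("from", "to")], 1, paste, collapse = "-"))
  expect_identical(got, c("b1-b2", "b1-b3", "b2-b3"))
  expect_true(all(net$edges$sign == 1L))
  expect_true(all(abs(net$edges$r) > 0.8 & net$edges$q < 0.01))
  # negative correlations carry sign -1
  tab2 <- make_table(list(u = base, v = -base + 11, w = c(5, 5, 1, 5, 5, 5, 5, 2, 5, 3)))
  net2 <- build_network(tab2, transform = identity)
  e <- net2$edges
  expect_identical(e$sign[e$from == "u" & e$to == "v"], -1L)
})

test_that("the r threshold is strictly exclusive", {
  set.seed(4)
  x <- rnorm(10); y <- 0.9 * x + rnorm(10, sd = 0.3)
  tab <- make_table(list(a = x - min(x) + 1, b = y - min(y) + 1))
  r_obs <- cor(tab["a", ], tab["b", ])
  # at r_min just below, the edge exists; at r_min equal to r, it does not
  n_lo <- build_network(tab, r_min = r_obs - 1e-9, q_max = 1, transform = identity)
  n_eq <- build_network(tab, r_min = r_obs, q_max = 1, transform = identity)
  expect_equal(nrow(n_lo$edges), 1L)
  expect_equal(nrow(n_eq$edges), 0L)
  expect_true(n_eq$empty)
})

test_that("independent noise yields a median edge count of zero", {
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    tab <- matrix(rpois(30 * 12, exp(rnorm(30 * 12, 3, 0.5))), 30, 12,
                  dimnames = list(paste0("t", 1:30), paste0("s", 1:12)))
    tab <- tab[apply(tab, 1, var) > 0, , drop = FALSE]
    nrow(build_network(tab)$edges)
  }, numeric(1))
  expect_equal(median(counts), 0)
})

test_that("network construction ignores taxon row order and sample labels", {
  set.seed(10)
  cfg <- synthetic_config(n_per_group = 5, n_taxa_bacteria = 40,
                          n_taxa_fungi = 20, depth = 10000, seed = 2,
                          blocks_bacteria = list(
                            list(size = 6, rho = 0.98, treatment = "grazed")),
                          blocks_fungi = list())
  tab <- generate_otu_tables(cfg)$bacteria
  net1 <- build_network(tab)
  perm <- sample(nrow(tab))
  net2 <- build_network(tab[perm, ])
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), round(e$r, 10)))
  }
  expect_identical(key(net1), key(net2))
  tab3 <- tab
  colnames(tab3) <- paste0("x", seq_len(ncol(tab3)))
  expect_identical(key(build_network(tab3)), key(net1))
})

test_that("natural connectivity matches its closed-form spectra", {
  expect_equal(natural_connectivity(toy_k(3)), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(toy_path3()),
               log((exp(sqrt(2)) + 1 + exp(-sqrt(2))) / 3), tolerance = 1e-12)
  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(edgeless), 0)
  expect_error(natural_connectivity(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("natural connectivity never decreases when edges are added", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 8
    g <- igraph::make_empty_graph(n, directed = FALSE)
    prev <- natural_connectivity(g)
    pairs <- t(combn(n, 2))
    pairs <- pairs[sample(nrow(pairs)), ]
    for (i in seq_len(nrow(pairs))) {
      g <- igraph::add_edges(g, pairs[i, ])
      cur <- natural_connectivity(g)
      expect_gte(cur, prev - 1e-12)
      prev <- cur
    }
  }
})

test_that("vulnerability reproduces hand-enumerated efficiency losses", {
  p3 <- toy_path3()  # star with center b
  expect_equal(vulnerability(p3), 1, tolerance = 1e-12)
  # leaf contribution on P3: E = 5/6, E_leaf = 1/3 -> 0.6
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  e0 <- efficiency_brute(a)
  a_leaf <- a; a_leaf[1, ] <- 0; a_leaf[, 1] <- 0
  expect_equal(e0, 5 / 6)
  expect_equal((e0 - efficiency_brute(a_leaf)) / e0, 0.6)
  k4 <- toy_k(4)
  a4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(vulnerability(k4), vulnerability_brute(a4), tolerance = 1e-12)
  expect_lt(vulnerability(k4), 1)
  expect_error(vulnerability(igraph::make_empty_graph(3, directed = FALSE)),
               "edgeless")
})

test_that("global metrics are exact on regular and star graphs", {
  mk4 <- global_metrics(toy_k(4))
  expect_equal(mk4$average_degree, 3)
  expect_equal(mk4$connectance, 1)
  expect_equal(mk4$n_clusters, 1)
  expect_equal(mk4$centralization_degree, 0)
  s5 <- igraph::make_star(5, mode = "undirected")
  expect_equal(global_metrics(s5)$centralization_degree, 1)
})

test_that("two disjoint triangles: components and best-partition modularity", {
  g <- igraph::disjoint_union(toy_k(3), toy_k(3))
  gm <- global_metrics(g)
  expect_equal(gm$n_clusters, 2)
  # brute-force search over 3-label membership assignments
  best <- -Inf
  for (code in 0:(3^6 - 1)) {
    mem <- (code %/% 3^(0:5)) %% 3 + 1
    best <- max(best, igraph::modularity(g, membership = mem))
  }
  expect_equal(gm$modularity, best, tolerance = 1e-12)
  expect_equal(best, 0.5, tolerance = 1e-12)
})

test_that("node metrics agree with brute-force path and triangle counts", {
  tri <- global_metrics(toy_k(3))  # smoke for class
  nm <- node_metrics(toy_k(3))
  expect_equal(nm$degree, rep(2L, 3))
  expect_equal(nm$transitivity, rep(1, 3))
  expect_equal(nm$closeness, rep(1, 3))
  hub <- node_metrics(igraph::make_star(5, mode = "undirected"))
  expect_equal(hub$transitivity[1], 0)
  # 5-node toy: square with a diagonal plus a pendant
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - a, a - c, d - e)
  nm5 <- node_metrics(g)
  a5 <- as.matrix(igraph::as_adjacency_matrix(g))
  d5 <- bfs_distances(a5)
  expect_equal(nm5$closeness, (5 - 1) / rowSums(d5), tolerance = 1e-12)
  deg <- rowSums(a5)
  tri_count <- diag(a5 %*% a5 %*% a5) / 2
  loc <- ifelse(deg < 2, 0, tri_count / (deg * (deg - 1) / 2))
  expect_equal(nm5$transitivity, unname(loc), tolerance = 1e-12)
  ev <- eigen(a5)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(nm5$eigenvector, unname(ev), tolerance = 1e-8)
  expect_equal(nm5$degree, unname(as.integer(deg)))
})

test_that("per-sample subnetworks are the induced presence subgraphs", {
  base <- c(1, 5, 2, 8, 3, 9, 4, 7, 6, 10)
  tab <- make_table(list(b1 = base, b2 = 2 * base, b3 = 3 * base,
                         n1 = c(5, 5, 1, 5, 5, 5, 5, 2, 5, 5)))
  net <- build_network(tab, transform = identity)   # triangle b1-b2-b3
  # presence table: sample p1 has all taxa, p2 only b1, p3 only b1+b2
  ptab <- make_table(list(b1 = c(3, 2, 4), b2 = c(1, 0, 5),
                          b3 = c(2, 0, 0), n1 = c(1, 1, 1)))
  sub <- sample_subnetworks(net, ptab)
  expect_equal(unname(sub["s1", ]),
               c(3, 3, 2, 1, natural_connectivity(toy_k(3))))
  expect_equal(unname(sub["s2", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(sub["s3", c("n_nodes", "n_edges")]), c(2, 1))
  gm <- global_metrics(net)
  expect_equal(unname(sub["s1", "average_degree"]), gm$average_degree)
})
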