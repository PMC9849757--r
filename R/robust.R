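# Network robustness under random node/edge removal and bootstrap stability
# comparison at a fixed removal fraction.

#' Randomly remove a fraction of nodes or edges
#'
#' Deletes \code{floor(fraction * count)} uniformly sampled nodes (with
#' their incident edges) or edges. Node removal shrinks the node set;
#' metrics on the result are computed on the remaining nodes.
#'
#' @param net a \code{co_network} or igraph graph.
#' @param mode \code{"nodes"} or \code{"edges"}.
#' @param fraction removal proportion in [0, 1).
#' @param seed integer seed (removal is deterministic given the seed).
#' @return igraph graph after removal.
#' @export
remove_random <- function(net, mode = c("nodes", "edges"), fraction, seed = 1) {
  mode <- match.arg(mode)
  g <- as_conet_graph(net)
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  count <- if (mode == "nodes") igraph::vcount(g) else igraph::ecount(g)
  k <- floor(fraction * count + 1e-9)
  if (k == 0L) return(g)
  with_seed(seed, {
    idx <- sample.int(count, k)
    if (mode == "nodes") igraph::delete_vertices(g, idx)
    else igraph::delete_edges(g, idx)
  })
}

# Average degree / natural connectivity of a possibly-emptied graph.
reduced_metrics <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(c(average_degree = 0, natural_connectivity = 0))
  c(average_degree = 2 * igraph::ecount(g) / n,
    natural_connectivity = natural_connectivity(g))
}

#' Robustness curve under progressive random removal
#'
#' For each removal fraction, performs \code{reps} independent random
#' removals (each fraction removed independently from the intact network,
#' not cumulatively) and records the mean and standard deviation of the
#' average degree and natural connectivity of the reduced network. A
#' network emptied to zero nodes contributes 0 for both metrics. A smaller
#' decline at the same removal proportion indicates a more stable network.
#'
#' @param net a \code{co_network} or igraph graph.
#' @param mode \code{"nodes"} or \code{"edges"}.
#' @param fractions increasing removal proportions in [0, 1); a 0 entry
#'   reproduces the intact network's metrics exactly.
#' @param reps replicates per fraction (>= 1).
#' @param seed integer root seed.
#' @return data.frame of class \code{"robustness_curve"} with columns
#'   \code{mode}, \code{fraction}, \code{reps}, and mean/sd of both metrics.
#' @export
robustness_curve <- function(net, mode = c("nodes", "edges"),
                             fractions = seq(0, 0.9, 0.1), reps = 100,
                             seed = 1) {
  mode <- match.arg(mode)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)", call. = FALSE)
  g <- as_conet_graph(net)
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    if (f == 0) {
      m <- reduced_metrics(g)
      return(data.frame(mode = mode, fraction = f, reps = reps,
                        mean_average_degree = m[["average_degree"]],
                        sd_average_degree = 0,
                        mean_natural_connectivity = m[["natural_connectivity"]],
                        sd_natural_connectivity = 0))
    }
    vals <- vapply(seq_len(reps), function(r) {
      reduced_metrics(remove_random(g, mode, f,
                                    seed = substream_seed(seed,
                                      paste0("curve", fi, "_", r))))
    }, numeric(2))
    data.frame(mode = mode, fraction = f, reps = reps,
               mean_average_degree = mean(vals[1, ]),
               sd_average_degree = stats::sd(vals[1, ]),
               mean_natural_connectivity = mean(vals[2, ]),
               sd_natural_connectivity = stats::sd(vals[2, ]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' Bootstrap stability distributions at a fixed removal fraction
#'
#' Repeatedly removes \code{floor(fraction * n)} random nodes (default half
#' of them) and collects the average degree and natural connectivity of
#' each reduced network. The two distributions operationalise network
#' stability and feed \code{\link{compare_stability}}.
#'
#' @param net a \code{co_network} or igraph graph with >= 2 nodes.
#' @param fraction node-removal fraction (default 0.5).
#' @param reps bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @return List of class \code{"stability_distribution"} with numeric
#'   vectors \code{average_degree} and \code{natural_connectivity} of
#'   length \code{reps}.
#' @export
stability_bootstrap <- function(net, fraction = 0.5, reps = 1000, seed = 1) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("network must have at least 2 nodes", call. = FALSE)
  if (reps < 100) stop("use at least 100 bootstrap replicates", call. = FALSE)
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  a[a != 0] <- 1
  k <- floor(fraction * n + 1e-9)
  res <- with_seed(seed, vapply(seq_len(reps), function(r) {
    keep <- if (k == 0L) seq_len(n) else sort(sample.int(n, n - k))
    sub <- a[keep, keep, drop = FALSE]
    nn <- length(keep)
    if (nn == 0L) return(c(0, 0))
    ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
    mx <- max(ev)
    c(sum(sub) / nn, mx + log(mean(exp(ev - mx))))
  }, numeric(2)))
  out <- list(average_degree = res[1, ], natural_connectivity = res[2, ],
              fraction = fraction, reps = reps, seed = seed)
  class(out) <- "stability_distribution"
  out
}

ci95 <- function(x) {
  hw <- 1.96 * stats::sd(x) / sqrt(length(x))
  c(mean = mean(x), ci_low = mean(x) - hw, ci_high = mean(x) + hw,
    ci_halfwidth = hw)
}

#' Compare the stability of two networks
#'
#' Given two bootstrap stability distributions (see
#' \code{\link{stability_bootstrap}}), runs for each metric a two-sample
#' Kolmogorov-Smirnov test (distribution shape) and a Kruskal-Wallis test
#' (location), and reports mean with a normal-approximation 95% confidence
#' interval per distribution. The network with the higher mean is labelled
#' more stable.
#'
#' @param distA,distB \code{stability_distribution} objects.
#' @param names_ab labels for the two networks.
#' @return List of class \code{"stability_comparison"}, one entry per
#'   metric with \code{ks}, \code{kruskal}, per-network summaries and
#'   \code{more_stable}.
#' @export
compare_stability <- function(distA, distB, names_ab = c("A", "B")) {
  stopifnot(inherits(distA, "stability_distribution"),
            inherits(distB, "stability_distribution"))
  metric <- c("average_degree", "natural_connectivity")
  out <- lapply(metric, function(m) {
    a <- distA[[m]]; b <- distB[[m]]
    if (length(a) == 0L || length(b) == 0L)
      stop("empty stability distribution", call. = FALSE)
    if (identical(a, b)) {
      ks <- list(statistic = c(D = 0), p.value = 1)
    } else {
      ks <- suppressWarnings(stats::ks.test(a, b))
    }
    kw <- stats::kruskal.test(list(a, b))
    list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
         kruskal_p = kw$p.value,
         summary = stats::setNames(list(ci95(a), ci95(b)), names_ab),
         more_stable = names_ab[which.max(c(mean(a), mean(b)))])
  })
  names(out) <- metric
  class(out) <- "stability_comparison"
  out
}

#' @export
print.stability_comparison <- function(x, ...) {
  for (m in names(x)) {
    cat(m, ": KS D = ", signif(x[[m]]$ks_statistic, 4),
        " (p = ", signif(x[[m]]$ks_p, 3), "), Kruskal p = ",
        signif(x[[m]]$kruskal_p, 3), "; more stable: ",
        x[[m]]$more_stable, "\n", sep = "")
  }
  invisible(x)
}
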