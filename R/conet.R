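# Signed microbial co-occurrence networks from OTU tables, and the global,
# node-level and per-sample subnetwork attributes reported for them.

#' Prevalence / relative-abundance taxon filter
#'
#' Keeps taxa present (abundance > 0) in at least \code{min_prevalence} of
#' samples and with mean relative abundance at least
#' \code{min_rel_abundance}. Row order is preserved.
#'
#' @param table taxa x samples non-negative matrix with dimnames.
#' @param min_prevalence,min_rel_abundance fractions in [0, 1].
#' @return The filtered matrix.
#' @export
filter_taxa <- function(table, min_prevalence = 0, min_rel_abundance = 0) {
  table <- validate_otu_table(table)
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_rel_abundance < 0 || min_rel_abundance > 1)
    stop("filter thresholds must lie in [0, 1]", call. = FALSE)
  rel <- sweep(table, 2, colSums(table), "/")
  keep <- rowMeans(table > 0) >= min_prevalence &
          rowMeans(rel) >= min_rel_abundance
  if (!any(keep)) stop("taxon filter removed every taxon", call. = FALSE)
  table[keep, , drop = FALSE]
}

#' Pairwise Pearson correlations between taxon profiles
#'
#' Correlates taxa on per-sample relative abundances (the default transform;
#' set \code{transform = identity} to correlate raw rows). Two-sided
#' p-values come from the t-distribution with n - 2 degrees of freedom.
#' Zero-variance taxa cannot be correlated and are dropped with a warning;
#' the dropped IDs are kept in the \code{"excluded"} attribute.
#'
#' @param table taxa x samples matrix, >= 3 samples.
#' @param transform function applied to the table before correlating;
#'   default per-sample relative abundance.
#' @return List with symmetric matrices \code{r} and \code{p} (unit
#'   diagonal / zero diagonal) over the retained taxa.
#' @export
correlation_edges <- function(table, transform = NULL) {
  table <- validate_otu_table(table)
  n <- ncol(table)
  if (n < 3L) stop("need at least 3 samples to correlate taxa", call. = FALSE)
  x <- if (is.null(transform)) sweep(table, 2, colSums(table), "/")
       else transform(table)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    excluded <- rownames(x)[v == 0]
    warning(length(excluded), " zero-variance taxa excluded from correlation",
            call. = FALSE)
    x <- x[v > 0, , drop = FALSE]
  } else excluded <- character(0)
  r <- stats::cor(t(x))
  # guard rounding before the t transform
  rc <- pmin(pmax(r, -1), 1)
  tt <- abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  diag(p) <- 0
  out <- list(r = r, p = p, n_samples = n)
  attr(out, "excluded") <- excluded
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH adjustment (monotone, order-preserving), as applied
#' to the correlation p-values before edge selection.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Build a signed co-occurrence network
#'
#' Links two taxa when the absolute Pearson correlation of their profiles
#' strictly exceeds \code{r_min} and the Benjamini-Hochberg adjusted p-value
#' is strictly below \code{q_max} (defaults |r| > 0.8, q < 0.01). The sign
#' of r is stored per edge; taxa without any edge are excluded from the
#' graph.
#'
#' @param table taxa x samples matrix (already filtered as desired).
#' @param r_min correlation threshold (strict).
#' @param q_max adjusted-p threshold (strict).
#' @param transform passed to \code{\link{correlation_edges}}.
#' @return Object of class \code{"co_network"}: list with \code{graph}
#'   (igraph, edge attributes \code{r}, \code{q}, \code{sign}),
#'   \code{edges} data.frame, the thresholds, and \code{empty} flag.
#' @export
build_network <- function(table, r_min = 0.8, q_max = 0.01, transform = NULL) {
  ce <- correlation_edges(table, transform = transform)
  taxa <- rownames(ce$r)
  ut <- upper.tri(ce$r)
  q <- ce$r * 0
  q[ut] <- bh_adjust(ce$p[ut])
  keep <- ut & abs(ce$r) > r_min & q < q_max
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                      r = ce$r[keep], q = q[keep],
                      sign = ifelse(ce$r[keep] > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  net <- list(graph = g, edges = edges, r_min = r_min, q_max = q_max,
              n_taxa_input = length(taxa), empty = nrow(edges) == 0L)
  class(net) <- "co_network"
  net
}

#' @export
print.co_network <- function(x, ...) {
  cat("Co-occurrence network: ", igraph::vcount(x$graph), " nodes, ",
      nrow(x$edges), " edges (|r| > ", x$r_min, ", q < ", x$q_max, ")\n",
      sep = "")
  if (nrow(x$edges))
    cat("  positive/negative edges: ", sum(x$edges$sign > 0), "/",
        sum(x$edges$sign < 0), "\n", sep = "")
  invisible(x)
}

#' Natural connectivity of a graph
#'
#' The spectral robustness measure \code{ln((1/n) sum_i exp(lambda_i))} over
#' the eigenvalues of the unsigned 0/1 adjacency matrix. An edgeless graph
#' has natural connectivity 0; larger values indicate more redundant routes
#' and a more robust network.
#'
#' @param net a \code{co_network} or igraph graph with >= 1 node.
#' @return A single number.
#' @export
natural_connectivity <- function(net) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 1L) stop("natural connectivity undefined for an empty graph",
                   call. = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  a[a != 0] <- 1
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  # stable log-mean-exp
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

# Principal-eigenvector centrality scores from a deterministic (LAPACK)
# symmetric eigendecomposition, scaled to unit maximum. Avoids the
# randomly-started iterative solver so repeated runs are bit-identical.
eigen_scores <- function(g) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) return(rep(0, n))
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  a[a != 0] <- 1
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v / max(v)
}

# Global efficiency: mean of 1/d_ij over ordered pairs (1/Inf = 0).
global_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' Latora-efficiency based: with global efficiency
#' \code{E = (1/(n(n-1))) sum_{i != j} 1/d_ij}, each node i is disabled by
#' deleting its incident edges (the node count is unchanged) giving
#' \code{E_i}; vulnerability is \code{max_i (E - E_i)/E}, the worst relative
#' efficiency loss a single node failure can cause.
#'
#' @param net a \code{co_network} or igraph graph with >= 2 nodes.
#' @return A single number in [0, 1] for connected graphs.
#' @export
vulnerability <- function(net) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("vulnerability needs at least 2 nodes", call. = FALSE)
  e0 <- global_efficiency(g)
  if (e0 == 0) stop("vulnerability undefined for an edgeless graph",
                    call. = FALSE)
  drop <- vapply(seq_len(n), function(i) {
    gi <- igraph::delete_edges(g, igraph::incident(g, i))
    (e0 - global_efficiency(gi)) / e0
  }, numeric(1))
  max(drop)
}

#' Global network attributes
#'
#' Computes the full set of whole-network attributes: node and edge counts,
#' positive/negative edge split, average degree (2E/N), connectance
#' (2E/(N(N-1))), number of clusters (connected components), modularity of
#' the greedy-agglomerative community partition, degree and eigenvector
#' centralization (normalised to the star maximum), natural connectivity
#' and vulnerability. Topological metrics use the unsigned simple graph.
#'
#' @param net a \code{co_network} (or igraph graph, in which case all edges
#'   count as positive).
#' @return Named list of class \code{"network_metrics"}.
#' @export
global_metrics <- function(net) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 1L) stop("empty graph", call. = FALSE)
  m <- igraph::ecount(g)
  sgn <- if (inherits(net, "co_network") && m > 0) net$edges$sign
         else rep(1L, m)
  npos <- sum(sgn > 0); nneg <- sum(sgn < 0)
  comm <- igraph::cluster_fast_greedy(g)
  res <- list(
    n_nodes = n, n_edges = m, n_positive = npos, n_negative = nneg,
    positive_proportion = if (m > 0) npos / m else NA_real_,
    negative_proportion = if (m > 0) nneg / m else NA_real_,
    average_degree = 2 * m / n,
    connectance = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
    n_clusters = igraph::count_components(g),
    modularity = igraph::modularity(comm),
    centralization_degree = igraph::centr_degree(g, loops = FALSE)$centralization,
    centralization_eigen = if (n > 2) {
      sc <- eigen_scores(g)
      sum(max(sc) - sc) / igraph::centr_eigen_tmax(nodes = n)
    } else NA_real_,
    natural_connectivity = natural_connectivity(g),
    vulnerability = if (m > 0 && n > 1) vulnerability(g) else NA_real_
  )
  class(res) <- c("network_metrics", "list")
  res
}

#' Node-level network attributes
#'
#' Per node: degree; closeness \code{(n_c - 1)/sum_j d_ij} computed within
#' the node's connected component (component size \code{n_c}); transitivity
#' (local clustering coefficient, 0 for degree < 2); and eigenvector
#' centrality of the unsigned adjacency, scaled to unit maximum.
#'
#' @param net a \code{co_network} or igraph graph.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{closeness}, \code{transitivity}, \code{eigenvector}.
#' @export
node_metrics <- function(net) {
  g <- as_conet_graph(net)
  n <- igraph::vcount(g)
  if (n < 1L) stop("empty graph", call. = FALSE)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    members <- which(comp$membership == comp$membership[i])
    if (length(members) < 2L) return(0)
    (length(members) - 1) / sum(d[i, members])
  }, numeric(1))
  tra <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  eig <- eigen_scores(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(node = ids, degree = as.integer(deg),
             closeness = clo, transitivity = tra, eigenvector = eig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample subnetwork attributes
#'
#' For each sample, the induced subgraph of the treatment network on the
#' taxa present (abundance > 0) in that sample is extracted, and a compact
#' attribute vector (node count, edge count, average degree, connectance,
#' natural connectivity) is computed. The resulting samples x attributes
#' matrix is the substrate for the "network complexity" PC1 score.
#'
#' @param net a \code{co_network} built from the same taxon universe.
#' @param table taxa x samples matrix.
#' @return samples x 5 numeric matrix with attribute columns; samples with
#'   no network taxon present get a zero row and are listed in the
#'   \code{"absent_samples"} attribute.
#' @export
sample_subnetworks <- function(net, table) {
  g <- as_conet_graph(net)
  table <- validate_otu_table(table)
  cols <- c("n_nodes", "n_edges", "average_degree", "connectance",
            "natural_connectivity")
  out <- base::matrix(0, ncol(table), length(cols),
                      dimnames = list(colnames(table), cols))
  absent <- character(0)
  for (s in colnames(table)) {
    present <- rownames(table)[table[, s] > 0]
    keep <- intersect(igraph::V(g)$name, present)
    if (length(keep) == 0L) { absent <- c(absent, s); next }
    sg <- igraph::induced_subgraph(g, keep)
    nv <- igraph::vcount(sg); ne <- igraph::ecount(sg)
    out[s, ] <- c(nv, ne, 2 * ne / nv,
                  if (nv > 1) 2 * ne / (nv * (nv - 1)) else 0,
                  natural_connectivity(sg))
  }
  attr(out, "absent_samples") <- absent
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  v <- unlist(x)
  cat("Network attributes:\n")
  print(round(v, 4))
  invisible(x)
}
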