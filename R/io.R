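# Table readers/writers and the seeded end-to-end pipeline.

#' Read an OTU table from TSV
#'
#' Expects a tab-separated file whose first column holds taxon IDs and
#' whose header row holds sample IDs. Duplicate IDs and non-numeric cells
#' are rejected with the offending location.
#'
#' @param path file path.
#' @return taxa x samples numeric matrix.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("empty or malformed OTU table: ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate taxon ID(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric abundance at row ", bad[1, 1], ", column ",
         bad[1, 2] + 1L, " of ", path, call. = FALSE)
  }
  rownames(m) <- ids
  storage.mode(m) <- "double"
  validate_otu_table(m)
}

#' Write an OTU table as TSV
#' @param table taxa x samples matrix.
#' @param path file path.
#' @export
write_otu_table <- function(table, path) {
  table <- validate_otu_table(table)
  df <- data.frame(taxon_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, treatment) from TSV
#' @param path file path.
#' @return data.frame with columns \code{sample_id}, \code{treatment}.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "treatment") %in% colnames(df)))
    stop("metadata must have sample_id and treatment columns", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  df
}

#' Read a samples x variables matrix (soil functions, enzymes) from TSV
#' @param path file path.
#' @return numeric matrix with sample rownames.
#' @export
read_soil_functions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric soil-function value in ", path,
                           call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a samples x variables matrix as TSV
#' @param matrix samples x variables matrix with rownames.
#' @param path file path.
#' @export
write_soil_functions <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes GraphML (node degree; edge r, q, sign attributes) and an
#' edge-list CSV next to it.
#'
#' @param net a \code{co_network}.
#' @param path_graphml,path_csv output paths.
#' @export
write_network <- function(net, path_graphml, path_csv) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  igraph::V(g)$degree <- igraph::degree(g)
  if (nrow(net$edges)) {
    igraph::E(g)$r <- net$edges$r
    igraph::E(g)$q <- net$edges$q
    igraph::E(g)$sign <- net$edges$sign
  }
  igraph::write_graph(g, path_graphml, format = "graphml")
  utils::write.csv(net$edges, path_csv, row.names = FALSE)
  invisible(path_graphml)
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full grazed/ungrazed analysis pipeline on synthetic data
#'
#' Orchestrates every stage end to end: data generation, enzyme-limitation
#' vectors, the reflection transforms, the three multifunctionality
#' indices with group tests, one co-occurrence network per treatment and
#' kingdom with global/node/subnetwork attributes, robustness curves and
#' the 50%-removal stability comparison, niche breadth and the
#' dispersal-niche continuum index, and the zero-/first-order correlation
#' battery. All outputs (TSV/CSV/GraphML/JSON) plus a machine-readable
#' manifest recording every seed and threshold are written under
#' \code{out_dir}. Identical config and seed give byte-identical output.
#'
#' @param cfg a \code{\link{synthetic_config}}; its \code{seed} drives
#'   every stage through named substreams.
#' @param out_dir output directory (created if needed).
#' @param r_min,q_max network edge thresholds.
#' @param robustness_reps replicates per robustness-curve fraction.
#' @param stability_reps bootstrap replicates at 50% node removal.
#' @param n_perm DNCI permutations.
#' @param mf_subsets_per_k subset cap for the increasing-functions index.
#' @return Invisible list with the in-memory results of each stage.
#' @export
run_pipeline <- function(cfg, out_dir, r_min = 0.8, q_max = 0.01,
                         robustness_reps = 50, stability_reps = 1000,
                         n_perm = 199, mf_subsets_per_k = 100) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  log_stage <- function(name) message("[soilnetmf] stage: ", name)

  log_stage("datagen")
  tabs <- generate_otu_tables(cfg)
  soil <- generate_soil_functions(cfg)
  meta <- tabs$metadata
  groups <- factor(meta$treatment, levels = c("grazed", "ungrazed"))
  write_otu_table(tabs$bacteria, pth("otu_bacteria.tsv"))
  write_otu_table(tabs$fungi, pth("otu_fungi.tsv"))
  utils::write.table(meta, pth("metadata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_soil_functions(soil, pth("soil_functions.tsv"))
  json_write(tabs$truth, pth("ground_truth.json"))

  log_stage("enzyme_limits")
  vl <- vector_limitation(bg = soil[, "BGC"], nag = soil[, "NAG"],
                          lap = soil[, "LAP"], acp = soil[, "ACP"],
                          trans = "ln")
  vl_out <- data.frame(sample_id = rownames(soil), vl)
  utils::write.table(vl_out, pth("enzyme_limitation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("multifunc")
  prepared <- prepare_functions(soil)
  mf1 <- entropy_mf(prepared, groups = groups)
  mf2 <- entropy_mf_increasing(prepared, groups = groups,
                               max_subsets_per_k = mf_subsets_per_k,
                               seed = substream_seed(cfg$seed, "mf_subsets"))
  mf3 <- threshold_mf(prepared, groups = groups)
  mf_tidy <- rbind(
    data.frame(sample_id = names(mf1$scores), method = "entropy_max",
               k = ncol(prepared), score = unname(mf1$scores)),
    do.call(rbind, lapply(mf2$by_k, function(e)
      data.frame(sample_id = names(e$scores), method = "entropy_increasing",
                 k = e$k, score = unname(e$scores)))),
    do.call(rbind, lapply(seq_along(mf3$thresholds), function(i)
      data.frame(sample_id = rownames(mf3$counts), method = "threshold",
                 k = mf3$thresholds[i], score = mf3$counts[, i]))))
  utils::write.table(mf_tidy, pth("multifunctionality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mf_summary <- list(
    entropy_max = list(
      grazed_mean = mean(mf1$scores[groups == "grazed"]),
      ungrazed_mean = mean(mf1$scores[groups == "ungrazed"]),
      t_p = mf1$group_test$p.value),
    entropy_increasing = list(
      t_p_by_k = vapply(mf2$by_k, function(e) e$group_test$p.value,
                        numeric(1))),
    threshold = list(
      kruskal_p = vapply(mf3$group_tests, function(t) t$p.value, numeric(1))))
  json_write(mf_summary, pth("multifunctionality_summary.json"))

  nets <- list(); net_metrics <- list(); stab <- list(); sub <- list()
  for (k in c("bacteria", "fungi")) {
    for (tr in c("grazed", "ungrazed")) {
      id <- paste(k, tr, sep = "_")
      log_stage(paste("conet", id))
      tab <- tabs[[k]][, meta$treatment == tr, drop = FALSE]
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      net <- build_network(tab, r_min = r_min, q_max = q_max)
      nets[[id]] <- net
      if (net$empty) {
        message("[soilnetmf] network ", id,
                " is empty at these thresholds; robustness skipped")
        next
      }
      write_network(net, pth(paste0("network_", id, ".graphml")),
                    pth(paste0("network_", id, "_edges.csv")))
      net_metrics[[id]] <- global_metrics(net)
      utils::write.table(node_metrics(net),
                         pth(paste0("node_metrics_", id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sub[[id]] <- sample_subnetworks(net, tabs[[k]])
      log_stage(paste("robust", id))
      if (igraph::vcount(net$graph) >= 4) {
        curve <- rbind(
          robustness_curve(net, "nodes", reps = robustness_reps,
                           seed = substream_seed(cfg$seed,
                                                 paste0("curve_n_", id))),
          robustness_curve(net, "edges", reps = robustness_reps,
                           seed = substream_seed(cfg$seed,
                                                 paste0("curve_e_", id))))
        utils::write.table(cbind(network = id, curve),
                           pth(paste0("robustness_", id, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stab[[id]] <- stability_bootstrap(net, fraction = 0.5,
                                          reps = stability_reps,
                                          seed = substream_seed(cfg$seed,
                                            paste0("stability_", id)))
      }
    }
  }
  json_write(lapply(net_metrics, unclass), pth("network_metrics.json"))
  stab_cmp <- list()
  for (k in c("bacteria", "fungi")) {
    a <- stab[[paste0(k, "_grazed")]]; b <- stab[[paste0(k, "_ungrazed")]]
    if (!is.null(a) && !is.null(b))
      stab_cmp[[k]] <- compare_stability(a, b, c("grazed", "ungrazed"))
  }
  json_write(lapply(stab_cmp, unclass), pth("stability_comparison.json"))

  log_stage("niche_dnci")
  niche <- list(); dnci_res <- list()
  for (k in c("bacteria", "fungi")) {
    gtab <- tabs[[k]][, meta$treatment == "grazed", drop = FALSE]
    utab <- tabs[[k]][, meta$treatment == "ungrazed", drop = FALSE]
    gtab <- gtab[rowSums(gtab) > 0, , drop = FALSE]
    utab <- utab[rowSums(utab) > 0, , drop = FALSE]
    niche[[k]] <- compare_breadth(gtab, utab)
    dnci_res[[k]] <- tryCatch(
      dnci(tabs[[k]], meta$treatment, n_perm = n_perm,
           seed = substream_seed(cfg$seed, paste0("dnci_", k))),
      error = function(e) {
        message("[soilnetmf] DNCI skipped for ", k, ": ", conditionMessage(e))
        NULL
      })
    breadth_out <- rbind(
      data.frame(taxon = names(niche[[k]]$breadth_a), treatment = "grazed",
                 breadth = unname(niche[[k]]$breadth_a)),
      data.frame(taxon = names(niche[[k]]$breadth_b), treatment = "ungrazed",
                 breadth = unname(niche[[k]]$breadth_b)))
    utils::write.table(breadth_out, pth(paste0("niche_breadth_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json_write(list(
    breadth = lapply(niche, function(x)
      list(mean_grazed = x$mean_a, mean_ungrazed = x$mean_b,
           wilcoxon_p = x$p_value)),
    dnci = lapply(dnci_res, function(x) {
      if (is.null(x)) return(list(status = "skipped"))
      list(dnci = x$dnci, se = x$dnci_se,
           median_E = vapply(x$E, function(v) stats::median(v[is.finite(v)]),
                             numeric(1)))
    })),
    pth("assembly_summary.json"))

  log_stage("assoc_stats")
  avail <- composite_pc1(soil[, c("AN", "AP", "AK", "ACa", "AMg")])
  phys <- composite_pc1(soil[, c("WC", "BD", "SH", "pH")])
  merged <- data.frame(
    sample_id = meta$sample_id,
    available_elements = avail$scores,
    physical_environment = phys$scores,
    C_limitation = soil[, "C_limitation"],
    multifunctionality = mf1$scores,
    check.names = FALSE)
  if (!is.null(sub$bacteria_grazed) || !is.null(sub$bacteria_ungrazed)) {
    submat <- sub[["bacteria_grazed"]]
    if (is.null(submat)) submat <- sub[["bacteria_ungrazed"]]
    cols <- apply(submat, 2, stats::var) > 0
    if (sum(cols) >= 2) {
      cplx <- composite_pc1(submat[, cols, drop = FALSE])
      merged$bacterial_network_complexity <- cplx$scores[meta$sample_id]
    }
  }
  comp <- tryCatch(composition_axis(tabs$bacteria,
                                    seed = substream_seed(cfg$seed, "nmds")),
                   error = function(e) NULL)
  if (!is.null(comp)) merged$bacterial_composition <- comp$scores
  drivers <- intersect(c("available_elements", "physical_environment",
                         "C_limitation"), colnames(merged))
  responses <- intersect(c("multifunctionality",
                           "bacterial_network_complexity",
                           "bacterial_composition"), colnames(merged))
  battery <- association_battery(merged, drivers, responses,
                                 controls = "C_limitation")
  utils::write.table(merged, pth("analysis_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(battery, pth("association_battery.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "soilnetmf",
    version = as.character(utils::packageVersion("soilnetmf")),
    seed = cfg$seed,
    substreams = list(
      otu_bacteria = substream_seed(cfg$seed, "otu_bacteria"),
      otu_fungi = substream_seed(cfg$seed, "otu_fungi"),
      soil = substream_seed(cfg$seed, "soil"),
      mf_subsets = substream_seed(cfg$seed, "mf_subsets"),
      nmds = substream_seed(cfg$seed, "nmds")),
    thresholds = list(r_min = r_min, q_max = q_max,
                      mf_thresholds = seq(10, 90, 10),
                      stability_fraction = 0.5),
    reps = list(robustness = robustness_reps, stability = stability_reps,
                dnci_permutations = n_perm,
                mf_subsets_per_k = mf_subsets_per_k),
    config = unclass(cfg))
  json_write(manifest, pth("manifest.json"))

  invisible(list(tables = tabs, soil = soil, limitation = vl,
                 mf = list(entropy_max = mf1, entropy_increasing = mf2,
                           threshold = mf3),
                 networks = nets, network_metrics = net_metrics,
                 subnetworks = sub, stability = stab,
                 stability_comparison = stab_cmp,
                 niche = niche, dnci = dnci_res, battery = battery,
                 merged = merged, manifest = manifest))
}
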