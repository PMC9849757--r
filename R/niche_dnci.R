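# Levins niche breadth and PER-SIMPER / dispersal-niche continuum analysis.

#' Levins niche breadth per taxon
#'
#' For taxon i with sample shares \code{p_ij = x_ij / sum_j x_ij}, the
#' breadth is \code{B_i = 1 / sum_j p_ij^2} -- the effective number of
#' samples the taxon occupies (1 = found in a single sample, n = spread
#' uniformly over n samples). All-zero taxa cannot be scored and are
#' excluded (their IDs are kept in the \code{"excluded"} attribute).
#'
#' @param table taxa x samples non-negative matrix.
#' @return Named numeric vector of breadths.
#' @examples
#' m <- rbind(t1 = rep(5, 6), t2 = c(9, 0, 0, 0, 0, 0))
#' colnames(m) <- paste0("s", 1:6)
#' levins_breadth(m)  # 6 and 1
#' @export
levins_breadth <- function(table) {
  if (!is.matrix(table) || !is.numeric(table) || any(table < 0) || anyNA(table))
    stop("table must be a non-negative numeric matrix", call. = FALSE)
  tot <- rowSums(table)
  excluded <- rownames(table)[tot == 0]
  keep <- tot > 0
  p <- sweep(table[keep, , drop = FALSE], 1, tot[keep], "/")
  b <- 1 / rowSums(p^2)
  names(b) <- rownames(table)[keep]
  attr(b, "excluded") <- excluded
  b
}

#' Compare niche-breadth distributions between two communities
#'
#' Computes Levins breadth within each table (e.g. the grazed and ungrazed
#' sample subsets) and compares the two per-taxon breadth vectors with a
#' two-sample Wilcoxon rank-sum test.
#'
#' @param tableA,tableB taxa x samples matrices (breadth computed within
#'   each table's own samples).
#' @return List with \code{breadth_a}, \code{breadth_b}, \code{statistic}
#'   (W), \code{p_value}, and the two means.
#' @export
compare_breadth <- function(tableA, tableB) {
  ba <- levins_breadth(tableA)
  bb <- levins_breadth(tableB)
  if (length(ba) < 3L || length(bb) < 3L)
    stop("need at least 3 scored taxa on each side", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(ba, bb))
  list(breadth_a = ba, breadth_b = bb,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_a = mean(ba), mean_b = mean(bb))
}

# Core SIMPER decomposition. Per between-group sample pair (i, j) the
# Bray-Curtis dissimilarity decomposes per taxon k as
# |x_ik - x_jk| / sum_l (x_il + x_jl); a taxon's contribution is the mean
# over pairs. Pairs whose two samples are entirely zero are undefined and
# (for permuted matrices) skipped.
simper_contributions <- function(table, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("SIMPER needs exactly 2 groups", call. = FALSE)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  acc <- numeric(nrow(table))
  npair <- 0L
  for (i in ia) for (j in ib) {
    denom <- sum(table[, i] + table[, j])
    if (denom == 0) next
    acc <- acc + abs(table[, i] - table[, j]) / denom
    npair <- npair + 1L
  }
  if (npair == 0L)
    stop("no between-group pair with nonzero total abundance", call. = FALSE)
  acc / npair
}

#' SIMPER profile: per-taxon contributions to between-group dissimilarity
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into
#' per-taxon contributions, expressed as percentages of their sum and
#' sorted in decreasing order.
#'
#' @param table taxa x samples matrix.
#' @param groups two-level factor over samples.
#' @return Named numeric vector (percent, sums to 100), sorted descending.
#' @export
simper_profile <- function(table, groups) {
  if (!is.matrix(table) || ncol(table) != length(groups))
    stop("groups must label every sample column", call. = FALSE)
  contr <- simper_contributions(table, groups)
  total <- sum(contr)
  if (total == 0)
    stop("groups are indistinguishable: all between-group dissimilarities are 0",
         call. = FALSE)
  out <- 100 * contr / total
  names(out) <- rownames(table)
  sort(out, decreasing = TRUE)
}

dnci_schemes <- c(fix_taxa = "r0", fix_sites = "c0", fix_both = "curveball")
scheme_labels <- c(fix_taxa = "dispersal-controlled",
                   fix_sites = "niche-controlled",
                   fix_both = "niche-and-dispersal-controlled")

#' PER-SIMPER null distribution of profile deviations (E-values)
#'
#' Transforms the table to presence/absence, computes the observed sorted
#' SIMPER profile, and generates \code{n_perm} null matrices preserving
#' taxon occupancy totals (\code{fix_taxa}, "dispersal-controlled"), sample
#' richness totals (\code{fix_sites}, "niche-controlled"), or both
#' (\code{fix_both}, curveball swaps), via \code{vegan::nullmodel}. For
#' each permutation the sorted profile is recomputed and
#' \code{E = log10(sum_ranks (obs_k - perm_k)^2)} recorded; an exact-zero
#' deviation yields \code{-Inf}. Lower E means the constraint reproduces
#' the observed taxon-contribution structure better.
#'
#' @param table taxa x samples matrix.
#' @param groups two-level factor over samples.
#' @param scheme one of \code{"fix_taxa"}, \code{"fix_sites"},
#'   \code{"fix_both"}.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return Numeric vector of E-values of length \code{n_perm}, with
#'   attributes \code{"scheme"} and \code{"label"}.
#' @export
per_simper <- function(table, groups, scheme = c("fix_taxa", "fix_sites",
                                                 "fix_both"),
                       n_perm = 999, seed = 1) {
  scheme <- match.arg(scheme)
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  pa <- (table > 0) * 1
  obs <- sort(simper_contributions(pa, groups), decreasing = TRUE)
  obs <- 100 * obs / sum(obs)
  nm <- vegan::nullmodel(pa, dnci_schemes[[scheme]])
  perms <- stats::simulate(nm, nsim = n_perm, seed = substream_seed(seed, scheme))
  e <- vapply(seq_len(n_perm), function(i) {
    m <- perms[, , i]
    contr <- tryCatch(simper_contributions(m, groups), error = function(e) NULL)
    if (is.null(contr) || sum(contr) == 0) return(NA_real_)
    prof <- sort(100 * contr / sum(contr), decreasing = TRUE)
    ss <- sum((obs - prof)^2)
    if (ss == 0) -Inf else log10(ss)
  }, numeric(1))
  if (anyNA(e))
    warning(sum(is.na(e)), " degenerate permutation(s) dropped", call. = FALSE)
  e <- e[!is.na(e)]
  attr(e, "scheme") <- scheme
  attr(e, "label") <- scheme_labels[[scheme]]
  e
}

#' Dispersal-niche continuum index
#'
#' Runs all three PER-SIMPER null schemes and summarises where the
#' community sits on the dispersal-niche continuum. E-values from each
#' scheme are standardised against the both-fixed (curveball) null:
#' \code{d_scheme = (E_scheme - mean(E_both)) / sd(E_both)}, and
#' \code{DNCI = mean(d_niche) - mean(d_dispersal)}. Negative values
#' indicate niche dominance (the niche-controlled null reproduces the
#' observed SIMPER profile better), positive values dispersal dominance.
#' Infinite sentinels from exactly-invariant permutations are excluded
#' from the summary statistic.
#'
#' @inheritParams per_simper
#' @return List of class \code{"dnci_result"}: \code{profile} (observed
#'   abundance-based SIMPER profile), \code{E} (list of the three E-value
#'   distributions), \code{dnci}, \code{dnci_se}, \code{n_perm},
#'   \code{seed}.
#' @export
dnci <- function(table, groups, n_perm = 999, seed = 1) {
  e <- lapply(c("fix_taxa", "fix_sites", "fix_both"), function(s)
    per_simper(table, groups, s, n_perm = n_perm, seed = seed))
  names(e) <- c("fix_taxa", "fix_sites", "fix_both")
  finite <- lapply(e, function(v) v[is.finite(v)])
  if (any(lengths(finite) < 2L))
    stop("too few finite E-values to standardise", call. = FALSE)
  mb <- mean(finite$fix_both); sb <- stats::sd(finite$fix_both)
  if (sb == 0) stop("degenerate both-fixed null (zero spread)", call. = FALSE)
  d_niche <- (finite$fix_sites - mb) / sb
  d_disp <- (finite$fix_taxa - mb) / sb
  val <- mean(d_niche) - mean(d_disp)
  se <- sqrt(stats::var(d_niche) / length(d_niche) +
             stats::var(d_disp) / length(d_disp))
  res <- list(profile = simper_profile(table, groups), E = e,
              dnci = val, dnci_se = se, n_perm = n_perm, seed = seed)
  class(res) <- "dnci_result"
  res
}

#' @export
print.dnci_result <- function(x, ...) {
  cat("Dispersal-niche continuum index: ", signif(x$dnci, 4),
      " (se ", signif(x$dnci_se, 3), ", ", x$n_perm, " permutations)\n",
      sep = "")
  cat("  interpretation: ", if (x$dnci < 0) "niche" else "dispersal",
      " processes dominate\n", sep = "")
  med <- vapply(x$E, function(v) stats::median(v[is.finite(v)]), numeric(1))
  cat("  median E by null scheme:\n")
  print(round(med, 3))
  invisible(x)
}
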