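# Soil multifunctionality: reflection preparation, entropy-weighted index
# (maximum and increasing numbers of functions) and threshold counting.

#' Canonical soil-function names
#'
#' The fifteen soil properties entering multifunctionality by default:
#' available N/P/K/Ca/Mg, pH, water content, bulk density, soil hardness,
#' four extracellular enzyme activities, microbial C limitation (vector
#' length) and the N/P-limitation vector angle.
#' @export
soil_function_names <- c("AN", "AP", "AK", "ACa", "AMg", "pH", "WC", "BD",
                         "SH", "BGC", "NAG", "LAP", "ACP", "C_limitation",
                         "vector_angle")

# Functions whose raw direction is "high = bad": reflected before scoring.
reflect_default <- c("C_limitation", "SH", "BD", "vector_angle")

#' Prepare a soil-function matrix for multifunctionality scoring
#'
#' Reflects the "bad-is-high" functions so that a high value always
#' corresponds to the desired good state: \code{vector_angle} is folded
#' about 45 degrees (\code{\link{reflect_angle}}), every other requested
#' function is mapped through \code{r(f) = -f + max(f)}
#' (\code{\link{reflect_negative}}). Reflection state is tracked in the
#' \code{"reflected"} attribute and a function cannot be reflected twice.
#'
#' @param matrix samples x functions numeric matrix with column names.
#' @param reflect character vector of function names to reflect; default is
#'   the intersection of \code{c("C_limitation","SH","BD","vector_angle")}
#'   with the columns present.
#' @return The matrix with reflected columns and updated
#'   \code{"reflected"} attribute (named logical vector).
#' @export
prepare_functions <- function(matrix, reflect = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix) || is.null(colnames(matrix)))
    stop("matrix must be a numeric samples x functions matrix with column names",
         call. = FALSE)
  if (anyNA(matrix)) stop("matrix contains missing values", call. = FALSE)
  if (is.null(reflect)) reflect <- intersect(reflect_default, colnames(matrix))
  bad <- setdiff(reflect, colnames(matrix))
  if (length(bad))
    stop("unknown function name(s) in reflect: ", paste(bad, collapse = ", "),
         call. = FALSE)
  flags <- attr(matrix, "reflected")
  if (is.null(flags)) {
    flags <- stats::setNames(rep(FALSE, ncol(matrix)), colnames(matrix))
  }
  already <- reflect[flags[reflect]]
  if (length(already))
    stop("function(s) already reflected: ", paste(already, collapse = ", "),
         call. = FALSE)
  for (fn in reflect) {
    matrix[, fn] <- if (fn == "vector_angle") reflect_angle(matrix[, fn])
                    else reflect_negative(matrix[, fn])
    flags[fn] <- TRUE
  }
  attr(matrix, "reflected") <- flags
  matrix
}

# Min-max normalise columns to [0, 1]; constant columns map to 0 and are
# reported in the "constant" attribute (they receive entropy weight 0).
minmax_columns <- function(m) {
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  out <- sweep(m, 2, rng[1, ], "-")
  out[, !const] <- sweep(out[, !const, drop = FALSE], 2, span[!const], "/")
  out[, const] <- 0
  attr(out, "constant") <- const
  out
}

#' Entropy-weighted multifunctionality (maximum number of functions)
#'
#' Each function is min-max normalised across samples; per-function
#' information entropy of the sample shares \code{p_ij = x'_ij / sum_i x'_ij}
#' is \code{E_j = -(1/ln n) sum_i p_ij ln p_ij} (with 0 ln 0 = 0); the
#' divergence \code{d_j = 1 - E_j} yields weights \code{w_j = d_j / sum d},
#' and the multifunctionality of sample i is \code{MF_i = sum_j w_j x'_ij}.
#' If every function is constant, equal weights are used and the result is
#' flagged degenerate.
#'
#' @param matrix prepared samples x functions matrix
#'   (see \code{\link{prepare_functions}}).
#' @param groups optional factor/character of length \code{nrow(matrix)};
#'   when given with two levels, a Welch two-sample t-test between groups is
#'   attached.
#' @return List of class \code{"mf_result"}: \code{method}, \code{scores}
#'   (named per-sample), \code{weights}, \code{degenerate} flag and, when
#'   groups are supplied, \code{group_test} (htest).
#' @export
entropy_mf <- function(matrix, groups = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) < 2L)
    stop("entropy multifunctionality needs a matrix with >= 2 samples",
         call. = FALSE)
  if (ncol(matrix) < 1L) stop("need at least one function", call. = FALSE)
  xn <- minmax_columns(matrix)
  n <- nrow(xn)
  colsum <- colSums(xn)
  ej <- vapply(seq_len(ncol(xn)), function(j) {
    if (colsum[j] == 0) return(1)          # constant function: no information
    p <- xn[, j] / colsum[j]
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  }, numeric(1))
  d <- 1 - ej
  degenerate <- all(d <= 0)
  w <- if (degenerate) rep(1 / ncol(xn), ncol(xn)) else d / sum(d)
  names(w) <- colnames(matrix)
  scores <- as.numeric(xn %*% w)
  names(scores) <- rownames(matrix)
  if (degenerate)
    warning("all functions constant: equal entropy weights used", call. = FALSE)
  res <- list(method = "entropy_max", scores = scores, weights = w,
              degenerate = degenerate)
  if (!is.null(groups)) res$group_test <- mf_group_ttest(scores, groups)
  class(res) <- "mf_result"
  res
}

mf_group_ttest <- function(scores, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("group tests need exactly two treatment levels", call. = FALSE)
  stats::t.test(scores ~ groups)
}

#' Entropy multifunctionality over increasing numbers of functions
#'
#' For each subset size k = 1..J, enumerates all function subsets when
#' \code{choose(J, k) <= max_subsets_per_k}, otherwise draws
#' \code{max_subsets_per_k} distinct subsets uniformly (seeded). The
#' entropy-weighted multifunctionality is computed on each subset; per k the
#' per-sample mean score over subsets is returned, with a Welch t-test
#' between treatments when groups are supplied.
#'
#' @inheritParams entropy_mf
#' @param max_subsets_per_k cap on sampled subsets per k (default 500).
#' @param seed integer seed for subset sampling.
#' @return List of class \code{"mf_result"}: \code{method}, \code{by_k}
#'   (list per k with \code{n_subsets}, \code{scores} = per-sample
#'   subset-mean, and \code{group_test} when groups given), and
#'   \code{scores} = per-sample grand mean across k.
#' @export
entropy_mf_increasing <- function(matrix, groups = NULL,
                                  max_subsets_per_k = 500, seed = 1) {
  if (!is.matrix(matrix) || nrow(matrix) < 2L)
    stop("need a matrix with >= 2 samples", call. = FALSE)
  if (max_subsets_per_k < 1) stop("max_subsets_per_k must be >= 1", call. = FALSE)
  J <- ncol(matrix)
  by_k <- with_seed(seed, lapply(seq_len(J), function(k) {
    n_all <- choose(J, k)
    subsets <- if (n_all <= max_subsets_per_k) {
      utils::combn(J, k, simplify = FALSE)
    } else {
      # draw distinct subsets uniformly via rejection on sorted index keys
      seen <- new.env(hash = TRUE)
      out <- vector("list", max_subsets_per_k)
      got <- 0L
      while (got < max_subsets_per_k) {
        s <- sort(sample.int(J, k))
        key <- paste(s, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- s
        }
      }
      out
    }
    score_mat <- vapply(subsets, function(s) {
      suppressWarnings(entropy_mf(matrix[, s, drop = FALSE])$scores)
    }, numeric(nrow(matrix)))
    sc <- rowMeans(score_mat)
    names(sc) <- rownames(matrix)
    entry <- list(k = k, n_subsets = length(subsets), scores = sc)
    if (!is.null(groups)) entry$group_test <- mf_group_ttest(sc, groups)
    entry
  }))
  grand <- rowMeans(vapply(by_k, `[[`, numeric(nrow(matrix)), "scores"))
  names(grand) <- rownames(matrix)
  res <- list(method = "entropy_increasing", by_k = by_k, scores = grand)
  class(res) <- "mf_result"
  res
}

#' Threshold-approach multifunctionality
#'
#' For each function a reference maximum is computed (\code{"max"}: the
#' maximum across samples; \code{"top5pct_mean"}: the mean of the top 5% of
#' values, at least the single largest). Per sample and threshold t (percent)
#' the index is the count of functions whose value is at least
#' \code{(t/100) * reference}. Functions with reference 0 are excluded with
#' a warning. A Kruskal-Wallis test between treatments is attached per
#' threshold when groups are supplied.
#'
#' @inheritParams entropy_mf
#' @param thresholds numeric percents, each in (0, 100); default 10..90 by 10.
#' @param max_rule reference-maximum rule.
#' @return List of class \code{"mf_result"}: \code{counts} (samples x
#'   thresholds integer matrix), \code{reference} (per function),
#'   \code{excluded}, and \code{group_tests} (list per threshold) when
#'   groups are supplied.
#' @export
threshold_mf <- function(matrix, groups = NULL, thresholds = seq(10, 90, 10),
                         max_rule = c("max", "top5pct_mean")) {
  max_rule <- match.arg(max_rule)
  if (!is.matrix(matrix) || nrow(matrix) < 1L)
    stop("matrix must be a samples x functions matrix", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 100))
    stop("thresholds must lie strictly between 0 and 100", call. = FALSE)
  ref <- apply(matrix, 2, function(v) {
    if (max_rule == "max") max(v)
    else mean(sort(v, decreasing = TRUE)[seq_len(max(1L, ceiling(0.05 * length(v))))])
  })
  excluded <- names(ref)[ref == 0]
  if (length(excluded)) {
    warning("function(s) with zero reference excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    matrix <- matrix[, ref != 0, drop = FALSE]
    ref <- ref[ref != 0]
  }
  counts <- vapply(thresholds, function(t) {
    as.integer(rowSums(sweep(matrix, 2, (t / 100) * ref, ">=")))
  }, integer(nrow(matrix)))
  counts <- base::matrix(counts, nrow = nrow(matrix),
                         dimnames = list(rownames(matrix),
                                         paste0("t", thresholds)))
  res <- list(method = "threshold", counts = counts, thresholds = thresholds,
              reference = ref, excluded = excluded, max_rule = max_rule)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    res$group_tests <- lapply(seq_along(thresholds), function(i) {
      stats::kruskal.test(counts[, i], groups)
    })
    names(res$group_tests) <- colnames(counts)
  }
  class(res) <- "mf_result"
  res
}

#' @export
print.mf_result <- function(x, ...) {
  cat("Soil multifunctionality (", x$method, ")\n", sep = "")
  if (!is.null(x$scores)) {
    cat("  per-sample scores:\n")
    print(round(x$scores, 4))
  }
  if (!is.null(x$counts)) {
    cat("  function counts by threshold:\n")
    print(x$counts)
  }
  invisible(x)
}
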