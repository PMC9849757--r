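# Composite variables (PC1, ordination axis) and zero-/first-order Pearson
# correlation dissection.

#' First-principal-component composite score
#'
#' Standardises the variables (z-scores), extracts the first principal
#' axis, and orients its sign deterministically: the score must correlate
#' positively with the |loading|-weighted mean of the standardised
#' variables. Constant variables are dropped with a warning.
#'
#' @param matrix samples x variables numeric matrix (>= 3 samples,
#'   >= 2 variables).
#' @return List of class \code{"composite_scores"}: \code{scores} (named,
#'   zero mean, unit standard deviation, so the composite is invariant to
#'   duplicating the variable set), \code{variance_explained},
#'   \code{loadings}, \code{flipped} (orientation flag).
#' @export
composite_pc1 <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 3L || ncol(matrix) < 2L)
    stop("need a samples x variables matrix with >= 3 samples and >= 2 variables",
         call. = FALSE)
  v <- apply(matrix, 2, stats::var)
  if (all(v == 0)) stop("all variables constant", call. = FALSE)
  if (any(v == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(matrix)[v == 0], collapse = ", "), call. = FALSE)
    matrix <- matrix[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  z <- scale(matrix)
  anchor <- as.numeric(z %*% abs(loadings))
  flipped <- FALSE
  cc <- suppressWarnings(stats::cor(scores, anchor))
  if (!is.na(cc) && cc < 0) {
    scores <- -scores; loadings <- -loadings; flipped <- TRUE
  }
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores <- scores / stats::sd(scores)
  res <- list(scores = stats::setNames(as.numeric(scores), rownames(matrix)),
              variance_explained = ve, loadings = loadings, flipped = flipped)
  class(res) <- "composite_scores"
  res
}

#' Community-composition axis (NMDS1)
#'
#' Bray-Curtis dissimilarities on per-sample relative abundances are
#' ordinated with two-axis non-metric multidimensional scaling (seeded
#' random restarts, minimal stress retained); if NMDS fails or the
#' configuration is degenerate, metric principal coordinates are used as a
#' fallback. Axis-1 scores are oriented to correlate positively with the
#' most abundant taxon's relative abundance (ties broken by first
#' occurrence).
#'
#' @param table taxa x samples matrix with >= 4 samples.
#' @param restarts number of seeded NMDS restarts (default 16).
#' @param seed integer seed.
#' @return \code{"composite_scores"} list: \code{scores} (NMDS1 per
#'   sample), \code{stress}, \code{method} ("nmds" or "pcoa"),
#'   \code{flipped}.
#' @export
composition_axis <- function(table, restarts = 16, seed = 1) {
  table <- validate_otu_table(table)
  if (ncol(table) < 4L) stop("need at least 4 samples", call. = FALSE)
  rel <- sweep(table, 2, colSums(table), "/")
  comm <- t(rel)                       # vegan convention: sites x species
  d <- vegan::vegdist(comm, method = "bray")
  if (all(d == 0))
    stop("all samples identical: ordination undefined", call. = FALSE)
  # near-zero stress on tightly clustered data is reported via $stress,
  # so metaMDS's warning to that effect is muted
  fit <- with_seed(substream_seed(seed, "nmds"), tryCatch(
    suppressWarnings(
      vegan::metaMDS(comm, k = 2, distance = "bray", trymax = restarts,
                     trace = 0, autotransform = FALSE, wascores = FALSE)),
    error = function(e) NULL))
  if (!is.null(fit) && is.finite(fit$stress)) {
    scores <- vegan::scores(fit, display = "sites")[, 1]
    method <- "nmds"; stress <- fit$stress
  } else {
    pco <- stats::cmdscale(d, k = 2)
    scores <- pco[, 1]
    method <- "pcoa"; stress <- NA_real_
  }
  top <- which.max(rowMeans(rel))[1]
  flipped <- FALSE
  cc <- suppressWarnings(stats::cor(scores, rel[top, ]))
  if (!is.na(cc) && cc < 0) { scores <- -scores; flipped <- TRUE }
  res <- list(scores = stats::setNames(as.numeric(scores), colnames(table)),
              stress = stress, method = method, flipped = flipped,
              orientation_taxon = rownames(table)[top])
  class(res) <- "composite_scores"
  res
}

#' Zero-order Pearson correlation
#'
#' Pearson correlation with a two-sided p-value from the t-distribution
#' with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
zero_order <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' First-order (single-control) partial Pearson correlation
#'
#' \code{r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))},
#' with a two-sided p-value from the t-distribution with n - 3 degrees of
#' freedom. When a controlling correlation is +-1 the partial correlation
#' is undefined and an error is raised.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return List with \code{r}, \code{p}, \code{n}, \code{control_r}
#'   (the two controlling correlations).
#' @export
partial_first_order <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4L)
    stop("x, y, z must have equal length >= 4", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0)
    stop("zero-variance input", call. = FALSE)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("partial correlation undefined: a control correlation is +-1",
         call. = FALSE)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(max(r, -1), 1)
  df <- n - 3
  tt <- abs(r) * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = df, lower.tail = FALSE)
  list(r = r, p = p, n = n, control_r = c(xz = rxz, yz = ryz))
}

#' Zero- and first-order correlation battery
#'
#' For every driver-response pair, computes the zero-order Pearson
#' correlation and, per control variable, the first-order partial
#' correlation. P-values are reported unadjusted by default (set
#' \code{adjust = "BH"} for a false-discovery-rate adjustment across the
#' battery). Degenerate entries (a control identical to the driver or
#' response) are flagged rather than failing the battery.
#'
#' @param data samples x variables numeric matrix or data.frame with named
#'   columns.
#' @param drivers,responses,controls character vectors of column names.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with columns \code{driver}, \code{response},
#'   \code{order} ("zero" or "first"), \code{control}, \code{r}, \code{p},
#'   \code{n}, \code{flag}.
#' @export
association_battery <- function(data, drivers, responses, controls = character(0),
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  data <- as.data.frame(data)
  need <- unique(c(drivers, responses, controls))
  missing <- setdiff(need, colnames(data))
  if (length(missing))
    stop("variables not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (dv in drivers) for (rv in responses) {
    z0 <- tryCatch(zero_order(data[[dv]], data[[rv]]), error = function(e) e)
    rows[[length(rows) + 1L]] <-
      if (inherits(z0, "error"))
        data.frame(driver = dv, response = rv, order = "zero", control = NA,
                   r = NA_real_, p = NA_real_, n = nrow(data),
                   flag = conditionMessage(z0))
      else
        data.frame(driver = dv, response = rv, order = "zero", control = NA,
                   r = z0$r, p = z0$p, n = z0$n, flag = "")
    for (cv in controls) {
      p1 <- tryCatch(partial_first_order(data[[dv]], data[[rv]], data[[cv]]),
                     error = function(e) e)
      rows[[length(rows) + 1L]] <-
        if (inherits(p1, "error"))
          data.frame(driver = dv, response = rv, order = "first", control = cv,
                     r = NA_real_, p = NA_real_, n = nrow(data),
                     flag = conditionMessage(p1))
        else
          data.frame(driver = dv, response = rv, order = "first", control = cv,
                     r = p1$r, p = p1$p, n = p1$n, flag = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") out$q <- bh_adjust(ifelse(is.na(out$p), 1, out$p))
  out
}
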