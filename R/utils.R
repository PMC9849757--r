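#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a root seed and a stage name
#'
#' All randomness in the package flows from one root seed; each stage draws
#' its own substream seed so stages are independently reproducible.
#'
#' @param root integer root seed.
#' @param name character stage name.
#' @return A single integer in [0, 2^31 - 1).
#' @export
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name),
            length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(root) %% 2147483647 + h) %% 2147483647)
}

# Run code with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Validate a taxa x samples abundance matrix.
validate_otu_table <- function(x, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix (taxa x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(arg, " must have taxon rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon IDs in ", arg, ": ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample IDs in ", arg, call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop(arg, " must be non-negative with no missing values", call. = FALSE)
  if (any(colSums(x) <= 0))
    stop("every sample column of ", arg, " must have positive total",
         call. = FALSE)
  x
}

# Accept a co_network or a bare igraph object.
as_conet_graph <- function(net) {
  if (inherits(net, "co_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  stop("expected a 'co_network' or an igraph graph", call. = FALSE)
}
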