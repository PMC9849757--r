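# Synthetic grazed/ungrazed study generator: compositional OTU count tables
# with planted co-abundance blocks, and a 15-variable soil-function matrix
# with planted treatment effects, all with known ground truth.

# Ungrazed baseline means for the 15 soil functions. Units: mg/kg for
# available elements, % for WC, g/cm3 for BD, kg/cm2 for SH, nmol/g/h for
# enzyme activities; C_limitation is the (unitless) enzyme vector length and
# vector_angle is in degrees.
soil_baselines <- c(AN = 120, AP = 15, AK = 150, ACa = 800, AMg = 120,
                    pH = 5.8, WC = 30, BD = 1.0, SH = 2.0, BGC = 40,
                    NAG = 25, LAP = 30, ACP = 60, C_limitation = 0.65,
                    vector_angle = 38)

# Replicate-to-replicate noise: log-scale SD for multiplicative variables
# (field CVs: precise physical measurements ~10-15%, penetrometer hardness
# and available nutrients 30-40%, ratio-derived limitation indices tight),
# absolute SD for the additive ones (pH, vector_angle).
soil_noise_sd <- c(AN = 0.3, AP = 0.3, AK = 0.3, ACa = 0.3, AMg = 0.3,
                   pH = 0.2, WC = 0.15, BD = 0.1, SH = 0.4, BGC = 0.25,
                   NAG = 0.25, LAP = 0.25, ACP = 0.25, C_limitation = 0.12,
                   vector_angle = 4)

soil_additive_vars <- c("pH", "vector_angle")

# Grazed-vs-ungrazed treatment effects as printed: multiplicative ratios
# (a "+6.5 times increase" is ratio 7.5) except pH (+0.5 unit) and the
# vector angle (ungrazed below 45 degrees, grazed crossing 45).
default_effects <- list(
  mult = c(SH = 7.5, ACa = 2.9, AMg = 2.9, BD = 1.59, BGC = 1.9,
           ACP = 1.08, C_limitation = 1.78, WC = 0.53, AP = 0.27),
  add = c(pH = 0.5, vector_angle = 7)
)

default_blocks <- function(kingdom) {
  if (kingdom == "bacteria")
    list(list(size = 12, rho = 0.99, treatment = "grazed"),
         list(size = 10, rho = 0.99, treatment = "grazed"),
         list(size = 8,  rho = 0.99, treatment = "grazed"),
         list(size = 8,  rho = 0.99, treatment = "ungrazed"),
         list(size = 6,  rho = 0.99, treatment = "ungrazed"))
  else
    list(list(size = 8, rho = 0.99, treatment = "grazed"),
         list(size = 6, rho = 0.99, treatment = "grazed"),
         list(size = 5, rho = 0.99, treatment = "ungrazed"))
}

#' Configuration for the synthetic grazed/ungrazed generator
#'
#' Defines the emulated study conditions: two treatments (grazed/ungrazed)
#' with \code{n_per_group} replicates each (default 3, the triplicate
#' design), bacterial and fungal compositional count tables with planted
#' co-abundance blocks whose number and size differ by treatment (the
#' grazed community carries more and larger blocks, so its co-occurrence
#' network is denser), a mild compositional turnover between treatments,
#' an occupancy restriction on grazed background taxa (narrowing niche
#' breadth), and a 15-variable soil-function matrix whose treatment
#' effects default to the printed fold-changes.
#'
#' @param n_per_group samples per treatment (>= 3; default 3).
#' @param n_taxa_bacteria,n_taxa_fungi taxon counts (defaults 300 / 150).
#' @param depth expected sequencing depth per sample (default 50000).
#' @param blocks_bacteria,blocks_fungi lists of planted co-abundance
#'   blocks, each \code{list(size, rho, treatment)} with \code{rho} the
#'   within-block latent correlation target in (0, 1).
#' @param effect_table list with numeric vectors \code{mult}
#'   (multiplicative grazed/ungrazed ratios) and \code{add} (additive
#'   shifts), named by soil-function; defaults to the printed effects.
#'   Variables not named receive no planted effect.
#' @param noise_sd log-scale residual SD of taxon abundances (default 0.8).
#' @param mu_sd log-scale SD of between-taxon mean abundances (default 1.2).
#' @param comp_shift log-scale SD of the per-taxon grazed compositional
#'   offset (treatment turnover; default 0.5).
#' @param occupancy_drop named numeric: probability that a background
#'   (non-block) taxon's count is zeroed in a sample of each treatment;
#'   default \code{c(grazed = 0.1, ungrazed = 0)} (the grazed community
#'   occupies fewer samples, reducing niche breadth).
#' @param limitation one of \code{"direct"} (generate C_limitation and
#'   vector_angle columns directly with their printed effects; default) or
#'   \code{"enzymes"} (recompute both from the generated enzyme activities
#'   via \code{\link{vector_limitation}}).
#' @param seed integer root seed; identical config and seed give
#'   bit-identical output.
#' @return List of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_per_group = 3,
                             n_taxa_bacteria = 300, n_taxa_fungi = 150,
                             depth = 50000,
                             blocks_bacteria = default_blocks("bacteria"),
                             blocks_fungi = default_blocks("fungi"),
                             effect_table = default_effects,
                             noise_sd = 0.8, mu_sd = 1.2, comp_shift = 0.5,
                             occupancy_drop = c(grazed = 0.1, ungrazed = 0),
                             limitation = c("direct", "enzymes"),
                             seed = 1) {
  limitation <- match.arg(limitation)
  cfg <- list(n_per_group = n_per_group,
              n_taxa_bacteria = n_taxa_bacteria, n_taxa_fungi = n_taxa_fungi,
              depth = depth, blocks_bacteria = blocks_bacteria,
              blocks_fungi = blocks_fungi, effect_table = effect_table,
              noise_sd = noise_sd, mu_sd = mu_sd, comp_shift = comp_shift,
              occupancy_drop = occupancy_drop, limitation = limitation,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 3)
    stop("invalid config: n_per_group must be >= 3", call. = FALSE)
  for (k in c("bacteria", "fungi")) {
    blocks <- cfg[[paste0("blocks_", k)]]
    ntax <- cfg[[paste0("n_taxa_", k)]]
    if (ntax < 1) stop("invalid config: n_taxa_", k, call. = FALSE)
    for (b in blocks) {
      if (!all(c("size", "rho", "treatment") %in% names(b)))
        stop("invalid config: blocks_", k,
             " entries need size, rho, treatment", call. = FALSE)
      if (b$size < 2 || b$size > ntax)
        stop("invalid config: blocks_", k, " block size out of range",
             call. = FALSE)
      if (b$rho <= 0 || b$rho >= 1)
        stop("invalid config: blocks_", k,
             " correlation target must lie in (0, 1)", call. = FALSE)
      if (!b$treatment %in% c("grazed", "ungrazed"))
        stop("invalid config: blocks_", k,
             " treatment must be 'grazed' or 'ungrazed'", call. = FALSE)
    }
    if (sum(vapply(blocks, `[[`, numeric(1), "size")) > ntax)
      stop("invalid config: blocks_", k, " exceed the taxon count",
           call. = FALSE)
  }
  eff <- cfg$effect_table
  unknown <- setdiff(c(names(eff$mult), names(eff$add)),
                     names(soil_baselines))
  if (length(unknown))
    stop("invalid config: unknown soil variable in effect_table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(cfg$occupancy_drop < 0 | cfg$occupancy_drop >= 1))
    stop("invalid config: occupancy_drop must lie in [0, 1)", call. = FALSE)
  invisible(cfg)
}

sample_ids <- function(n_per_group) {
  c(paste0("G", seq_len(n_per_group)), paste0("U", seq_len(n_per_group)))
}

generate_one_table <- function(cfg, kingdom, seed) {
  n <- cfg$n_per_group
  ntax <- cfg[[paste0("n_taxa_", kingdom)]]
  blocks <- cfg[[paste0("blocks_", kingdom)]]
  samples <- sample_ids(n)
  treatment <- rep(c("grazed", "ungrazed"), each = n)
  prefix <- if (kingdom == "bacteria") "B_OTU" else "F_OTU"
  taxa <- sprintf("%s%03d", prefix, seq_len(ntax))

  with_seed(seed, {
    base_mu <- log(cfg$depth / ntax)
    mu <- stats::rnorm(ntax, base_mu, cfg$mu_sd)
    # block taxa kept at moderate abundance: planted modules emulate the
    # abundant core taxa that co-occurrence analysis actually detects
    membership <- rep(0L, ntax)
    pos <- 1L
    for (bi in seq_along(blocks)) {
      idx <- pos:(pos + blocks[[bi]]$size - 1L)
      membership[idx] <- bi
      mu[idx] <- stats::rnorm(length(idx), base_mu + 0.7, 0.4)
      pos <- pos + blocks[[bi]]$size
    }
    # grazed/ungrazed compositional turnover for background taxa
    shift <- stats::rnorm(ntax, 0, cfg$comp_shift)
    shift[membership > 0L] <- 0

    logabund <- base::matrix(0, ntax, 2L * n,
                             dimnames = list(taxa, samples))
    for (j in seq_len(2L * n)) {
      eps <- stats::rnorm(ntax, 0, 1)
      x <- mu + cfg$noise_sd * eps
      if (treatment[j] == "grazed") x <- x + shift
      for (bi in seq_along(blocks)) {
        if (blocks[[bi]]$treatment != treatment[j]) next
        idx <- which(membership == bi)
        f <- stats::rnorm(1)
        rho <- blocks[[bi]]$rho
        x[idx] <- mu[idx] +
          cfg$noise_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps[idx])
      }
      logabund[, j] <- x
    }
    lambda <- exp(logabund)
    lambda <- sweep(lambda, 2, colSums(lambda), "/") * cfg$depth
    counts <- base::matrix(stats::rpois(length(lambda), lambda),
                           nrow(lambda), ncol(lambda),
                           dimnames = dimnames(lambda))
    # occupancy restriction on background taxa
    for (tr in c("grazed", "ungrazed")) {
      pdrop <- unname(cfg$occupancy_drop[tr])
      if (is.na(pdrop) || pdrop == 0) next
      cols <- which(treatment == tr)
      bg <- which(membership == 0L)
      drop <- base::matrix(stats::runif(length(bg) * length(cols)) < pdrop,
                           length(bg), length(cols))
      counts[bg, cols][drop] <- 0
    }
    truth <- data.frame(
      taxon = taxa, block = membership,
      rho = ifelse(membership > 0L,
                   vapply(membership, function(b)
                     if (b > 0L) blocks[[b]]$rho else NA_real_, numeric(1)),
                   NA_real_),
      treatment = ifelse(membership > 0L,
                         vapply(membership, function(b)
                           if (b > 0L) blocks[[b]]$treatment else NA_character_,
                           character(1)),
                         NA_character_),
      stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Generate synthetic bacterial and fungal OTU tables
#'
#' Taxa are log-normal (log-scale mean \code{mu_sd}-dispersed across taxa,
#' residual SD \code{noise_sd}) sampled through a Poisson layer at the
#' configured depth, so the tables are compositional counts. Taxa inside a
#' planted block share a latent factor within that block's treatment
#' samples, so their pairwise abundance correlations approach the block's
#' target \code{rho}; grazed-configured blocks are denser/stronger when so
#' configured. Background taxa receive a per-taxon grazed log-offset
#' (compositional turnover) and an occupancy restriction in grazed samples.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return List with \code{bacteria} and \code{fungi} (taxa x samples count
#'   matrices), \code{metadata} (data.frame: sample_id, treatment) and
#'   \code{truth} (per-kingdom block membership data.frames).
#' @export
generate_otu_tables <- function(cfg) {
  validate_config(cfg)
  bac <- generate_one_table(cfg, "bacteria",
                            substream_seed(cfg$seed, "otu_bacteria"))
  fun <- generate_one_table(cfg, "fungi",
                            substream_seed(cfg$seed, "otu_fungi"))
  meta <- data.frame(sample_id = sample_ids(cfg$n_per_group),
                     treatment = rep(c("grazed", "ungrazed"),
                                     each = cfg$n_per_group),
                     stringsAsFactors = FALSE)
  list(bacteria = bac$counts, fungi = fun$counts, metadata = meta,
       truth = list(bacteria = bac$truth, fungi = fun$truth))
}

#' Generate a synthetic soil-function matrix
#'
#' Produces the samples x 15 soil-function matrix (see
#' \code{\link{soil_function_names}}). Multiplicative variables are
#' log-normal around their ungrazed baselines with per-variable replicate
#' CVs; grazed samples are scaled by the configured ratio. pH and the
#' vector angle are additive-normal (the angle is clamped to [0, 90] and
#' the vector length to [0, sqrt(2)], their geometric ranges). With
#' \code{limitation = "enzymes"} the C_limitation and vector_angle columns
#' are recomputed from the generated enzyme activities via
#' \code{\link{vector_limitation}} instead of being generated directly.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return samples x 15 numeric matrix (rownames = sample IDs), with the
#'   planted effect table in the \code{"effects"} attribute.
#' @export
generate_soil_functions <- function(cfg) {
  validate_config(cfg)
  n <- cfg$n_per_group
  samples <- sample_ids(n)
  grazed <- rep(c(TRUE, FALSE), each = n)
  eff <- cfg$effect_table
  with_seed(substream_seed(cfg$seed, "soil"), {
    m <- base::matrix(0, 2L * n, length(soil_baselines),
                      dimnames = list(samples, names(soil_baselines)))
    for (v in names(soil_baselines)) {
      base <- soil_baselines[[v]]
      sdv <- soil_noise_sd[[v]]
      if (v %in% soil_additive_vars) {
        shift <- if (!is.null(eff$add) && v %in% names(eff$add))
          eff$add[[v]] else 0
        vals <- base + shift * grazed + stats::rnorm(2L * n, 0, sdv)
      } else {
        ratio <- if (!is.null(eff$mult) && v %in% names(eff$mult))
          eff$mult[[v]] else 1
        vals <- base * ifelse(grazed, ratio, 1) *
          exp(stats::rnorm(2L * n, 0, sdv))
      }
      if (v == "vector_angle") vals <- pmin(pmax(vals, 0), 90)
      if (v == "C_limitation") vals <- pmin(vals, sqrt(2))
      m[, v] <- vals
    }
    if (cfg$limitation == "enzymes") {
      vl <- vector_limitation(bg = m[, "BGC"], nag = m[, "NAG"],
                              lap = m[, "LAP"], acp = m[, "ACP"],
                              trans = "ln")
      m[, "C_limitation"] <- vl$length
      m[, "vector_angle"] <- vl$angle
    }
    attr(m, "effects") <- eff
    m
  })
}
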