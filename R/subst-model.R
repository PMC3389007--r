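## GTR-family substitution models. The rate matrix Q is built from stationary
## frequencies and six exchangeabilities (order AC, AG, AT, CG, CT, GT; GT = 1
## by convention), then normalized so that one unit of branch length equals
## one expected substitution per site when averaged over all sites, i.e.
## (1 - p_inv) * sum_i pi_i * (-Q_ii) = 1 with mean gamma rate 1. Transition
## probabilities use the symmetrized eigendecomposition, which is exact and
## stable for reversible Q.

BASES <- c("A", "C", "G", "T")

#' GTR-family substitution model
#'
#' Builds a reversible nucleotide substitution model with optional invariant
#' sites (`+I`) and discrete-gamma rate variation (`+G`). Submodels such as
#' TrN or TPM2uf are expressed through the general GTR parameterization.
#'
#' @param freqs Stationary base frequencies, in order A, C, G, T. Must be
#'   positive and sum to 1 within 0.02 (published, rounded frequency sets
#'   are accepted); renormalized exactly.
#' @param rates Six positive exchangeabilities in order AC, AG, AT, CG, CT,
#'   GT (GT conventionally 1).
#' @param p_inv Proportion of invariant sites, in `[0, 1)`.
#' @param gamma_shape Gamma shape parameter alpha (> 0), or `NULL` for no
#'   among-site rate variation.
#' @param n_categories Number of discrete gamma categories (>= 1).
#' @return An object of class `subst_model` with elements `freqs`, `rates`,
#'   `p_inv`, `gamma_shape`, `n_categories`, the normalized rate matrix `Q`,
#'   its eigendecomposition, and the site-rate categories.
#' @examples
#' m <- substitution_model()         # Jukes-Cantor configuration
#' transition_matrix(m, 0)           # identity
#' @export
substitution_model <- function(freqs = rep(0.25, 4),
                               rates = rep(1, 6),
                               p_inv = 0,
                               gamma_shape = NULL,
                               n_categories = 4L) {
  freqs <- as.numeric(freqs)
  rates <- as.numeric(rates)
  if (length(freqs) != 4L || any(freqs <= 0)) stop("freqs must be 4 positive numbers")
  ## published frequency sets are often rounded to 2 d.p. and may miss 1 by
  ## up to a few percent; renormalize exactly, reject anything worse
  if (abs(sum(freqs) - 1) > 0.02) stop("freqs must sum to 1")
  freqs <- freqs / sum(freqs)
  if (length(rates) != 6L || any(rates <= 0)) stop("rates must be 6 positive numbers")
  if (!is.numeric(p_inv) || p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (!is.null(gamma_shape)) {
    if (!is.numeric(gamma_shape) || gamma_shape <= 0) stop("gamma_shape must be > 0")
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  names(freqs) <- BASES
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    R[pair[k, 1], pair[k, 2]] <- rates[k]
    R[pair[k, 2], pair[k, 1]] <- rates[k]
  }
  Q <- R %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(freqs * diag(Q))
  Q <- Q / ((1 - p_inv) * mean_rate)   # subs/site averaged over all sites = t
  dimnames(Q) <- list(BASES, BASES)

  ## symmetrize: B = D^{1/2} Q D^{-1/2} with D = diag(freqs); B symmetric
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)

  cats <- if (is.null(gamma_shape) || n_categories == 1L) {
    list(rates = 1, weights = 1)
  } else {
    g <- discrete_gamma_rates(gamma_shape, n_categories)
    list(rates = g$rate, weights = g$weight)
  }

  structure(list(freqs = freqs, rates = rates, p_inv = p_inv,
                 gamma_shape = gamma_shape, n_categories = n_categories,
                 Q = Q,
                 eigvec = diag(1 / sq) %*% eig$vectors,
                 inv_eigvec = t(eig$vectors) %*% diag(sq),
                 eigval = eig$values,
                 cat_rates = cats$rates, cat_weights = cats$weights),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR-family substitution model\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", BASES, x$freqs), collapse = " "), "\n")
  cat("  rates (AC AG AT CG CT GT):", paste(sprintf("%.4g", x$rates), collapse = " "), "\n")
  cat("  p_inv:", x$p_inv, "  gamma shape:",
      if (is.null(x$gamma_shape)) "none" else x$gamma_shape,
      " (", x$n_categories, "categories )\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model A `subst_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param rate Site-rate multiplier (e.g. a discrete gamma category rate).
#' @return The 4x4 matrix `P(t * rate) = exp(Q * t * rate)`.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"), t >= 0, rate >= 0)
  P <- model$eigvec %*% (exp(model$eigval * t * rate) * model$inv_eigvec)
  dimnames(P) <- list(BASES, BASES)
  ## numerical cleanup: tiny negatives from the eigendecomposition
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete gamma rate categories
#'
#' Mean-of-quantile-slice discretization of a Gamma(shape = alpha,
#' rate = alpha) distribution (mean 1) into `k` equal-weight categories,
#' as used by `+G` models.
#'
#' @param shape Gamma shape alpha (> 0).
#' @param k Number of categories (>= 1).
#' @return A data frame with columns `rate` and `weight`; rates average to 1.
#' @export
discrete_gamma_rates <- function(shape, k) {
  if (!is.numeric(shape) || length(shape) != 1L || shape <= 0) stop("shape must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(data.frame(rate = 1, weight = 1))
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  ## E[X | slice] via the incomplete-gamma identity; shape/rate = 1 overall
  upper <- stats::pgamma(bounds[-1L], shape = shape + 1, rate = shape)
  lower <- stats::pgamma(bounds[-(k + 1L)], shape = shape + 1, rate = shape)
  rate <- (upper - lower) * k
  rate <- rate / mean(rate)  # guard against quantile round-off
  data.frame(rate = rate, weight = rep(1 / k, k))
}

#' Shipped model presets
#'
#' `"coi_paper"` holds GTR+I+G parameters typical of a mitochondrial COI
#' fragment (TrN-style exchangeabilities, p_inv = 0.58, shape = 1.57);
#' `"its2_paper"` holds TPM2uf+G-style parameters for a nuclear ITS2 region
#' (shape = 0.45, no invariant class). Presets are stored as YAML under
#' `inst/extdata/models` and can serve as templates for custom model files.
#'
#' @param name Preset name (`"coi_paper"` or `"its2_paper"`) or a path to a
#'   YAML file with keys `freqs`, `rates`, `p_inv`, `gamma_shape`,
#'   `categories`.
#' @return A `subst_model`.
#' @export
model_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "models", paste0(name, ".yml"), package = "egdelim")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown model preset or missing file: ", name)
  }
  cfg <- yaml::read_yaml(path)
  shape <- cfg$gamma_shape
  if (!is.null(shape) && (identical(shape, "none") || is.na(shape))) shape <- NULL
  substitution_model(freqs = unlist(cfg$freqs),
                     rates = unlist(cfg$rates),
                     p_inv = cfg$p_inv %||% 0,
                     gamma_shape = shape,
                     n_categories = cfg$categories %||% 4L)
}
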