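## Pairwise distances. d ("p-distance") is the uncorrected proportion of
## differing sites with pairwise deletion of gaps/N. The model-corrected
## distance maximizes the two-sequence likelihood under a GTR(+I+G) model
## by one-dimensional numerical search; for the Jukes-Cantor configuration
## this coincides with the classed-form -(3/4)log(1 - 4p/3).

comparable_sites <- function(aln, i, j) {
  x <- unclass(aln)[i, ]
  y <- unclass(aln)[j, ]
  ok <- x %in% BASES & y %in% BASES
  list(x = x[ok], y = y[ok])
}

#' Uncorrected pairwise distance (p-distance)
#'
#' Fraction of differing sites among sites where both sequences carry a plain
#' base (A/C/G/T); gap and N positions are deleted pairwise.
#'
#' @param aln An `alignment`.
#' @param i,j Sequence labels.
#' @return Proportion of differing comparable sites.
#' @export
p_distance <- function(aln, i, j) {
  s <- comparable_sites(aln, i, j)
  n <- length(s$x)
  if (n == 0L) stop("no comparable (ungapped) sites between '", i, "' and '", j, "'")
  sum(s$x != s$y) / n
}

## Count the 16 ordered site patterns between two sequences.
pair_pattern_counts <- function(aln, i, j) {
  s <- comparable_sites(aln, i, j)
  if (length(s$x) == 0L) stop("no comparable (ungapped) sites between '", i, "' and '", j, "'")
  tab <- table(factor(s$x, BASES), factor(s$y, BASES))
  matrix(as.numeric(tab), 4, 4, dimnames = list(BASES, BASES))
}

pair_loglik <- function(model, counts, t) {
  k <- length(model$cat_rates)
  M <- matrix(0, 4, 4)
  for (c in seq_len(k)) {
    M <- M + model$cat_weights[c] * transition_matrix(model, t, model$cat_rates[c])
  }
  lik <- model$freqs * M                     # pi_x * P_xy averaged over categories
  lik <- (1 - model$p_inv) * lik
  if (model$p_inv > 0) diag(lik) <- diag(lik) + model$p_inv * model$freqs
  lik[lik <= 0] <- .Machine$double.xmin
  sum(counts * log(lik))
}

#' Maximum-likelihood pairwise distance under a GTR-family model
#'
#' Finds the branch length `t` (expected substitutions per site) maximizing
#' the two-sequence likelihood under the model, integrating over invariant
#' sites and discrete gamma rate categories. The search interval is
#' `[0, 10]` substitutions/site; a pair whose optimum sits at the upper
#' bound is returned with attribute `saturated = TRUE`.
#'
#' @param model A `subst_model`.
#' @param aln An `alignment`.
#' @param i,j Sequence labels.
#' @param upper Upper search bound (default 10 substitutions/site).
#' @return The ML distance (numeric scalar); identical sequences give 0.
#' @export
ml_pairwise_distance <- function(model, aln, i, j, upper = 10) {
  stopifnot(inherits(model, "subst_model"))
  counts <- pair_pattern_counts(aln, i, j)
  if (sum(counts) - sum(diag(counts)) == 0) return(0)
  opt <- stats::optimize(function(t) pair_loglik(model, counts, t),
                         interval = c(0, upper), maximum = TRUE, tol = 1e-8)
  t_hat <- opt$maximum
  ## optimize() never returns the exact boundary; snap near-zero optima and
  ## flag near-bound optima as saturated.
  if (t_hat < 1e-7 && pair_loglik(model, counts, 0) >= opt$objective - 1e-10) t_hat <- 0
  if (t_hat > upper - 1e-4) {
    t_hat <- upper
    attr(t_hat, "saturated") <- TRUE
  }
  t_hat
}

#' Pairwise distance matrix
#'
#' @param aln An `alignment` with at least two records.
#' @param method `"p"` for uncorrected p-distances or `"model"` for
#'   maximum-likelihood model-corrected distances.
#' @param model A `subst_model`; required when `method = "model"`.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal,
#'   labelled by sequence.
#' @export
distance_matrix <- function(aln, method = c("p", "model"), model = NULL) {
  method <- match.arg(method)
  labs <- aln_labels(aln)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 sequences")
  if (method == "model" && is.null(model)) stop("method 'model' requires a model")
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  if (method == "p") {
    ## vectorized: compare all pairs of rows on comparable sites
    M <- unclass(aln)
    isb <- matrix(M %in% BASES, nrow = n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      ok <- isb[a, ] & isb[b, ]
      nn <- sum(ok)
      if (nn == 0L) stop("no comparable sites between '", labs[a], "' and '", labs[b], "'")
      D[a, b] <- D[b, a] <- sum(M[a, ok] != M[b, ok]) / nn
    }
  } else {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      D[a, b] <- D[b, a] <- as.numeric(ml_pairwise_distance(model, aln, labs[a], labs[b]))
    }
  }
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Write / read a labelled distance matrix as TSV
#'
#' `read_distance_matrix` also accepts the square PHYLIP dialect (a first
#' line holding the number of taxa, then label + row values).
#'
#' @param dm A square labelled matrix.
#' @param path File path.
#' @return `write_distance_matrix`: invisibly `path`;
#'   `read_distance_matrix`: a `dist_matrix`.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(as.matrix(dm), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[[:space:]]+")[[1L]]
  if (length(fields) == 1L && grepl("^[0-9]+$", fields)) {
    ## PHYLIP square format
    n <- as.integer(fields)
    body <- utils::read.table(path, skip = 1L, stringsAsFactors = FALSE)
    if (nrow(body) != n) stop("PHYLIP matrix: expected ", n, " rows")
    D <- as.matrix(body[, -1L, drop = FALSE])
    dimnames(D) <- list(body[[1L]], body[[1L]])
  } else {
    D <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1L, check.names = FALSE))
    colnames(D) <- rownames(D)
  }
  storage.mode(D) <- "double"
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) stop("matrix is not symmetric")
  structure(D, class = c("dist_matrix", "matrix"))
}
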