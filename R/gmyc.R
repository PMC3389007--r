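## Generalized mixed Yule-coalescent (GMYC) species delimitation.
##
## Branching events on an ultrametric tree are ordered from the root to the
## present. The waiting interval i (duration x_i, with n_i = i + 1 lineages)
## carries a hazard
##     b_i = lambda_spec * k_i^p_spec + lambda_coal * sum_j [m_ij (m_ij - 1)]^p_coal
## where k_i counts species-level lineages (lineages whose most recent
## crossing of the applicable threshold lies above them) and m_ij counts
## lineages inside within-species cluster j. The log-likelihood is
## sum_i [ln b_i - b_i x_i]; the final interval runs to the present. The
## null model treats all branching as one process, b_i = lambda *
## [n_i (n_i - 1)]^p, and is recovered exactly by the degenerate
## classification with no diversification events, so the GMYC fit nests it
## by construction. The single-threshold likelihood is piecewise constant
## in the threshold age between node ages, so candidate thresholds sit at
## midpoints between consecutive distinct ages, plus just-above-root and
## just-above-tips.

P_RANGE <- c(0.01, 10)

## ---- preprocessing ---------------------------------------------------------

## Interval/edge bookkeeping shared by all fits. Internal nodes are ranked
## by age, oldest (root) first; edge e is alive in intervals
## rank(parent) .. rank(child) - 1 (tips: .. N - 1). Internal-node ages of
## exactly zero (duplicate haplotypes) are jittered to 1e-9 * height so no
## cluster is empty.
gmyc_data <- function(tree, tol = 1e-6) {
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  if (!ape::is.binary(tree)) {
    stop("tree must be binary; resolve polytomies (ape::multi2di) first")
  }
  tree <- stats::reorder(tree, "cladewise")
  ages_named <- node_ages(tree, tol)        # sorted desc, names = node ids
  N <- length(tree$tip.label)
  h <- max(ages_named)
  if (h <= 0) stop("tree height must be positive")
  ages_named[ages_named == 0] <- 1e-9 * h
  ord_nodes <- as.integer(names(ages_named))
  rank_of <- integer(N + tree$Nnode)
  rank_of[ord_nodes] <- seq_along(ord_nodes)
  t_ev <- c(unname(ages_named), 0)
  x <- t_ev[-length(t_ev)] - t_ev[-1L]      # N - 1 interval durations
  edge <- tree$edge
  rp <- rank_of[edge[, 1L]]
  rc <- ifelse(edge[, 2L] <= N, N, rank_of[edge[, 2L]])
  ## parent edge index for each edge (0 for edges hanging off the root)
  pe <- match(edge[, 1L], edge[, 2L])
  pe[is.na(pe)] <- 0L
  list(tree = tree, N = N, Nint = N - 1L, nodes = ord_nodes,
       ages = unname(ages_named), x = x, edge = edge,
       first_int = rp, last_int = rc - 1L, parent_edge = pe,
       height = h, rank_of = rank_of)
}

## Classification: `spec` is a logical vector over internal nodes (indexed
## by rank order, i.e. spec[r] refers to the r-th oldest node) and must be
## rootward-closed. Returns per-interval species-lineage counts, cluster
## size multisets, species count and crossing-edge ids.
gmyc_classify <- function(gd, spec) {
  stopifnot(length(spec) == gd$Nint)
  edge <- gd$edge
  N <- gd$N
  node_rank <- gd$rank_of
  par_spec <- spec[node_rank[edge[, 1L]]]
  child_spec <- rep(FALSE, nrow(edge))
  int_child <- which(edge[, 2L] > N)
  child_spec[int_child] <- spec[node_rank[edge[int_child, 2L]]]
  crossing <- par_spec & !child_spec
  ## cluster root for each edge, in cladewise (root-to-tip) edge order;
  ## 0 denotes the virtual root cluster when the root event is coalescent
  cr <- integer(nrow(edge))
  for (e in seq_len(nrow(edge))) {
    if (par_spec[e]) cr[e] <- e
    else if (gd$parent_edge[e] == 0L) cr[e] <- 0L
    else cr[e] <- cr[gd$parent_edge[e]]
  }
  k <- integer(gd$Nint)
  clusters <- vector("list", gd$Nint)
  for (i in seq_len(gd$Nint)) {
    alive <- gd$first_int <= i & gd$last_int >= i
    k[i] <- sum(alive & par_spec)
    below <- alive & !par_spec
    if (any(below)) {
      m <- as.integer(table(cr[below]))
      clusters[[i]] <- m
    } else clusters[[i]] <- integer(0L)
  }
  n_species <- if (any(spec)) sum(crossing) else 1L
  list(k = k, clusters = clusters, n_species = n_species,
       crossing = which(crossing), spec = spec)
}

## tips of each species under a classification
gmyc_members <- function(gd, cls) {
  if (!any(cls$spec)) return(list(gd$tree$tip.label))
  lapply(cls$crossing, function(e) {
    child <- gd$edge[e, 2L]
    if (child <= gd$N) gd$tree$tip.label[child]
    else tip_labels_below(gd$tree, child)
  })
}

## ---- likelihood and optimization ------------------------------------------

#' GMYC log-likelihood for a given threshold and parameters
#'
#' @param tree Rooted ultrametric `phylo`.
#' @param thresholds Threshold age(s). A single age classifies every node
#'   older than it as a diversification event; an age at or above the root
#'   age gives the degenerate all-coalescent (null-type) classification.
#' @param lambda_spec,lambda_coal Rate parameters (> 0).
#' @param p_spec,p_coal Scaling exponents.
#' @param tol Ultrametricity tolerance.
#' @return The log-likelihood (may be `-Inf` for invalid classifications).
#' @export
gmyc_loglik <- function(tree, thresholds, lambda_spec, p_spec,
                        lambda_coal, p_coal, tol = 1e-6) {
  gd <- gmyc_data(tree, tol)
  if (length(thresholds) != 1L) {
    stop("gmyc_loglik takes a single global threshold; multiple-threshold ",
         "classifications are handled by fit_gmyc_multiple()")
  }
  if (thresholds <= 0) stop("threshold must be positive")
  spec <- gd$ages > thresholds
  cls <- gmyc_classify(gd, spec)
  gmyc_ll_params(cls, gd$x, lambda_spec, p_spec, lambda_coal, p_coal)
}

gmyc_ll_params <- function(cls, x, ls, ps, lc, pc) {
  coalw <- vapply(cls$clusters, function(m) {
    if (length(m) == 0L) 0 else sum((m * (m - 1))^pc)
  }, numeric(1L))
  b <- ifelse(cls$k > 0L, ls * cls$k^ps, 0) + lc * coalw
  if (any(b <= 0)) return(-Inf)
  sum(log(b) - b * x)
}

## exact profile fit for single-process classifications:
## b_i = lambda * w_i(p); lambda-hat = Nint / sum(w_i x_i)
profile_single_process <- function(w_of_p, x) {
  nint <- length(x)
  obj <- function(p) {
    w <- w_of_p(p)
    sx <- sum(w * x)
    if (sx <= 0) return(-Inf)
    lam <- nint / sx
    sum(log(lam * w)) - nint
  }
  opt <- stats::optimize(obj, interval = P_RANGE, maximum = TRUE, tol = 1e-8)
  ends <- vapply(P_RANGE, obj, numeric(1L))
  if (max(ends) > opt$objective) {
    p_hat <- P_RANGE[which.max(ends)]
    best <- max(ends)
  } else {
    p_hat <- opt$maximum
    best <- opt$objective
  }
  lam <- nint / sum(w_of_p(p_hat) * x)
  list(ll = best, lambda = lam, p = p_hat)
}

## Maximize the GMYC likelihood over (lambda_spec, p_spec, lambda_coal,
## p_coal) for a fixed classification. Rates are log-transformed and the
## exponents mapped smoothly into [0.01, 10]; derivative-free Nelder-Mead
## with deterministic restarts.
gmyc_optimize <- function(cls, x, init = NULL) {
  has_spec <- any(cls$k > 0L)
  has_coal <- any(vapply(cls$clusters, length, integer(1L)) > 0L)
  if (has_spec && !has_coal) {
    pr <- profile_single_process(function(p) cls$k^p, x)
    return(list(ll = pr$ll, lambda_spec = pr$lambda, p_spec = pr$p,
                lambda_coal = NA_real_, p_coal = NA_real_))
  }
  if (!has_spec && has_coal) {
    pr <- profile_single_process(function(p) {
      vapply(cls$clusters, function(m) {
        if (length(m) == 0L) 0 else sum((m * (m - 1))^p)
      }, numeric(1L))
    }, x)
    return(list(ll = pr$ll, lambda_spec = NA_real_, p_spec = NA_real_,
                lambda_coal = pr$lambda, p_coal = pr$p))
  }

  to_p <- function(u) P_RANGE[1L] + diff(P_RANGE) * stats::plogis(u)
  to_u <- function(p) stats::qlogis((min(max(p, P_RANGE[1L] + 1e-6), P_RANGE[2L] - 1e-6) -
                                     P_RANGE[1L]) / diff(P_RANGE))
  negll <- function(par) {
    v <- -gmyc_ll_params(cls, x, exp(par[1L]), to_p(par[2L]),
                         exp(par[3L]), to_p(par[4L]))
    if (!is.finite(v)) 1e12 else v
  }
  nint <- length(x)
  cw_of <- function(p) vapply(cls$clusters, function(m) {
    if (length(m) == 0L) 0 else sum((m * (m - 1))^p)
  }, numeric(1L))
  ## coarse exponent grid with moment-matched rates (each component scaled
  ## to explain half the events on the intervals where it is active), then
  ## Nelder-Mead polish from the best grid points; the surface has narrow
  ## near-saturated ridges at large exponents that a single start misses
  p_grid <- c(0.01, 0.5, 1, 2, 4, 8, 10)
  grid_pts <- expand.grid(ps = p_grid, pc = p_grid)
  grid_starts <- lapply(seq_len(nrow(grid_pts)), function(i) {
    ps <- grid_pts$ps[i]; pc <- grid_pts$pc[i]
    ls <- 0.5 * nint / max(sum(cls$k^ps * x), 1e-300)
    lc <- 0.5 * nint / max(sum(cw_of(pc) * x), 1e-300)
    c(log(ls), to_u(ps), log(lc), to_u(pc))
  })
  grid_vals <- vapply(grid_starts, negll, numeric(1L))
  starts <- grid_starts[order(grid_vals)[1:4]]
  if (!is.null(init) && all(is.finite(init))) {
    starts <- c(list(c(log(init[1L]), to_u(init[2L]), log(init[3L]), to_u(init[4L]))),
                starts)
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 3000L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## one restart from the incumbent: Nelder-Mead simplexes can collapse
  ## before reaching a boundary-adjacent optimum
  fit <- stats::optim(best$par, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 3000L))
  if (fit$value < best$value) best <- fit
  list(ll = -best$value,
       lambda_spec = exp(best$par[1L]), p_spec = to_p(best$par[2L]),
       lambda_coal = exp(best$par[3L]), p_coal = to_p(best$par[4L]))
}

## ---- fits ------------------------------------------------------------------

#' Fit the single-threshold GMYC model
#'
#' Profiles the likelihood over candidate threshold ages (midpoints between
#' consecutive distinct node ages, just above the root -- the degenerate
#' classification equal to the null model -- and just above the tips),
#' maximizing the four rate/exponent parameters at each. The confidence set
#' on the species count collects the counts of all candidate thresholds
#' within 2 log-likelihood units of the maximum.
#'
#' @param tree Rooted ultrametric `phylo` with >= 3 tips.
#' @param tol Relative ultrametricity tolerance.
#' @return An object of class `gmyc`.
#' @export
fit_gmyc_single <- function(tree, tol = 1e-6) {
  if (length(tree$tip.label) < 3L) stop("need at least 3 tips")
  gd <- gmyc_data(tree, tol)
  u <- sort(unique(gd$ages), decreasing = TRUE)
  thr <- c(u[1L] * (1 + 1e-9),
           if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
           u[length(u)] / 2)
  cand <- lapply(thr, function(T) {
    cls <- gmyc_classify(gd, gd$ages > T)
    opt <- gmyc_optimize(cls, gd$x)
    list(threshold = T, cls = cls, opt = opt, n_species = cls$n_species)
  })
  lls <- vapply(cand, function(cc) cc$opt$ll, numeric(1L))
  if (any(!is.finite(lls))) stop("optimizer failed on a candidate threshold")
  ll_null <- lls[1L]                         # degenerate all-coalescent candidate
  best_i <- which.max(lls)
  best <- cand[[best_i]]
  within2 <- which(lls >= max(lls) - 2)
  ci <- range(vapply(cand[within2], `[[`, integer(1L), "n_species"))
  new_gmyc(gd, best, ll_null, "single",
           candidates = data.frame(threshold = thr, ll = lls,
                                   n_species = vapply(cand, `[[`, integer(1L), "n_species")),
           ci = ci)
}

#' Fit the multiple-threshold GMYC model
#'
#' Greedy refinement from the single-threshold optimum: the diversification
#' /coalescent boundary is moved one node rootward or tipward on one lineage
#' at a time, parameters are re-optimized for each proposal, and the best
#' likelihood-improving move is accepted until no move improves the
#' log-likelihood by more than 1e-6. Ties are broken toward fewer
#' thresholds.
#'
#' @inheritParams fit_gmyc_single
#' @return An object of class `gmyc`.
#' @export
fit_gmyc_multiple <- function(tree, tol = 1e-6) {
  single <- fit_gmyc_single(tree, tol)
  gd <- gmyc_data(tree, tol)
  spec <- single$classification$spec
  cur_cls <- gmyc_classify(gd, spec)
  cur_opt <- gmyc_optimize(cur_cls, gd$x, init = fit_params(single))
  repeat {
    props <- boundary_moves(gd, spec)
    if (length(props) == 0L) break
    fits <- lapply(props, function(sp) {
      cls <- gmyc_classify(gd, sp)
      list(cls = cls, opt = gmyc_optimize(cls, gd$x, init = unlist(cur_opt[-1L],
                                                                   use.names = FALSE)))
    })
    lls <- vapply(fits, function(f) f$opt$ll, numeric(1L))
    j <- which.max(lls)
    if (lls[j] <= cur_opt$ll + 1e-6) break
    spec <- props[[j]]
    cur_cls <- fits[[j]]$cls
    cur_opt <- fits[[j]]$opt
  }
  best <- list(threshold = NA_real_, cls = cur_cls, opt = cur_opt,
               n_species = cur_cls$n_species)
  new_gmyc(gd, best, single$ll_null, "multiple",
           candidates = single$candidates,
           ci = range(c(single$ci_species, cur_cls$n_species)))
}

## legal boundary moves: add an internal node whose parent is already a
## diversification node (or the root), or remove a boundary-leaf node
boundary_moves <- function(gd, spec) {
  N <- gd$N
  props <- list()
  for (r in seq_along(spec)) {
    v <- gd$nodes[r]
    par <- gd$edge[gd$edge[, 2L] == v, 1L]
    if (!spec[r]) {
      ok <- length(par) == 0L || spec[gd$rank_of[par]]
      if (ok) { s <- spec; s[r] <- TRUE; props[[length(props) + 1L]] <- s }
    } else {
      kids <- gd$edge[gd$edge[, 1L] == v, 2L]
      kids <- kids[kids > N]
      if (all(!spec[gd$rank_of[kids]])) {
        s <- spec; s[r] <- FALSE; props[[length(props) + 1L]] <- s
      }
    }
  }
  props
}

fit_params <- function(fit) {
  c(fit$lambda_spec, fit$p_spec, fit$lambda_coal, fit$p_coal)
}

## threshold ages of a classification: a single global age when the
## boundary is expressible as one, otherwise one midpoint age per
## transition (crossing) edge
classification_thresholds <- function(gd, cls) {
  if (!any(cls$spec)) return(numeric(0L))
  a_min <- min(gd$ages[cls$spec])
  b_max <- if (any(!cls$spec)) max(gd$ages[!cls$spec]) else 0
  if (a_min > b_max) return((a_min + b_max) / 2)
  sort(unique(vapply(cls$crossing, function(e) {
    top <- gd$ages[gd$rank_of[gd$edge[e, 1L]]]
    child <- gd$edge[e, 2L]
    bot <- if (child <= gd$N) 0 else gd$ages[gd$rank_of[child]]
    (top + bot) / 2
  }, numeric(1L))), decreasing = TRUE)
}

new_gmyc <- function(gd, best, ll_null, method, candidates, ci) {
  thr <- if (method == "single") {
    if (any(best$cls$spec)) best$threshold else numeric(0L)
  } else classification_thresholds(gd, best$cls)
  structure(list(tree = gd$tree, method = method,
                 ll_null = ll_null, ll_gmyc = best$opt$ll,
                 lambda_spec = best$opt$lambda_spec, p_spec = best$opt$p_spec,
                 lambda_coal = best$opt$lambda_coal, p_coal = best$opt$p_coal,
                 thresholds = thr,
                 n_species = best$cls$n_species, ci_species = ci,
                 species = gmyc_members(gd, best$cls),
                 classification = best$cls,
                 intervals = data.frame(x = gd$x, n = seq_len(gd$Nint) + 1L,
                                        k = best$cls$k),
                 candidates = candidates),
            class = "gmyc")
}

## ---- tests and reports -----------------------------------------------------

#' Likelihood-ratio test
#'
#' @param ll_constrained,ll_general Log-likelihoods of the nested and the
#'   general model (`ll_general >= ll_constrained` up to 1e-6).
#' @param df Degrees of freedom (>= 1).
#' @return A list of class `lr_test` with `statistic`, `df` and `p_value`.
#' @export
lr_test <- function(ll_constrained, ll_general, df) {
  if (df < 1) stop("df must be >= 1")
  if (ll_general < ll_constrained - 1e-6) {
    stop("general model has lower likelihood than the constrained model")
  }
  stat <- max(0, 2 * (ll_general - ll_constrained))
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test: 2*dLL = %.4g, df = %d, p = %.4g\n",
              x$statistic, as.integer(x$df), x$p_value))
  invisible(x)
}

#' Test the GMYC model against its null
#'
#' Three extra parameters (second rate, second exponent, threshold).
#'
#' @param fit A `gmyc` fit.
#' @return An `lr_test`.
#' @export
gmyc_lr_test <- function(fit) {
  lr_test(fit$ll_null, fit$ll_gmyc, df = 3L)
}

#' Compare single- and multiple-threshold fits
#'
#' @param single,multiple `gmyc` fits of the same tree.
#' @return An `lr_test` with `df = max(1, n_thresholds(multiple) - 1)`.
#' @export
compare_thresholds <- function(single, multiple) {
  if (!identical(ape::write.tree(single$tree), ape::write.tree(multiple$tree))) {
    stop("fits are not on the same tree")
  }
  df <- max(1L, length(multiple$thresholds) - 1L)
  lr_test(single$ll_gmyc, multiple$ll_gmyc, df = df)
}

#' @export
print.gmyc <- function(x, ...) {
  cat("GMYC fit (", x$method, " threshold)\n", sep = "")
  cat(sprintf("  LL null: %.4f   LL GMYC: %.4f\n", x$ll_null, x$ll_gmyc))
  lt <- gmyc_lr_test(x)
  cat(sprintf("  LR test: 2*dLL = %.4g, df = %d, p = %.4g\n",
              lt$statistic, lt$df, lt$p_value))
  cat(sprintf("  species: %d (CI %d-%d)\n", x$n_species,
              x$ci_species[1L], x$ci_species[2L]))
  if (length(x$thresholds)) {
    cat("  threshold age(s):", paste(signif(x$thresholds, 6), collapse = ", "), "\n")
  } else cat("  no diversification events (degenerate classification)\n")
  invisible(x)
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  cat("  cluster sizes:",
      paste(sort(vapply(object$species, length, integer(1L)), decreasing = TRUE),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
logLik.gmyc <- function(object, ...) {
  structure(object$ll_gmyc, df = 4L + length(object$thresholds),
            class = "logLik")
}

#' Lineage-through-time plot with the fitted threshold
#'
#' @param x A `gmyc` fit.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.gmyc <- function(x, ...) {
  bt <- branching_times(x$tree)
  ages <- c(bt, 0)
  n <- c(seq_along(bt) + 1L, length(x$tree$tip.label))
  plot(-ages, n, type = "s", xlab = "age (time before present)",
       ylab = "lineages", main = paste0("GMYC (", x$method, " threshold)"), ...)
  if (length(x$thresholds)) {
    graphics::abline(v = -x$thresholds, col = "firebrick", lty = 2)
  }
  invisible(x)
}
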