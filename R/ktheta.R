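## The K/theta (4x) rule. Within a candidate clade, the mean uncorrected
## pairwise difference d gives the nucleotide diversity pi = d*n/(n-1) and a
## multiple-hit-corrected diversity theta = pi/(1 - 4*pi/3) ~ 2*Ne*mu.
## Between two clades, K is the mean model-corrected (ML) distance over all
## cross pairs ~ 2*mu*t at divergence time t. Drift-only gaps average 2*Ne
## generations (95% within 4*Ne), so K/theta >= 4 marks divergence too deep
## for drift within one species; the call additionally requires the
## probability of reciprocal monophyly at the implied separation time to
## reach 0.95.

#' Within-clade diversity: d, pi and theta
#'
#' `d` is the mean pairwise uncorrected difference over all within-clade
#' pairs. When all sequences are identical, `d` is computed as if one
#' sequence differed from each of the others at a single site:
#' `d = 2/(L*n)`. Then `pi = d*n/(n-1)` and `theta = pi/(1 - 4*pi/3)`.
#' For a singleton clade (`n = 1`) the three quantities are undefined (`NA`).
#'
#' @param aln An `alignment`.
#' @param tips Character vector of clade member labels.
#' @return A list of class `clade_diversity`: `tips`, `n`, `d`, `pi`,
#'   `theta`, `all_identical`.
#' @export
clade_diversity <- function(aln, tips) {
  if (length(tips) == 0L) stop("empty clade")
  sub <- aln_subset(aln, tips)
  n <- length(tips)
  if (n == 1L) {
    return(structure(list(tips = tips, n = 1L, d = NA_real_, pi = NA_real_,
                          theta = NA_real_, all_identical = TRUE),
                     class = "clade_diversity"))
  }
  pairs <- utils::combn(tips, 2L)
  d <- mean(apply(pairs, 2L, function(p) p_distance(sub, p[1L], p[2L])))
  all_identical <- d == 0
  if (all_identical) d <- 2 / (aln_length(aln) * n)
  pi <- d * n / (n - 1)
  if (pi >= 0.75) {
    stop("within-clade diversity pi = ", signif(pi, 3),
         " exceeds the domain of the correction theta = pi/(1 - 4 pi/3)")
  }
  theta <- pi / (1 - 4 * pi / 3)
  structure(list(tips = tips, n = n, d = d, pi = pi, theta = theta,
                 all_identical = all_identical),
            class = "clade_diversity")
}

#' Corrected mean divergence K between two clades
#'
#' Mean maximum-likelihood model-corrected distance over all cross-clade
#' sequence pairs.
#'
#' @param aln An `alignment`.
#' @param tips_a,tips_b Disjoint label sets.
#' @param model A `subst_model` used for the multiple-hit correction.
#' @return K in expected substitutions per site.
#' @export
between_clade_K <- function(aln, tips_a, tips_b, model) {
  if (length(intersect(tips_a, tips_b))) stop("clades overlap")
  vals <- outer(tips_a, tips_b,
                Vectorize(function(i, j) as.numeric(ml_pairwise_distance(model, aln, i, j))))
  mean(vals)
}

#' Pick clade pairs to test
#'
#' For each maximal (non-nested) well-supported clade, pairs it with its
#' sister clade when the sister is itself well-supported or a single tip;
#' otherwise with the well-supported, non-nested clade minimizing K. Each
#' unordered pair is reported once.
#'
#' @param tree Rooted `phylo` with bootstrap supports (the NJ tree).
#' @param clades List from [well_supported_clades()].
#' @param aln An `alignment` (used for K in the fallback).
#' @param model A `subst_model` (used for K in the fallback).
#' @return A list of pairs, each a list `a`, `b` (label vectors) and
#'   `is_sister` (logical).
#' @export
select_comparison_pairs <- function(tree, clades, aln, model) {
  if (length(clades) < 2L) return(list())
  tipsets <- lapply(clades, `[[`, "tips")
  is_nested <- vapply(seq_along(tipsets), function(i) {
    any(vapply(seq_along(tipsets), function(j) {
      i != j && all(tipsets[[i]] %in% tipsets[[j]])
    }, logical(1L)))
  }, logical(1L))
  maximal <- clades[!is_nested]
  if (length(maximal) == 0L) return(list())

  sister_tips <- function(node) {
    par <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(par) == 0L) return(NULL)              # clade is the root
    sibs <- tree$edge[tree$edge[, 1L] == par, 2L]
    sibs <- setdiff(sibs, node)
    unlist(lapply(sibs, function(s) tip_labels_below(tree, s)))
  }
  max_sets <- lapply(maximal, `[[`, "tips")
  is_supported_set <- function(tips) {
    any(vapply(tipsets, function(ts) setequal(ts, tips), logical(1L)))
  }

  pairs <- list()
  seen <- character(0L)
  add_pair <- function(a, b, is_sister) {
    key <- paste(sort(c(paste(sort(a), collapse = ","),
                        paste(sort(b), collapse = ","))), collapse = "|")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    pairs[[length(pairs) + 1L]] <<- list(a = a, b = b, is_sister = is_sister)
  }

  for (cl in maximal) {
    sis <- sister_tips(cl$node)
    if (!is.null(sis) && length(sis) >= 1L &&
        (length(sis) == 1L || is_supported_set(sis))) {
      add_pair(cl$tips, sis, TRUE)
      next
    }
    ## fallback: well-supported, non-nested clade with the smallest K
    cand <- Filter(function(ts) length(intersect(ts, cl$tips)) == 0L, max_sets)
    if (length(cand) == 0L) next
    Ks <- vapply(cand, function(ts) between_clade_K(aln, cl$tips, ts, model),
                 numeric(1L))
    add_pair(cl$tips, cand[[which.min(Ks)]], FALSE)
  }
  pairs
}

tip_labels_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tip_labels_below, tree = tree))
}

#' K/theta test for one clade pair
#'
#' Assembles within-clade diversities, the corrected between-clade
#' divergence K, the ratio K/theta, and the probability that samples of the
#' two clade sizes drawn from populations separated `tau = K/theta` (in
#' units of Ne generations) are reciprocally monophyletic. The pair is
#' called a species when `K/theta >= ratio_threshold` and
#' `p >= p_threshold`; when the ratio passes but p falls short of the
#' threshold by less than 5% the pair is flagged for inspection rather than
#' rejected outright.
#'
#' @param aln An `alignment`.
#' @param pair A list with elements `a`, `b` (label vectors) and optionally
#'   `is_sister`.
#' @param model A `subst_model`.
#' @param config See [ktheta_config()].
#' @return A list of class `ktheta_result`.
#' @export
ktheta_test <- function(aln, pair, model, config = ktheta_config()) {
  div_a <- clade_diversity(aln, pair$a)
  div_b <- clade_diversity(aln, pair$b)
  if (div_a$n == 1L && div_b$n == 1L) {
    stop("theta is undefined on both sides: both clades are singletons")
  }
  K <- between_clade_K(aln, pair$a, pair$b, model)
  th <- select_theta(div_a, div_b, config$theta_rule)
  ratio <- K / th$theta
  tau <- ratio          # separation time in Ne generations implied by K/theta
  p <- reciprocal_monophyly_prob(div_a$n, div_b$n, tau,
                                 mode = if (div_a$n <= 2L && div_b$n <= 2L) "closed" else "mc",
                                 mc_reps = config$mc_reps, seed = config$seed)
  decision <- ktheta_decision(ratio, p, config)
  structure(list(clade_a = div_a, clade_b = div_b, K = K,
                 theta_used = th$theta, theta_source = th$source,
                 ratio = ratio, n1 = div_a$n, n2 = div_b$n,
                 tau = tau, p_2clades = p,
                 is_sister = isTRUE(pair$is_sister), decision = decision),
            class = "ktheta_result")
}

## theta selection: default the larger theta (conservative). With rule
## "smaller_on_n2", when the larger-theta clade has n = 2 -- where
## pi = 2*d is likely an over-correction -- the smaller theta is used.
select_theta <- function(div_a, div_b, rule = c("larger", "smaller_on_n2")) {
  rule <- match.arg(rule)
  if (div_a$n == 1L) return(list(theta = div_b$theta, source = "clade_b (other clade is a singleton)"))
  if (div_b$n == 1L) return(list(theta = div_a$theta, source = "clade_a (other clade is a singleton)"))
  larger <- if (div_a$theta >= div_b$theta) "a" else "b"
  big <- if (larger == "a") div_a else div_b
  sml <- if (larger == "a") div_b else div_a
  if (rule == "smaller_on_n2" && big$n == 2L) {
    return(list(theta = sml$theta,
                source = sprintf("clade_%s (larger theta from n = 2 treated as over-corrected)",
                                 if (larger == "a") "b" else "a")))
  }
  list(theta = big$theta, source = sprintf("clade_%s (larger theta)", larger))
}

## The ratio threshold is hard (K/theta >= 4 defines the gap); only a p
## value narrowly below its threshold downgrades a pass to "flagged".
ktheta_decision <- function(ratio, p, config = ktheta_config()) {
  if (ratio < config$ratio_threshold) return("not-species")
  if (p >= config$p_threshold) return("species")
  if (p >= config$p_threshold * (1 - config$flag_margin)) return("flagged")
  "not-species"
}

#' Configuration for the K/theta pipeline
#'
#' @param support_threshold Minimum bootstrap proportion for a clade to be
#'   considered (default 0.90).
#' @param ratio_threshold Species threshold on K/theta (default 4).
#' @param p_threshold Minimum reciprocal-monophyly probability (default
#'   0.95).
#' @param flag_margin Relative shortfall in p below `p_threshold` still
#'   reported as "flagged" rather than "not-species" (default 0.05).
#' @param theta_rule `"larger"` (default) or `"smaller_on_n2"`.
#' @param boot_replicates Bootstrap replicates for clade support (default
#'   1000).
#' @param boot_method Distance method for bootstrap replicates (`"model"`
#'   or `"p"`).
#' @param mc_reps Monte Carlo replicates for the reciprocal-monophyly
#'   probability (default 1e5).
#' @param seed Integer RNG seed.
#' @param outgroup Optional outgroup labels, removed before delimitation.
#' @return A named list.
#' @export
ktheta_config <- function(support_threshold = 0.90, ratio_threshold = 4,
                          p_threshold = 0.95, flag_margin = 0.05,
                          theta_rule = c("larger", "smaller_on_n2"),
                          boot_replicates = 1000L, boot_method = c("model", "p"),
                          mc_reps = 1e5, seed = 1L, outgroup = character(0L)) {
  list(support_threshold = support_threshold, ratio_threshold = ratio_threshold,
       p_threshold = p_threshold, flag_margin = flag_margin,
       theta_rule = match.arg(theta_rule),
       boot_replicates = as.integer(boot_replicates),
       boot_method = match.arg(boot_method),
       mc_reps = mc_reps, seed = as.integer(seed), outgroup = outgroup)
}

#' Run the full K/theta delimitation
#'
#' The four-step procedure: (1) neighbor-joining tree on model-corrected
#' distances, midpoint-rooted (after removing any outgroup), bootstrap
#' supports, clades at `support_threshold`; (2) within-clade d, pi and
#' theta; (3) model-corrected between-clade K for each sister (or
#' closest-K) pair; (4) the K/theta ratio and reciprocal-monophyly
#' probability, and the species call. Deterministic under a fixed seed.
#'
#' @param aln An `alignment` with at least 4 sequences.
#' @param model A `subst_model`.
#' @param config See [ktheta_config()].
#' @return An object of class `ktheta` with elements `results` (list of
#'   `ktheta_result`), `table` (data frame), `tree` (rooted NJ tree with
#'   supports), `clades`, `config`.
#' @export
ktheta <- function(aln, model, config = ktheta_config()) {
  if (nrow(aln) < 4L) stop("need at least 4 sequences")
  if (length(config$outgroup)) {
    keep <- setdiff(aln_labels(aln), config$outgroup)
    aln <- aln_subset(aln, keep)
  }
  dm <- distance_matrix(aln, "model", model)
  nj_tree <- neighbor_joining(dm)
  rooted <- phangorn::midpoint(nj_tree)
  rooted <- bootstrap_support(aln, rooted, method = config$boot_method,
                              model = model, replicates = config$boot_replicates,
                              seed = config$seed)
  clades <- well_supported_clades(rooted, config$support_threshold)
  if (length(clades) == 0L) {
    warning("no clades reach the support threshold; nothing to test")
    return(structure(list(results = list(), table = ktheta_table(list()),
                          tree = rooted, clades = clades, config = config),
                     class = "ktheta"))
  }
  pairs <- select_comparison_pairs(rooted, clades, aln, model)
  results <- lapply(pairs, function(p) ktheta_test(aln, p, model, config))
  structure(list(results = results, table = ktheta_table(results),
                 tree = rooted, clades = clades, config = config),
            class = "ktheta")
}

ktheta_table <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(pair = character(0L), K = numeric(0L), theta = numeric(0L),
                      ratio = numeric(0L), n1 = integer(0L), n2 = integer(0L),
                      p_2clades = numeric(0L), is_sister = logical(0L),
                      decision = character(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(pair = paste0("{", paste(r$clade_a$tips, collapse = ","), "} vs {",
                             paste(r$clade_b$tips, collapse = ","), "}"),
               K = r$K, theta = r$theta_used, ratio = r$ratio,
               n1 = r$n1, n2 = r$n2, p_2clades = r$p_2clades,
               is_sister = r$is_sister, decision = r$decision,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.ktheta <- function(x, digits = 4, ...) {
  cat("K/theta species delimitation\n")
  cat("  clades at support >= ", x$config$support_threshold, ": ",
      length(x$clades), "; pairs tested: ", length(x$results), "\n", sep = "")
  if (nrow(x$table)) {
    tab <- x$table
    tab$K <- signif(tab$K, digits)
    tab$theta <- signif(tab$theta, digits)
    tab$ratio <- round(tab$ratio, 2)       # printed at 2 d.p., stored full
    tab$p_2clades <- round(tab$p_2clades, 3)
    tab$pair <- substr(tab$pair, 1L, 48L)
    print(tab, row.names = FALSE)
  } else cat("  (no testable pairs)\n")
  invisible(x)
}

#' @export
summary.ktheta <- function(object, ...) {
  tab <- object$table
  cat("K/theta delimitation summary\n")
  cat("  pairs tested:      ", nrow(tab), "\n")
  cat("  species calls:     ", sum(tab$decision == "species"), "\n")
  cat("  flagged:           ", sum(tab$decision == "flagged"), "\n")
  cat("  not-species:       ", sum(tab$decision == "not-species"), "\n")
  invisible(object)
}

#' @export
as.data.frame.ktheta <- function(x, ...) x$table

#' Write a K/theta report
#'
#' @param x A `ktheta` object.
#' @param tsv,json Optional output paths for the tabular (TSV) and full
#'   (JSON) reports.
#' @return Invisibly, `x`.
#' @export
write_ktheta_report <- function(x, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(x$table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(config = x$config,
                    tau_convention = "tau = K/theta, time in units of Ne generations",
                    results = lapply(x$results, function(r) {
                      r <- unclass(r)
                      r$clade_a <- unclass(r$clade_a)
                      r$clade_b <- unclass(r$clade_b)
                      r$p_2clades <- as.numeric(r$p_2clades)
                      r
                    }))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}
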