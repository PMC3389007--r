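## Multispecies-coalescent simulator. Within each species, lineages
## coalesce at pairwise rate 1/Ne per generation (haploid-style, so the
## expected coalescence time of two samples is Ne generations and
## theta = 2*Ne*mu exactly); surviving lineages enter the ancestral
## population at each divergence time and continue as a standard Kingman
## coalescent. Sequences evolve along the genealogy under a GTR(+I+G)
## model: the root sequence is drawn from the stationary frequencies and
## each branch applies P(mu * branch_length * site_rate). No
## recombination, migration or selection.

#' Simulation configuration
#'
#' @param species Data frame with columns `name`, `n` (tips sampled) and
#'   `Ne` (effective size, individuals), one row per species.
#' @param species_tree For one species `NULL`; for two species a single
#'   divergence time in generations; otherwise a rooted ultrametric `phylo`
#'   whose tip labels are the species names and whose branch lengths are in
#'   generations.
#' @param mu Mutation rate per site per generation.
#' @param L Number of sites.
#' @param model A `subst_model` (default Jukes-Cantor configuration).
#' @param Ne_ancestral Effective size of ancestral populations (default:
#'   mean of the species `Ne`).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`. Derived per-species
#'   `theta_true = 2 * Ne * mu` and, per species pair, divergence time `t`
#'   and expected divergence `E[K] = 2 * mu * t + 2 * Ne_ancestral * mu`
#'   are attached.
#' @export
sim_config <- function(species, species_tree = NULL, mu = 1e-8, L = 385L,
                       model = substitution_model(), Ne_ancestral = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(species), all(c("name", "n", "Ne") %in% names(species)))
  if (any(species$Ne <= 0) || mu <= 0 || L < 1L) stop("Ne, mu must be > 0 and L >= 1")
  if (anyDuplicated(species$name)) stop("species names must be unique")
  if (nrow(species) > 1L) {
    if (is.numeric(species_tree) && nrow(species) == 2L) {
      species_tree <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                                    species$name[1L], species_tree,
                                                    species$name[2L], species_tree))
    }
    if (!inherits(species_tree, "phylo")) stop("species_tree required for > 1 species")
    if (!setequal(species_tree$tip.label, species$name)) {
      stop("species_tree tips must match species names")
    }
    if (!is_ultrametric_tol(species_tree, 1e-6)) stop("species_tree must be ultrametric")
  }
  Ne_ancestral <- Ne_ancestral %||% mean(species$Ne)
  cfg <- structure(list(species = species, species_tree = species_tree,
                        mu = mu, L = as.integer(L), model = model,
                        Ne_ancestral = Ne_ancestral, seed = as.integer(seed)),
                   class = "sim_config")
  cfg$theta_true <- stats::setNames(2 * species$Ne * mu, species$name)
  cfg$pairs <- sim_pair_table(cfg)
  cfg
}

sim_pair_table <- function(cfg) {
  sp <- cfg$species$name
  if (length(sp) < 2L) return(NULL)
  cmb <- utils::combn(sp, 2L)
  dm <- ape::cophenetic.phylo(cfg$species_tree) / 2   # divergence times
  data.frame(a = cmb[1L, ], b = cmb[2L, ],
             t = dm[cbind(cmb[1L, ], cmb[2L, ])],
             expected_K = 2 * cfg$mu * dm[cbind(cmb[1L, ], cmb[2L, ])] +
               2 * cfg$Ne_ancestral * cfg$mu,
             stringsAsFactors = FALSE)
}

#' Read a simulation configuration from YAML
#'
#' The file holds `species` (a list of `name`/`n_tips`/`Ne` entries), `mu`, `L`,
#' optional `species_tree` (Newick string, branch lengths in generations, or
#' a single divergence time for two species), optional `Ne_ancestral`,
#' `seed`, and optionally `model` (a preset name or keys as in
#' [model_preset()]).
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## YAML 1.1 quirks: exponent notation without a sign (2.0e5) parses as
  ## text, and a bare key `n` parses as boolean FALSE -- hence `n_tips`
  num <- function(x) as.numeric(x)
  species <- do.call(rbind, lapply(cfg$species, function(s) {
    n <- s[["n_tips"]] %||% s[["n"]] %||% s[["FALSE"]]
    data.frame(name = s$name, n = num(n), Ne = num(s$Ne),
               stringsAsFactors = FALSE)
  }))
  tree <- cfg$species_tree
  if (is.character(tree)) {
    tree <- if (grepl("(", tree, fixed = TRUE)) ape::read.tree(text = tree)
    else as.numeric(tree)
  }
  model <- if (is.null(cfg$model)) substitution_model()
  else if (is.character(cfg$model)) model_preset(cfg$model)
  else substitution_model(freqs = unlist(cfg$model$freqs),
                          rates = unlist(cfg$model$rates),
                          p_inv = cfg$model$p_inv %||% 0,
                          gamma_shape = cfg$model$gamma_shape,
                          n_categories = cfg$model$categories %||% 4L)
  sim_config(species, species_tree = tree, mu = num(cfg$mu %||% 1e-8),
             L = num(cfg$L %||% 385L), model = model,
             Ne_ancestral = if (!is.null(cfg$Ne_ancestral)) num(cfg$Ne_ancestral),
             seed = cfg$seed %||% 1L)
}

#' Simulate a multispecies-coalescent genealogy
#'
#' @param config A `sim_config`.
#' @param seed Optional override of `config$seed`.
#' @return A rooted ultrametric `phylo` in units of generations; tips are
#'   labelled `<species>_<i>`. The mapping tip -> species is attached as
#'   attribute `species_map`.
#' @export
simulate_genealogy <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed %||% config$seed, simulate_genealogy_impl(config))
}

simulate_genealogy_impl <- function(config) {
  sp <- config$species
  tip_labels <- character(0L)
  tip_species <- character(0L)

  ## lineages carry their subtree as a growing Newick fragment plus the age
  ## of their top; the final phylo is parsed from the assembled string
  make_tips <- function(name, n) {
    labs <- paste0(name, "_", seq_len(n))
    tip_labels <<- c(tip_labels, labs)
    tip_species <<- c(tip_species, rep(name, n))
    lapply(labs, function(l) list(nwk = l, age = 0))
  }
  join <- function(l1, l2, age) {
    list(nwk = sprintf("(%s:%.12g,%s:%.12g)", l1$nwk, age - l1$age,
                       l2$nwk, age - l2$age),
         age = age)
  }
  coalesce <- function(lineages, Ne, t_start, t_end) {
    t <- t_start
    while (length(lineages) > 1L) {
      k <- length(lineages)
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / Ne)
      if (t > t_end) return(lineages)
      pick <- sample.int(k, 2L)
      merged <- join(lineages[[pick[1L]]], lineages[[pick[2L]]], t)
      lineages <- c(lineages[-pick], list(merged))
    }
    lineages
  }

  if (nrow(sp) == 1L) {
    pool <- coalesce(make_tips(sp$name[1L], sp$n[1L]), sp$Ne[1L], 0, Inf)
  } else {
    st <- stats::reorder(config$species_tree, "cladewise")
    nsp <- length(st$tip.label)
    depths <- ape::node.depth.edgelength(st)
    age_of <- max(depths[seq_len(nsp)]) - depths
    age_of[age_of < 0] <- 0
    ## process species-tree nodes by increasing age: coalesce each child
    ## population over its time span, then pool survivors in the ancestor
    pools <- vector("list", nsp + st$Nnode)
    for (i in seq_len(nsp)) {
      row <- match(st$tip.label[i], sp$name)
      pools[[i]] <- make_tips(sp$name[row], sp$n[row])
    }
    ord <- order(age_of[(nsp + 1L):(nsp + st$Nnode)]) + nsp
    for (v in ord) {
      kids <- st$edge[st$edge[, 1L] == v, 2L]
      for (kid in kids) {
        Ne_kid <- if (kid <= nsp) sp$Ne[match(st$tip.label[kid], sp$name)] else
          config$Ne_ancestral
        pools[[kid]] <- coalesce(pools[[kid]], Ne_kid, age_of[kid], age_of[v])
      }
      pools[[v]] <- do.call(c, pools[kids])
    }
    root <- ord[length(ord)]
    pool <- coalesce(pools[[root]], config$Ne_ancestral, age_of[root], Inf)
  }

  tr <- ape::read.tree(text = paste0(pool[[1L]]$nwk, ";"))
  attr(tr, "species_map") <- stats::setNames(tip_species, tip_labels)
  tr
}

#' Simulate sequences along a genealogy
#'
#' @param tree A rooted `phylo` with branch lengths in generations.
#' @param model A `subst_model`.
#' @param mu Mutation rate per site per generation.
#' @param L Number of sites.
#' @param seed Integer RNG seed.
#' @return An `alignment` of the tip sequences.
#' @export
simulate_sequences <- function(tree, model, mu, L, seed = 1L) {
  stopifnot(inherits(model, "subst_model"), mu >= 0, L >= 1L)
  with_seed(seed, {
    tr <- stats::reorder(tree, "cladewise")
    n <- length(tr$tip.label)
    nnode <- tr$Nnode
    ## per-site rate categories: invariant with prob p_inv, otherwise one of
    ## the discrete gamma categories (rate 0 encodes invariant)
    k <- length(model$cat_rates)
    cat_idx <- sample.int(k, L, replace = TRUE)
    site_rate <- model$cat_rates[cat_idx]
    if (model$p_inv > 0) {
      site_rate[stats::runif(L) < model$p_inv] <- 0
    }
    seqs <- matrix(NA_integer_, n + nnode, L)
    root <- n + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$freqs)
    rates_used <- sort(unique(site_rate[site_rate > 0]))
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      t <- mu * tr$edge.length[e]
      child_seq <- seqs[par, ]
      if (t > 0) {
        for (r in rates_used) {
          P <- transition_matrix(model, t, r)
          sites <- which(site_rate == r)
          for (b in 1:4) {
            sb <- sites[seqs[par, sites] == b]
            if (length(sb)) {
              child_seq[sb] <- sample.int(4L, length(sb), replace = TRUE,
                                          prob = P[b, ])
            }
          }
        }
      }
      seqs[child, ] <- child_seq
    }
    mat <- matrix(BASES[seqs[seq_len(n), , drop = FALSE]], nrow = n,
                  dimnames = list(tr$tip.label, NULL))
    structure(mat, class = "alignment")
  })
}
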