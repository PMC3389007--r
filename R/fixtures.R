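## Benchmark fixtures with the statistical shape of real single-locus
## delimitation data sets: several morphospecies containing 1-7 cryptic
## species, within-species theta of order 0.001-0.02, between-species
## corrected divergence of order 0.02-0.14, and duplicate specimens so the
## complete/haplotype-pruned analysis pair is exercised. Specimen and
## distinct-haplotype counts are engineered to fixed values (58/29 for the
## COI-like preset, 22/14 for the ITS2-like preset) so report layouts and
## the pruned variants are reproducible; the engineering step either
## collapses the closest within-species haplotype pair or introduces a
## single extra substitution, whichever direction is needed.

#' Generate a benchmark fixture
#'
#' @param preset `"coi_like"` (58 specimens, 29 distinct haplotypes, 16
#'   species in 5 morphospecies, GTR+I+G model, 385 bp) or `"its2_like"`
#'   (22 specimens, 14 distinct haplotypes, 5 species, GTR+G model), or a
#'   `sim_config` for a custom simulation (no haplotype engineering).
#' @param seed Integer RNG seed.
#' @return A list with `alignment`, `tree` (the true genealogy, branch
#'   lengths in generations), `config`, and `truth`: a list with
#'   `specimens` (label, species, morphospecies), `species` (name,
#'   theta_true) and `pairs` (divergence time and expected K per species
#'   pair).
#' @export
generate_fixture <- function(preset = "coi_like", seed = 1L) {
  if (inherits(preset, "sim_config")) {
    return(build_fixture(preset, n_extra = 0L, n_haplotypes = NA_integer_,
                         morpho = NULL, seed = seed))
  }
  preset <- match.arg(preset, c("coi_like", "its2_like"))
  if (preset == "coi_like") {
    ## 5 morphospecies; 16 species; 29 haplotype carriers + 29 duplicates
    spec <- data.frame(
      name = c(paste0("bra", 1:7), paste0("ste", 1:5), paste0("aot", 1:2),
               "rei1", "koh1"),
      n = c(3, 2, 2, 2, 1, 1, 1,  3, 2, 2, 1, 1,  3, 2,  2, 1),
      Ne = c(2.5e5, 1e5, 3e5, 2e5, 1.5e5, 2.5e5, 1e5,
             3e5, 1.2e5, 2e5, 1.5e5, 1e5,  3.3e5, 1.7e5,  5e5, 1e6),
      morpho = c(rep("brasiliensis", 7), rep("stevensoni", 5),
                 rep("aotearoa", 2), "reidae", "kohanga"),
      stringsAsFactors = FALSE)
    st <- fixture_species_tree(spec$name, split(spec$name, spec$morpho),
                               t_within = 2.5e6, t_between = 9e6)
    cfg <- sim_config(spec[, c("name", "n", "Ne")], species_tree = st,
                      mu = 1e-8, L = 385L, model = model_preset("coi_paper"),
                      Ne_ancestral = 2e5, seed = seed)
    build_fixture(cfg, n_extra = 29L, n_haplotypes = 29L,
                  morpho = stats::setNames(spec$morpho, spec$name), seed = seed)
  } else {
    spec <- data.frame(
      name = c("braAE", "braBR", "ste1", "aot1", "koh1"),
      n = c(4, 3, 3, 2, 2),
      Ne = c(4e5, 5e5, 4e5, 3e5, 5e5),
      morpho = c("brasiliensis", "brasiliensis", "stevensoni", "aotearoa",
                 "kohanga"),
      stringsAsFactors = FALSE)
    st <- fixture_species_tree(spec$name, split(spec$name, spec$morpho),
                               t_within = 8e6, t_between = 2e7)
    cfg <- sim_config(spec[, c("name", "n", "Ne")], species_tree = st,
                      mu = 2e-9, L = 300L, model = model_preset("its2_paper"),
                      Ne_ancestral = 4e5, seed = seed)
    build_fixture(cfg, n_extra = 8L, n_haplotypes = 14L,
                  morpho = stats::setNames(spec$morpho, spec$name), seed = seed)
  }
}

## Ladder species tree: species of the same morphospecies split at
## staggered times around t_within; morphospecies split at t_between and
## deeper. Built as (subtree, age) pairs joined at explicit ages, so the
## result is ultrametric by construction.
fixture_species_tree <- function(names, groups, t_within, t_between) {
  join_at <- function(l1, l2, age) {
    list(nwk = sprintf("(%s:%.10g,%s:%.10g)", l1$nwk, age - l1$age,
                       l2$nwk, age - l2$age),
         age = age)
  }
  ladder <- function(items, ages) {
    cur <- items[[1L]]
    for (i in seq_along(ages)) cur <- join_at(cur, items[[i + 1L]], ages[i])
    cur
  }
  subtrees <- lapply(groups, function(members) {
    tips <- lapply(members, function(m) list(nwk = m, age = 0))
    if (length(members) == 1L) return(tips[[1L]])
    ladder(tips, t_within * (1 + 0.35 * seq(0, length(members) - 2L)))
  })
  root <- if (length(subtrees) == 1L) subtrees[[1L]] else
    ladder(subtrees, t_between * (1 + 0.25 * seq(0, length(subtrees) - 2L)))
  ape::read.tree(text = paste0(root$nwk, ";"))
}

build_fixture <- function(cfg, n_extra, n_haplotypes, morpho, seed) {
  tree <- simulate_genealogy(cfg, seed = child_seed(seed, 1L))
  aln <- simulate_sequences(tree, cfg$model, cfg$mu, cfg$L,
                            seed = child_seed(seed, 2L))
  species_map <- attr(tree, "species_map")

  ## duplicate specimens: extra copies of existing haplotypes, spread over
  ## the sampled specimens round-robin (larger species first)
  if (n_extra > 0L) {
    donors <- with_seed(child_seed(seed, 3L), {
      ord <- names(sort(table(species_map), decreasing = TRUE))
      by_sp <- split(names(species_map), species_map)[ord]
      pool <- unlist(lapply(by_sp, function(v) v[order(v)]), use.names = FALSE)
      rep_len(pool, n_extra)
    })
    M <- unclass(aln)
    extra <- M[donors, , drop = FALSE]
    rownames(extra) <- paste0(donors, "_dup", seq_len(n_extra))
    aln <- structure(rbind(M, extra), class = "alignment")
    species_map <- c(species_map, stats::setNames(species_map[donors],
                                                  rownames(extra)))
  }
  if (!is.na(n_haplotypes)) {
    aln <- adjust_haplotype_count(aln, species_map, n_haplotypes,
                                  seed = child_seed(seed, 4L))
  }
  specimens <- data.frame(label = aln_labels(aln),
                          species = unname(species_map[aln_labels(aln)]),
                          stringsAsFactors = FALSE)
  if (!is.null(morpho)) specimens$morphospecies <- unname(morpho[specimens$species])
  truth <- list(specimens = specimens,
                species = data.frame(name = names(cfg$theta_true),
                                     theta_true = unname(cfg$theta_true),
                                     stringsAsFactors = FALSE),
                pairs = cfg$pairs)
  list(alignment = aln, tree = tree, config = cfg, truth = truth)
}

## Force the number of distinct haplotypes to `target`: merge the closest
## within-species haplotype pair while there are too many, or add a single
## substitution to a duplicated haplotype while there are too few.
adjust_haplotype_count <- function(aln, species_map, target, seed) {
  with_seed(seed, {
    M <- unclass(aln)
    repeat {
      seqs <- apply(M, 1L, paste, collapse = "")
      h <- length(unique(seqs))
      if (h == target) break
      if (h > target) {
        ## merge: within some species, overwrite the rarer of the two
        ## closest distinct haplotypes with the other
        best <- NULL
        for (sp in unique(species_map)) {
          rows <- names(species_map)[species_map == sp]
          rows <- rows[rows %in% rownames(M)]
          u <- rows[!duplicated(seqs[rows])]
          useq <- seqs[u]
          u <- u[!duplicated(useq)]
          if (length(u) < 2L) next
          for (a in seq_len(length(u) - 1L)) for (b in (a + 1L):length(u)) {
            dd <- sum(M[u[a], ] != M[u[b], ])
            if (is.null(best) || dd < best$d) best <- list(d = dd, a = u[a], b = u[b])
          }
        }
        if (is.null(best)) stop("cannot reduce haplotype count further")
        victims <- rownames(M)[seqs == seqs[best$b]]
        M[victims, ] <- matrix(M[best$a, ], length(victims), ncol(M), byrow = TRUE)
      } else {
        ## split: mutate one copy of a duplicated haplotype at one site
        dup_rows <- rownames(M)[duplicated(seqs) | duplicated(seqs, fromLast = TRUE)]
        if (length(dup_rows) == 0L) stop("cannot increase haplotype count further")
        row <- sample(dup_rows, 1L)
        site <- sample.int(ncol(M), 1L)
        cur <- M[row, site]
        M[row, site] <- sample(setdiff(BASES, cur), 1L)
      }
    }
    structure(M, class = "alignment")
  })
}

#' Write fixture files
#'
#' Emits the alignment (FASTA), the true genealogy (Newick, both in
#' generations and rescaled to expected substitutions/site), and the truth
#' table (TSV).
#'
#' @param fx A fixture from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_fixture <- function(fx, dir, prefix = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    tree_gen = file.path(dir, paste0(prefix, "_genealogy_generations.nwk")),
    tree_subs = file.path(dir, paste0(prefix, "_genealogy_subs.nwk")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_fasta(fx$alignment, paths["fasta"])
  write_newick(fx$tree, paths["tree_gen"])
  scaled <- fx$tree
  scaled$edge.length <- scaled$edge.length * fx$config$mu
  write_newick(scaled, paths["tree_subs"])
  utils::write.table(fx$truth$specimens, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
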