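## Tree building and bookkeeping on ape "phylo" objects. Bootstrap supports
## are stored in node.label as proportions in [0, 1]; Newick percentage
## supports (values > 1) are rescaled on parse.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (via [ape::nj()]); negative estimated branch
#' lengths are clamped to zero and the total clamped deficit reported in
#' attribute `clamped`.
#'
#' @param dm Symmetric labelled distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D))) stop("non-finite distances")
  tr <- if (nrow(D) == 3L) {
    ## 3-taxon star solved directly from the pairwise equations
    labs <- rownames(D)
    v <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    structure(list(edge = cbind(4L, 1:3), edge.length = v,
                   tip.label = labs, Nnode = 1L),
              class = "phylo", order = "cladewise")
  } else {
    ape::nj(D)
  }
  clamp_branches(tr)
}

clamp_branches <- function(tr) {
  neg <- tr$edge.length < 0
  deficit <- 0
  if (any(neg)) {
    deficit <- -sum(tr$edge.length[neg])
    if (deficit > 1e-8) {
      message("clamped ", sum(neg), " negative branch length(s); total deficit ",
              signif(deficit, 4))
    }
    tr$edge.length[neg] <- 0
  }
  attr(tr, "clamped") <- deficit
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree; node
#' ages are half the merge distances.
#'
#' @param dm Symmetric labelled distance matrix (>= 2 taxa).
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma <- function(dm) {
  D <- as.matrix(dm)
  if (nrow(D) < 2L) stop("UPGMA needs at least 2 taxa")
  if (any(!is.finite(D))) stop("non-finite distances")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(hc)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Root-to-tip consistency check
#'
#' @param tree A rooted `phylo`.
#' @param tol Relative tolerance on root-to-tip path spread, as a fraction of
#'   tree height.
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  if (!ape::is.rooted(tree)) return(FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (max(depths) - min(depths)) <= tol * h
}

#' Node ages of an ultrametric tree
#'
#' @param tree A rooted, ultrametric `phylo` (within `tol`).
#' @param tol Relative ultrametricity tolerance.
#' @return Named numeric vector of internal-node ages (time before present),
#'   sorted in decreasing order (root first). A binary tree with N tips
#'   yields N - 1 ages.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is_ultrametric_tol(tree, tol)) {
    stop("tree is not ultrametric within relative tolerance ", tol,
         "; build one with upgma() on model distances or supply a chronogram")
  }
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(n)])
  ages <- h - depth[(n + 1L):(n + tree$Nnode)]
  ages[ages < 0] <- 0
  names(ages) <- as.character((n + 1L):(n + tree$Nnode))
  sort(ages, decreasing = TRUE)
}

#' Branching times, root first
#'
#' @inheritParams node_ages
#' @return Numeric vector of internal node ages in decreasing order.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  unname(node_ages(tree, tol))
}

#' Bootstrap supports on a reference tree
#'
#' Resamples alignment columns with replacement, rebuilds a neighbor-joining
#' tree per replicate and annotates each internal edge of the reference tree
#' with the proportion of replicates containing the same bipartition.
#'
#' @param aln An `alignment`.
#' @param reference A `phylo` built from the same labels.
#' @param method Distance method per replicate (`"p"` or `"model"`).
#' @param model A `subst_model` when `method = "model"`.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed; the run is bit-reproducible.
#' @return The reference tree with `node.label` set to support proportions.
#' @export
bootstrap_support <- function(aln, reference, method = c("p", "model"),
                              model = NULL, replicates = 100L, seed = 1L) {
  method <- match.arg(method)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (ncol(aln) < 2L) stop("alignment too short to resample")
  if (!setequal(aln_labels(aln), reference$tip.label)) {
    stop("reference tree labels do not match the alignment")
  }
  M <- unclass(aln)
  trees <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      baln <- structure(M[, cols, drop = FALSE], class = "alignment")
      neighbor_joining(distance_matrix(baln, method, model))
    })
  })
  counts <- ape::prop.clades(reference, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  reference$node.label <- counts / replicates
  reference
}

#' Clades supported above a bootstrap threshold
#'
#' @param tree A rooted `phylo` with numeric `node.label` supports in
#'   `[0, 1]`.
#' @param threshold Minimum support (default 0.90).
#' @return A list of clades, largest first; each is a list with elements
#'   `tips`, `support` and `node`. Single tips are excluded.
#' @export
well_supported_clades <- function(tree, threshold = 0.90) {
  if (is.null(tree$node.label)) stop("tree carries no support values")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(sup))) stop("tree carries no numeric support values")
  n <- length(tree$tip.label)
  nodes <- (n + 1L):(n + tree$Nnode)
  desc <- node_tips(tree)
  ntip <- vapply(desc, length, integer(1L))
  ## the root (all tips) is a trivial clade; tips are excluded by construction
  keep <- which(!is.na(sup) & sup >= threshold & ntip < n)
  clades <- lapply(keep, function(k) {
    list(tips = desc[[k]], support = sup[k], node = nodes[k])
  })
  clades[order(vapply(clades, function(cl) length(cl$tips), integer(1L)),
               decreasing = TRUE)]
}

#' Write a clade report as TSV
#'
#' One row per clade: id, support, tip count and comma-separated tip list.
#'
#' @param clades List from [well_supported_clades()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clade_report <- function(clades, path) {
  df <- do.call(rbind, lapply(seq_along(clades), function(i) {
    cl <- clades[[i]]
    data.frame(clade = i, support = cl$support, n_tips = length(cl$tips),
               tips = paste(sort(cl$tips), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(clade = integer(0), support = numeric(0),
                     n_tips = integer(0), tips = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## tip labels under each internal node, in internal-node order
node_tips <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(ix) attr(pp, "labels")[ix])
}

#' Parse and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that check
#' label uniqueness, rescale percentage supports (values > 1) to
#' proportions, and optionally enforce ultrametricity.
#'
#' @param text Newick string (or use `path`).
#' @param path Path to a Newick file.
#' @param ultrametric If `TRUE`, error unless the tree is ultrametric within
#'   `tol`.
#' @param tol Relative ultrametricity tolerance.
#' @return A `phylo`.
#' @export
parse_newick <- function(text = NULL, path = NULL, ultrametric = FALSE,
                         tol = 1e-6) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in Newick input")
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (any(!is.na(sup) & sup > 1)) {
      sup <- sup / 100   # percentage dialect
      tr$node.label <- ifelse(is.na(sup), tr$node.label, sup)
    }
  }
  if (ultrametric && !is_ultrametric_tol(tr, tol)) {
    stop("tree is not ultrametric within relative tolerance ", tol)
  }
  tr
}

#' @rdname parse_newick
#' @param tree A `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}
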