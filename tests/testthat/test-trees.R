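test_that("neighbor joining solves the 3-taxon case and is consistent on additive data", {
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = .05, b = .15, c = .25))

  # additive 5-taxon matrix from a known tree is recovered exactly
  ref <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.1,e:0.3);")
  Dref <- ape::cophenetic.phylo(ref)
  rec <- neighbor_joining(Dref)
  expect_equal(ape::dist.topo(ape::unroot(ref), rec), 0, ignore_attr = TRUE)
  expect_equal(sort(ape::cophenetic.phylo(rec)[rownames(Dref), colnames(Dref)]),
               sort(Dref), tolerance = 1e-9)

  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  D_bad <- D; D_bad[1, 2] <- D_bad[2, 1] <- NA
  expect_error(neighbor_joining(D_bad), "non-finite")
})

test_that("negative NJ branch estimates are clamped to zero", {
  # a quartet violating the four-point condition induces a negative branch
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[lower.tri(D)] <- c(0.221, 0.400, 0.471, 0.145, 0.343, 0.106)
  D <- D + t(D)
  tr <- suppressMessages(neighbor_joining(D))
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamped"), 0)
})

test_that("UPGMA returns ultrametric trees and recovers ultrametric input", {
  D2 <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  u2 <- upgma(D2)
  expect_equal(max(node_ages(u2)), 0.1)   # root age = half the distance

  ref <- ape::read.tree(text = "((a:1,b:1):2,(c:2.5,d:2.5):0.5);")
  Du <- ape::cophenetic.phylo(ref)
  rec <- upgma(Du)
  expect_true(is_ultrametric_tol(rec))
  expect_equal(sort(branching_times(rec)), sort(branching_times(ref)),
               tolerance = 1e-9)

  # non-ultrametric input: deterministic, ages non-decreasing toward root
  Dn <- ape::cophenetic.phylo(ape::read.tree(
    text = "((a:0.1,b:0.4):0.2,(c:0.3,d:0.9):0.1);"))
  tr <- upgma(Dn)
  expect_true(is_ultrametric_tol(tr))
  expect_identical(ape::write.tree(tr), ape::write.tree(upgma(Dn)))
})

test_that("Newick parse/write round-trips and validates", {
  tr <- parse_newick("((a:1,b:1):1,c:2);")
  expect_equal(branching_times(tr), c(2, 1))
  expect_true(is_ultrametric_tol(tr))

  # 50-tip random tree round-trip
  big <- random_coalescent_tree(50, seed = 11)
  txt <- write_newick(big)
  back <- parse_newick(txt)
  expect_identical(write_newick(back), txt)

  expect_error(parse_newick("((a:1,b:2):1,a:2);"), "duplicate")
  expect_error(parse_newick("((a:1,b:2):1,c:2);", ultrametric = TRUE),
               "not ultrametric")

  # percentage supports are rescaled to proportions
  ts <- parse_newick("((a:1,b:1)95:1,(c:1,d:1)60:1);")
  expect_equal(suppressWarnings(as.numeric(ts$node.label)),
               c(NA, 0.95, 0.60))
})

test_that("branching times require rooted ultrametric trees", {
  t4 <- parse_newick("((a:1,b:1):2,(c:1,d:1):2);")
  expect_equal(branching_times(t4), c(3, 1, 1))
  nonum <- parse_newick("((a:1,b:2):1,c:2);")
  expect_error(branching_times(nonum), "upgma|chronogram")
  # tied ages from a zero-length internal branch are preserved
  tz <- parse_newick("(((a:1,b:1):0,c:1):1,d:2);")
  expect_equal(branching_times(tz), c(2, 1, 1))
})

test_that("bootstrap supports are reproducible and sensible", {
  # two deeply divergent groups of identical sequences: support 1
  g1 <- paste(rep("A", 60), collapse = "")
  g2 <- paste(c(rep("C", 30), rep("A", 30)), collapse = "")
  aln <- alignment(c(a1 = g1, a2 = g1, b1 = g2, b2 = g2))
  ref <- phangorn::midpoint(neighbor_joining(distance_matrix(aln, "p")))
  bs <- bootstrap_support(aln, ref, method = "p", replicates = 100, seed = 1)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_true(any(sup == 1, na.rm = TRUE))

  # same seed reproduces bit-identically; different seed stays close
  bs2 <- bootstrap_support(aln, ref, method = "p", replicates = 100, seed = 1)
  expect_identical(bs$node.label, bs2$node.label)

  # conflicting sites: equidistant taxa get weak internal support
  conf <- alignment(c(a = "AACCAACCAACC", b = "AAAACCCCAACC",
                      c = "CCAACCAAAACC", d = "CCCCAAAAAACC"))
  refc <- phangorn::midpoint(neighbor_joining(distance_matrix(conf, "p")))
  bsc <- bootstrap_support(conf, refc, method = "p", replicates = 200, seed = 2)
  supc <- suppressWarnings(as.numeric(bsc$node.label))
  expect_true(all(supc[-1] < 0.9, na.rm = TRUE))

  expect_error(bootstrap_support(alignment(c(a = "A", b = "C", c = "G")),
                                 ref, replicates = 10, seed = 1),
               "too short|labels")
})

test_that("well-supported clade extraction respects threshold and nesting", {
  tr <- parse_newick("(((a:1,b:1)0.95:1,c:2)0.5:1,(d:1.5,e:1.5)0.92:1.5);")
  cl <- well_supported_clades(tr, 0.9)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, function(x) paste(sort(x$tips), collapse = ","),
                         character(1)), c("a,b", "d,e"))
  # threshold 0 returns every internal (non-root) labelled edge
  cl0 <- well_supported_clades(tr, 0)
  expect_length(cl0, 3L)
  # nested clades both above threshold are both returned
  tn <- parse_newick("(((a:1,b:1)0.99:1,c:2)0.95:1,d:3);")
  cln <- well_supported_clades(tn, 0.9)
  expect_length(cln, 2L)
  expect_error(well_supported_clades(ape::rtree(4)), "no support")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_clade_report(cl, f)
  rep <- read.delim(f)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$support >= 0.9))
})

test_that("bipartition supports are invariant under re-rooting of the reference", {
  aln <- random_aln(6, 200, seed = 21)
  nj <- neighbor_joining(distance_matrix(aln, "p"))
  r1 <- phangorn::midpoint(nj)
  r2 <- ape::root(nj, outgroup = aln_labels(aln)[1], resolve.root = TRUE)
  b1 <- bootstrap_support(aln, r1, method = "p", replicates = 50, seed = 9)
  b2 <- bootstrap_support(aln, r2, method = "p", replicates = 50, seed = 9)
  # compare supports attached to identical bipartitions
  key <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sup <- suppressWarnings(as.numeric(tr$node.label))
    out <- vapply(seq_along(pp), function(i) {
      side <- sort(labs[pp[[i]]])
      other <- sort(setdiff(labs, side))
      paste(min(paste(side, collapse = ","), paste(other, collapse = ",")),
            collapse = "|")
    }, character(1))
    setNames(sup, out)
  }
  k1 <- key(b1); k2 <- key(b2)
  shared <- intersect(names(k1), names(k2))
  shared <- shared[!is.na(k1[shared]) & !is.na(k2[shared])]
  expect_gt(length(shared), 0)
  expect_equal(k1[shared], k2[shared])
})
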