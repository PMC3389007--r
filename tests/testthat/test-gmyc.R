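test_that("the GMYC interval likelihood matches hand-computed cases", {
  # 2-tip tree, height 1, degenerate (all-coalescent) classification with
  # hazard b = lambda*[2*1]^p: at b = 1, LL = ln(1) - 1 = -1
  t2 <- parse_newick("(a:1,b:1);")
  expect_equal(gmyc_loglik(t2, thresholds = 1 + 1e-9, lambda_spec = 1,
                           p_spec = 1, lambda_coal = 0.5, p_coal = 1), -1)
  # all-speciation classification on the same tree: b = lambda_spec*2^p
  expect_equal(gmyc_loglik(t2, thresholds = 0.5, lambda_spec = 0.5,
                           p_spec = 1, lambda_coal = 7, p_coal = 1), -1)

  # 3-tip tree ((a:1,b:1):1,c:2): intervals x = (1,1) with n = (2,3);
  # null: LL = sum(log(l*(n(n-1))^p) - l*(n(n-1))^p * x)
  t3 <- parse_newick("((a:1,b:1):1,c:2);")
  l <- 0.2; p <- 0.7
  manual <- sum(log(l * c(2, 6)^p) - l * c(2, 6)^p * 1)
  expect_equal(gmyc_loglik(t3, thresholds = 2 + 1e-9, 1, 1, l, p), manual)

  # threshold between the two nodes: interval 1 is diversification (k=2),
  # interval 2 one cluster of 2 plus a singleton crossing (k=1, m=2)
  ls <- 0.3; ps <- 1.2; lc <- 0.5; pc <- 0.8
  b1 <- ls * 2^ps
  b2 <- ls * 1^ps + lc * (2 * 1)^pc
  expect_equal(gmyc_loglik(t3, thresholds = 1.5, ls, ps, lc, pc),
               (log(b1) - b1) + (log(b2) - b2))

  # label permutation leaves the likelihood unchanged
  t3b <- parse_newick("((b:1,a:1):1,c:2);")
  expect_equal(gmyc_loglik(t3b, 1.5, ls, ps, lc, pc),
               gmyc_loglik(t3, 1.5, ls, ps, lc, pc))
})

test_that("single-threshold fit nests the null and separates clean clusters", {
  # two near-monomorphic species, deep split: n_species = 2 with a tight CI
  tr <- parse_newick(paste0("((a1:0.001,(a2:0.0005,a3:0.0005):0.0005):0.999,",
                            "(b1:0.0008,(b2:0.0004,b3:0.0004):0.0004):0.9992);"))
  fit <- fit_gmyc_single(tr)
  expect_s3_class(fit, "gmyc")
  expect_gte(fit$ll_gmyc, fit$ll_null - 1e-6)
  expect_equal(fit$n_species, 2L)
  expect_equal(fit$ci_species, c(2L, 2L))
  expect_gt(gmyc_lr_test(fit)$statistic, 0)
  # threshold separates the two clusters
  expect_gt(fit$thresholds, 0.001)
  expect_lt(fit$thresholds, 0.999)
  expect_setequal(lapply(fit$species, sort),
                  list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  expect_error(fit_gmyc_single(parse_newick("(a:1,b:1);")), "3 tips")
  expect_error(fit_gmyc_single(parse_newick("((a:1,b:2):1,c:2);")),
               "not ultrametric")
})

test_that("fits are invariant to time rescaling up to a deterministic offset", {
  tr <- random_coalescent_tree(12, seed = 33)
  f1 <- fit_gmyc_single(tr)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 1000
  f2 <- fit_gmyc_single(tr2)
  # LL shifts by (N-1) * log(c) for both null and GMYC; counts unchanged
  n <- length(tr$tip.label)
  expect_equal(f2$ll_gmyc, f1$ll_gmyc - (n - 1) * log(1000), tolerance = 1e-4)
  expect_equal(f2$ll_null, f1$ll_null - (n - 1) * log(1000), tolerance = 1e-4)
  expect_equal(f2$n_species, f1$n_species)
  expect_equal(gmyc_lr_test(f2)$statistic, gmyc_lr_test(f1)$statistic,
               tolerance = 1e-3)
})

test_that("multiple-threshold fit improves monotonically on the single fit", {
  # simulated two-regime tree: five low-diversity species plus one deep
  # cluster whose coalescences overlap the speciation zone, so no single
  # global threshold fits every lineage
  st <- ape::read.tree(text = paste0(
    "(((((s1:1000000,s2:1000000):500000,s3:1500000):500000,s4:2000000):500000,",
    "s5:2500000):1500000,big:4000000);"))
  cfg <- sim_config(data.frame(name = c(paste0("s", 1:5), "big"),
                               n = c(rep(3, 5), 8), Ne = c(rep(2e3, 5), 3e5)),
                    species_tree = st, Ne_ancestral = 1e4, seed = 6)
  tr <- simulate_genealogy(cfg)
  s <- fit_gmyc_single(tr)
  m <- fit_gmyc_multiple(tr)
  # a lineage-local boundary strictly improves on the global threshold here
  expect_gt(m$ll_gmyc, s$ll_gmyc + 1e-6)
  expect_gte(m$ll_gmyc, m$ll_null - 1e-6)
  expect_gte(m$n_species, 6L)
  cmp <- compare_thresholds(s, m)
  expect_gte(cmp$statistic, 0)

  # clean single-regime tree: multiple degenerates to the single solution
  tr1 <- parse_newick(paste0("((a1:0.001,(a2:0.0005,a3:0.0005):0.0005):0.999,",
                             "(b1:0.0008,(b2:0.0004,b3:0.0004):0.0004):0.9992);"))
  s1 <- fit_gmyc_single(tr1)
  m1 <- fit_gmyc_multiple(tr1)
  expect_equal(m1$n_species, s1$n_species)
  expect_lt(compare_thresholds(s1, m1)$statistic, 1e-3)
  expect_gt(compare_thresholds(s1, m1)$p_value, 0.999)
  expect_error(compare_thresholds(s1, m), "same tree")
})

test_that("likelihood-ratio test machinery", {
  expect_equal(lr_test(-10, -10, 3)$statistic, 0)
  expect_equal(lr_test(-10, -10, 3)$p_value, 1)
  lt <- lr_test(-12.5, -9.2, 2)
  expect_equal(lt$statistic, 2 * (12.5 - 9.2))
  expect_equal(lt$p_value, pchisq(lt$statistic, 2, lower.tail = FALSE))
  expect_error(lr_test(-5, -6, 2), "lower likelihood")
  expect_error(lr_test(-5, -4, 0), "df")
})

test_that("the analysis grid mirrors the complete/pruned x single/multiple layout", {
  fx <- generate_fixture("its2_like", seed = 1)
  grid <- gmyc_grid(fx$alignment, model = fx$config$model)
  expect_s3_class(grid, "gmyc_grid")
  expect_equal(nrow(grid$table), 4L)
  expect_setequal(grid$table$n, c(22L, 14L))
  expect_setequal(unique(grid$table$dataset), c("complete", "pruned"))
  expect_true(all(grid$table$ll_gmyc >= grid$table$ll_null - 1e-6))

  # user-supplied ultrametric tree skips tree building: complete fits only
  g2 <- gmyc_grid(grid$trees$pruned, threshold_mode = "single")
  expect_equal(nrow(g2$table), 1L)
  expect_error(gmyc_grid(parse_newick("((a:1,b:2):1,c:2);")), "not ultrametric")

  # outgroup labels are pruned from every fit
  og <- aln_labels(fx$alignment)[1]
  g3 <- gmyc_grid(fx$alignment, model = fx$config$model, outgroup = og,
                  threshold_mode = "single")
  expect_false(og %in% unlist(g3$fits$complete_single$species))
})

test_that("duplicate haplotypes produce tied ages handled without error", {
  s <- paste(rep("A", 50), collapse = "")
  s2 <- paste(c(rep("C", 25), rep("A", 25)), collapse = "")
  aln <- alignment(c(a1 = s, a2 = s, a3 = s, b1 = s2, b2 = s2))
  tr <- upgma(distance_matrix(aln, "p"))
  fit <- fit_gmyc_single(tr)
  expect_true(is.finite(fit$ll_gmyc))
  expect_equal(fit$n_species, 2L)
})
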