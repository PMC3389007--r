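test_that("clade diversity implements d, pi and theta exactly", {
  # 5 identical sequences of length 385: d = 2/(L n)
  s <- paste(rep("A", 385), collapse = "")
  aln <- alignment(setNames(rep(s, 5), paste0("t", 1:5)))
  cd <- clade_diversity(aln, aln_labels(aln))
  expect_true(cd$all_identical)
  expect_equal(cd$d, 2 / (385 * 5), tolerance = 1e-7)
  expect_equal(cd$d, 0.0010390, tolerance = 1e-4)
  expect_equal(cd$pi, cd$d * 5 / 4)
  expect_equal(cd$pi, 0.0012987, tolerance = 1e-4)

  # d = 0.01 at n = 2: pi = 0.02, theta = 0.02/(1 - 0.0266667)
  L <- 200
  a2 <- two_seq_aln(L, L * 0.01)
  cd2 <- clade_diversity(a2, c("x", "y"))
  expect_equal(cd2$d, 0.01)
  expect_equal(cd2$pi, 0.02)
  expect_equal(cd2$theta, 0.02 / (1 - 4 * 0.02 / 3))
  expect_equal(cd2$theta, 0.0205479, tolerance = 1e-5)

  # singleton: quantities undefined, no error
  cd1 <- clade_diversity(aln, "t1")
  expect_equal(cd1$n, 1L)
  expect_true(is.na(cd1$d) && is.na(cd1$pi) && is.na(cd1$theta))
  expect_error(clade_diversity(aln, character(0)), "empty")

  # ordering invariants: theta >= pi >= d for n >= 2 on realistic data
  cfgr <- one_pop_config(n = 6)
  trr <- simulate_genealogy(cfgr, seed = 31)
  aln_r <- simulate_sequences(trr, cfgr$model, cfgr$mu, cfgr$L, seed = 32)
  cdr <- clade_diversity(aln_r, aln_labels(aln_r))
  expect_gte(cdr$pi, cdr$d)
  expect_gte(cdr$theta, cdr$pi)
  # the correction has a pole at pi = 0.75: unrealistic diversity errors
  expect_error(clade_diversity(random_aln(6, 200, seed = 31),
                               paste0("t", 1:6)), "domain")
})

test_that("between-clade K averages model-corrected cross distances", {
  s <- paste(rep("A", 100), collapse = "")
  aln <- alignment(c(a1 = s, a2 = s, b1 = s, b2 = s))
  expect_equal(between_clade_K(aln, c("a1", "a2"), c("b1", "b2"), jc_model()), 0)
  expect_error(between_clade_K(aln, c("a1", "a2"), c("a2", "b1"), jc_model()),
               "overlap")

  # all cross pairs at p = 0.25 under JC: K = 0.30410
  L <- 400
  sA <- paste(rep("A", L), collapse = "")
  sB <- paste(c(rep("C", 100), rep("A", 300)), collapse = "")
  aln2 <- alignment(c(a1 = sA, a2 = sA, b1 = sB, b2 = sB))
  expect_equal(between_clade_K(aln2, c("a1", "a2"), c("b1", "b2"), jc_model()),
               0.30410, tolerance = 1e-4)
})

test_that("K matches the coalescent expectation on simulated data", {
  # t = 10 Ne, theta = 2 Ne mu = 0.01: E[K] = 2 mu t + 2 Ne_anc mu = 0.11
  cfg <- two_pop_config(n = 4, Ne = 2.5e5, tau_Ne = 10, mu = 2e-8, L = 2000)
  Ks <- vapply(1:50, function(r) {
    tr <- simulate_genealogy(cfg, seed = 40000 + r)
    a <- simulate_sequences(tr, cfg$model, cfg$mu, cfg$L, seed = 50000 + r)
    between_clade_K(a, grep("^A", aln_labels(a), value = TRUE),
                    grep("^B", aln_labels(a), value = TRUE), cfg$model)
  }, numeric(1))
  expect_lt(abs(mean(Ks) - 0.11) / 0.11, 0.15)
})

test_that("theta selection follows the documented rules", {
  big <- structure(list(n = 5L, theta = 0.02), class = "clade_diversity")
  sml <- structure(list(n = 3L, theta = 0.01), class = "clade_diversity")
  one <- structure(list(n = 1L, theta = NA_real_), class = "clade_diversity")
  n2 <- structure(list(n = 2L, theta = 0.03), class = "clade_diversity")
  expect_equal(egdelim:::select_theta(big, sml, "larger")$theta, 0.02)
  expect_equal(egdelim:::select_theta(sml, big, "larger")$theta, 0.02)
  # singleton on one side: use the other side's theta
  expect_equal(egdelim:::select_theta(one, big, "larger")$theta, 0.02)
  # n = 2 over-correction switch
  expect_equal(egdelim:::select_theta(n2, sml, "smaller_on_n2")$theta, 0.01)
  expect_equal(egdelim:::select_theta(n2, sml, "larger")$theta, 0.03)
})

test_that("species decisions follow the ratio-and-probability rule", {
  cfg <- ktheta_config()
  expect_equal(egdelim:::ktheta_decision(12.53, 0.995, cfg), "species")
  # ratio passes, p narrowly fails (the published 0.94 case): flagged
  expect_equal(egdelim:::ktheta_decision(4.04, 0.94, cfg), "flagged")
  # ratio below 4: never a species, whatever p
  expect_equal(egdelim:::ktheta_decision(3.9, 0.999, cfg), "not-species")
  # p far below: rejected
  expect_equal(egdelim:::ktheta_decision(6, 0.5, cfg), "not-species")
})

test_that("published clade-pair summaries reproduce their printed ratios", {
  tab <- read.delim(system.file("extdata", "ktheta_coi_published.tsv",
                                package = "egdelim"))
  expect_equal(nrow(tab), 7L)
  recomputed <- tab$K / tab$theta
  expect_equal(recomputed, tab$ratio, tolerance = 5e-3)
  expect_true(all(recomputed >= 4))
  # with the printed n1/n2 and tau = K/theta, every pair clears p = 0.94
  p <- mapply(function(n1, n2, tau) {
    reciprocal_monophyly_prob(n1, n2, tau,
                              mode = if (n1 <= 2 && n2 <= 2) "closed" else "mc",
                              mc_reps = 20000, seed = 17)
  }, tab$n1, tab$n2, recomputed)
  expect_true(all(p >= 0.94))
})

test_that("ktheta_test assembles a full result and validates input", {
  L <- 400
  sA <- paste(rep("A", L), collapse = "")
  sB <- paste(c(rep("C", 60), rep("A", L - 60)), collapse = "")
  aln <- alignment(c(a1 = sA, a2 = sA, b1 = sB))
  cfg <- ktheta_config(mc_reps = 5000)
  res <- ktheta_test(aln, list(a = c("a1", "a2"), b = "b1", is_sister = TRUE),
                     jc_model(), cfg)
  expect_s3_class(res, "ktheta_result")
  expect_equal(res$n1, 2L)
  expect_equal(res$n2, 1L)
  # clade a is identical-pair: theta from d = 2/(L*2)
  expect_equal(res$theta_used, egdelim:::select_theta(res$clade_a, res$clade_b,
                                                      "larger")$theta)
  expect_equal(res$ratio, res$K / res$theta_used)
  expect_equal(res$tau, res$ratio)
  expect_equal(res$decision, "species")

  # ratio is invariant to clade order
  res_swap <- ktheta_test(aln, list(a = "b1", b = c("a1", "a2")), jc_model(), cfg)
  expect_equal(res_swap$ratio, res$ratio)

  expect_error(ktheta_test(aln, list(a = "a1", b = "b1"), jc_model(), cfg),
               "singletons")
})

test_that("pair selection prefers supported sisters, then minimum K", {
  # tree with two supported sisters and one unsupported clade
  tr <- parse_newick(paste0("(((a1:1,a2:1)0.99:4,(b1:1,b2:1)0.98:4)0.5:4,",
                            "((c1:1,c2:1)0.97:6,d:7)0.3:2);"))
  L <- 600
  base <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
  mk <- function(sites) { s <- base; s[sites] <- "C"; paste(s, collapse = "") }
  aln <- alignment(c(a1 = mk(1:10), a2 = mk(1:11), b1 = mk(101:140),
                     b2 = mk(101:141), c1 = mk(201:320), c2 = mk(201:321),
                     d = mk(401:540)))
  clades <- well_supported_clades(tr, 0.9)
  pairs <- select_comparison_pairs(tr, clades, aln, jc_model())
  keys <- vapply(pairs, function(p)
    paste(sort(c(paste(sort(p$a), collapse = ""), paste(sort(p$b), collapse = ""))),
          collapse = "|"), character(1))
  # a-b are sisters; c's sister (d, a tip) pairs as sister too
  expect_true("a1a2|b1b2" %in% keys)
  sis <- vapply(pairs, `[[`, logical(1), "is_sister")
  expect_true(all(sis[keys == "a1a2|b1b2"]))

  # nested supported clades: only the maximal one is paired
  tn <- parse_newick("(((a1:1,a2:1)0.99:1,a3:2)0.95:3,(b1:2,b2:2)0.99:3);")
  alnn <- alignment(c(a1 = mk(1:5), a2 = mk(1:6), a3 = mk(c(1:5, 20)),
                      b1 = mk(301:360), b2 = mk(301:361)))
  cn <- well_supported_clades(tn, 0.9)
  pn <- select_comparison_pairs(tn, cn, alnn, jc_model())
  expect_length(pn, 1L)
  expect_setequal(c(pn[[1]]$a, pn[[1]]$b), c("a1", "a2", "a3", "b1", "b2"))

  expect_length(select_comparison_pairs(tn, cn[1], alnn, jc_model()), 0L)
})

test_that("the full K/theta pipeline calls clear two-population data", {
  cfg <- two_pop_config(n = 5)
  tr <- simulate_genealogy(cfg, seed = 61)
  a <- simulate_sequences(tr, cfg$model, cfg$mu, cfg$L, seed = 62)
  kcfg <- ktheta_config(boot_replicates = 100, boot_method = "p",
                        mc_reps = 2000, seed = 5)
  fit <- ktheta(a, cfg$model, kcfg)
  expect_s3_class(fit, "ktheta")
  expect_gte(nrow(fit$table), 1L)
  # determinism under a fixed seed
  fit2 <- ktheta(a, cfg$model, kcfg)
  expect_identical(fit$table, fit2$table)
  # ratio is invariant to the labelling of sequences
  expect_true(all(fit$table$ratio == fit$table$K / fit$table$theta))
  expect_error(ktheta(alignment(c(a = "ACGT", b = "ACGA")), cfg$model, kcfg),
               "at least 4")

  # an impossible support threshold yields an empty result with a warning
  kcfg99 <- ktheta_config(boot_replicates = 50, boot_method = "p",
                          support_threshold = 0.999999, mc_reps = 500, seed = 5)
  aln_flat <- random_aln(6, 50, seed = 77)
  expect_warning(empty <- ktheta(aln_flat, jc_model(), kcfg99), "no clades")
  expect_equal(nrow(empty$table), 0L)
})

test_that("reports round-trip through TSV and JSON", {
  cfg <- two_pop_config(n = 4)
  tr <- simulate_genealogy(cfg, seed = 71)
  a <- simulate_sequences(tr, cfg$model, cfg$mu, cfg$L, seed = 72)
  fit <- ktheta(a, cfg$model,
                ktheta_config(boot_replicates = 50, boot_method = "p",
                              mc_reps = 1000, seed = 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ktheta_report(fit, tsv = tsv, json = js)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(fit$table))
  parsed <- jsonlite::read_json(js)
  expect_true(grepl("Ne generations", parsed$tau_convention))
})
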