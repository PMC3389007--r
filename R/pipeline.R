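## Orchestration used by the command-line entry point (inst/scripts/egdelim)
## and convenient for scripted analyses. Each command reads FASTA/Newick
## inputs, runs the corresponding analysis and writes TSV/JSON reports plus
## a provenance block (config, seed, package version) sufficient to replay
## the run.

#' Run configuration
#'
#' @param input Path to a FASTA alignment (or Newick tree where supported).
#' @param preset Model preset name or YAML path (see [model_preset()]).
#' @param outdir Output directory.
#' @param outgroup Outgroup labels to remove before delimitation.
#' @param boot_replicates,support_threshold,ratio_threshold,p_threshold,
#'   theta_rule,mc_reps As in [ktheta_config()].
#' @param threshold_mode As in [gmyc_grid()].
#' @param seed Integer RNG seed, recorded in every output.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = "coi_paper", outdir = ".",
                       outgroup = character(0L), boot_replicates = 1000L,
                       support_threshold = 0.90, ratio_threshold = 4,
                       p_threshold = 0.95, theta_rule = "larger",
                       mc_reps = 1e5, threshold_mode = "both", seed = 1L) {
  structure(list(input = input, preset = preset, outdir = outdir,
                 outgroup = outgroup, boot_replicates = as.integer(boot_replicates),
                 support_threshold = support_threshold,
                 ratio_threshold = ratio_threshold, p_threshold = p_threshold,
                 theta_rule = theta_rule, mc_reps = mc_reps,
                 threshold_mode = threshold_mode, seed = as.integer(seed)),
            class = "run_config")
}

ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  cfg$outdir
}

write_provenance <- function(cfg, path, extra = list()) {
  payload <- c(list(config = unclass(cfg),
                    seed = cfg$seed,
                    package = "egdelim",
                    version = as.character(utils::packageVersion("egdelim")),
                    r_version = paste(R.version$major, R.version$minor, sep = ".")),
               extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline commands
#'
#' `cmd_simulate` writes a benchmark fixture; `cmd_ktheta` runs the
#' K/theta delimitation; `cmd_gmyc` runs the GMYC analysis grid;
#' `cmd_full` runs both and emits a per-species concordance table.
#'
#' @param cfg A [run_config()].
#' @param preset_name Fixture preset for `cmd_simulate`.
#' @return The analysis object (fixture paths for `cmd_simulate`),
#'   invisibly; files are written under `cfg$outdir`.
#' @export
cmd_simulate <- function(cfg, preset_name = "coi_like") {
  out <- ensure_outdir(cfg)
  fx <- generate_fixture(preset_name, seed = cfg$seed)
  paths <- write_fixture(fx, out, prefix = preset_name)
  write_provenance(cfg, file.path(out, paste0(preset_name, "_provenance.json")),
                   list(command = "simulate", preset = preset_name))
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_ktheta <- function(cfg) {
  out <- ensure_outdir(cfg)
  aln <- read_fasta(cfg$input)
  model <- model_preset(cfg$preset)
  kcfg <- ktheta_config(support_threshold = cfg$support_threshold,
                        ratio_threshold = cfg$ratio_threshold,
                        p_threshold = cfg$p_threshold,
                        theta_rule = cfg$theta_rule,
                        boot_replicates = cfg$boot_replicates,
                        mc_reps = cfg$mc_reps, seed = cfg$seed,
                        outgroup = cfg$outgroup)
  fit <- ktheta(aln, model, kcfg)
  write_ktheta_report(fit, tsv = file.path(out, "ktheta.tsv"),
                      json = file.path(out, "ktheta.json"))
  write_provenance(cfg, file.path(out, "ktheta_provenance.json"),
                   list(command = "ktheta"))
  invisible(fit)
}

#' @rdname cmd_simulate
#' @export
cmd_gmyc <- function(cfg) {
  out <- ensure_outdir(cfg)
  is_tree <- grepl("\\.(nwk|newick|tre|tree)$", cfg$input, ignore.case = TRUE)
  x <- if (is_tree) parse_newick(path = cfg$input) else read_fasta(cfg$input)
  model <- if (is_tree) NULL else model_preset(cfg$preset)
  grid <- gmyc_grid(x, model = model, outgroup = cfg$outgroup,
                    threshold_mode = cfg$threshold_mode)
  write_gmyc_report(grid, tsv = file.path(out, "gmyc.tsv"),
                    json = file.path(out, "gmyc.json"))
  write_provenance(cfg, file.path(out, "gmyc_provenance.json"),
                   list(command = "gmyc"))
  invisible(grid)
}

#' @rdname cmd_simulate
#' @param truth Optional truth table (data frame with columns `label` and
#'   `species`) for precision/recall scoring.
#' @export
cmd_full <- function(cfg, truth = NULL) {
  out <- ensure_outdir(cfg)
  aln <- read_fasta(cfg$input)
  model <- model_preset(cfg$preset)
  kcfg <- ktheta_config(support_threshold = cfg$support_threshold,
                        ratio_threshold = cfg$ratio_threshold,
                        p_threshold = cfg$p_threshold,
                        theta_rule = cfg$theta_rule,
                        boot_replicates = cfg$boot_replicates,
                        mc_reps = cfg$mc_reps, seed = cfg$seed,
                        outgroup = cfg$outgroup)
  kfit <- ktheta(aln, model, kcfg)
  grid <- gmyc_grid(aln, model = model, outgroup = cfg$outgroup,
                    threshold_mode = "both")
  conc <- concordance_table(kfit, grid)
  utils::write.table(conc, file.path(out, "concordance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ktheta_report(kfit, tsv = file.path(out, "ktheta.tsv"))
  write_gmyc_report(grid, tsv = file.path(out, "gmyc.tsv"))
  scores <- NULL
  if (!is.null(truth)) {
    scores <- score_against_truth(kfit, grid, truth)
    utils::write.table(scores, file.path(out, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_provenance(cfg, file.path(out, "full_provenance.json"),
                   list(command = "full"))
  invisible(list(ktheta = kfit, gmyc = grid, concordance = conc,
                 scores = scores))
}

## Species sets proposed by each method. K/theta contributes the clades of
## species-positive (or flagged) pairs; GMYC contributes its clusters.
method_species_sets <- function(kfit, grid) {
  kt <- list()
  for (r in kfit$results) {
    if (r$decision %in% c("species", "flagged")) {
      kt <- c(kt, list(sort(r$clade_a$tips)), list(sort(r$clade_b$tips)))
    }
  }
  kt <- unique(kt)
  list(ktheta = kt,
       gmyc_single = lapply(grid$fits$complete_single$species, sort),
       gmyc_multiple = lapply(grid$fits$complete_multiple$species, sort))
}

#' Concordance between delimitation methods
#'
#' One row per putative species (any tip set proposed by K/theta, GMYC
#' single or GMYC multiple), with a flag per method and a summary label
#' (`both`, `K/theta-only`, `GMYC-only`).
#'
#' @param kfit A `ktheta` fit.
#' @param grid A `gmyc_grid` on the same data.
#' @return A data frame.
#' @export
concordance_table <- function(kfit, grid) {
  sets <- method_species_sets(kfit, grid)
  all_sets <- unique(c(sets$ktheta, sets$gmyc_single, sets$gmyc_multiple))
  if (length(all_sets) == 0L) {
    return(data.frame(species = character(0L), n_tips = integer(0L),
                      ktheta = logical(0L), gmyc_single = logical(0L),
                      gmyc_multiple = logical(0L), agreement = character(0L),
                      stringsAsFactors = FALSE))
  }
  has <- function(pool, s) any(vapply(pool, identical, logical(1L), s))
  rows <- lapply(all_sets, function(s) {
    k <- has(sets$ktheta, s)
    g1 <- has(sets$gmyc_single, s)
    g2 <- has(sets$gmyc_multiple, s)
    agreement <- if (k && (g1 || g2)) "both" else if (k) "K/theta-only" else "GMYC-only"
    data.frame(species = paste(s, collapse = ","), n_tips = length(s),
               ktheta = k, gmyc_single = g1, gmyc_multiple = g2,
               agreement = agreement, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score delimitations against a truth table
#'
#' Exact tip-set matching: precision = matched predicted species /
#' predicted species; recall = matched predicted species / true species.
#'
#' @param kfit A `ktheta` fit.
#' @param grid A `gmyc_grid`.
#' @param truth Data frame with columns `label`, `species`.
#' @return A data frame, one row per method.
#' @export
score_against_truth <- function(kfit, grid, truth) {
  true_sets <- lapply(split(truth$label, truth$species), sort)
  sets <- method_species_sets(kfit, grid)
  has <- function(pool, s) any(vapply(pool, identical, logical(1L), s))
  do.call(rbind, lapply(names(sets), function(m) {
    pred <- sets[[m]]
    matched <- sum(vapply(pred, function(s) has(true_sets, s), logical(1L)))
    data.frame(method = m, n_predicted = length(pred),
               n_true = length(true_sets), n_matched = matched,
               precision = if (length(pred)) matched / length(pred) else NA_real_,
               recall = matched / length(true_sets),
               stringsAsFactors = FALSE)
  }))
}
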