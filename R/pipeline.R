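# End-to-end orchestration: dichotomized cohort in (or synthetic spec),
# LCC age adjustment, main/pairwise/three-way permutation screens,
# regression benchmark, post-hoc groups, network files and a manifest.

#' Run the full epistasis-screening pipeline
#'
#' Stages, in order: load or generate the cohort; local case-control
#' subsampling on the confounders; permutation screens for main
#' effects, pairwise and three-way interactions (three separate
#' Bonferroni families); regression benchmark of every non-null screen
#' hit; post-hoc interaction groups for the top significant pair;
#' network assembly and export. Optionally the screens are re-run in
#' strata of a binary variable (which is then excluded from the
#' stratified predictor sets, with the familywise m recomputed
#' accordingly). Every output is written under `out_dir` together with
#' a machine-readable manifest recording seeds, thresholds and stage
#' status; a failed stage is recorded and later stages that depend on
#' it are skipped.
#'
#' @param cohort A [discrete_cohort()], a path to a cohort CSV, or a
#'   [cohort_spec()] to simulate from.
#' @param out_dir Output directory (created if needed).
#' @param confounders Confounder columns for the LCC stage (default
#'   `"age_years"`); `NULL` skips adjustment.
#' @param B Permutations per family (default 1000).
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param stratify_by Optional binary column (e.g. `"sex"`) for
#'   stratified reruns of the screens.
#' @param fwer_sig,fwer_sug Familywise error budgets.
#' @return The manifest (a list), invisibly; all artifacts are on disk.
#' @export
run_pipeline <- function(cohort, out_dir, confounders = "age_years",
                         B = 1000, seed = 1, stratify_by = NULL,
                         fwer_sig = 0.05, fwer_sug = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, B = B, confounders = confounders,
                   fwer = c(significant = fwer_sig, suggestive = fwer_sug),
                   stages = list())
  note <- function(stage, status, detail = NULL) {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
  }

  if (inherits(cohort, "cohort_spec")) {
    manifest$cohort_source <- "synthetic"
    manifest$cohort_spec_seed <- cohort$seed
    cohort <- generate_cohort(cohort)
  } else if (is.character(cohort)) {
    manifest$cohort_source <- cohort
    cohort <- load_cohort(cohort)
  } else {
    manifest$cohort_source <- "in-memory"
  }
  write_cohort(cohort, file.path(out_dir, "cohort_full.csv"))
  manifest$n_full <- nrow(cohort)
  note("cohort", "ok")

  analysis <- cohort
  if (!is.null(confounders)) {
    adj <- tryCatch(
      lcc_subsample(cohort, confounders = confounders, seed = seed),
      error = function(e) e)
    if (inherits(adj, "error")) {
      note("lcc", "failed", conditionMessage(adj))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      return(invisible(manifest))
    }
    analysis <- adj$cohort
    report <- list(pilot_coefficients = as.list(adj$pilot_coefficients),
                   kept = length(adj$kept),
                   expected_size = adj$expected_size, seed = adj$seed,
                   balance = if (!is.null(adj$balance))
                     adj$balance$diagnostics else NULL)
    jsonlite::write_json(report, file.path(out_dir, "lcc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_cohort(analysis, file.path(out_dir, "cohort_adjusted.csv"))
    manifest$n_adjusted <- nrow(analysis)
    note("lcc", "ok")
  }

  screen_one <- function(data, tag, seed_offset) {
    res <- list()
    for (ord in 1:3) {
      r <- run_screen(data, order = ord, B = B,
                      seed = seed + seed_offset + ord,
                      fwer_sig = fwer_sig, fwer_sug = fwer_sug)
      utils::write.csv(r, file.path(out_dir,
                                    sprintf("screen_%s_order%d.csv", tag,
                                            ord)),
                       row.names = FALSE)
      res[[ord]] <- r
    }
    res
  }

  screens <- tryCatch(screen_one(analysis, "full", 10L),
                      error = function(e) e)
  if (inherits(screens, "error")) {
    note("screen", "failed", conditionMessage(screens))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(manifest))
  }
  families <- lapply(screens, function(r) attr(r, "family"))
  manifest$families <- families
  note("screen", "ok")

  if (!is.null(stratify_by)) {
    strata_ok <- stratify_by %in% c(names(analysis))
    if (strata_ok) {
      preds <- setdiff(attr(analysis, "predictors"), stratify_by)
      for (lev in sort(unique(analysis[[stratify_by]]))) {
        sub <- as.data.frame(analysis)[analysis[[stratify_by]] == lev, ,
                                       drop = FALSE]
        subc <- discrete_cohort(sub, predictors = preds,
                                outcome = attr(analysis, "outcome"))
        tag <- sprintf("%s%s", stratify_by, lev)
        tryCatch(screen_one(subc, tag, 20L + as.integer(lev)),
                 error = function(e) note(paste0("screen_", tag), "failed",
                                          conditionMessage(e)))
      }
      note("stratified", "ok",
           sprintf("%d predictors per stratum", length(preds)))
    } else {
      note("stratified", "failed", "stratification column absent")
    }
  }

  sel2 <- screens[[2]][screens[[2]]$class != "null", , drop = FALSE]
  sel3 <- screens[[3]][screens[[3]]$class != "null", , drop = FALSE]
  sel <- rbind(
    if (nrow(sel2)) cbind(sel2[, c("v1", "v2")], v3 = NA_character_,
                          sel2[, c("bits", "pct", "p")]) else NULL,
    if (nrow(sel3)) sel3[, c("v1", "v2", "v3", "bits", "pct", "p")]
    else NULL)
  if (!is.null(sel) && nrow(sel)) {
    bench <- tryCatch(benchmark_models(analysis, sel),
                      error = function(e) e)
    if (inherits(bench, "error")) {
      note("regression", "failed", conditionMessage(bench))
    } else {
      utils::write.csv(bench,
                       file.path(out_dir, "regression_comparison.csv"),
                       row.names = FALSE)
      note("regression", "ok")
    }
  } else {
    note("regression", "skipped", "no non-null screen hits")
  }

  sig_pairs <- screens[[2]][screens[[2]]$class == "significant", ,
                            drop = FALSE]
  if (nrow(sig_pairs)) {
    top <- sig_pairs[which.max(sig_pairs$bits), ]
    groups <- assign_groups(analysis[[top$v1]], analysis[[top$v2]])
    y <- outcome_vector(analysis)
    gs <- group_summary(analysis$bdr_pct, groups,
                        sex = if ("sex" %in% names(analysis))
                          analysis$sex else NULL)
    utils::write.csv(gs, file.path(out_dir, "posthoc_group_summary.csv"),
                     row.names = FALSE)
    cmp <- compare_group_proportions(y, groups)
    utils::write.csv(cmp,
                     file.path(out_dir, "posthoc_group_proportions.csv"),
                     row.names = FALSE)
    manifest$posthoc_pair <- c(top$v1, top$v2)
    note("posthoc", "ok")
  } else {
    note("posthoc", "skipped", "no significant pairwise model")
  }

  net <- build_network(screens[[1]], screens[[2]], screens[[3]])
  export_network(net, file.path(out_dir, "network.json"), "json")
  export_network(net, file.path(out_dir, "network.graphml"), "graphml")
  export_network(net, file.path(out_dir, "network.dot"), "dot")
  note("network", "ok")

  desc <- descriptive_table(analysis, B = B, seed = seed + 1L)
  utils::write.csv(desc, file.path(out_dir, "descriptive_table.csv"),
                   row.names = FALSE)
  note("descriptives", "ok")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
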