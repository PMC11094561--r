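# Orchestration: configuration, the simulate -> extract -> screen ->
# composite -> decision-tree pipeline, provenance-stamped outputs, and a
# human-readable run report.

#' Default pipeline configuration
#'
#' All stage parameters in one list: simulation spec fields, rendering and
#' extraction settings, target specificity, tree settings and the seed.
#' `render_streams = TRUE` runs the full raw-stream round-trip (extract
#' stage); with `FALSE` the downstream stages consume the simulated
#' biomarker table directly.
#'
#' @param ... Overrides of default entries (unknown names are an error).
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 20240514L,
    n_autism = 102L,
    n_nonautism = 44L,
    missingness_rate_per_task = 0.2,
    pcp_sensitivity = 0.70,
    pcp_specificity = 0.82,
    p_certain_given_correct = 0.75,
    p_certain_given_incorrect = 0.35,
    render_streams = TRUE,
    sampling_rate = 100,
    noise_sd = 0.08,
    pupil_noise_mm = 0.002,
    dispersion_deg = 1.0,
    min_duration_ms = 100,
    target_specificity = 0.95,
    max_splits = 5L,
    min_node = 5L,
    cv_folds = 5L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$n_autism < 5L || cfg$n_nonautism < 5L)
    stop("pipeline needs at least 5 children per group (cutoff derivation ",
         "and stratified folds)", call. = FALSE)
  if (cfg$target_specificity <= 0 || cfg$target_specificity > 1)
    stop("`target_specificity` must be in (0, 1]", call. = FALSE)
  if (cfg$sampling_rate <= 0) stop("`sampling_rate` must be > 0",
                                   call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Entries in the file override [default_run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, yaml::read_yaml(path))
}

# 32-bit rolling hash (djb2) of the serialized config, for provenance
# stamping of every artifact a run writes.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gazedx run config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-stamped pipeline CSV
#' @param path CSV written by [run_pipeline()].
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> extract -> screen -> composite -> decision tree and
#' (when `out_dir` is given) writes every artifact with provenance metadata
#' (config hash and seed). Identical configurations produce identical
#' results.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @return List of class `gazedx_run` with elements `cohort`, `biomarkers`
#'   (extracted or simulated), `screen`, `composite` (rules, per-child
#'   table, stats), `tree` (fitted tree, published-tree evaluations, CV
#'   report), `config`, `config_hash`, and `paths` when written.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  hash <- config_hash(config)
  paths <- list()
  emit_csv <- function(df, name) {
    if (is.null(out_dir)) return()
    p <- file.path(out_dir, name)
    write_csv_prov(df, p, hash, config$seed)
    paths[[name]] <<- p
  }
  emit_json <- function(x, name) {
    if (is.null(out_dir)) return()
    p <- file.path(out_dir, name)
    jsonlite::write_json(c(list(config_hash = hash, seed = config$seed), x),
                         p, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    paths[[name]] <<- p
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # -- simulate ------------------------------------------------------------
  spec <- simulation_spec(
    n_autism = config$n_autism, n_nonautism = config$n_nonautism,
    missingness_rate_per_task = config$missingness_rate_per_task,
    pcp_sensitivity = config$pcp_sensitivity,
    pcp_specificity = config$pcp_specificity,
    p_certain_given_correct = config$p_certain_given_correct,
    p_certain_given_incorrect = config$p_certain_given_incorrect,
    seed = config$seed)
  cohort <- simulate_biomarker_table(spec)
  emit_csv(as.data.frame(cohort), "cohort.csv")

  # -- extract -------------------------------------------------------------
  if (isTRUE(config$render_streams)) {
    extracted <- extract_cohort_biomarkers(
      cohort, sampling_rate = config$sampling_rate,
      noise_sd = config$noise_sd, pupil_noise_mm = config$pupil_noise_mm,
      seed = config$seed, dispersion_deg = config$dispersion_deg,
      min_duration_ms = config$min_duration_ms)
    biomarkers <- cbind(
      cohort[, c("id", "group", "age_months", "sex", "eae_dx", "certainty")],
      extracted[, setdiff(names(extracted), c("id", "group"))])
  } else {
    biomarkers <- as.data.frame(cohort)
  }
  emit_csv(biomarkers, "biomarkers.csv")

  # -- screen --------------------------------------------------------------
  screen <- screen_biomarkers(biomarkers)
  emit_csv(as.data.frame(screen), "screen.csv")

  # -- composite -----------------------------------------------------------
  comp <- composite_accuracy(biomarkers,
                             target_specificity = config$target_specificity)
  emit_json(lapply(unclass(comp$rules), unclass), "cutoffs.json")
  emit_csv(cbind(biomarkers[, c("id", "group")], comp$composite),
           "composite.csv")
  emit_json(accuracy_stats_as_list(comp$stats), "composite_accuracy.json")

  # -- decision tree -------------------------------------------------------
  cases <- cbind(biomarkers[, c("id", "group", "eae_dx", "certainty")],
                 comp$composite[, c("positive", "frequency")])
  fitted <- fit_cart(cases, "group",
                     c("positive", "frequency", "eae_dx", "certainty"),
                     max_splits = config$max_splits,
                     min_node = config$min_node)
  ptree <- published_tree()
  tree <- list(fitted = fitted,
               published_tree_counts_eval = evaluate_decided(ptree),
               published_tree_cohort_eval = evaluate_decided(ptree, cases),
               cv = cross_validate(cases, "group",
                                   c("positive", "frequency", "eae_dx",
                                     "certainty"),
                                   k = config$cv_folds, seed = config$seed,
                                   max_splits = config$max_splits,
                                   min_node = config$min_node))
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, "tree.json")
    write_tree_json(fitted, p)
    paths[["tree.json"]] <- p
    emit_json(accuracy_stats_as_list(tree$published_tree_counts_eval),
              "published_tree_accuracy.json")
  }

  run <- structure(list(cohort = cohort, biomarkers = biomarkers,
                        screen = screen, composite = comp, tree = tree,
                        cases = cases, config = config, config_hash = hash,
                        paths = paths),
                   class = "gazedx_run")
  if (!is.null(out_dir)) {
    emit_json(list(stages = c("simulate",
                              if (isTRUE(config$render_streams)) "extract",
                              "screen", "composite", "cart"),
                   config = unclass(config)), "run_metadata.json")
    run$paths <- paths
  }
  run
}

accuracy_stats_as_list <- function(st) {
  if (is.null(st)) return(NULL)
  list(tp = st$table$tp, fp = st$table$fp, fn = st$table$fn,
       tn = st$table$tn, referred = st$referred,
       sensitivity = st$sensitivity, sensitivity_ci = st$sensitivity_ci,
       specificity = st$specificity, specificity_ci = st$specificity_ci,
       ppv = st$ppv, ppv_ci = st$ppv_ci, npv = st$npv, npv_ci = st$npv_ci,
       kappa = st$kappa, kappa_ci = st$kappa_ci,
       concordant = st$concordant, n = st$n)
}

#' @export
print.gazedx_run <- function(x, ...) {
  cat("gazedx pipeline run (config ", x$config_hash, ", seed ",
      x$config$seed, ")\n\n", sep = "")
  cat(make_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable report of a pipeline run
#'
#' Four sections: the screening table, the cutoff table, the composite
#' accuracy block, and the decision tree with terminal decisions. A section
#' whose stage output is absent is marked absent.
#'
#' @param run A `gazedx_run` from [run_pipeline()].
#' @return Character vector of report lines (invisibly); also printable via
#'   `cat`.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "gazedx_run"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, ...)
  add(sprintf("== gazedx report (config %s, seed %d) ==", run$config_hash,
              run$config$seed), "")

  add("-- Biomarker screening --")
  if (is.null(run$screen)) add("   [absent]")
  else {
    s <- run$screen
    add(sprintf("   %-34s %9s %9s %7s %7s %6s",
                "biomarker", "aut mean", "non mean", "OR", "p", "AUC"))
    for (i in seq_len(nrow(s)))
      add(sprintf("   %-34s %9.2f %9.2f %7.3f %7.4f %6.3f",
                  s$biomarker[i], s$autism_mean[i], s$nonautism_mean[i],
                  s$or[i], s$p_value[i], s$auc[i]))
  }
  add("")

  add("-- 95%-specificity cutoffs --")
  if (is.null(run$composite$rules)) add("   [absent]")
  else for (r in run$composite$rules)
    add(sprintf("   %-34s positive if %s %8.2f (achieved spec %.3f)",
                r$biomarker_name,
                if (r$direction == "high_is_positive") ">" else "<",
                r$threshold, r$achieved_specificity))
  add("")

  add("-- Composite biomarker accuracy --")
  if (is.null(run$composite$stats)) add("   [absent]")
  else add(utils::capture.output(print(run$composite$stats)))
  add("")

  add("-- Decision tree --")
  if (is.null(run$tree$fitted)) add("   [absent]")
  else {
    add(utils::capture.output(print(run$tree$fitted)))
    if (!is.null(run$tree$cv))
      add(utils::capture.output(print(run$tree$cv)))
    if (!is.null(run$tree$published_tree_counts_eval)) {
      add("   Published tree, decisions applied to its stored node counts:")
      add(utils::capture.output(print(run$tree$published_tree_counts_eval)))
    }
  }
  invisible(lines)
}
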