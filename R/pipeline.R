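# End-to-end pipeline: screen -> fit -> evaluate -> assess -> randomize for
# every fittable species, with per-species failure isolation, map export, and
# a machine-readable manifest.

#' Published Overall Insecurity of the Spanish National Park assessment
#'
#' The per-species Overall Insecurity Index values (and permutation-test
#' counts) reported for 37 vertebrate species highlighted by the 10 National
#' Parks of mainland Spain, whose network covers 0.667% of the territory.
#' Useful as a worked input for [summarize_run()] and for checking
#' Representativeness arithmetic against published values.
#'
#' @return data.frame with columns `species`, `group`, `insecurity`,
#'   `times_actual_gt_random`.
#' @export
spain_np_insecurity <- function() {
  utils::read.csv(system.file("extdata", "np_insecurity_spain.csv",
                              package = "favsec"),
                  stringsAsFactors = FALSE)
}

#' Run the full gap-analysis pipeline
#'
#' For each fittable species: predictor screening (within-set correlation
#' pruning, trend-surface descriptor, FDR filter), stepwise favourability
#' model, evaluation, Insecurity assessment and the permuted-coverage null
#' model. Species failing a precondition are skipped with a logged cause,
#' never aborting the run. Per-species favourability and Insecurity maps,
#' screening tables and model summaries are written under `out_dir`, along
#' with group Insecurity maps, the assessment table and a manifest.
#'
#' @param cells a [cell_table()] with coverage filled.
#' @param dataset a [species_dataset()].
#' @param predictors a [predictor_matrix()].
#' @param out_dir output directory (created if needed); `NULL` skips all file
#'   output.
#' @param r_threshold correlation-pruning threshold.
#' @param q FDR level.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param threshold favourability classification threshold.
#' @param hl_bins Hosmer-Lemeshow bins.
#' @param n_reps permutation replicates for the null model.
#' @param seed master seed; per-species null-model seeds are derived by fixed
#'   offsets.
#' @param coverage optional coverage-fraction override (see
#'   [assess_species()]).
#' @return An object of class `pipeline_run`: list with `assessment`
#'   (data.frame, one row per fitted species), `skipped` (data.frame of
#'   species and causes), `models`, `screenings`, `assessments`,
#'   `group_maps`, and `out_dir`.
#' @export
run_pipeline <- function(cells, dataset, predictors, out_dir = NULL,
                         r_threshold = 0.8, q = 0.05,
                         fdr_method = c("BH", "BY"),
                         threshold = 0.5, hl_bins = 10,
                         n_reps = 20, seed = 1, coverage = NULL) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(inherits(cells, "cell_table"),
            inherits(dataset, "species_dataset"),
            inherits(predictors, "predictor_matrix"))
  if (nrow(dataset$species) == 0L)
    stop("empty species set", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list(); skipped <- list()
  models <- list(); screenings <- list(); assessments <- list()
  for (i in seq_len(nrow(dataset$species))) {
    sp <- dataset$species$species[i]
    if (!dataset$species$fittable[i]) {
      skipped[[sp]] <- "no presences or no absences"
      message(sprintf("skipping %s: %s", sp, skipped[[sp]]))
      next
    }
    presence <- dataset$presence[, sp]
    sp_seed <- (seed + 7919L * i) %% .Machine$integer.max
    res <- tryCatch({
      scr <- screen_predictors(predictors, presence, cells,
                               r_threshold = r_threshold, q = q,
                               method = fdr_method)
      fm <- favourability_model(presence, scr$data)
      ev <- suppressWarnings(evaluate_model(fm, presence,
                                            threshold = threshold,
                                            hl_bins = hl_bins))
      as_ <- assess_species(fm$F, presence, cells, n_reps = n_reps,
                            seed = sp_seed, coverage = coverage)
      list(scr = scr, fm = fm, ev = ev, as_ = as_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[sp]] <- conditionMessage(res)
      message(sprintf("skipping %s: %s", sp, skipped[[sp]]))
      next
    }
    models[[sp]] <- res$fm
    screenings[[sp]] <- res$scr
    assessments[[sp]] <- res$as_
    rows[[sp]] <- data.frame(
      species = sp, group = dataset$species$group[i],
      n1 = res$fm$n1, n0 = res$fm$n0,
      n_terms = length(res$fm$terms),
      AUC = res$ev$AUC, kappa = res$ev$kappa,
      sensitivity = res$ev$sensitivity, specificity = res$ev$specificity,
      CCR = res$ev$CCR, HL = res$ev$HL, HL_p = res$ev$HL_p,
      I_overall = res$as_$I_overall, S = res$as_$S, R = res$as_$R,
      S_occ = res$as_$S_occ, R_occ = res$as_$R_occ, c = res$as_$c,
      times_actual_gt_random = res$as_$randomization$times_actual_gt_random,
      n_reps = n_reps, seed = sp_seed, stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      write_cell_map(res$fm$F, cells,
                     file.path(out_dir, sprintf("%s_favourability.asc", sp)))
      write_cell_map(res$as_$I_surface, cells,
                     file.path(out_dir, sprintf("%s_insecurity.asc", sp)))
      utils::write.csv(res$scr$fdr,
                       file.path(out_dir, sprintf("%s_screening.csv", sp)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(terms = res$fm$terms,
             coefficients = as.list(res$fm$coefficients),
             n1 = res$fm$n1, n0 = res$fm$n0,
             AIC = stats::AIC(res$fm$model),
             separation = res$fm$separation),
        file.path(out_dir, sprintf("%s_model.json", sp)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  assessment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0))
  rownames(assessment) <- NULL
  group_maps <- list()
  if (nrow(assessment) > 0L) {
    for (grp in unique(assessment$group)) {
      members <- assessment$species[assessment$group == grp]
      gm <- suppressWarnings(group_insecurity_map(
        lapply(assessments[members], `[[`, "I_surface")))
      group_maps[[grp]] <- gm
      if (!is.null(out_dir))
        write_cell_map(gm, cells,
                       file.path(out_dir,
                                 sprintf("group_%s_insecurity.asc", grp)))
    }
  }
  skipped_df <- data.frame(species = names(skipped),
                           cause = unlist(skipped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    utils::write.csv(assessment, file.path(out_dir, "assessment.csv"),
                     row.names = FALSE)
    if (nrow(skipped_df))
      utils::write.csv(skipped_df, file.path(out_dir, "skipped.csv"),
                       row.names = FALSE)
    manifest <- list(
      package = "favsec",
      package_version = as.character(utils::packageVersion("favsec")),
      r_version = R.version.string,
      seed = seed,
      params = list(r_threshold = r_threshold, q = q,
                    fdr_method = fdr_method, threshold = threshold,
                    hl_bins = hl_bins, n_reps = n_reps,
                    coverage = coverage),
      n_cells = nrow(cells), n_species = nrow(dataset$species),
      n_fitted = nrow(assessment), n_skipped = nrow(skipped_df))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(assessment = assessment, skipped = skipped_df,
                 models = models, screenings = screenings,
                 assessments = assessments, group_maps = group_maps,
                 out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d species fitted, %d skipped\n",
              nrow(x$assessment), nrow(x$skipped)))
  if (nrow(x$assessment))
    print(x$assessment[, c("species", "group", "I_overall", "S", "R",
                           "times_actual_gt_random")])
  invisible(x)
}

#' Summarize a pipeline run (or any assessment table)
#'
#' Ranks species by Representativeness, counts species below/above the given
#' thresholds, and flags species beating all permuted networks as
#' well-represented (and those beating none as under-represented).
#'
#' @param run a `pipeline_run`, a run directory containing `assessment.csv`,
#'   or an assessment data.frame with at least columns `species`, `R` (or
#'   `I_overall` plus `c` to recompute it) and optionally
#'   `times_actual_gt_random` and `n_reps`.
#' @param thresholds Representativeness thresholds to count against
#'   (default `c(1, 3)`).
#' @return list of class `run_summary` with `ranked` (the table sorted by
#'   decreasing R with a `status` column), `n_below` / `n_above` (named
#'   counts per threshold).
#' @export
summarize_run <- function(run, thresholds = c(1, 3)) {
  df <- if (inherits(run, "pipeline_run")) run$assessment
        else if (is.character(run)) {
          f <- file.path(run, "assessment.csv")
          if (!file.exists(f))
            stop(sprintf("incomplete run directory: no %s", f), call. = FALSE)
          utils::read.csv(f, stringsAsFactors = FALSE)
        } else as.data.frame(run)
  if (!"R" %in% names(df)) {
    if (!all(c("I_overall", "c") %in% names(df)))
      stop("assessment table needs column R, or I_overall and c",
           call. = FALSE)
    df$R <- (1 - df$I_overall) / df$c
  }
  df <- df[order(-df$R), , drop = FALSE]
  rownames(df) <- NULL
  if (all(c("times_actual_gt_random", "n_reps") %in% names(df))) {
    df$status <- ifelse(df$times_actual_gt_random == df$n_reps,
                        "well-represented",
                 ifelse(df$times_actual_gt_random == 0,
                        "under-represented", "intermediate"))
  }
  n_below <- vapply(thresholds, function(t) sum(df$R < t), 0L)
  n_above <- vapply(thresholds, function(t) sum(df$R > t), 0L)
  names(n_below) <- names(n_above) <- as.character(thresholds)
  structure(list(ranked = df, n_below = n_below, n_above = n_above,
                 thresholds = thresholds),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  for (t in as.character(x$thresholds))
    cat(sprintf("species with R < %s: %d | R > %s: %d\n",
                t, x$n_below[[t]], t, x$n_above[[t]]))
  cols <- intersect(c("species", "group", "I_overall", "R", "status"),
                    names(x$ranked))
  print(utils::head(x$ranked[, cols], 10))
  invisible(x)
}
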