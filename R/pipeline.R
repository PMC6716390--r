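# End-to-end orchestration: synthetic study (or supplied inputs) ->
# predictor extraction -> imputation -> acquisition models -> consistency,
# with every stage output written to disk and checksummed in a manifest.

#' Pipeline run configuration
#'
#' Collects every tunable default of the pipeline in one serializable list.
#' All seeds are derived from the single master `seed`.
#'
#' @param languages,n_items,n_children,n_utterances,measures,age_ranges,
#'   category_proportions,missingness_rates,truth Synthetic-study parameters
#'   (see [generate_study()]); `truth = NULL` uses [default_truth()].
#' @param seed Master integer seed.
#' @param min_occurrences MLU-w missingness threshold.
#' @param imputation List: `max_iterations`, `tolerance`.
#' @param model List: `include_age_interactions`,
#'   `include_category_interactions`, `category_coding`, `random_slope`,
#'   `engine`.
#' @param consistency List: `n_bootstrap`, `linkage`, `method`.
#' @return A `lexacq_config` list.
#' @export
run_config <- function(languages = c("lang1", "lang2", "lang3"),
                       n_items = 100, n_children = 500, n_utterances = 5000,
                       measures = c("comprehension", "production"),
                       age_ranges = list(comprehension = c(8, 18),
                                         production = c(8, 30)),
                       category_proportions = c(0.5, 0.25, 0.125, 0.125),
                       missingness_rates = c(concreteness = 0.005,
                                             valence = 0.10, arousal = 0.10,
                                             babiness = 0.20),
                       truth = NULL,
                       seed = 1,
                       min_occurrences = 10,
                       imputation = list(max_iterations = 20, tolerance = 1e-6),
                       model = list(include_age_interactions = TRUE,
                                    include_category_interactions = TRUE,
                                    category_coding = "deviation",
                                    random_slope = TRUE,
                                    engine = "glmmTMB"),
                       consistency = list(n_bootstrap = 1000,
                                          linkage = "complete",
                                          method = "pearson")) {
  structure(list(
    languages = languages, n_items = n_items, n_children = n_children,
    n_utterances = n_utterances, measures = measures,
    age_ranges = age_ranges, category_proportions = category_proportions,
    missingness_rates = missingness_rates, truth = truth,
    seed = check_seed(seed), min_occurrences = min_occurrences,
    imputation = imputation, model = model, consistency = consistency
  ), class = "lexacq_config")
}

#' Write a synthetic study's input files
#'
#' Emits the four input families in their interchange formats:
#' administrations CSV; per-language CHAT-lite corpora; per-language norms
#' and transcription CSVs; mapping CSVs (word forms / translation
#' equivalents, inflections, wide-format polysemy, item categories); plus a
#' YAML record of the generating ground truth.
#'
#' @param study A `lexacq_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "corpora"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "norms"), showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  readr::write_csv(study$administrations, file.path(dir, "administrations.csv"))
  items <- study$lexicon$items[, c("item_id", "lexical_category")]
  readr::write_csv(items, file.path(dir, "items.csv"))
  readr::write_csv(study$lexicon$forms, file.path(dir, "maps", "forms.csv"))
  readr::write_csv(study$lexicon$inflections,
                   file.path(dir, "maps", "inflections.csv"))
  poly <- study$lexicon$polysemy
  if (nrow(poly) > 0) {
    poly_wide <- dplyr::mutate(
      dplyr::group_by(poly, .data$language, .data$word_form),
      sense = paste0("sense_item_", dplyr::row_number()))
    poly_wide <- tidyr::pivot_wider(poly_wide, names_from = "sense",
                                    values_from = "item_id")
  } else {
    poly_wide <- tibble::tibble(language = character(), word_form = character())
  }
  readr::write_csv(poly_wide, file.path(dir, "maps", "polysemy.csv"))
  for (lang in names(study$corpora)) {
    write_chat_lite(study$corpora[[lang]],
                    file.path(dir, "corpora", paste0(lang, ".txt")))
    readr::write_csv(study$norms[[lang]],
                     file.path(dir, "norms", paste0(lang, ".csv")))
    readr::write_csv(study$transcriptions[[lang]],
                     file.path(dir, "norms", paste0(lang, "_phonemes.csv")))
  }
  if (!is.null(study$truth))
    yaml::write_yaml(unclass(study$truth), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read study input files written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return A `lexacq_study`-shaped list (without latent ground truth).
#' @export
read_study <- function(dir) {
  adm <- readr::read_csv(file.path(dir, "administrations.csv"),
                         show_col_types = FALSE)
  items <- readr::read_csv(file.path(dir, "items.csv"), show_col_types = FALSE)
  forms <- readr::read_csv(file.path(dir, "maps", "forms.csv"),
                           show_col_types = FALSE)
  infl <- readr::read_csv(file.path(dir, "maps", "inflections.csv"),
                          show_col_types = FALSE)
  poly_wide <- readr::read_csv(file.path(dir, "maps", "polysemy.csv"),
                               show_col_types = FALSE)
  poly <- if (nrow(poly_wide) > 0)
    tidyr::pivot_longer(poly_wide, dplyr::starts_with("sense_item_"),
                        values_to = "item_id", values_drop_na = TRUE,
                        names_to = NULL)[, c("language", "word_form", "item_id")]
  else tibble::tibble(language = character(), word_form = character(),
                      item_id = character())
  langs <- unique(forms$language)
  corpora <- list(); norms <- list(); transcriptions <- list(); maps <- list()
  for (lang in langs) {
    corpora[[lang]] <- read_chat_lite(file.path(dir, "corpora",
                                                paste0(lang, ".txt")))
    norms[[lang]] <- readr::read_csv(file.path(dir, "norms",
                                               paste0(lang, ".csv")),
                                     show_col_types = FALSE)
    transcriptions[[lang]] <- readr::read_csv(
      file.path(dir, "norms", paste0(lang, "_phonemes.csv")),
      show_col_types = FALSE)
    maps[[lang]] <- list(
      forms = forms[forms$language == lang, c("item_id", "word_form")],
      inflection_map = infl[infl$language == lang,
                            c("variant_form", "canonical_item")],
      polysemy_map = poly[poly$language == lang, c("word_form", "item_id")])
  }
  list(administrations = adm, corpora = corpora, norms = norms,
       transcriptions = transcriptions, maps = maps,
       items = items, measures = unique(adm$measure))
}

stage_error <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s%s] %s", stage,
                 if (nzchar(context)) paste0(", ", context) else "",
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a study, extracts and scales predictors per
#' language, imputes missing values, fits the per-language, per-measure
#' mixed-effects logistic models, runs the consistency analyses, and writes
#' every stage output plus a checksum manifest under `out_dir`. Identical
#' configuration and seed yield byte-identical outputs.
#'
#' @param config A `lexacq_config` from [run_config()].
#' @param out_dir Output directory.
#' @param study Optional pre-built `lexacq_study` (or [read_study()] result);
#'   if `NULL`, one is generated from `config`.
#' @param write_inputs Also serialize the study input files under
#'   `out_dir/study/`.
#' @param last_stage Run the pipeline up to and including this stage
#'   (`"predictors"`, `"impute"`, `"fit"`, or `"consistency"`, the default).
#' @return The manifest list (also written to `manifest.json`): file
#'   checksums, fit summaries, warnings, timings.
#' @export
run_pipeline <- function(config = run_config(), out_dir, study = NULL,
                         write_inputs = TRUE, last_stage = "consistency") {
  stages <- c("predictors", "impute", "fit", "consistency")
  last_stage <- match.arg(last_stage, stages)
  stage_on <- function(s) match(s, stages) <= match(last_stage, stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); warnings <- character()
  tick <- function(name, expr) {
    t <- system.time(res <- force(expr))
    timings[[name]] <<- unname(t["elapsed"])
    res
  }

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  if (is.null(study)) {
    study <- tick("simulate", stage_error("simulate", "", generate_study(
      languages = config$languages, n_items = config$n_items,
      n_children = config$n_children, n_utterances = config$n_utterances,
      measures = config$measures, age_ranges = config$age_ranges,
      truth = config$truth, seed = config$seed,
      category_proportions = config$category_proportions,
      missingness_rates = config$missingness_rates)))
  }
  items <- if (!is.null(study$lexicon))
    study$lexicon$items[, c("item_id", "lexical_category")] else study$items
  langs <- names(study$corpora)
  measures <- intersect(lexacq_measures(), unique(study$administrations$measure))

  if (write_inputs && !is.null(study$lexicon))
    tick("write_inputs", write_study(study, file.path(out_dir, "study")))

  dir.create(file.path(out_dir, "predictors"), showWarnings = FALSE)
  predictor_tables <- list()
  tick("predictors", for (lang in langs) {
    predictor_tables[[lang]] <- stage_error("predictors", lang, {
      maps <- study$maps[[lang]]
      build_predictor_table(
        corpus = study$corpora[[lang]], forms = maps$forms,
        norms = study$norms[[lang]],
        transcriptions = study$transcriptions[[lang]],
        item_table = items,
        inflection_map = maps$inflection_map,
        polysemy_map = maps$polysemy_map,
        min_occurrences = config$min_occurrences)
    })
    tab <- predictor_tables[[lang]]
    readr::write_csv(tab, file.path(out_dir, "predictors",
                                    paste0(lang, ".csv")), na = "")
    meta <- attr(tab, "metadata")
    meta$scaling <- if (!is.null(meta$scaling)) as.list(meta$scaling)
    jsonlite::write_json(meta,
                         file.path(out_dir, "predictors",
                                   paste0(lang, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  })

  imputed <- list()
  if (stage_on("impute")) {
  dir.create(file.path(out_dir, "imputed"), showWarnings = FALSE)
  tick("impute", for (lang in langs) {
    res <- stage_error("impute", lang, impute_predictors(
      predictor_tables[[lang]], seed = derive_seed(config$seed, 5000 + match(lang, langs)),
      max_iterations = config$imputation$max_iterations,
      tolerance = config$imputation$tolerance))
    imputed[[lang]] <- res$table
    readr::write_csv(res$table, file.path(out_dir, "imputed",
                                          paste0(lang, ".csv")))
    jsonlite::write_json(res$report,
                         file.path(out_dir, "imputed",
                                   paste0(lang, "_report.json")),
                         auto_unbox = TRUE, digits = NA)
    diag <- stage_error("collinearity", lang,
                        collinearity_diagnostics(res$table))
    readr::write_csv(
      tibble::as_tibble(diag$correlations, rownames = "predictor"),
      file.path(out_dir, "imputed", paste0(lang, "_correlations.csv")))
    readr::write_csv(tibble::tibble(predictor = names(diag$vif),
                                    vif = unname(diag$vif)),
                     file.path(out_dir, "imputed", paste0(lang, "_vif.csv")))
  })
  }

  coef_tables <- list(); fit_meta <- list()
  if (stage_on("fit")) {
  tick("fit", for (m in measures) {
    for (lang in langs) {
      key <- paste(lang, m, sep = "_")
      coef_tables[[key]] <- stage_error("fit", paste(lang, m), {
        spec <- model_spec(
          m,
          include_age_interactions = config$model$include_age_interactions,
          include_category_interactions = config$model$include_category_interactions,
          category_coding = config$model$category_coding,
          random_slope = config$model$random_slope)
        adm <- study$administrations[study$administrations$language == lang, ]
        design <- build_design(adm, imputed[[lang]], spec,
                               age_range = config$age_ranges[[m]])
        fit_glmm(design, engine = config$model$engine)
      })
      alias <- attr(coef_tables[[key]], "aliased_terms")
      if (length(alias) > 0)
        warnings <- c(warnings,
                      paste0(key, ": aliased terms dropped (",
                             paste(alias, collapse = ", "), ")"))
      re <- attr(coef_tables[[key]], "random_effects")
      fit_meta[[key]] <- tibble::tibble(
        language = lang, measure = m,
        log_lik = attr(coef_tables[[key]], "log_lik"),
        n_obs = attr(coef_tables[[key]], "n_obs"),
        n_words = attr(coef_tables[[key]], "n_words"),
        sd_intercept = re$sd_intercept, sd_age_slope = re$sd_age_slope,
        re_correlation = re$correlation)
    }
  })
  all_coefs <- dplyr::bind_rows(coef_tables)
  readr::write_csv(all_coefs, file.path(out_dir, "coefficients.csv"))
  readr::write_csv(dplyr::bind_rows(fit_meta),
                   file.path(out_dir, "model_fits.csv"))
  }

  if (stage_on("consistency")) {
  dir.create(file.path(out_dir, "consistency"), showWarnings = FALSE)
  tick("consistency", for (m in measures) {
    stage_error("consistency", m, {
      vecs <- lapply(langs, function(lang) {
        t <- coef_tables[[paste(lang, m, sep = "_")]]
        setNames(t$estimate[t$type == "main"], t$predictor[t$type == "main"])
      })
      names(vecs) <- langs
      bad_main <- unique(unlist(lapply(vecs, function(v) names(v)[!is.finite(v)])))
      if (length(bad_main) > 0) {
        warnings <- c(warnings, paste0(
          m, ": predictors excluded from consistency (aliased main effect): ",
          paste(bad_main, collapse = ", ")))
        vecs <- lapply(vecs, function(v) v[setdiff(names(v), bad_main)])
      }
      if (length(langs) >= 2) {
        pc <- pairwise_correlations(vecs, method = config$consistency$method)
        readr::write_csv(
          tibble::as_tibble(pc$pairwise_r, rownames = "language"),
          file.path(out_dir, "consistency", paste0("pairwise_", m, ".csv")))
        bl <- shuffled_baseline(vecs,
                                n_bootstrap = config$consistency$n_bootstrap,
                                seed = derive_seed(config$seed, 7000 + match(m, measures)),
                                method = config$consistency$method)
        warnings <- c(warnings, bl$warnings)
        readr::write_csv(
          dplyr::mutate(bl$baseline_ci, n_bootstrap = bl$n_bootstrap,
                        seed = bl$seed),
          file.path(out_dir, "consistency", paste0("baseline_", m, ".csv")))
        cl <- cluster_languages(pc$pairwise_r,
                                linkage = config$consistency$linkage)
        writeLines(cl$newick,
                   file.path(out_dir, "consistency",
                             paste0("dendrogram_", m, ".nwk")))
      }
      if (config$model$include_category_interactions && length(langs) >= 2) {
        cat_eff <- dplyr::bind_rows(lapply(langs, function(lang)
          compose_category_effects(coef_tables[[paste(lang, m, sep = "_")]])))
        readr::write_csv(cat_eff,
                         file.path(out_dir, "consistency",
                                   paste0("category_effects_", m, ".csv")))
        # Aliased interaction terms (too few items in a category) leave NA
        # cell effects; those predictors are excluded with a recorded warning.
        bad_cat <- unique(cat_eff$predictor[!is.finite(cat_eff$effect)])
        if (length(bad_cat) > 0)
          warnings <- c(warnings, paste0(
            m, ": predictors excluded from category consistency (aliased): ",
            paste(bad_cat, collapse = ", ")))
        cat_ok <- cat_eff[!cat_eff$predictor %in% bad_cat, , drop = FALSE]
        if (length(unique(cat_ok$predictor)) >= 2)
          readr::write_csv(category_consistency(cat_ok,
                                                method = config$consistency$method),
                           file.path(out_dir, "consistency",
                                     paste0("category_consistency_", m, ".csv")))
      }
    })
  })
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lexacq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    languages = langs,
    measures = measures,
    n_model_fits = length(coef_tables),
    files = as.list(setNames(unname(sums), files)),
    warnings = warnings,
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
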