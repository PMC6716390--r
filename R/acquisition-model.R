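# Per-language, per-measure mixed-effects logistic acquisition models:
# each child x word response is predicted from standardized age, standardized
# word properties, property x age and property x lexical-category
# interactions, with a by-word random intercept and random age slope.
#
# Because every covariate is a function of (word, age) only -- the model has
# no child-level terms -- Bernoulli child x word rows are aggregated to
# word x age binomial counts before fitting. The likelihood is identical and
# fits are an order of magnitude faster.

#' Specification of an acquisition model
#'
#' @param measure `"comprehension"` or `"production"`.
#' @param predictors Ordered predictor names.
#' @param include_age_interactions Include predictor x age terms.
#' @param include_category_interactions Include lexical-category main-effect
#'   contrasts and predictor x category terms.
#' @param category_coding `"deviation"` (sum-to-zero, default) or
#'   `"treatment"` (cell-reference); both drop the `Other` level.
#' @param random_slope Include the by-word random age slope (with estimated
#'   correlation to the random intercept) in addition to the random intercept.
#' @return A `lexacq_model_spec` list.
#' @export
model_spec <- function(measure,
                       predictors = lexacq_predictors(),
                       include_age_interactions = TRUE,
                       include_category_interactions = TRUE,
                       category_coding = "deviation",
                       random_slope = TRUE) {
  if (!measure %in% lexacq_measures())
    abort_config("`measure` must be one of: comprehension, production")
  if (length(predictors) == 0) abort_config("`predictors` must be nonempty")
  structure(list(
    measure = measure,
    predictors = predictors,
    include_age_interactions = isTRUE(include_age_interactions),
    include_category_interactions = isTRUE(include_category_interactions),
    category_coding = match.arg(category_coding, c("deviation", "treatment")),
    random_slope = isTRUE(random_slope)
  ), class = "lexacq_model_spec")
}

#' Build the fixed-effect design for an acquisition model
#'
#' Produces one row per child x item observation with columns: intercept,
#' standardized age, each predictor, each predictor x age (if requested),
#' the category contrast columns, and each predictor x contrast column (if
#' requested). Under deviation coding each contrast column sums to zero
#' across the four category levels.
#'
#' @param administrations Tibble of checklist responses (child_id, language,
#'   age_months, measure, item_id, value).
#' @param predictor_table Complete, scaled predictor tibble with
#'   `lexical_category`.
#' @param spec A `lexacq_model_spec`.
#' @param age_range Month range used to standardize age (midpoint scaling);
#'   default the observed range.
#' @param age_method `"midpoint"` or `"zscore"`.
#' @return A `lexacq_design` list: `x` (fixed-effect matrix), `y` (0/1),
#'   `word` (factor), `age_z`, `spec`, `contrasts`, `language`, `measure`.
#' @export
build_design <- function(administrations, predictor_table, spec,
                         age_range = NULL, age_method = "midpoint") {
  adm <- administrations[administrations$measure == spec$measure, , drop = FALSE]
  if (nrow(adm) == 0)
    abort_config(paste0("no administrations for measure '", spec$measure, "'"))
  preds <- spec$predictors
  missing_cols <- setdiff(c(preds, "lexical_category"), names(predictor_table))
  if (length(missing_cols))
    abort_config(paste0("predictor table lacks: ",
                        paste(missing_cols, collapse = ", ")))
  if (anyNA(predictor_table[, preds]))
    abort_config("predictor table has missing cells; impute first")
  # Sanity check against raw (unscaled) tables. Bounds are deliberately
  # loose: MLU-w is missing for low-frequency items (not at random), so its
  # imputed cells can legitimately pull the column mean well away from 0;
  # raw corpus or rating scales (means of 3-14) are still caught.
  for (p in preds) {
    x <- predictor_table[[p]]
    if (abs(mean(x)) > 2 || sd(x) < 0.1 || sd(x) > 4)
      abort_config(paste0("predictor '", p, "' does not look standardized; ",
                          "run scale_predictors() before modelling"))
  }
  bad_cat <- setdiff(unique(predictor_table$lexical_category), lexacq_categories())
  if (length(bad_cat))
    abort_config(paste0("unknown lexical category: ", bad_cat[1]))
  if (!all(adm$item_id %in% predictor_table$item_id))
    abort_config("administrations reference items absent from the predictor table")

  if (is.null(age_range)) age_range <- range(adm$age_months)
  age_z <- scale_age(adm$age_months, age_range, age_method)
  ix <- match(adm$item_id, predictor_table$item_id)
  p_mat <- as.matrix(predictor_table[ix, preds])
  cm <- category_contrasts(spec$category_coding)
  cat_ix <- match(predictor_table$lexical_category[ix], rownames(cm))

  cols <- list(`(Intercept)` = rep(1, nrow(adm)), age_z = age_z)
  for (p in preds) cols[[p]] <- p_mat[, p]
  if (spec$include_age_interactions)
    for (p in preds) cols[[paste0(p, ":age_z")]] <- p_mat[, p] * age_z
  if (spec$include_category_interactions) {
    for (j in seq_len(ncol(cm))) cols[[colnames(cm)[j]]] <- cm[cat_ix, j]
    for (p in preds)
      for (j in seq_len(ncol(cm)))
        cols[[paste0(p, ":", colnames(cm)[j])]] <- p_mat[, p] * cm[cat_ix, j]
  }
  x <- do.call(cbind, cols)
  structure(list(
    x = x,
    y = as.integer(adm$value),
    word = factor(adm$item_id),
    age_z = age_z,
    spec = spec,
    contrasts = cm,
    language = if (length(unique(adm$language)) == 1) adm$language[1] else "multiple",
    measure = spec$measure
  ), class = "lexacq_design")
}

# Collapse Bernoulli rows to word x age binomial cells (identical likelihood:
# no covariate varies within a cell).
aggregate_design <- function(design) {
  key <- paste(design$word, design$age_z)
  g <- match(key, unique(key))
  first <- !duplicated(key)
  list(
    x = design$x[first, , drop = FALSE],
    k = as.numeric(rowsum(design$y, g)),
    n = as.numeric(rowsum(rep(1L, length(g)), g)),
    word = design$word[first],
    age_z = design$age_z[first]
  )
}

term_metadata <- function(terms, predictors) {
  type <- character(length(terms))
  predictor <- rep(NA_character_, length(terms))
  contrast <- rep(NA_integer_, length(terms))
  for (i in seq_along(terms)) {
    t <- terms[i]
    if (t == "(Intercept)") type[i] <- "intercept"
    else if (t == "age_z") type[i] <- "age"
    else if (t %in% predictors) { type[i] <- "main"; predictor[i] <- t }
    else if (grepl(":age_z$", t)) {
      type[i] <- "age_interaction"
      predictor[i] <- sub(":age_z$", "", t)
    } else if (grepl("^cat[0-9]+$", t)) {
      type[i] <- "category"
      contrast[i] <- as.integer(sub("^cat", "", t))
    } else {
      type[i] <- "category_interaction"
      predictor[i] <- sub(":cat[0-9]+$", "", t)
      contrast[i] <- as.integer(sub("^.*:cat", "", t))
    }
  }
  tibble::tibble(term = terms, type = type, predictor = predictor,
                 contrast = contrast)
}

#' Fit the mixed-effects logistic acquisition model
#'
#' Maximum-likelihood fit of the logistic GLMM under the Laplace
#' approximation, with Wald standard errors and p-values. The default engine
#' is glmmTMB; `engine = "glmer"` uses lme4 (also Laplace) and serves as an
#' independent cross-check.
#'
#' @param design A `lexacq_design` from [build_design()].
#' @param engine `"glmmTMB"` or `"glmer"`.
#' @param check_separation Run a fast fixed-effects GLM first and error if
#'   fitted coefficients diverge (complete or quasi-complete separation).
#' @return A coefficient tibble (language, measure, term, type, predictor,
#'   contrast, estimate, se, z, p, significant) with attributes:
#'   `random_effects` (estimated SDs and correlation), `log_lik`, `engine`,
#'   `contrasts`, `predictors`, `n_obs`, `n_words`, `spec`.
#' @export
fit_glmm <- function(design, engine = c("glmmTMB", "glmer"),
                     check_separation = TRUE) {
  engine <- match.arg(engine)
  if (!all(design$y %in% c(0L, 1L))) abort_config("response must be binary")
  if (nlevels(design$word) < 2) abort_config("need at least 2 words")
  agg <- aggregate_design(design)
  p <- ncol(agg$x)
  bn <- paste0("b", seq_len(p))
  dat <- as.data.frame(agg$x)
  names(dat) <- bn
  dat$k <- agg$k
  dat$n <- agg$n
  dat$word <- agg$word
  dat$age_z_re <- agg$age_z

  if (check_separation) {
    g <- suppressWarnings(glm(
      as.formula(paste("cbind(k, n - k) ~ 0 +", paste(bn, collapse = "+"))),
      data = dat, family = binomial()))
    # Separation shows up as a diverging fitted linear predictor (fitted
    # probabilities numerically 0/1; |eta| > 30 means within ~1e-13 of the
    # boundary). Large but mutually compensating coefficients under
    # near-collinearity are not separation, so the check is on eta, not on
    # coefficient magnitudes.
    if (max(abs(predict(g))) > 30)
      abort_config("complete or quasi-complete separation detected in fixed effects")
  }

  re_term <- if (design$spec$random_slope) "(1 + age_z_re | word)" else "(1 | word)"
  f <- as.formula(paste("cbind(k, n - k) ~ 0 +",
                        paste(bn, collapse = "+"), "+", re_term))
  if (engine == "glmmTMB") {
    fit <- suppressMessages(suppressWarnings(glmmTMB::glmmTMB(
      f, data = dat, family = binomial(),
      control = glmmTMB::glmmTMBControl(
        optCtrl = list(iter.max = 1000, eval.max = 1000)))))
    sdr <- fit$sdr
    co <- summary(fit)$coefficients$cond
    # Aliased rows carry NA estimates; they do not indicate non-convergence.
    if (any(!is.finite(co[, "Std. Error"]) & is.finite(co[, "Estimate"])))
      abort_config(paste0("GLMM did not converge (non-finite standard errors; ",
                          "pdHess=", isTRUE(sdr$pdHess), ")"))
    vc <- glmmTMB::VarCorr(fit)$cond$word
    ll <- as.numeric(logLik(fit))
  } else {
    fit <- suppressMessages(lme4::glmer(f, data = dat, family = binomial()))
    conv <- fit@optinfo$conv$lme4
    if (!is.null(conv$code) && conv$code != 0)
      abort_config(paste0("GLMM did not converge: ",
                          paste(unlist(conv$messages), collapse = "; ")))
    co <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)$word
    ll <- as.numeric(logLik(fit))
  }
  sds <- attr(vc, "stddev")
  corr <- if (design$spec$random_slope) attr(vc, "correlation")[1, 2] else NA_real_

  # Engines drop aliased (rank-deficient) columns; align estimates back to
  # the declared term order, leaving NA for aliased terms.
  ix <- match(bn, rownames(co))
  est <- co[ix, "Estimate"]
  se <- co[ix, "Std. Error"]
  aliased <- is.na(ix)

  terms <- colnames(design$x)
  meta <- term_metadata(terms, design$spec$predictors)
  z <- est / se
  out <- dplyr::bind_cols(
    tibble::tibble(language = design$language, measure = design$measure),
    meta,
    tibble::tibble(estimate = unname(est), se = unname(se), z = unname(z),
                   p = 2 * pnorm(-abs(z)),
                   significant = 2 * pnorm(-abs(z)) < 0.05))
  attr(out, "aliased_terms") <- terms[aliased]
  attr(out, "random_effects") <- tibble::tibble(
    sd_intercept = sds[1],
    sd_age_slope = if (design$spec$random_slope) sds[2] else NA_real_,
    correlation = corr)
  attr(out, "log_lik") <- ll
  attr(out, "engine") <- engine
  attr(out, "contrasts") <- design$contrasts
  attr(out, "predictors") <- design$spec$predictors
  attr(out, "n_obs") <- length(design$y)
  attr(out, "n_words") <- nlevels(design$word)
  attr(out, "spec") <- design$spec
  out
}

#' Fit a logistic acquisition trajectory for one word
#'
#' Maximum-likelihood logistic regression of the proportion of children
#' knowing the word on age in months.
#'
#' @param ages Age (months) per age group.
#' @param n_known Children knowing the word in each group.
#' @param n_children Children asked in each group.
#' @return A list: `intercept`, `slope` (logit units per month), and
#'   `fitted` (tibble age, proportion).
#' @export
fit_logistic_trajectory <- function(ages, n_known, n_children) {
  if (length(unique(ages)) < 2) abort_config("need at least 2 age groups")
  if (any(n_known < 0 | n_known > n_children))
    abort_config("`n_known` must lie in [0, n_children]")
  if (sum(n_known) == 0 || sum(n_known) == sum(n_children))
    abort_config("all-0 or all-1 responses: logistic MLE undefined")
  fit <- glm(cbind(n_known, n_children - n_known) ~ ages, family = binomial())
  co <- coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       fitted = tibble::tibble(age = ages,
                               proportion = unname(predict(fit, type = "response"))))
}

#' Average coefficient estimates across fitted models
#'
#' The cross-model mean estimate per term, with counts of models reaching
#' p < .05 and of models agreeing with the majority sign.
#'
#' @param tables List of coefficient tibbles from [fit_glmm()].
#' @param types Term types to keep (default `"main"`).
#' @return Tibble (term, type, predictor, mean_estimate, n_models,
#'   n_significant, n_sign_consistent).
#' @export
summarize_coefficients <- function(tables, types = "main") {
  if (length(tables) < 1) abort_config("need at least one coefficient table")
  term_sets <- lapply(tables, function(t) sort(t$term))
  if (length(unique(term_sets)) != 1)
    abort_config("mismatched term sets across coefficient tables")
  all_t <- dplyr::bind_rows(tables)
  all_t <- all_t[all_t$type %in% types, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(all_t, .data$term, .data$type, .data$predictor),
    mean_estimate = mean(.data$estimate),
    n_models = dplyr::n(),
    n_significant = sum(.data$significant),
    n_sign_consistent = max(sum(.data$estimate > 0), sum(.data$estimate < 0)),
    .groups = "drop")
}

#' Combined per-category effect of a predictor
#'
#' Maps the fitted contrast-coded terms to each lexical category's cell
#' effect: main effect of the predictor + the category's main effect + the
#' predictor x category interaction, all translated through the contrast
#' coding.
#'
#' @param table A coefficient tibble from a model fit with category
#'   interactions.
#' @param predictors,categories Which cells to return; default all.
#' @return Tibble (language, measure, predictor, category, effect).
#' @export
compose_category_effects <- function(table,
                                     predictors = attr(table, "predictors"),
                                     categories = lexacq_categories()) {
  cm <- attr(table, "contrasts")
  if (is.null(cm)) abort_config("coefficient table lacks contrast metadata")
  est <- setNames(table$estimate, table$term)
  need <- c(predictors, colnames(cm),
            as.vector(outer(predictors, colnames(cm), paste, sep = ":")))
  missing_terms <- setdiff(need, names(est))
  if (length(missing_terms))
    abort_config(paste0("missing model term(s): ",
                        paste(head(missing_terms, 3), collapse = ", ")))
  out <- list()
  for (p in predictors) {
    for (cat in categories) {
      w <- cm[cat, ]
      eff <- est[p] +
        sum(w * est[colnames(cm)]) +
        sum(w * est[paste0(p, ":", colnames(cm))])
      out[[paste(p, cat)]] <- tibble::tibble(
        language = table$language[1], measure = table$measure[1],
        predictor = p, category = cat, effect = unname(eff))
    }
  }
  dplyr::bind_rows(out)
}
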