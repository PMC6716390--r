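# Synthetic study generation: checklist administrations, child-directed-speech
# corpora, rating norms and mapping tables, all driven by a known ground truth
# so downstream estimation can be validated against it.

#' Ground-truth effect structure for a synthetic study
#'
#' Defines the generative coefficients used by [generate_administrations()].
#' All effects live on the logit scale in standardized-predictor units, so a
#' fitted standardized coefficient estimates the corresponding entry directly.
#'
#' @param languages Character vector of language labels.
#' @param beta Named numeric vector of main effects, one per predictor (names
#'   must be `lexacq_predictors()` in order), or a list of such vectors, one
#'   per language.
#' @param beta_age Fixed effect of standardized age (logit units per unit
#'   standardized age).
#' @param beta_age_interactions Per-predictor age-interaction effects; a named
#'   vector (recycled across languages) or per-language list. Default all 0.
#' @param beta_category_interactions Per-predictor, per-category interaction
#'   effects: a `predictors x categories` matrix (or per-language list of
#'   them), on the cell scale. Rows are centered across categories so the main
#'   effect keeps its meaning as the across-category average. Default all 0.
#' @param beta_category_main Length-4 vector of category main effects (cell
#'   scale, centered). Default all 0.
#' @param intercept Baseline log-odds of knowing a word at the age midpoint
#'   for a word with all predictors at 0.
#' @param random_intercept_sd,random_slope_sd Standard deviations of the
#'   by-word random intercept and random age slope (logit units).
#' @param random_effect_corr Correlation between the two random effects.
#' @return An object of class `lexacq_truth`.
#' @export
ground_truth <- function(languages,
                         beta,
                         beta_age = 2,
                         beta_age_interactions = NULL,
                         beta_category_interactions = NULL,
                         beta_category_main = NULL,
                         intercept = 0,
                         random_intercept_sd = 0.5,
                         random_slope_sd = 0.2,
                         random_effect_corr = 0.25) {
  preds <- lexacq_predictors()
  cats <- lexacq_categories()
  if (!is.character(languages) || length(languages) < 1)
    abort_config("`languages` must be a nonempty character vector")
  if (random_intercept_sd < 0 || random_slope_sd < 0)
    abort_config("random-effect SDs must be nonnegative")
  if (abs(random_effect_corr) > 1)
    abort_config("`random_effect_corr` must lie in [-1, 1]")

  per_language_vec <- function(x, what) {
    if (is.null(x)) x <- setNames(rep(0, length(preds)), preds)
    if (!is.list(x)) x <- setNames(rep(list(x), length(languages)), languages)
    x <- lapply(x, function(v) {
      if (is.null(names(v))) names(v) <- preds
      if (!identical(sort(names(v)), sort(preds)))
        abort_config(paste0("`", what, "` must be named by the 9 predictors"))
      v[preds]
    })
    if (length(unique(vapply(x, length, 1L))) != 1)
      abort_config("beta vectors must have the same length across languages")
    if (is.null(names(x))) names(x) <- languages
    x[languages]
  }
  per_language_mat <- function(x) {
    if (is.null(x))
      x <- matrix(0, length(preds), length(cats), dimnames = list(preds, cats))
    if (!is.list(x)) x <- setNames(rep(list(x), length(languages)), languages)
    x <- lapply(x, function(m) {
      m <- as.matrix(m)
      stopifnot(nrow(m) == length(preds), ncol(m) == length(cats))
      dimnames(m) <- list(preds, cats)
      m - rowMeans(m)  # center cell effects so main effects stay interpretable
    })
    if (is.null(names(x))) names(x) <- languages
    x[languages]
  }
  cat_main <- if (is.null(beta_category_main)) rep(0, length(cats)) else beta_category_main
  stopifnot(length(cat_main) == length(cats))
  cat_main <- setNames(cat_main - mean(cat_main), cats)

  structure(list(
    languages = languages,
    beta = per_language_vec(beta, "beta"),
    beta_age = beta_age,
    beta_age_interactions = per_language_vec(beta_age_interactions, "beta_age_interactions"),
    beta_category_interactions = per_language_mat(beta_category_interactions),
    beta_category_main = cat_main,
    intercept = intercept,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    random_effect_corr = random_effect_corr
  ), class = "lexacq_truth")
}

#' Default ground truth mirroring typical cross-linguistic effect magnitudes
#'
#' Main effects are set to the across-language, across-measure mean
#' standardized coefficients reported in large-scale checklist studies of
#' early word learning: frequency is the strongest positive predictor,
#' concreteness and the residual solo/final frequencies follow, word length
#' and utterance length act negatively, valence and arousal are near zero.
#'
#' @param languages Character vector of language labels.
#' @inheritParams ground_truth
#' @return A `lexacq_truth` object.
#' @export
default_truth <- function(languages, ...) {
  beta <- c(frequency = 0.23, solo_frequency = 0.17, final_frequency = 0.13,
            mlu_w = -0.14, n_phonemes = -0.19, concreteness = 0.18,
            valence = 0.06, arousal = 0.003, babiness = 0.13)
  ground_truth(languages, beta = beta, ...)
}

#' Default correlation structure for latent item properties
#'
#' Mimics the correlation structure observed among real corpus-derived
#' predictors: frequency is negatively correlated with concreteness and with
#' word length (Zipf's law), and utterance length with solo frequency.
#'
#' @return A 9 x 9 positive-definite correlation matrix.
#' @export
default_property_corr <- function() {
  preds <- lexacq_predictors()
  r <- diag(length(preds))
  dimnames(r) <- list(preds, preds)
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_r("frequency", "concreteness", -0.35)
  set_r("frequency", "n_phonemes", -0.33)
  set_r("mlu_w", "solo_frequency", -0.44)
  r
}

#' Generate a synthetic lexicon
#'
#' Draws item lexical categories from a multinomial and latent standardized
#' item properties from a multivariate normal with a configurable correlation
#' matrix, and builds per-language word forms plus inflection and polysemy
#' mapping tables.
#'
#' @param n_items Number of checklist items (>= 1).
#' @param category_proportions Probabilities over
#'   Nouns/Predicates/Function Words/Other; must sum to 1.
#' @param languages Language labels.
#' @param seed Integer seed; identical seeds give byte-identical lexicons.
#' @param property_corr Correlation matrix for the latent properties.
#' @param n_polysemy_pairs Number of item pairs sharing a surface form.
#' @param inflected_fraction Fraction of items given an inflected variant.
#' @return A `lexacq_lexicon` list with elements `items` (item_id, category,
#'   latent property columns `latent_*`), `forms`, `inflections`, `polysemy`.
#' @export
generate_lexicon <- function(n_items,
                             category_proportions = c(0.5, 0.25, 0.125, 0.125),
                             languages = "lang1",
                             seed = 1,
                             property_corr = default_property_corr(),
                             n_polysemy_pairs = 2,
                             inflected_fraction = 0.5) {
  if (n_items < 1) abort_config("`n_items` must be >= 1")
  if (!is_simplex(category_proportions) || length(category_proportions) != 4)
    abort_config("`category_proportions` must be 4 nonnegative values summing to 1")
  preds <- lexacq_predictors()
  with_seed(seed, {
    item_id <- sprintf("item%04d", seq_len(n_items))
    category <- sample(lexacq_categories(), n_items, replace = TRUE,
                       prob = category_proportions)
    latent <- MASS::mvrnorm(n_items, mu = rep(0, length(preds)),
                            Sigma = property_corr)
    latent <- matrix(latent, nrow = n_items)
    colnames(latent) <- paste0("latent_", preds)
    items <- tibble::tibble(item_id = item_id, lexical_category = category)
    items <- dplyr::bind_cols(items, tibble::as_tibble(latent))

    n_poly <- min(n_polysemy_pairs, floor(n_items / 2))
    poly_items <- if (n_poly > 0) sample(item_id, 2 * n_poly) else character()
    inflect_pool <- setdiff(item_id, poly_items)
    n_infl <- round(inflected_fraction * length(inflect_pool))
    inflected <- if (n_infl > 0) sample(inflect_pool, n_infl) else character()

    forms <- list(); inflections <- list(); polysemy <- list()
    for (lang in languages) {
      wf <- paste0(lang, "_w", sprintf("%04d", seq_len(n_items)))
      names(wf) <- item_id
      if (n_poly > 0) {
        for (k in seq_len(n_poly)) {
          pair <- poly_items[c(2 * k - 1, 2 * k)]
          shared <- paste0(lang, "_poly", k)
          wf[pair] <- shared
          polysemy[[length(polysemy) + 1]] <- tibble::tibble(
            language = lang, word_form = shared, item_id = pair)
        }
      }
      forms[[lang]] <- tibble::tibble(language = lang, item_id = item_id,
                                      word_form = unname(wf))
      if (length(inflected) > 0) {
        inflections[[lang]] <- tibble::tibble(
          language = lang,
          variant_form = paste0(wf[inflected], "s"),
          canonical_item = unname(wf[inflected]))
      }
    }
    structure(list(
      items = items,
      forms = dplyr::bind_rows(forms),
      inflections = if (length(inflections)) dplyr::bind_rows(inflections)
        else tibble::tibble(language = character(), variant_form = character(),
                            canonical_item = character()),
      polysemy = if (length(polysemy)) dplyr::bind_rows(polysemy)
        else tibble::tibble(language = character(), word_form = character(),
                            item_id = character())
    ), class = "lexacq_lexicon")
  })
}

# Per-language mapping tables in the interchange layout used by the
# predictor-extraction module.
lexicon_maps <- function(lexicon, language) {
  infl <- dplyr::filter(lexicon$inflections, .data$language == !!language)
  poly <- dplyr::filter(lexicon$polysemy, .data$language == !!language)
  forms <- dplyr::filter(lexicon$forms, .data$language == !!language)
  list(
    forms = forms[, c("item_id", "word_form")],
    inflection_map = infl[, c("variant_form", "canonical_item")],
    polysemy_map = poly[, c("word_form", "item_id")]
  )
}

#' Generate a synthetic child-directed-speech corpus
#'
#' Emits tokenized utterances whose empirical per-item log frequencies track
#' `target_log_frequencies` and whose per-item mean utterance lengths track
#' `mlu_profile`. Each utterance carries one item token (possibly as an
#' inflected variant or shared polysemous form) padded with filler tokens;
#' item position within the utterance is uniform, so solo and utterance-final
#' occurrences arise naturally.
#'
#' @param lexicon A `lexacq_lexicon`.
#' @param language Which language's word forms to use.
#' @param n_utterances Number of utterances (>= 1).
#' @param seed Integer seed.
#' @param target_log_frequencies Per-item relative log frequencies (any
#'   additive constant is irrelevant); default `freq_spread *` the latent
#'   frequency property.
#' @param mlu_profile Per-item target mean utterance length in words; default
#'   an affine map of the latent utterance-length property, floored at 1.
#' @param freq_spread Scale applied to latent frequency for the default
#'   targets (log units per latent SD).
#' @param mlu_sd Utterance-to-utterance SD of lengths around the item target.
#' @param inflect_rate Probability an occurrence uses the inflected variant.
#' @param child_fraction Fraction of utterances tagged as child speech.
#' @param n_filler_types Size of the filler (non-item) vocabulary.
#' @return A tibble with class `lexacq_corpus`: columns `speaker`
#'   (`"ADU"`/`"CHI"`) and `tokens` (list of character vectors).
#' @export
generate_corpus <- function(lexicon, language = lexicon$forms$language[1],
                            n_utterances, seed = 1,
                            target_log_frequencies = NULL,
                            mlu_profile = NULL,
                            freq_spread = 1.5,
                            mlu_sd = 1.5,
                            inflect_rate = 0.3,
                            child_fraction = 0.05,
                            n_filler_types = 200) {
  if (n_utterances < 1) abort_config("`n_utterances` must be >= 1")
  items <- lexicon$items
  n <- nrow(items)
  if (is.null(target_log_frequencies))
    target_log_frequencies <- freq_spread * items$latent_frequency
  if (is.null(mlu_profile))
    mlu_profile <- pmax(1, 4 + 1.2 * items$latent_mlu_w)
  if (length(target_log_frequencies) != n || length(mlu_profile) != n)
    abort_config("targets must have one value per item")
  if (!all(is.finite(target_log_frequencies)) || !all(is.finite(mlu_profile)))
    abort_config("targets must be finite")
  maps <- lexicon_maps(lexicon, language)
  wf <- setNames(maps$forms$word_form, maps$forms$item_id)
  variant <- setNames(maps$inflection_map$variant_form,
                      maps$inflection_map$canonical_item)

  with_seed(seed, {
    w <- exp(target_log_frequencies - max(target_log_frequencies))
    head_ix <- sample.int(n, n_utterances, replace = TRUE, prob = w)
    len <- pmax(1L, as.integer(round(rnorm(n_utterances, mlu_profile[head_ix], mlu_sd))))
    pos <- 1L + as.integer(floor(runif(n_utterances) * len))
    form <- wf[items$item_id[head_ix]]
    has_var <- form %in% names(variant)
    use_var <- has_var & (runif(n_utterances) < inflect_rate)
    form[use_var] <- variant[form[use_var]]
    fillers <- sprintf("f%03d", seq_len(n_filler_types))
    fill_prob <- 1 / seq_len(n_filler_types)
    speaker <- ifelse(runif(n_utterances) < child_fraction, "CHI", "ADU")
    tokens <- vector("list", n_utterances)
    for (u in seq_len(n_utterances)) {
      toks <- if (len[u] > 1)
        sample(fillers, len[u], replace = TRUE, prob = fill_prob)
      else character(1)
      toks[pos[u]] <- form[u]
      tokens[[u]] <- toks
    }
    out <- tibble::tibble(speaker = speaker, tokens = tokens)
    class(out) <- c("lexacq_corpus", class(out))
    out
  })
}

# Standardize age in months. "midpoint" maps the range endpoints to -1/+1;
# "zscore" standardizes by the sample mean and SD of the supplied ages.
scale_age <- function(age, age_range, method = c("midpoint", "zscore")) {
  method <- match.arg(method)
  if (method == "midpoint") {
    mid <- mean(age_range)
    half <- diff(age_range) / 2
    if (half <= 0) abort_config("`age_range` must span more than one month")
    (age - mid) / half
  } else {
    (age - mean(age)) / sd(age)
  }
}

#' Generate checklist administrations from the ground truth
#'
#' For each synthetic child (one administration per child, cross-sectional),
#' the probability of knowing item \eqn{w} at standardized age \eqn{a} is
#' \eqn{logit^{-1}(\alpha + u_w + (\beta_{age} + s_w) a + x_w'\beta +
#' (x_w'\beta_{age\times}) a + \gamma_{c(w)} + x_w'\delta_{\cdot c(w)})},
#' with \eqn{(u_w, s_w)} bivariate normal per the ground truth.
#'
#' @param lexicon A `lexacq_lexicon`.
#' @param truth A `lexacq_truth`.
#' @param language Language label (must appear in `truth$languages`).
#' @param n_children Number of children (>= 1).
#' @param measure `"comprehension"` or `"production"`.
#' @param age_range Integer months, e.g. `c(8, 30)`.
#' @param seed Integer seed.
#' @param age_method Age standardization method (see details in the vignette).
#' @return A tibble with columns child_id, language, age_months, measure,
#'   item_id, value (0/1).
#' @export
generate_administrations <- function(lexicon, truth, language,
                                     n_children, measure,
                                     age_range = c(8, 30), seed = 1,
                                     age_method = "midpoint") {
  if (!measure %in% lexacq_measures())
    abort_config("`measure` must be one of: comprehension, production")
  if (n_children < 1) abort_config("`n_children` must be >= 1")
  if (!language %in% truth$languages)
    abort_config(paste0("language '", language, "' not in ground truth"))
  items <- lexicon$items
  preds <- lexacq_predictors()
  x <- as.matrix(items[, paste0("latent_", preds)])
  colnames(x) <- preds
  beta <- truth$beta[[language]]
  beta_age_int <- truth$beta_age_interactions[[language]]
  cat_int <- truth$beta_category_interactions[[language]]
  cat_ix <- match(items$lexical_category, lexacq_categories())

  with_seed(seed, {
    ages <- sample(seq(age_range[1], age_range[2]), n_children, replace = TRUE)
    age_z <- scale_age(ages, age_range, age_method)
    re_sig <- matrix(c(
      truth$random_intercept_sd^2,
      truth$random_effect_corr * truth$random_intercept_sd * truth$random_slope_sd,
      truth$random_effect_corr * truth$random_intercept_sd * truth$random_slope_sd,
      truth$random_slope_sd^2), 2)
    re <- if (all(diag(re_sig) == 0)) matrix(0, nrow(items), 2)
      else MASS::mvrnorm(nrow(items), c(0, 0), re_sig)
    re <- matrix(re, ncol = 2)

    base <- truth$intercept + re[, 1] +
      as.numeric(x %*% beta) +
      truth$beta_category_main[cat_ix] +
      rowSums(x * t(cat_int)[cat_ix, , drop = FALSE])
    slope <- truth$beta_age + re[, 2] + as.numeric(x %*% beta_age_int)
    eta <- outer(base, rep(1, n_children)) + outer(slope, age_z)
    y <- matrix(rbinom(length(eta), 1, plogis(eta)), nrow(items))

    tibble::tibble(
      child_id = rep(sprintf("%s_%s_c%05d", language, measure,
                             seq_len(n_children)), each = nrow(items)),
      language = language,
      age_months = rep(ages, each = nrow(items)),
      measure = measure,
      item_id = rep(items$item_id, n_children),
      value = as.integer(y)
    )
  })
}

#' Inject missing-completely-at-random cells into a norms table
#'
#' @param norm_table Tibble with `item_id` plus numeric norm columns.
#' @param rates Named vector of per-column missingness fractions in \[0, 1\].
#'   `n_phonemes` may not be made missing (word length is always computable
#'   from a transcription, so that column is complete by construction).
#' @param mechanism Only `"MCAR"` is supported.
#' @param seed Integer seed.
#' @return The table with the selected cells set to `NA`.
#' @export
inject_missingness <- function(norm_table, rates, mechanism = "MCAR", seed = 1) {
  mechanism <- match.arg(mechanism, "MCAR")
  if (length(rates) == 0) return(norm_table)
  if (is.null(names(rates)) || !all(names(rates) %in% names(norm_table)))
    abort_config("`rates` must be named by columns of `norm_table`")
  if (any(rates < 0 | rates > 1))
    abort_config("missingness rates must lie in [0, 1]")
  if ("n_phonemes" %in% names(rates))
    abort_config("`n_phonemes` must remain complete")
  with_seed(seed, {
    for (col in names(rates)) {
      miss <- runif(nrow(norm_table)) < rates[[col]]
      norm_table[[col]][miss] <- NA
    }
    norm_table
  })
}

#' Generate a complete multi-language synthetic study
#'
#' Bundles a shared lexicon (items play the role of cross-language
#' translation equivalents), per-language corpora, rating norms with
#' language-specific missingness, phonemic transcriptions, mapping tables,
#' and checklist administrations for each requested measure.
#'
#' @param languages Language labels.
#' @param n_items,n_children,n_utterances Study sizes (children are per
#'   language and measure).
#' @param measures Subset of `c("comprehension", "production")`.
#' @param age_ranges Named list of integer month ranges per measure.
#' @param truth A `lexacq_truth`; default [default_truth()].
#' @param seed Master integer seed; all per-language, per-stage seeds are
#'   derived from it deterministically.
#' @param category_proportions,missingness_rates,corpus_args Generator knobs;
#'   see [generate_lexicon()], [inject_missingness()], [generate_corpus()].
#' @return A `lexacq_study` list: `administrations`, `corpora`, `norms`,
#'   `transcriptions`, `maps`, `lexicon`, `truth`, `age_ranges`, `seed`.
#' @export
generate_study <- function(languages = c("lang1", "lang2", "lang3"),
                           n_items = 100, n_children = 500,
                           n_utterances = 5000,
                           measures = c("comprehension", "production"),
                           age_ranges = list(comprehension = c(8, 18),
                                             production = c(8, 30)),
                           truth = NULL,
                           seed = 1,
                           category_proportions = c(0.5, 0.25, 0.125, 0.125),
                           missingness_rates = c(concreteness = 0.005,
                                                 valence = 0.10,
                                                 arousal = 0.10,
                                                 babiness = 0.20),
                           corpus_args = list()) {
  measures <- match.arg(measures, lexacq_measures(), several.ok = TRUE)
  if (is.null(truth)) truth <- default_truth(languages)
  seed <- check_seed(seed)
  lexicon <- generate_lexicon(n_items, category_proportions,
                              languages = languages,
                              seed = derive_seed(seed, 1))
  items <- lexicon$items

  # Rating norms: affine maps of the latent properties onto instrument-like
  # scales (concreteness 1-5, valence/arousal 1-9, babiness 1-10).
  norms_full <- tibble::tibble(
    item_id = items$item_id,
    concreteness = 3 + 0.8 * items$latent_concreteness,
    valence = 5 + 1.5 * items$latent_valence,
    arousal = 5 + 1.5 * items$latent_arousal,
    babiness = 5.5 + 1.8 * items$latent_babiness
  )
  n_phon <- pmax(1L, as.integer(round(3.5 + 1.3 * items$latent_n_phonemes)))
  inventory <- c("p", "t", "k", "b", "d", "g", "m", "n", "s", "z",
                 "l", "r", "a", "e", "i", "o", "u")

  corpora <- list(); norms <- list(); transcriptions <- list(); maps <- list()
  admins <- list()
  for (li in seq_along(languages)) {
    lang <- languages[li]
    corpora[[lang]] <- do.call(generate_corpus, c(list(
      lexicon = lexicon, language = lang, n_utterances = n_utterances,
      seed = derive_seed(seed, 100 + li)), corpus_args))
    norms[[lang]] <- inject_missingness(norms_full, missingness_rates,
                                        seed = derive_seed(seed, 200 + li))
    transcriptions[[lang]] <- with_seed(derive_seed(seed, 300 + li), {
      tibble::tibble(
        item_id = items$item_id,
        phonemes = vapply(n_phon, function(k)
          paste(sample(inventory, k, replace = TRUE), collapse = " "), "")
      )
    })
    maps[[lang]] <- lexicon_maps(lexicon, lang)
    for (mi in seq_along(measures)) {
      m <- measures[mi]
      admins[[paste(lang, m)]] <- generate_administrations(
        lexicon, truth, lang, n_children, m,
        age_range = age_ranges[[m]],
        seed = derive_seed(seed, 1000 + 10 * li + mi))
    }
  }
  structure(list(
    administrations = dplyr::bind_rows(admins),
    corpora = corpora,
    norms = norms,
    transcriptions = transcriptions,
    maps = maps,
    lexicon = lexicon,
    truth = truth,
    measures = measures,
    age_ranges = age_ranges,
    seed = seed
  ), class = "lexacq_study")
}
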