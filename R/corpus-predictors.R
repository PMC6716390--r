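# Extraction of environmental and form predictors from a corpus, and assembly
# of the per-language predictor table.
#
# Token-to-item resolution order (deterministic, auditable):
#   1. case-fold the token;
#   2. collapse inflected/synonym variants to their canonical surface form;
#   3. if the canonical form is listed as polysemous, split its unit mass
#      uniformly over the k mapped senses (1/k each);
#   4. otherwise match the canonical form against the item form table;
#   5. tokens matching nothing are tallied as unmapped.
# Every token therefore contributes total mass 1 (or is counted as unmapped),
# so mass is conserved: sum(item counts) + unmapped = total tokens.

# Resolve every token of the speaker-filtered corpus to (item, mass) rows.
# Returns a tibble(utt, utt_len, pos, item_id, mass) with attributes
# total_tokens and unmapped_tokens.
token_item_mass <- function(corpus, forms, inflection_map = NULL,
                            polysemy_map = NULL, speaker_filter = "adult") {
  if (nrow(corpus) == 0) abort_config("corpus is empty")
  corpus <- filter_speaker(corpus, speaker_filter)
  n_utt <- nrow(corpus)
  lens <- lengths(corpus$tokens)
  tok <- tolower(unlist(corpus$tokens, use.names = FALSE))
  utt <- rep(seq_len(n_utt), lens)
  pos <- sequence(lens)
  utt_len <- rep(lens, lens)
  total_tokens <- length(tok)

  # inflection/synonym collapsing
  if (!is.null(inflection_map) && nrow(inflection_map) > 0) {
    mi <- match(tok, tolower(inflection_map$variant_form))
    hit <- !is.na(mi)
    tok[hit] <- tolower(inflection_map$canonical_item[mi[hit]])
  }

  poly_forms <- if (!is.null(polysemy_map) && nrow(polysemy_map) > 0)
    tolower(polysemy_map$word_form) else character()
  direct <- forms[!(tolower(forms$word_form) %in% poly_forms), , drop = FALSE]

  is_poly <- tok %in% poly_forms
  di <- match(tok, tolower(direct$word_form))
  is_direct <- !is.na(di) & !is_poly
  unmapped <- sum(!is_poly & !is_direct)

  out <- list()
  if (any(is_direct)) {
    out$direct <- tibble::tibble(
      utt = utt[is_direct], utt_len = utt_len[is_direct],
      pos = pos[is_direct],
      item_id = direct$item_id[di[is_direct]], mass = 1)
  }
  if (any(is_poly)) {
    senses <- split(polysemy_map$item_id, tolower(polysemy_map$word_form))
    k <- lengths(senses)
    ptok <- tok[is_poly]
    reps <- k[ptok]
    out$poly <- tibble::tibble(
      utt = rep(utt[is_poly], reps),
      utt_len = rep(utt_len[is_poly], reps),
      pos = rep(pos[is_poly], reps),
      item_id = unlist(senses[ptok], use.names = FALSE),
      mass = rep(1 / k[ptok], reps))
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(utt = integer(), utt_len = integer(), pos = integer(),
                   item_id = character(), mass = numeric())
  attr(res, "total_tokens") <- total_tokens
  attr(res, "unmapped_tokens") <- unmapped
  res
}

sum_mass_by_item <- function(mass_tbl, item_ids, which = rep(TRUE, nrow(mass_tbl))) {
  m <- mass_tbl[which, , drop = FALSE]
  agg <- tapply(m$mass, factor(m$item_id, levels = item_ids), sum, default = 0)
  tibble::tibble(item_id = item_ids, count = as.numeric(agg))
}

#' Count unigram occurrences per checklist item
#'
#' Collapses inflected/synonym variants, splits polysemous forms uniformly
#' over their senses (so counts may be fractional), and restricts to
#' utterances of the requested speaker role.
#'
#' @param corpus A `lexacq_corpus` (see [read_chat_lite()]).
#' @param forms Tibble (item_id, word_form) defining the item universe.
#' @param inflection_map Tibble (variant_form, canonical_item) mapping
#'   variants to canonical surface forms; may be `NULL`.
#' @param polysemy_map Tibble (word_form, item_id), one row per sense; may be
#'   `NULL`.
#' @param speaker_filter `"adult"` (default), `"child"`, or `"all"`.
#' @return A list: `counts` (tibble item_id, count, zero for unseen items),
#'   `total_tokens` (all tokens in the filtered corpus), `unmapped_tokens`.
#' @export
count_unigrams <- function(corpus, forms, inflection_map = NULL,
                           polysemy_map = NULL, speaker_filter = "adult") {
  m <- token_item_mass(corpus, forms, inflection_map, polysemy_map, speaker_filter)
  list(counts = sum_mass_by_item(m, unique(forms$item_id)),
       total_tokens = attr(m, "total_tokens"),
       unmapped_tokens = attr(m, "unmapped_tokens"))
}

#' Laplace-smoothed, length-normalized log frequency
#'
#' Counts of zero are replaced by one (Laplace smoothing), normalized to the
#' corpus length on a per-million-token base, and natural-log transformed:
#' `ln(max(count, 1) / corpus_token_total * base)`.
#'
#' @param counts Numeric per-item counts (possibly fractional). Counts
#'   strictly between 0 and 1 (fractional polysemy mass) are left as is;
#'   only exact zeros are floored to 1.
#' @param corpus_token_total Total tokens in the (speaker-filtered) corpus.
#' @param base Normalization base; tokens per million by default, recorded in
#'   output metadata by [build_predictor_table()].
#' @return Per-item log frequencies.
#' @export
log_normalized_frequency <- function(counts, corpus_token_total, base = 1e6) {
  if (any(counts < 0)) abort_config("counts must be nonnegative")
  if (corpus_token_total < 1) abort_config("`corpus_token_total` must be >= 1")
  log(ifelse(counts == 0, 1, counts) / corpus_token_total * base)
}

#' Solo and utterance-final occurrence counts
#'
#' A solo occurrence is a token that is the only word of its utterance; a
#' final occurrence is the last token of an utterance of length >= 2
#' (single-word utterances are not counted as final). Polysemy mass splitting
#' and variant collapsing follow [count_unigrams()].
#'
#' @inheritParams count_unigrams
#' @return A list with tibbles `solo` and `final` (item_id, count), plus
#'   `total_tokens`.
#' @export
solo_and_final_counts <- function(corpus, forms, inflection_map = NULL,
                                  polysemy_map = NULL, speaker_filter = "adult") {
  m <- token_item_mass(corpus, forms, inflection_map, polysemy_map, speaker_filter)
  ids <- unique(forms$item_id)
  list(solo = sum_mass_by_item(m, ids, m$utt_len == 1),
       final = sum_mass_by_item(m, ids, m$utt_len >= 2 & m$pos == m$utt_len),
       total_tokens = attr(m, "total_tokens"))
}

#' Residualize a covariate out of a target
#'
#' Ordinary least-squares residuals from the simple regression of `target`
#' on `covariate`; used to remove unigram frequency from solo and final log
#' frequencies so they measure variance beyond plain frequency.
#'
#' @param target,covariate Numeric vectors over the same items.
#' @return Residual vector (NA where `target` is NA).
#' @export
residualize <- function(target, covariate) {
  if (length(target) != length(covariate))
    abort_config("`target` and `covariate` must have the same length")
  ok <- !is.na(target) & !is.na(covariate)
  if (sum(ok) < 3) abort_config("need at least 3 complete item pairs")
  if (obs_sd(covariate[ok]) == 0 || is.na(obs_sd(covariate[ok])))
    abort_config("`covariate` is constant; residualization undefined")
  fit <- lm.fit(cbind(1, covariate[ok]), target[ok])
  out <- rep(NA_real_, length(target))
  out[ok] <- target[ok] - cbind(1, covariate[ok]) %*% fit$coefficients
  out
}

#' Mean length (in words) of the utterances containing each item
#'
#' Each occurrence contributes its utterance's token length once, weighted by
#' its (possibly fractional) polysemy mass. Items whose total occurrence mass
#' is below `min_occurrences` get `NA` (too few contexts for a stable
#' estimate).
#'
#' @inheritParams count_unigrams
#' @param min_occurrences Occurrence threshold below which MLU-w is missing.
#' @return Tibble (item_id, mlu_w, occurrences).
#' @export
compute_mlu_w <- function(corpus, forms, inflection_map = NULL,
                          polysemy_map = NULL, speaker_filter = "adult",
                          min_occurrences = 10) {
  m <- token_item_mass(corpus, forms, inflection_map, polysemy_map, speaker_filter)
  ids <- unique(forms$item_id)
  f <- factor(m$item_id, levels = ids)
  tot <- as.numeric(tapply(m$mass, f, sum, default = 0))
  wlen <- as.numeric(tapply(m$mass * m$utt_len, f, sum, default = 0))
  mlu <- ifelse(tot >= min_occurrences, wlen / tot, NA_real_)
  tibble::tibble(item_id = ids, mlu_w = mlu, occurrences = tot)
}

#' Count phonemes from delimiter-separated transcriptions
#'
#' @param transcription_table Tibble (item_id, phonemes) where `phonemes` is
#'   a whitespace-delimited string of phoneme symbols.
#' @return Tibble (item_id, n_phonemes); never missing.
#' @export
count_phonemes <- function(transcription_table) {
  ph <- trimws(transcription_table$phonemes)
  if (any(is.na(ph) | !nzchar(ph)))
    abort_config("empty phonemic transcription")
  tibble::tibble(item_id = transcription_table$item_id,
                 n_phonemes = lengths(stringr::str_split(ph, "\\s+")))
}

#' Center and scale predictor columns within a language
#'
#' Each numeric predictor is z-scored using the mean and sample SD of its
#' non-missing values; missing cells stay missing. The per-column means and
#' SDs are recorded in the `"scaling"` attribute so values can be mapped back
#' to their original units.
#'
#' @param table Predictor tibble.
#' @param predictors Columns to scale; defaults to the canonical 9.
#' @return The scaled tibble with a `"scaling"` attribute
#'   (tibble: column, mean, sd).
#' @export
scale_predictors <- function(table, predictors = intersect(lexacq_predictors(),
                                                           names(table))) {
  scaling <- list()
  for (col in predictors) {
    x <- table[[col]]
    mu <- mean(x, na.rm = TRUE)
    sdv <- obs_sd(x)
    if (is.na(sdv) || sdv == 0)
      abort_config(paste0("predictor column '", col, "' is constant; cannot scale"))
    table[[col]] <- (x - mu) / sdv
    scaling[[col]] <- tibble::tibble(column = col, mean = mu, sd = sdv)
  }
  attr(table, "scaling") <- dplyr::bind_rows(scaling)
  table
}

#' Pairwise correlations and variance inflation factors
#'
#' Pearson correlations between all predictor pairs, and per-predictor VIFs
#' (`1 / (1 - R^2)` from regressing each predictor on all others, computed
#' via the inverse correlation matrix).
#'
#' @param table Complete (post-imputation) predictor tibble.
#' @param predictors Predictor columns to include.
#' @return List: `correlations` (matrix), `vif` (named vector).
#' @export
collinearity_diagnostics <- function(table,
                                     predictors = intersect(lexacq_predictors(),
                                                            names(table))) {
  x <- as.matrix(table[, predictors])
  if (anyNA(x)) abort_config("predictor table must be complete (impute first)")
  if (nrow(x) < length(predictors) + 1)
    abort_config("need at least one more item than predictors")
  r <- cor(x)
  inv <- tryCatch(solve(r), error = function(e)
    abort_config("singular predictor design; VIF undefined"))
  list(correlations = r, vif = setNames(diag(inv), predictors))
}

#' Build the per-language predictor table from corpus, norms and mappings
#'
#' Runs the full extraction: unigram, solo and final counts (variant
#' collapsing, polysemy splitting, adult-speech filter), Laplace-smoothed
#' per-million log frequencies, residualization of frequency out of solo and
#' final, MLU-w with the minimum-occurrence missingness rule, phoneme counts,
#' and a join of the rating norms and lexical categories; finally z-scores
#' all numeric predictors within the language.
#'
#' @inheritParams count_unigrams
#' @param norms Tibble (item_id, concreteness, valence, arousal, babiness),
#'   possibly with missing cells.
#' @param transcriptions Tibble (item_id, phonemes).
#' @param item_table Tibble (item_id, lexical_category).
#' @param min_occurrences MLU-w occurrence threshold.
#' @param scale Whether to z-score the predictors (default TRUE).
#' @return Predictor tibble (item_id, lexical_category, 9 predictor columns)
#'   with a `"metadata"` attribute: corpus token total, unmapped token count,
#'   normalization base, and scaling means/SDs.
#' @export
build_predictor_table <- function(corpus, forms, norms, transcriptions,
                                  item_table,
                                  inflection_map = NULL, polysemy_map = NULL,
                                  speaker_filter = "adult",
                                  min_occurrences = 10, scale = TRUE) {
  uni <- count_unigrams(corpus, forms, inflection_map, polysemy_map, speaker_filter)
  total <- uni$total_tokens
  freq <- log_normalized_frequency(uni$counts$count, total)
  sf <- solo_and_final_counts(corpus, forms, inflection_map, polysemy_map,
                              speaker_filter)
  solo_log <- log_normalized_frequency(sf$solo$count, total)
  final_log <- log_normalized_frequency(sf$final$count, total)
  mlu <- compute_mlu_w(corpus, forms, inflection_map, polysemy_map,
                       speaker_filter, min_occurrences)
  nph <- count_phonemes(transcriptions)

  tab <- tibble::tibble(item_id = uni$counts$item_id,
                        frequency = freq,
                        solo_frequency = residualize(solo_log, freq),
                        final_frequency = residualize(final_log, freq))
  tab <- dplyr::left_join(tab, mlu[, c("item_id", "mlu_w")], by = "item_id")
  tab <- dplyr::left_join(tab, nph, by = "item_id")
  tab <- dplyr::left_join(tab, norms, by = "item_id")
  tab <- dplyr::left_join(tab, item_table[, c("item_id", "lexical_category")],
                          by = "item_id")
  if (anyNA(tab$n_phonemes)) abort_config("missing phonemic transcription")
  if (anyNA(tab$lexical_category)) abort_config("item without lexical category")
  scaling <- NULL
  if (scale) {
    tab <- scale_predictors(tab)
    scaling <- attr(tab, "scaling")
  }
  attr(tab, "metadata") <- list(
    corpus_total_tokens = total,
    unmapped_tokens = uni$unmapped_tokens,
    normalization_base = 1e6,
    min_occurrences = min_occurrences,
    speaker_filter = speaker_filter,
    scaling = scaling
  )
  tab
}
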