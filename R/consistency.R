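# Cross-language consistency of coefficient profiles: pairwise correlations
# of per-language coefficient vectors, a shuffled bootstrap null baseline,
# agglomerative clustering of languages, and per-lexical-category
# consistency.

# Coerce input (matrix languages x predictors, or named list of equally-named
# vectors) to a validated matrix.
as_coef_matrix <- function(coefficient_vectors) {
  if (is.list(coefficient_vectors) && !is.data.frame(coefficient_vectors)) {
    nm <- lapply(coefficient_vectors, names)
    if (length(unique(nm)) != 1)
      abort_config("coefficient vectors must share an identical ordered predictor set")
    m <- do.call(rbind, coefficient_vectors)
  } else {
    m <- as.matrix(coefficient_vectors)
  }
  if (nrow(m) < 2) abort_config("need at least 2 languages")
  if (ncol(m) < 2) abort_config("coefficient vectors need length >= 2")
  if (anyNA(m)) abort_config("coefficient vectors contain missing values")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    abort_config(paste0("constant coefficient vector for '",
                        rownames(m)[which(sds == 0)[1]],
                        "': correlation undefined"))
  m
}

per_language_mean_r <- function(r) {
  n <- nrow(r)
  (rowSums(r) - 1) / (n - 1)  # exclude the unit self-correlation
}

#' Pairwise correlations of per-language coefficient vectors
#'
#' @param coefficient_vectors Matrix (languages x predictors) or named list
#'   of identically-named coefficient vectors (typically the main-effect
#'   estimates).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `pairwise_r` (symmetric correlation matrix with unit
#'   diagonal), `per_language_mean_r` (each language's mean correlation with
#'   all others), `overall_mean_r`.
#' @export
pairwise_correlations <- function(coefficient_vectors, method = "pearson") {
  m <- as_coef_matrix(coefficient_vectors)
  r <- cor(t(m), method = method)
  means <- per_language_mean_r(r)
  list(pairwise_r = r,
       per_language_mean_r = setNames(means, rownames(m)),
       overall_mean_r = mean(means))
}

#' Shuffled bootstrap baseline for cross-language consistency
#'
#' Null distribution of the per-language mean pairwise correlation obtained
#' by independently permuting each language's coefficient vector (a uniform
#' random permutation per language, redrawn each replicate) and recomputing
#' the correlations. The 95% percentile interval of this distribution is the
#' chance band against which observed consistency is judged.
#'
#' @inheritParams pairwise_correlations
#' @param n_bootstrap Number of replicates (default 1000; below 100 a
#'   warning is recorded in the result).
#' @param seed Integer seed.
#' @return List: `observed` (per-language mean r), `baseline_ci` (tibble
#'   language, ci_low, ci_high), `overall_observed`, `overall_ci`,
#'   `n_bootstrap`, `seed`, `warnings`.
#' @export
shuffled_baseline <- function(coefficient_vectors, n_bootstrap = 1000,
                              seed = 1, method = "pearson") {
  m <- as_coef_matrix(coefficient_vectors)
  warnings <- character()
  if (n_bootstrap < 100)
    warnings <- c(warnings, "n_bootstrap < 100: baseline CI will be unstable")
  obs <- pairwise_correlations(m, method)
  n_lang <- nrow(m); p <- ncol(m)
  boot <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      shuffled <- m
      for (i in seq_len(n_lang)) shuffled[i, ] <- m[i, sample.int(p)]
      r <- cor(t(shuffled), method = method)
      mr <- per_language_mean_r(r)
      c(mr, mean(mr))
    }, numeric(n_lang + 1))
  })
  ci <- t(apply(boot, 1, quantile, probs = c(0.025, 0.975)))
  list(
    observed = obs$per_language_mean_r,
    baseline_ci = tibble::tibble(language = rownames(m),
                                 observed_mean_r = unname(obs$per_language_mean_r),
                                 ci_low = ci[seq_len(n_lang), 1],
                                 ci_high = ci[seq_len(n_lang), 2]),
    overall_observed = obs$overall_mean_r,
    overall_ci = c(ci_low = unname(ci[n_lang + 1, 1]),
                   ci_high = unname(ci[n_lang + 1, 2])),
    n_bootstrap = n_bootstrap,
    seed = seed,
    warnings = warnings
  )
}

#' Hierarchically cluster languages by coefficient similarity
#'
#' Agglomerative clustering on the distance `1 - r` between languages'
#' coefficient profiles.
#'
#' @param pairwise_r Symmetric correlation matrix with unit diagonal (e.g.
#'   from [pairwise_correlations()]).
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return List: `hclust`, `phylo` (an [ape] tree), `newick` (serialized
#'   tree, branch lengths from merge heights).
#' @export
cluster_languages <- function(pairwise_r, linkage = "complete") {
  r <- as.matrix(pairwise_r)
  if (!isSymmetric(unname(r), tol = 1e-8))
    abort_config("`pairwise_r` must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-8))
    abort_config("`pairwise_r` must have unit diagonal")
  h <- hclust(as.dist(1 - r), method = linkage)
  phy <- ape::as.phylo(h)
  list(hclust = h, phylo = phy, newick = ape::write.tree(phy))
}

#' Per-lexical-category cross-language consistency
#'
#' Applies the pairwise-correlation machinery within each lexical category's
#' combined effect vectors (see [compose_category_effects()]).
#'
#' @param category_effects Tibble (language, predictor, category, effect),
#'   typically row-bound [compose_category_effects()] output across
#'   languages.
#' @param method Correlation method.
#' @return Tibble (category, mean_r, n_languages).
#' @export
category_consistency <- function(category_effects, method = "pearson") {
  if (length(unique(category_effects$language)) < 2)
    abort_config("need at least 2 languages")
  out <- list()
  for (cat in unique(category_effects$category)) {
    sub <- category_effects[category_effects$category == cat, , drop = FALSE]
    wide <- tidyr::pivot_wider(sub[, c("language", "predictor", "effect")],
                               names_from = "predictor",
                               values_from = "effect")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$language
    pc <- pairwise_correlations(m, method)
    out[[cat]] <- tibble::tibble(category = cat,
                                 mean_r = pc$overall_mean_r,
                                 n_languages = nrow(m))
  }
  dplyr::bind_rows(out)
}
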