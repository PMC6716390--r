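# Iterative regression imputation of missing predictor values within a
# language: missing cells are first filled with draws (with replacement) from
# each column's observed values, then repeatedly re-predicted from a linear
# regression of that column on all other predictors until the imputed cells
# stabilize.

#' Impute missing predictor values by iterative regression
#'
#' Initialization is stochastic (seeded resampling of observed values); the
#' subsequent sweeps are deterministic point imputations: for each predictor
#' in declared order, a linear regression of that predictor on all others is
#' fit on the rows where it was originally observed (using current working
#' values of the other predictors) and its missing cells are replaced by the
#' fitted predictions. Observed cells are never modified.
#'
#' @param table Predictor tibble (e.g. from [build_predictor_table()]).
#' @param predictors Columns participating in the imputation, in sweep order.
#' @param seed Integer seed for the initialization draws.
#' @param max_iterations Sweep cap.
#' @param tolerance Convergence threshold on the maximum absolute change of
#'   any imputed cell between consecutive sweeps.
#' @return A list: `table` (completed), `report` (iterations, final max
#'   change, converged flag, per-column imputed counts, sweep order).
#' @export
impute_predictors <- function(table,
                              predictors = intersect(lexacq_predictors(),
                                                     names(table)),
                              seed = 1, max_iterations = 20,
                              tolerance = 1e-6) {
  x <- as.data.frame(table[, predictors])
  miss <- is.na(x)
  n_missing <- colSums(miss)
  if (any(n_missing == nrow(x)))
    abort_config(paste0("column '", predictors[which(n_missing == nrow(x))[1]],
                        "' has no observed values"))
  if (any(nrow(x) - n_missing < 2))
    abort_config("every column needs at least 2 observed values")
  if (nrow(x) < length(predictors) + 2)
    abort_config("need at least predictors + 2 rows")

  report <- list(iterations = 0L, final_max_change = 0,
                 converged = TRUE,
                 imputed_counts = setNames(as.integer(n_missing), predictors),
                 sweep_order = predictors)
  if (!any(miss)) {
    return(list(table = table, report = report))
  }

  with_seed(seed, {
    for (j in seq_along(predictors)) {
      if (n_missing[j] > 0) {
        obs <- x[[j]][!miss[, j]]
        x[[j]][miss[, j]] <- sample(obs, n_missing[j], replace = TRUE)
      }
    }
  })

  it <- 0L
  max_change <- Inf
  while (it < max_iterations && max_change >= tolerance) {
    it <- it + 1L
    max_change <- 0
    for (j in seq_along(predictors)) {
      if (n_missing[j] == 0) next
      others <- as.matrix(x[, -j, drop = FALSE])
      design <- cbind(1, others)
      if (qr(design[!miss[, j], , drop = FALSE])$rank < ncol(design))
        abort_config(paste0("singular regression when imputing '",
                            predictors[j], "'"))
      fit <- lm.fit(design[!miss[, j], , drop = FALSE], x[[j]][!miss[, j]])
      pred <- as.numeric(design[miss[, j], , drop = FALSE] %*% fit$coefficients)
      max_change <- max(max_change, max(abs(pred - x[[j]][miss[, j]])))
      x[[j]][miss[, j]] <- pred
    }
  }
  report$iterations <- it
  report$final_max_change <- max_change
  report$converged <- max_change < tolerance
  for (col in predictors) table[[col]] <- x[[col]]
  list(table = table, report = report)
}
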