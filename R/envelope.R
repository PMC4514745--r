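#' Fit a bioclimatic envelope model
#'
#' The per-species classifier is a bagged ensemble of classification trees
#' with per-split random feature subsetting (the random-forest construction,
#' via the randomForest package), grown to at least 500 trees with library
#' defaults otherwise. Per-point out-of-bag (OOB) presence-vote fractions
#' are retained for evaluation; the fit is reproducible under a fixed seed.
#'
#' @param train a [assemble_training] `training_set` with both classes
#'   present (>= 2 points each).
#' @param n_trees number of trees (>= 500 by default; smaller values are
#'   refused).
#' @param seed integer seed.
#' @return object of class `envelope_model`: fields `species_id`, `rf` (the
#'   fitted ensemble), `layer_names`, `category_registry` (factor levels per
#'   categorical feature), `n_trees`, `seed`, `oob_votes` (per-point OOB
#'   presence fraction, NA for points never out of bag).
#' @export
fit_envelope <- function(train, n_trees = 500, seed = 1) {
  stopifnot(inherits(train, "training_set"))
  tab <- table(train$label)
  if (any(tab == 0))
    stop(sprintf("fit_envelope('%s'): training set has a single class",
                 train$species_id))
  if (any(tab < 2))
    stop(sprintf("fit_envelope('%s'): each class needs at least 2 points",
                 train$species_id))
  if (n_trees < 500)
    stop("n_trees must be at least 500")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = train$features, y = train$label, ntree = n_trees,
    importance = TRUE, keep.forest = TRUE)
  votes <- rf$votes[, "presence"]
  votes[!is.finite(votes)] <- NA          # points never out of bag
  cat_cols <- Filter(is.factor, train$features)
  registry <- lapply(cat_cols, levels)
  fallback <- lapply(cat_cols, function(f) names(which.max(table(f))))
  structure(list(species_id = train$species_id, rf = rf,
                 layer_names = colnames(train$features),
                 category_registry = registry,
                 category_fallback = fallback,
                 n_trees = n_trees, seed = seed,
                 oob_votes = unname(votes)),
            class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf("<envelope_model> %s: %d trees on %d covariates\n",
              x$species_id, x$n_trees, length(x$layer_names)))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney form, ties split)
#'
#' @param scores numeric scores (higher = more presence-like).
#' @param labels logical or 0/1 vector, TRUE/1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)                        # average ranks split ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-bag model evaluation
#'
#' AUC is computed from the OOB presence-vote fractions against the class
#' labels (rank statistic, ties split); class-wise correct fractions use the
#' symmetric decision rule `vote >= threshold` for presence. Overall
#' accuracy is the pooled correct fraction, which equals the class-weighted
#' mean of the two class-wise fractions. (Published evaluation tables in
#' this literature sometimes label the presence-correct fraction
#' "specificity" and the absence-correct fraction "sensitivity" — the
#' reverse of standard usage — so neutral names are used here.) Points that
#' were never out of bag have undefined votes and are excluded with a
#' reported count.
#'
#' @param model an [fit_envelope] `envelope_model`.
#' @param train the `training_set` the model was fitted on.
#' @param threshold presence decision threshold on the vote fraction.
#' @return object of class `model_evaluation`: one-row data.frame with
#'   columns `species_id`, `n_presence`, `n_absence`, `auc`,
#'   `frac_presence_correct`, `frac_absence_correct`, `overall_accuracy`
#'   (percents in `[0, 100]`), `threshold`.
#' @export
evaluate_oob <- function(model, train, threshold = 0.5) {
  votes <- model$oob_votes
  labels <- train$label
  ok <- !is.na(votes)
  if (any(!ok))
    message(sprintf("evaluate_oob('%s'): excluded %d point(s) never out of bag",
                    model$species_id, sum(!ok)))
  votes <- votes[ok]; labels <- labels[ok]
  is_pres <- labels == "presence"
  pred_pres <- votes >= threshold
  fp <- 100 * mean(pred_pres[is_pres])
  fa <- 100 * mean(!pred_pres[!is_pres])
  acc <- 100 * mean(pred_pres == is_pres)
  out <- data.frame(
    species_id = model$species_id,
    n_presence = sum(is_pres), n_absence = sum(!is_pres),
    auc = auc_rank(votes, is_pres),
    frac_presence_correct = fp, frac_absence_correct = fa,
    overall_accuracy = acc, threshold = threshold,
    stringsAsFactors = FALSE)
  class(out) <- c("model_evaluation", class(out))
  out
}

#' Permutation importance ranking of model covariates
#'
#' Layers ordered by permutation importance on the out-of-bag points (mean
#' decrease in accuracy when the layer is permuted), descending; ties broken
#' by layer name. Permutation importance is preferred over split-impurity
#' importance because impurity measures inflate covariates with many
#' categories.
#'
#' @param model an `envelope_model` (or the regression analogue from
#'   [rank_composite_drivers]).
#' @return data.frame with columns `layer`, `importance`, ordered.
#' @export
rank_importance <- function(model) {
  imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp))
  data.frame(layer = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Write a per-species evaluation table
#'
#' One row per species: class sizes, AUC, class-wise correct fractions and
#' overall accuracy.
#'
#' @param evaluations list of `model_evaluation` rows.
#' @param path output CSV.
#' @export
write_evaluation_table <- function(evaluations, path) {
  tab <- do.call(rbind, lapply(evaluations, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
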