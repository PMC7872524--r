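# The supersig model object: a supervised mutational signature. Fitting
# runs the full pipeline (ContextMatters feature engineering inside an
# inner 5x3 CV, AUC ranking, n* selection) and then represents the
# signature by (1) the exposed-minus-unexposed difference in mean counts
# (age) or rates (all other exposures) per predictive feature, and (2) the
# logistic regression coefficients used for prediction.

#' Fit a supervised mutational signature (SuperSig)
#'
#' @param profiles A \code{"mut_profiles"} cohort (already filtered, see
#'   [filter_samples()]).
#' @param labels Binary exposure labels (\code{"exposed"}/\code{"unexposed"},
#'   logical or 0/1), aligned to the samples; alternatively a
#'   \code{"group_assignment"} from [assign_exposure_groups()] (samples
#'   labelled \code{"excluded"} are dropped).
#' @param factor Name of the etiological factor (e.g. \code{"age"},
#'   \code{"smoking"}). Determines the default measure: counts for age,
#'   rates (counts/age) otherwise.
#' @param measure Override of the count/rate choice.
#' @param bg Background frequencies for the enrichment nulls.
#' @param iters,folds Inner selection CV shape (default 5 x 3).
#' @param seed Integer seed (folds and bootstraps).
#' @param n_boot,alpha,divisor,eval,max_features Passed to
#'   [rank_candidates_cv()].
#' @param auc_min Median-AUC discard threshold (default 0.6).
#' @return An object of class \code{"supersig"} with components
#'   \code{factor}, \code{tissue}, \code{measure}, \code{features} (named
#'   list of context index blocks), \code{mean_diff}, \code{beta}
#'   (intercept first), \code{auc_apparent}, \code{selection}, and
#'   \code{meta}. If no feature survives selection the object has zero
#'   features and predicts a constant probability.
#' @seealso [predict.supersig()], [cross_validated_auc()]
#' @export
supersig <- function(profiles, labels, factor = "exposure", measure = NULL,
                     bg = background_frequencies("exome"),
                     iters = 5, folds = 3, seed = 1L, n_boot = 100,
                     alpha = 0.05, divisor = 150, eval = "holdout",
                     max_features = 15, auc_min = 0.6) {
  if (inherits(labels, "group_assignment")) {
    keep <- labels$labels != "excluded"
    profiles <- profiles[keep]
    factor <- labels$factor
    labels <- labels$labels[keep]
  }
  if (is.null(measure)) measure <- if (identical(factor, "age")) "count" else "rate"
  y <- as_binary(labels)
  sel <- rank_candidates_cv(profiles, y, measure = measure, bg = bg,
                            iters = iters, folds = folds, seed = seed,
                            n_boot = n_boot, eval = eval,
                            max_features = max_features,
                            alpha = alpha, divisor = divisor)
  feats <- select_predictive_features(sel, auc_min = auc_min)
  fit <- fit_supersig(profiles, y, sel$partition[feats], measure = measure)
  fit$factor <- factor
  fit$tissue <- if (!is.null(profiles$meta$tissue)) unique(profiles$meta$tissue)[1] else NA
  fit$selection <- sel
  fit$meta$seed <- seed
  fit$meta$n <- n_samples(profiles)
  fit$meta$date <- format(Sys.Date())
  fit
}

#' Fit the signature representation for a fixed feature set
#'
#' Computes the exposed-minus-unexposed mean difference (counts for age,
#' rates otherwise) and the logistic regression coefficients for the given
#' features. Perfect separation falls back to a weak ridge penalty
#' (lambda = 1e-4 on the slopes), flagged in \code{meta$ridge}.
#'
#' @param profiles A \code{"mut_profiles"} object.
#' @param labels Binary labels.
#' @param features Named list of context-index blocks (e.g. a subset of a
#'   \code{"mut_partition"}), possibly empty.
#' @param measure \code{"count"} or \code{"rate"}.
#' @return A \code{"supersig"} object (without selection diagnostics).
#' @export
fit_supersig <- function(profiles, labels, features, measure = c("rate", "count")) {
  measure <- match.arg(measure)
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  features <- as.list(features)
  obj <- structure(list(factor = NA_character_, tissue = NA_character_,
                        measure = measure, features = features,
                        mean_diff = numeric(0),
                        beta = c("(Intercept)" = stats::qlogis(mean(y))),
                        auc_apparent = NA_real_,
                        meta = list(ridge = NA_real_)),
                   class = "supersig")
  if (!length(features)) return(obj)
  X <- feature_values(profiles, features, measure)
  obj$mean_diff <- colMeans(X[y == 1, , drop = FALSE]) -
    colMeans(X[y == 0, , drop = FALSE])
  beta <- fit_logistic_safe(X, y)
  obj$beta <- beta
  obj$meta$ridge <- if (is.null(attr(beta, "ridge"))) NA_real_ else attr(beta, "ridge")
  obj$auc_apparent <- compute_auc(stats::plogis(drop(cbind(1, X) %*% beta)), y)
  obj
}

# Feature-value matrix for a plain named list of blocks.
feature_values <- function(profiles, features, measure) {
  counts <- if (inherits(profiles, "mut_profiles")) profiles$counts else profiles
  X <- vapply(features, function(ix) rowSums(counts[, ix, drop = FALSE]),
              numeric(nrow(counts)))
  X <- matrix(X, nrow = nrow(counts), dimnames = list(rownames(counts), names(features)))
  if (measure == "rate") {
    age <- profiles$meta$age
    if (is.null(age) || anyNA(age)) stop("rate measure requires ages for all samples")
    X <- X / age
  }
  X
}

#' @export
print.supersig <- function(x, ...) {
  cat("SuperSig", if (!is.na(x$factor)) paste0("for '", x$factor, "'"),
      if (!is.na(x$tissue)) paste0("(tissue ", x$tissue, ")"), "\n")
  cat("  measure:", x$measure, "| features:", length(x$features), "\n")
  if (length(x$features)) {
    for (nm in names(x$features)) {
      cat(sprintf("  %-28s mean diff %+.4g  beta %+.4g\n", nm,
                  x$mean_diff[[nm]], x$beta[[nm]]))
    }
    cat(sprintf("  apparent AUC: %.3f\n", x$auc_apparent))
  } else {
    cat("  no predictive features survived selection (signature not found)\n")
  }
  invisible(x)
}

#' @export
summary.supersig <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("\nSelection diagnostics:\n")
    print(object$selection)
  }
  invisible(object)
}

#' @export
coef.supersig <- function(object, ...) object$beta

#' Predict exposure probability from a SuperSig
#'
#' Applies the fitted logistic model: p = logistic(intercept + beta' x)
#' with x the sample's feature values in the signature's measure (counts,
#' or counts/age for rate signatures).
#'
#' @param object A \code{"supersig"}.
#' @param newdata A \code{"mut_profiles"} object.
#' @param ... Unused.
#' @return Named vector of exposure probabilities.
#' @export
predict.supersig <- function(object, newdata, ...) {
  if (!length(object$features)) {
    p <- rep(stats::plogis(object$beta[["(Intercept)"]]), n_samples(newdata))
    return(stats::setNames(p, newdata$meta$sample_id))
  }
  if (object$measure == "rate" &&
      (is.null(newdata$meta$age) || anyNA(newdata$meta$age)))
    stop("missing covariate: rate signatures require age for every sample")
  X <- feature_values(newdata, object$features, object$measure)
  stats::setNames(stats::plogis(drop(cbind(1, X) %*% object$beta)),
                  newdata$meta$sample_id)
}

#' Bar plot of a SuperSig's mean-difference weights
#'
#' @param x A \code{"supersig"}.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.supersig <- function(x, ...) {
  if (!length(x$features)) {
    warning("empty signature; nothing to plot")
    return(invisible(x))
  }
  graphics::barplot(x$mean_diff, names.arg = names(x$features), las = 2,
                    ylab = paste("mean", x$measure, "difference (exposed - unexposed)"),
                    ...)
  invisible(x)
}

#' Serialize / load a SuperSig
#'
#' JSON carries the full object; the companion two-column TSV
#' (feature, mean_diff) is convenient for plotting.
#'
#' @param sig A \code{"supersig"}.
#' @param path Output path (\code{.json}); \code{write_supersig_tsv} writes
#'   the TSV form.
#' @return \code{path}, invisibly; \code{read_supersig} returns the object.
#' @export
write_supersig <- function(sig, path) {
  ctx <- sbs96_contexts()
  obj <- list(factor = sig$factor, tissue = sig$tissue, measure = sig$measure,
              features = lapply(sig$features, function(ix) ctx[ix]),
              mean_diff = as.list(sig$mean_diff),
              beta = as.list(sig$beta),
              auc_apparent = sig$auc_apparent,
              meta = sig$meta[c("ridge", "seed", "n")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_supersig
#' @export
read_supersig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctx <- sbs96_contexts()
  structure(list(factor = obj$factor, tissue = obj$tissue, measure = obj$measure,
                 features = lapply(obj$features, function(nm) match(nm, ctx)),
                 mean_diff = unlist(obj$mean_diff),
                 beta = unlist(obj$beta),
                 auc_apparent = obj$auc_apparent,
                 meta = as.list(obj$meta)),
            class = "supersig")
}

#' @rdname write_supersig
#' @export
write_supersig_tsv <- function(sig, path) {
  df <- data.frame(feature = names(sig$features),
                   mean_diff = unname(sig$mean_diff))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validated AUC of the full supervised pipeline
#'
#' Five iterations of fivefold cross-validation: the entire pipeline
#' (ContextMatters feature engineering, AUC-based selection, logistic fit)
#' is re-run inside each training fold, held-out samples are scored, and
#' each iteration's AUC is computed from its pooled held-out predictions.
#' The mean over the iterations is reported. \code{apparent = TRUE}
#' instead trains and evaluates on the full data.
#'
#' @inheritParams supersig
#' @param iters,folds Outer CV shape (default 5 x 5).
#' @param inner_iters,inner_folds Inner selection CV shape (default 5 x 3).
#' @param apparent If \code{TRUE}, return the apparent AUC instead.
#' @return List with \code{mean_auc}, \code{iteration_auc} (length
#'   \code{iters}), and \code{seed}.
#' @export
cross_validated_auc <- function(profiles, labels, factor = "exposure",
                                measure = NULL,
                                bg = background_frequencies("exome"),
                                iters = 5, folds = 5,
                                inner_iters = 5, inner_folds = 3,
                                seed = 1L, n_boot = 100, alpha = 0.05,
                                divisor = 150, auc_min = 0.6,
                                max_features = 15, apparent = FALSE) {
  if (is.null(measure)) measure <- if (identical(factor, "age")) "count" else "rate"
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (apparent) {
    fit <- supersig(profiles, y, factor = factor, measure = measure, bg = bg,
                    iters = inner_iters, folds = inner_folds, seed = seed,
                    n_boot = n_boot, alpha = alpha, divisor = divisor,
                    auc_min = auc_min, max_features = max_features)
    return(list(mean_auc = fit$auc_apparent, iteration_auc = fit$auc_apparent,
                seed = seed, fit = fit))
  }
  n_min <- min(table(y))
  if (n_min < 2) stop("class too small for cross-validation")
  if (n_min < folds) {
    warning("smallest class (", n_min, ") smaller than ", folds,
            " folds; reducing folds")
    folds <- n_min
  }
  n <- n_samples(profiles)
  it_auc <- numeric(iters)
  set.seed(seed)
  for (it in seq_len(iters)) {
    assign_f <- stratified_folds(y, folds)
    pred <- numeric(n)
    for (k in seq_len(folds)) {
      test <- which(assign_f == k)
      train <- setdiff(seq_len(n), test)
      fit <- supersig(profiles[train], y[train], factor = factor,
                      measure = measure, bg = bg,
                      iters = inner_iters, folds = inner_folds,
                      seed = child_seed(seed, it * 100L + k),
                      n_boot = n_boot, alpha = alpha, divisor = divisor,
                      auc_min = auc_min, max_features = max_features)
      pred[test] <- predict(fit, profiles[test])
    }
    it_auc[it] <- compute_auc(pred, y)
  }
  list(mean_auc = mean(it_auc), iteration_auc = it_auc, seed = seed)
}
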