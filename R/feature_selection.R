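# FeaturesSelection: inner 5 x 3-fold cross-validation. Each training fold
# runs ContextMatters (separately on exposed and unexposed samples for
# every factor other than age, then combining the two partitions); the 15
# fold partitions are combined into their minimal refinement, every final
# candidate is scored by AUC in every fold, and the fold-optimal top-n
# sizes give n* (their median).

#' Rank candidate features by cross-validated AUC
#'
#' @param profiles A \code{"mut_profiles"} object.
#' @param labels Binary exposure labels aligned to the samples
#'   (\code{"exposed"}/\code{"unexposed"}, logical, or 0/1).
#' @param measure \code{"count"} for the age factor, \code{"rate"}
#'   (counts/age) for every other exposure.
#' @param bg Background frequencies used by ContextMatters.
#' @param iters,folds Inner cross-validation shape (default 5 iterations of
#'   3 folds).
#' @param seed Integer seed governing fold assignment and the pseudo-count
#'   bootstraps.
#' @param n_boot Bootstrap resamples inside ContextMatters.
#' @param eval Where per-feature AUC and the top-n search are evaluated:
#'   the fold's held-out third (\code{"holdout"}, default; avoids
#'   optimistic ranking) or the training two-thirds (\code{"train"}).
#' @param max_features Cap on the top-n search (default 15).
#' @param alpha,divisor Passed to [context_matters()].
#' @return A \code{"supersig_selection"} list: \code{partition} (combined
#'   candidate partition), \code{auc} (fold x block AUC matrix),
#'   \code{median_auc}, \code{best_n} (per-fold optimum), \code{n_star},
#'   and bookkeeping (seed, measure, fold count).
#' @export
rank_candidates_cv <- function(profiles, labels, measure = c("rate", "count"),
                               bg = background_frequencies("exome"),
                               iters = 5, folds = 3, seed = 1L, n_boot = 100,
                               eval = c("holdout", "train"), max_features = 15,
                               alpha = 0.05, divisor = 150) {
  measure <- match.arg(measure)
  eval <- match.arg(eval)
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- n_samples(profiles)
  stopifnot(length(y) == n)

  set.seed(seed)
  fold_parts <- list()
  fold_train <- list()
  fold_test <- list()
  fid <- 0L
  for (it in seq_len(iters)) {
    assign_f <- stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      fid <- fid + 1L
      test <- which(assign_f == k)
      train <- setdiff(seq_len(n), test)
      cm_seed <- child_seed(seed, fid)
      part <- tryCatch(
        fold_partition(profiles, y, train, measure, bg, n_boot, cm_seed,
                       alpha, divisor),
        error = function(e) NULL)
      if (is.null(part) || length(unique(y[test])) < 2 ||
          length(unique(y[train])) < 2) {
        warning("fold ", fid, " skipped (single-class fold)")
        next
      }
      fold_parts[[length(fold_parts) + 1L]] <- part
      fold_train[[length(fold_train) + 1L]] <- train
      fold_test[[length(fold_test) + 1L]] <- test
    }
  }
  if (!length(fold_parts)) stop("all folds skipped; cannot select features")

  combined <- Reduce(combine_partitions, fold_parts)
  X <- partition_values(profiles, combined, measure = measure)

  n_used <- length(fold_parts)
  auc_mat <- matrix(NA_real_, n_used, ncol(X),
                    dimnames = list(NULL, colnames(X)))
  best_n <- integer(n_used)
  for (i in seq_len(n_used)) {
    train <- fold_train[[i]]
    test <- fold_test[[i]]
    ev <- if (eval == "holdout") test else train
    auc_mat[i, ] <- apply(X[ev, , drop = FALSE], 2, compute_auc, labels = y[ev])
    ord <- order(auc_mat[i, ], decreasing = TRUE)
    K <- min(max_features, ncol(X))
    top_auc <- -Inf
    top_n <- 1L
    for (nn in seq_len(K)) {
      sel <- ord[seq_len(nn)]
      beta <- tryCatch(fit_logistic_safe(X[train, sel, drop = FALSE], y[train]),
                       error = function(e) NULL)
      if (is.null(beta)) next
      p <- stats::plogis(drop(cbind(1, X[ev, sel, drop = FALSE]) %*% beta))
      a <- compute_auc(p, y[ev])
      if (a > top_auc + 1e-12) {  # ties resolved toward smaller n (parsimony)
        top_auc <- a
        top_n <- nn
      }
    }
    best_n[i] <- top_n
  }

  structure(list(partition = combined,
                 auc = auc_mat,
                 median_auc = apply(auc_mat, 2, stats::median),
                 best_n = best_n,
                 n_star = lower_median(best_n),
                 n_folds = n_used,
                 measure = measure, seed = seed, eval = eval),
            class = "supersig_selection")
}

# One fold's candidate partition: ContextMatters per group (exposed and
# unexposed separately, combined) for rate factors; pooled for age/count.
fold_partition <- function(profiles, y, train, measure, bg, n_boot, cm_seed,
                           alpha, divisor) {
  counts <- profiles$counts
  if (measure == "count") {
    return(context_matters(counts[train, , drop = FALSE], bg, n_boot = n_boot,
                           seed = cm_seed, alpha = alpha, divisor = divisor))
  }
  tr_exp <- train[y[train] == 1]
  tr_un <- train[y[train] == 0]
  pE <- context_matters(counts[tr_exp, , drop = FALSE], bg, n_boot = n_boot,
                        seed = cm_seed, alpha = alpha, divisor = divisor)
  pU <- context_matters(counts[tr_un, , drop = FALSE], bg, n_boot = n_boot,
                        seed = cm_seed + 1L, alpha = alpha, divisor = divisor)
  combine_partitions(pE, pU)
}

#' @export
print.supersig_selection <- function(x, ...) {
  cat("Candidate selection over", x$n_folds, "folds\n")
  cat("  candidate blocks:", length(x$partition), "\n")
  cat("  n* =", x$n_star, "\n")
  top <- sort(x$median_auc, decreasing = TRUE)
  show <- utils::head(top, 5)
  for (nm in names(show)) cat(sprintf("  %-28s median AUC %.3f\n", nm, show[nm]))
  invisible(x)
}

#' Select the final predictive features
#'
#' Takes the top \code{n_star} candidates by median AUC (\code{n_star} =
#' median of the per-fold optimal top-n values) and discards any with
#' median AUC at or below \code{auc_min} (default 0.6). An empty result is
#' returned as a zero-length vector with attribute
#' \code{"signature_found" = FALSE}, not an error.
#'
#' @param sel A \code{"supersig_selection"} from [rank_candidates_cv()].
#' @param auc_min Discard threshold on the median AUC (features with
#'   median AUC <= \code{auc_min} are dropped).
#' @return Character vector of predictive block names, ordered by
#'   decreasing median AUC.
#' @export
select_predictive_features <- function(sel, auc_min = 0.6) {
  stopifnot(inherits(sel, "supersig_selection"))
  med <- sort(sel$median_auc, decreasing = TRUE)
  top <- utils::head(med, sel$n_star)
  keep <- names(top)[top > auc_min]
  structure(keep, signature_found = length(keep) > 0)
}
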