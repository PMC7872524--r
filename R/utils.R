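# Small numerical utilities shared across the fitting pipeline.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' P(score_exposed > score_unexposed) + 0.5 P(equal), via average ranks.
#'
#' @param scores Numeric scores, higher = more exposed-like.
#' @param labels Binary labels (logical, 0/1, or a factor whose second
#'   level is the positive class).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' compute_auc(c(3, 1, 2, 4), c(0, 0, 1, 1))  # 0.75
compute_auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  n1 <- as.numeric(n1)
  n0 <- as.numeric(n0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (is.character(labels)) {
    if (all(labels %in% c("exposed", "unexposed")))
      return(as.integer(labels == "exposed"))
    stop("character labels must be 'exposed'/'unexposed'")
  }
  y <- as.integer(as.logical(labels) | labels == 1)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  y
}

# Logistic regression (intercept + features) by IRLS, with a weak ridge
# penalty fallback when the MLE diverges (perfect separation). The penalty
# (lambda = 1e-4) is applied to the slopes only, never the intercept, so
# e^beta keeps its odds-ratio interpretation on the raw count/rate scale.
logistic_fit <- function(X, y, lambda = 0, max_iter = 50, tol = 1e-8) {
  X <- cbind("(Intercept)" = 1, as.matrix(X))
  p <- ncol(X)
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(pen, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)), error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  names(beta) <- colnames(X)
  beta
}

fit_logistic_safe <- function(X, y, ridge_lambda = 1e-4) {
  beta <- logistic_fit(X, y)
  diverged <- is.null(beta) || any(!is.finite(beta))
  if (!diverged) {
    # perfect separation: fitted probabilities saturate and the MLE is
    # unbounded even when the coefficients look finite
    p <- stats::plogis(drop(cbind(1, as.matrix(X)) %*% beta))
    diverged <- max(abs(beta[-1])) > 1e3 ||
      (all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6))
  }
  if (diverged) {
    beta <- logistic_fit(X, y, lambda = ridge_lambda)
    if (is.null(beta) || any(!is.finite(beta)))
      stop("logistic fit failed even with ridge penalty")
    attr(beta, "ridge") <- ridge_lambda
  }
  beta
}

# Stratified, seeded fold assignment; returns integer fold ids per sample.
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    ix <- ix[sample.int(length(ix))]
    id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

# Lower median: for an even number of values, the smaller middle value
# (keeps n* integral when CV folds are skipped).
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Derive a reproducible child seed (kept below 2^31).
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1000003) %% 2147483587) + 1L
}

#' Perturb binary labels by shuffling or partial mislabeling
#'
#' \code{mode = "shuffle"} randomly permutes all labels; \code{mode =
#' "mislabel"} flips exactly \code{round(fraction * n)} labels chosen
#' uniformly without replacement (the robustness sweep in the source
#' analyses uses fractions 0.05, 0.10, 0.20 and 0.25).
#'
#' @param labels Binary label vector.
#' @param mode \code{"shuffle"} or \code{"mislabel"}.
#' @param fraction Fraction of labels to flip (mislabel mode only).
#' @param seed Optional integer seed.
#' @return Perturbed labels, same type and length as the input.
#' @export
perturb_labels <- function(labels, mode = c("shuffle", "mislabel"),
                           fraction = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "shuffle") return(labels[sample.int(length(labels))])
  stopifnot(fraction >= 0, fraction <= 1)
  n_flip <- round(fraction * length(labels))
  if (n_flip == 0) return(labels)
  ix <- sample.int(length(labels), n_flip)
  y <- as_binary(labels)
  y[ix] <- 1L - y[ix]
  restore_labels(y, labels)
}

restore_labels <- function(y, template) {
  if (is.character(template)) return(ifelse(y == 1, "exposed", "unexposed"))
  if (is.logical(template)) return(y == 1)
  if (is.factor(template)) return(factor(levels(template)[y + 1], levels = levels(template)))
  y
}
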