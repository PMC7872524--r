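# Signature attribution: non-negative least squares refitting of sample
# profiles onto signature matrices, aging-rate and aging-proportion
# estimation, and mutational-landscape construction and distances.

#' Non-negative least squares
#'
#' Solves min ||y - A x||_2 subject to x >= 0 by the Lawson-Hanson
#' active-set algorithm (deterministic).
#'
#' @param A Matrix (m x k), e.g. 96 contexts by k signatures.
#' @param y Length-m response (a sample's 96-context counts).
#' @param tol Numerical tolerance on the dual feasibility check.
#' @return List with \code{x} (non-negative coefficients, named after
#'   \code{A}'s columns), \code{fitted}, and \code{residual_norm}.
#' @export
#' @examples
#' nnls_fit(matrix(c(1, 1), 2, 1), c(3, 5))$x  # 4
nnls_fit <- function(A, y, tol = 1e-10) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("dimension mismatch: nrow(A) != length(y)")
  k <- ncol(A)
  if (k < 1) stop("A must have at least one column")
  ls_solve <- function(P) {
    z <- numeric(k)
    z[P] <- tryCatch(
      drop(solve(crossprod(A[, P, drop = FALSE]),
                 crossprod(A[, P, drop = FALSE], y))),
      error = function(e) drop(qr.coef(qr(A[, P, drop = FALSE]), y)))
    z[is.na(z)] <- 0
    z
  }
  x <- numeric(k)
  passive <- rep(FALSE, k)
  w <- drop(crossprod(A, y - A %*% x))
  scale <- max(abs(w), 1)
  iter <- 0L
  max_iter <- 30L * (k + 1L)
  while (any(!passive & w > tol * scale) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- ls_solve(P)
      if (min(z[P]) > 0) {
        x <- z
        break
      }
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol * scale] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) {
        x <- numeric(k)
        break
      }
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x <- pmax(x, 0)
  names(x) <- colnames(A)
  fitted <- drop(A %*% x)
  list(x = x, fitted = fitted, residual_norm = sqrt(sum((y - fitted)^2)))
}

#' Read / write a signature matrix (96 labeled rows, one column per signature)
#'
#' Compatible with published catalog TSVs: the first column names the 96
#' contexts in any order; remaining columns are signatures.
#'
#' @param path TSV path.
#' @return 96 x k numeric matrix, rows in canonical order.
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- tab[[1]]
  A <- as.matrix(tab[, -1, drop = FALSE])
  rownames(A) <- rn
  miss <- setdiff(sbs96_contexts(), rn)
  if (length(miss)) stop("signature matrix missing context: ", miss[1])
  A[sbs96_contexts(), , drop = FALSE]
}

#' @rdname read_signature_matrix
#' @param A Matrix to write.
#' @export
write_signature_matrix <- function(A, path) {
  df <- data.frame(context = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature aging rates from an unexposed cohort
#'
#' The aging rate of feature i is mean(count of feature i) / mean(age)
#' over unexposed patients: the number of mutations of that feature
#' accumulating per year attributable to age.
#'
#' @param profiles A \code{"mut_profiles"} cohort of unexposed samples.
#' @param features Named list of context-index blocks (e.g. an age
#'   SuperSig's features); \code{NULL} uses the 96 individual contexts.
#' @return Named vector of per-year rates.
#' @export
aging_rates <- function(profiles, features = NULL) {
  if (n_samples(profiles) == 0) stop("empty cohort")
  age <- profiles$meta$age
  if (is.null(age) || anyNA(age) || mean(age) <= 0)
    stop("aging rates require positive ages for all samples")
  if (is.null(features)) {
    return(colMeans(profiles$counts) / mean(age))
  }
  X <- feature_values(profiles, features, measure = "count")
  colMeans(X) / mean(age)
}

#' Proportion of a sample's mutations attributable to aging
#'
#' For each sample: (sum of aging rates x age) / total mutations, capped
#' at 1. Samples with zero total mutations give NA with a warning.
#'
#' @param rates Per-feature aging rates from [aging_rates()].
#' @param profiles A \code{"mut_profiles"} object (any cohort).
#' @return Numeric vector in [0, 1] (or NA), named by sample.
#' @export
aging_proportion <- function(rates, profiles) {
  age <- profiles$meta$age
  if (is.null(age) || anyNA(age)) stop("aging proportion requires ages")
  total <- total_mutations(profiles)
  pred <- sum(rates) * age
  out <- pmin(1, pred / total)
  if (any(total == 0)) {
    warning(sum(total == 0), " sample(s) with zero mutations: proportion undefined")
    out[total == 0] <- NA_real_
  }
  stats::setNames(out, profiles$meta$sample_id)
}

#' Mutational landscape of a cohort
#'
#' The 96-long vector whose entry is the average count of that mutation
#' type in the cohort divided by the average age. Optionally discounts the
#' aging landscape entrywise (entries may then be negative; they are kept,
#' since the correlation distance is translation-insensitive).
#'
#' @param profiles A \code{"mut_profiles"} cohort (one tissue/exposure).
#' @param discount Optional \code{"mut_landscape"} (typically the aging
#'   landscape of the same tissue) to subtract.
#' @param cohort Optional label, e.g. \code{c(tissue, exposure)}.
#' @return A \code{"mut_landscape"}: list with \code{vector} (length 96),
#'   \code{cohort}, \code{n}.
#' @export
build_landscape <- function(profiles, discount = NULL, cohort = NULL) {
  if (n_samples(profiles) == 0) stop("empty cohort")
  age <- profiles$meta$age
  if (is.null(age) || anyNA(age)) stop("landscape requires ages for all samples")
  v <- colMeans(profiles$counts) / mean(age)
  if (!is.null(discount)) v <- v - discount$vector
  structure(list(vector = v, cohort = cohort, n = n_samples(profiles)),
            class = "mut_landscape")
}

#' @export
print.mut_landscape <- function(x, ...) {
  cat("Mutational landscape", if (!is.null(x$cohort)) paste0("(", paste(x$cohort, collapse = ", "), ")"),
      "- n =", x$n, "\n")
  cat(sprintf("  total mutations/year: %.3f\n", sum(x$vector)))
  invisible(x)
}

#' Distance between two mutational landscapes
#'
#' Default: 1 - Pearson correlation of the two 96-vectors (a true
#' dissimilarity in [0, 2]); \code{method = "cosine"} uses 1 - cosine
#' similarity, which yields equivalent results; \code{method =
#' "correlation"} returns the raw Pearson correlation for compatibility.
#'
#' @param a,b \code{"mut_landscape"} objects (or bare 96-vectors).
#' @param method \code{"pearson"} (default), \code{"cosine"},
#'   or \code{"correlation"}.
#' @return Scalar distance.
#' @export
landscape_distance <- function(a, b, method = c("pearson", "cosine", "correlation")) {
  method <- match.arg(method)
  va <- if (inherits(a, "mut_landscape")) a$vector else as.numeric(a)
  vb <- if (inherits(b, "mut_landscape")) b$vector else as.numeric(b)
  if (inherits(a, "mut_landscape")) stopifnot(length(va) == 96)
  stopifnot(length(va) == length(vb))
  if (method == "cosine") {
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
    return(1 - sum(va * vb) / (na * nb))
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined: zero-variance landscape")
  r <- stats::cor(va, vb)
  if (method == "correlation") r else 1 - r
}

#' Pairwise landscape distance matrix
#'
#' @param landscapes Named list of \code{"mut_landscape"} objects.
#' @param method Passed to [landscape_distance()].
#' @return Symmetric matrix with zero diagonal (what a clustering heatmap
#'   consumes).
#' @export
landscape_distance_matrix <- function(landscapes, method = "pearson") {
  k <- length(landscapes)
  D <- matrix(0, k, k, dimnames = list(names(landscapes), names(landscapes)))
  if (k < 2) return(D)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- landscape_distance(landscapes[[i]], landscapes[[j]],
                                               method = method)
    }
  }
  D
}

#' Score samples by the NNLS contribution of one signature
#'
#' The attribution-based alternative prediction mode: each sample's
#' 96-context counts are decomposed onto the columns of \code{A} by NNLS
#' and the contribution of \code{which} is returned as the score.
#'
#' @param profiles A \code{"mut_profiles"} object.
#' @param A Signature matrix (96 x k): relative frequencies for
#'   catalog/random signatures, mean count/rate differences for SuperSigs.
#' @param which Column index or name of the signature of interest.
#' @return Named numeric score vector.
#' @export
nnls_scores <- function(profiles, A, which = 1L) {
  apply_names <- profiles$meta$sample_id
  s <- apply(profiles$counts, 1, function(y) nnls_fit(A, y)$x[which])
  stats::setNames(as.numeric(s), apply_names)
}
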