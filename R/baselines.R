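# Comparison arms: randomly generated single-peak signatures, NMF by
# Lee-Seung multiplicative updates, BestNMF / MatchedNMF selection, and
# the partially supervised extension (age-discounted NMF contributions).

peak_classes <- function(kind) {
  if (kind == "smoking") {
    list(classes = SUBSTITUTIONS, peak = "C>A")
  } else {
    # aging: [C>T]G must be its own class (the prior-knowledge peak);
    # [C>T]H collects the remaining C>T contexts (H = not G)
    list(classes = c("[C>T]G", "[C>T]H", "C>A", "C>G", "T>A", "T>C", "T>G"),
         peak = "[C>T]G")
  }
}

class_members <- function(cls) {
  ctxs <- sbs96_contexts()
  if (cls == "[C>T]G") return(which(endsWith(ctxs, "[C>T]G")))
  if (cls == "[C>T]H") {
    return(which(grepl("[C>T]", ctxs, fixed = TRUE) & !endsWith(ctxs, "[C>T]G")))
  }
  which(grepl(paste0("[", cls, "]"), ctxs, fixed = TRUE))
}

#' Randomly generated single-peak signature
#'
#' A prior-knowledge baseline: a probability distribution over the 96
#' contexts whose only informative property is the known peak class
#' (C>A for smoking; [C>T]G for aging). Step 1 draws
#' \code{n_candidates} (default 30, about the size of the COSMIC v2
#' catalog) class distributions by sampling one uniform variate per class
#' and dividing by their sum, and keeps the one with the highest
#' proportion in the peak class. Step 2 randomly breaks down each class
#' mass uniformly (flat Dirichlet) across its constituent trinucleotides.
#'
#' @param kind \code{"smoking"} (6 classes, peak C>A) or \code{"aging"}
#'   (7 classes: [C>T]G, [C>T]H, C>A, C>G, T>A, T>C, T>G; peak [C>T]G).
#' @param n_candidates Number of candidate class distributions (default 30).
#' @param seed Optional integer seed.
#' @return A \code{"peak_signature"}: list with \code{distribution}
#'   (96-vector summing to 1), \code{class_distribution}, \code{kind},
#'   \code{seed}.
#' @export
random_single_peak <- function(kind = c("smoking", "aging"), n_candidates = 30,
                               seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_candidates >= 1)
  if (!is.null(seed)) set.seed(seed)
  info <- peak_classes(kind)
  k <- length(info$classes)
  cand <- matrix(stats::runif(n_candidates * k), n_candidates, k)
  cand <- cand / rowSums(cand)
  colnames(cand) <- info$classes
  best <- which.max(cand[, info$peak])
  class_dist <- cand[best, ]
  dist96 <- stats::setNames(numeric(96), sbs96_contexts())
  for (cls in info$classes) {
    members <- class_members(cls)
    # flat Dirichlet split of the class mass over its trinucleotides
    g <- stats::rgamma(length(members), shape = 1)
    dist96[members] <- class_dist[cls] * g / sum(g)
  }
  structure(list(distribution = dist96, class_distribution = class_dist,
                 kind = kind, seed = seed),
            class = "peak_signature")
}

#' @export
print.peak_signature <- function(x, ...) {
  cat("Random single-peak signature (", x$kind, ")\n", sep = "")
  print(round(x$class_distribution, 3))
  invisible(x)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee-Seung updates minimizing the Frobenius reconstruction error
#' ||M - W H||_F, with \code{n_restarts} seeded random initializations
#' (best kept). Columns of W are normalized to sum to 1, the scale
#' absorbed into H.
#'
#' @param M Non-negative matrix (96 contexts x n samples).
#' @param rank Factorization rank r >= 1.
#' @param seed Integer seed.
#' @param max_iter,tol Update iterations per restart and relative
#'   convergence tolerance on the objective.
#' @param n_restarts Random restarts (default 5).
#' @return An \code{"nmf_result"}: \code{W} (96 x r), \code{H} (r x n),
#'   \code{rank}, \code{error} (Frobenius), \code{seed}.
#' @export
nmf_decompose <- function(M, rank, seed = 1L, max_iter = 2000, tol = 1e-6,
                          n_restarts = 5) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be non-negative")
  if (all(M == 0)) stop("cannot factorize an all-zero matrix")
  stopifnot(rank >= 1)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(child_seed(seed, r))
    W <- matrix(stats::runif(nrow(M) * rank, 0.1, 1), nrow(M), rank)
    H <- matrix(stats::runif(rank * ncol(M), 0.1, 1), rank, ncol(M))
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, M) / (crossprod(W, W %*% H) + eps))
      W <- W * (M %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10 == 0) {
        obj <- sqrt(sum((M - W %*% H)^2))
        if (is.finite(obj_prev) && abs(obj_prev - obj) < tol * max(obj_prev, eps)) break
        obj_prev <- obj
      }
    }
    err <- sqrt(sum((M - W %*% H)^2))
    if (is.null(best) || err < best$error) {
      best <- list(W = W, H = H, error = err)
    }
  }
  # normalize W columns to sum 1, absorb scale into H
  s <- colSums(best$W)
  s[s == 0] <- 1
  W <- sweep(best$W, 2, s, "/")
  H <- best$H * s
  dimnames(W) <- list(rownames(M), paste0("S", seq_len(rank)))
  dimnames(H) <- list(paste0("S", seq_len(rank)), colnames(M))
  structure(list(W = W, H = H, rank = rank, error = best$error, seed = seed),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("NMF decomposition: rank", x$rank, "- Frobenius error", format(x$error, digits = 4), "\n")
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Optimal cosine-similarity pairing of two signature sets
#'
#' Finds the one-to-one assignment of candidate to reference signatures
#' maximizing the total cosine similarity (exact search with
#' branch-and-bound over permutations; not greedy). Used by MatchedNMF to
#' pair NMF components with catalog signatures.
#'
#' @param candidates,references Matrices with one signature per column;
#'   equal column counts (at most 9).
#' @return List with \code{pairing} (for each candidate column, the index
#'   of its reference), \code{total} (summed cosine similarity), and
#'   \code{similarity} (the full candidate x reference matrix).
#' @export
cosine_match <- function(candidates, references) {
  candidates <- as.matrix(candidates)
  references <- as.matrix(references)
  k <- ncol(candidates)
  if (k != ncol(references)) stop("signature sets must have equal size")
  if (k > 9) stop("exact assignment limited to 9 signatures")
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    S[i, j] <- cosine_sim(candidates[, i], references[, j])
  best_total <- -Inf
  best_perm <- seq_len(k)
  col_max <- apply(S, 2, max)
  assign_rec <- function(i, used, total, perm) {
    if (i > k) {
      if (total > best_total) {
        best_total <<- total
        best_perm <<- perm
      }
      return()
    }
    # bound: remaining candidates can at best add the unused columns' maxima
    if (total + sum(col_max[!used]) <= best_total) return()
    for (j in which(!used)) {
      used[j] <- TRUE
      perm[i] <- j
      assign_rec(i + 1L, used, total + S[i, j], perm)
      used[j] <- FALSE
    }
  }
  assign_rec(1L, rep(FALSE, k), 0, integer(k))
  list(pairing = best_perm, total = best_total, similarity = S)
}

#' BestNMF: pick the NMF component most predictive of an exposure
#'
#' Returns the index of the W column whose contribution row of H achieves
#' the highest AUC in classifying the exposure on the training samples.
#' Ties go to the lowest index; if no component beats AUC 0.55 a
#' \code{low_signal} flag is set.
#'
#' @param nmf An \code{"nmf_result"}.
#' @param labels Binary exposure labels for the samples (columns of H).
#' @return List with \code{index}, \code{auc} (per component), and
#'   \code{low_signal}.
#' @export
best_nmf_select <- function(nmf, labels) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  aucs <- apply(nmf$H, 1, compute_auc, labels = y)
  idx <- which.max(aucs)  # which.max takes the first (lowest) on ties
  list(index = unname(idx), auc = aucs, low_signal = max(aucs) < 0.55)
}

#' Partially supervised signature extraction
#'
#' Compares plain NMF against age-discounted NMF on cohorts where the
#' exposed samples have a higher average mutation rate per year than the
#' unexposed (required by NMF's non-negativity and linearity). Per
#' repeat: half of the unexposed samples are held out to learn per-context
#' aging rates; the test set is a bootstrap of the remaining samples; NMF
#' with rank 3 decomposes the test counts; each patient's age-predicted
#' vector (aging rates x age) is projected onto the NMF directions by NNLS
#' and subtracted from the contributions, negatives clamped to zero; for
#' both the discounted and undiscounted contributions the component whose
#' contribution divided by total mutations best classifies the exposure
#' (highest AUC) is selected. Partial signatures are recovered by
#' non-negative regression of Y on the known contributions. AUCs are
#' averaged over \code{repeats} (default 50).
#'
#' @param profiles A \code{"mut_profiles"} cohort.
#' @param labels Binary exposure labels.
#' @param rank NMF rank (default 3).
#' @param repeats Number of repeats (default 50).
#' @param seed Integer seed.
#' @param max_iter,tol,n_restarts NMF parameters for the repeats (defaults
#'   lighter than [nmf_decompose()]'s: 1000 iterations, 2 restarts).
#' @return List with \code{auc_partial}, \code{auc_unsup} (means over
#'   repeats), \code{per_repeat} (repeats x 2), and \code{partial_signatures}
#'   (96 x rank, from the last repeat).
#' @export
partially_supervised <- function(profiles, labels, rank = 3, repeats = 50,
                                 seed = 1L, max_iter = 1000, tol = 1e-5,
                                 n_restarts = 2) {
  y <- as_binary(labels)
  age <- profiles$meta$age
  if (is.null(age) || anyNA(age)) stop("ages required")
  rate <- total_mutations(profiles) / age
  if (mean(rate[y == 1]) <= mean(rate[y == 0])) {
    stop("dataset rejected: exposed samples must have a higher average ",
         "mutation rate per year than unexposed ones (NMF non-negativity premise)")
  }
  unexp <- which(y == 0)
  expd <- which(y == 1)
  res <- matrix(NA_real_, repeats, 2,
                dimnames = list(NULL, c("partial", "unsup")))
  A_partial <- NULL
  for (r in seq_len(repeats)) {
    set.seed(child_seed(seed, r))
    train_un <- sample(unexp, floor(length(unexp) / 2))
    rest <- c(setdiff(unexp, train_un), expd)
    rates <- aging_rates(profiles[train_un])
    boot <- sample(rest, length(rest), replace = TRUE)
    Yc <- t(profiles$counts[boot, , drop = FALSE])  # 96 x m
    yb <- y[boot]
    if (length(unique(yb)) < 2) next
    nm <- nmf_decompose(Yc, rank, seed = child_seed(seed, r + repeats),
                        max_iter = max_iter, tol = tol, n_restarts = n_restarts)
    tot <- pmax(colSums(Yc), 1)
    # undiscounted: standard unsupervised contributions
    scores_un <- sweep(nm$H, 2, tot, "/")
    res[r, "unsup"] <- max(apply(scores_un, 1, compute_auc, labels = yb))
    # discount the age prediction projected onto the NMF directions
    Hd <- nm$H
    for (j in seq_len(ncol(Yc))) {
      v_age <- rates * age[boot[j]]
      proj <- nnls_fit(nm$W, v_age)$x
      Hd[, j] <- Hd[, j] - proj
    }
    Hd[Hd < 0] <- 0  # negative discounted contributions set to zero
    scores_d <- sweep(Hd, 2, tot, "/")
    res[r, "partial"] <- max(apply(scores_d, 1, compute_auc, labels = yb))
    # recover partial signatures: Y = A X with X known, A unknown, A >= 0
    A_partial <- t(apply(Yc, 1, function(row) nnls_fit(t(Hd), row)$x))
    dimnames(A_partial) <- list(sbs96_contexts(), rownames(nm$H))
  }
  ok <- stats::complete.cases(res)
  if (!any(ok)) stop("all repeats degenerate (single-class bootstrap)")
  list(auc_partial = mean(res[ok, "partial"]),
       auc_unsup = mean(res[ok, "unsup"]),
       per_repeat = res[ok, , drop = FALSE],
       partial_signatures = A_partial)
}
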