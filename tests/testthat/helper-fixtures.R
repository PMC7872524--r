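# Shared fixture builders; everything is generated in code at test time.

# A tiny profile container with explicit counts and metadata.
make_profiles <- function(counts, age = NULL, tissue = "TST", extra = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 96) {
    full <- matrix(0L, nrow(counts), 96, dimnames = list(NULL, sbs96_contexts()))
    full[, seq_len(ncol(counts))] <- counts
    counts <- full
  }
  n <- nrow(counts)
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     age = if (is.null(age)) rep(60, n) else age,
                     tissue = tissue, stringsAsFactors = FALSE)
  if (!is.null(extra)) meta <- cbind(meta, extra)
  mut_profiles(counts, meta)
}

# Profiles with prescribed total mutation loads, spread over contexts.
make_profiles_with_loads <- function(loads, age = NULL, extra = NULL) {
  counts <- t(vapply(loads, function(L) {
    v <- rep(L %/% 96, 96)
    if (L %% 96 > 0) v[seq_len(L %% 96)] <- v[seq_len(L %% 96)] + 1
    as.integer(v)
  }, integer(96)))
  colnames(counts) <- sbs96_contexts()
  make_profiles(counts, age = age, extra = extra)
}

# A uniform background (all 32 classes equal) for symmetric expectations.
uniform_bg <- function() {
  background_frequencies(stats::setNames(rep(1 / 32, 32), tri32_classes()))
}

# Small planted-effect cohort shared by the pipeline tests.
planted_cohort <- function(n = 100, effect = 3, feature = "A[C>T]G", seed = 42,
                           ...) {
  generate_cohort(cohort_spec(n_exposed = n, n_unexposed = n,
                              effects = stats::setNames(list(effect), feature),
                              seed = seed, ...))
}

# Exact upper-tail binomial probability by direct summation (oracle).
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# All-pairs AUC oracle: P(pos > neg) + 0.5 P(tie).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Brute-force NNLS oracle: enumerate all support subsets, solve the
# unconstrained least squares on each, keep feasible solutions, return the
# one with minimal residual.
nnls_oracle <- function(A, y) {
  k <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (m in 0:(2^k - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    x <- numeric(k)
    if (length(S)) {
      sol <- tryCatch(qr.coef(qr(A[, S, drop = FALSE]), y), error = function(e) NULL)
      if (is.null(sol) || anyNA(sol)) next
      x[S] <- sol
    }
    if (any(x < -1e-12)) next
    rss <- sum((y - A %*% pmax(x, 0))^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- pmax(x, 0)
    }
  }
  best
}

# Exhaustive assignment oracle over all permutations.
assignment_oracle <- function(C, R) {
  k <- ncol(C)
  perms <- permutations_of(seq_len(k))
  cs <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  best <- -Inf
  best_p <- NULL
  for (p in perms) {
    tot <- sum(vapply(seq_len(k), function(i) cs(C[, i], R[, p[i]]), 0))
    if (tot > best) {
      best <- tot
      best_p <- p
    }
  }
  list(pairing = best_p, total = best)
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
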