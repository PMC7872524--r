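test_that("single-peak signatures peak at the prior-knowledge class and conserve mass", {
  smk <- random_single_peak("smoking", seed = 5)
  expect_equal(sum(smk$distribution), 1)
  expect_equal(names(which.max(smk$class_distribution)), "C>A")

  age <- random_single_peak("aging", seed = 5)
  expect_equal(names(which.max(age$class_distribution)), "[C>T]G")
  expect_length(age$class_distribution, 7)  # [C>T]G, [C>T]H + five substitutions

  # re-aggregating the 96-vector reproduces the class distribution exactly
  ctxs <- sbs96_contexts()
  ctg <- sum(age$distribution[endsWith(ctxs, "[C>T]G")])
  cth <- sum(age$distribution[grepl("[C>T]", ctxs, fixed = TRUE) &
                                !endsWith(ctxs, "[C>T]G")])
  expect_equal(ctg, unname(age$class_distribution[["[C>T]G"]]))
  expect_equal(cth, unname(age$class_distribution[["[C>T]H"]]))
  expect_equal(sum(age$distribution[grepl("[T>C]", ctxs, fixed = TRUE)]),
               unname(age$class_distribution[["T>C"]]))

  # determinism under a fixed seed
  expect_equal(random_single_peak("smoking", seed = 9)$distribution,
               random_single_peak("smoking", seed = 9)$distribution)
})

test_that("NMF recovers a rank-1 structure and error decreases with rank", {
  prof <- runif(96, 0.1, 1)
  M <- outer(prof, c(10, 20, 15, 30))
  nm <- nmf_decompose(M, 1, seed = 3)
  expect_lt(nm$error / sqrt(sum(M^2)), 1e-4)
  expect_equal(unname(nm$W[, 1]), prof / sum(prof), tolerance = 1e-3)
  expect_equal(colSums(nm$W), c(S1 = 1))

  set.seed(8)
  M2 <- matrix(rpois(96 * 20, 5), 96, 20)
  errs <- vapply(1:3, function(r) nmf_decompose(M2, r, seed = 11)$error, 0)
  expect_true(all(diff(errs) <= 1e-8))

  expect_error(nmf_decompose(matrix(0, 96, 4), 2), "all-zero")
  # fixed seed -> reproducible factorization
  expect_equal(nmf_decompose(M2, 2, seed = 4, n_restarts = 2)$W,
               nmf_decompose(M2, 2, seed = 4, n_restarts = 2)$W)
})

test_that("misspecified rank spreads a rank-1 truth across components", {
  set.seed(13)
  prof <- runif(96, 0.05, 1)
  prof <- prof / sum(prof)
  M <- vapply(1:30, function(i) rpois(96, 400 * prof), numeric(96))
  nm <- nmf_decompose(M, 3, seed = 21, n_restarts = 2, max_iter = 500)
  cosines <- apply(nm$W, 2, function(w) sum(w * prof) / sqrt(sum(w^2) * sum(prof^2)))
  expect_lt(max(cosines), 1 - 1e-4)  # no single component equals the truth
})

test_that("cosine matching finds the optimal assignment, not the greedy one", {
  # worked example where greedy row-by-row pairing is suboptimal overall
  c1 <- c(1, 0); c2 <- c(0, 1)
  r1 <- c(0.6, 0.8); r2 <- c(1, 0)
  m <- cosine_match(cbind(c1, c2), cbind(r1, r2))
  expect_equal(m$pairing, c(2L, 1L))  # c1 -> r2, c2 -> r1
  expect_equal(m$total, 1.8)

  # identity pairing on identical sets
  set.seed(6)
  S <- matrix(runif(96 * 4), 96, 4)
  ident <- cosine_match(S, S)
  expect_equal(ident$pairing, 1:4)
  expect_equal(ident$total, 4)

  expect_error(cosine_match(S, S[, 1:3]), "equal size")
})

test_that("cosine matching equals brute-force permutation search for sets up to 5", {
  set.seed(27)
  for (k in 2:5) {
    C <- matrix(runif(10 * k), 10, k)
    R <- matrix(runif(10 * k), 10, k)
    got <- cosine_match(C, R)
    want <- assignment_oracle(C, R)
    expect_equal(got$total, want$total, tolerance = 1e-12)
    expect_equal(got$pairing, want$pairing)
  }
})

test_that("BestNMF picks the most discriminative component with deterministic ties", {
  H <- rbind(S1 = c(1, 2, 3, 10, 11, 12),  # separates perfectly
             S2 = c(5, 5, 5, 5, 5, 5),
             S3 = c(3, 1, 2, 2, 3, 1))
  y <- c(0, 0, 0, 1, 1, 1)
  nm <- structure(list(W = NULL, H = H, rank = 3), class = "nmf_result")
  pick <- best_nmf_select(nm, y)
  expect_equal(pick$index, 1L)
  expect_equal(unname(pick$auc[1]), 1)
  expect_false(pick$low_signal)

  # all-flat contributions: an index is still returned, flagged low-signal
  H0 <- rbind(S1 = rep(1, 6), S2 = rep(2, 6))
  pick0 <- best_nmf_select(structure(list(H = H0), class = "nmf_result"), y)
  expect_equal(pick0$index, 1L)  # AUC tie at 0.5 -> lowest index
  expect_true(pick0$low_signal)
  expect_error(best_nmf_select(nm, rep(1, 6)), "both classes")
})

test_that("partial supervision with a zero age signature reduces to plain NMF", {
  # unexposed samples carry no mutations, so the learned aging rates are 0
  # and discounting is a no-op: both arms must agree exactly
  set.seed(55)
  n <- 40
  counts <- matrix(0L, n, 96, dimnames = list(NULL, sbs96_contexts()))
  exposed <- rep(c(1L, 0L), each = n / 2)
  counts[exposed == 1, ] <- matrix(rpois(n / 2 * 96, 3), n / 2, 96)
  prof <- make_profiles(counts, age = rep(60, n),
                        extra = data.frame(exposure = exposed))
  res <- partially_supervised(prof, exposed, repeats = 3, seed = 2,
                              max_iter = 200, n_restarts = 1)
  expect_equal(res$auc_partial, res$auc_unsup)
  expect_true(all(res$partial_signatures >= 0))
})

test_that("the rate precondition rejects cohorts where exposed mutate no faster", {
  # exposed arm mutates at half the unexposed rate
  coh <- generate_cohort(cohort_spec(n_exposed = 20, n_unexposed = 20,
                                     effects = list("TOTAL" = 0.5), seed = 3))
  expect_error(partially_supervised(coh, coh$meta$exposure, repeats = 2),
               "higher average")
})

test_that("age discounting does not hurt exposure detection on an age+exposure cohort", {
  coh <- generate_cohort(cohort_spec(n_exposed = 60, n_unexposed = 60,
                                     effects = list("T>A" = 2.5), seed = 77))
  res <- partially_supervised(coh, coh$meta$exposure, repeats = 8, seed = 5,
                              max_iter = 400, n_restarts = 1)
  expect_gte(res$auc_partial, res$auc_unsup - 0.02)
  expect_true(all(res$per_repeat >= 0 & res$per_repeat <= 1))
})
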