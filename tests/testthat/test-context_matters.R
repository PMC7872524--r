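test_that("binomial enrichment p-values match direct tail summation", {
  # spec worked examples, expectations frozen from the summation oracle
  r <- test_feature_against_ancestor(20, 100, 0.1)
  expect_equal(r$p_value, binom_tail_oracle(20, 100, 0.1))
  expect_equal(r$p_value, 0.0019785609, tolerance = 1e-6)
  expect_false(r$significant)  # 2.0e-3 is not below 0.05/150 = 3.3e-4

  expect_gte(test_feature_against_ancestor(50, 500, 0.1)$p_value, 0.5)  # k = n*p

  r2 <- test_feature_against_ancestor(50, 50, 0.5)
  expect_equal(r2$p_value, 0.5^50)
  expect_true(r2$significant)

  # random cases against the oracle
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.99)
    expect_equal(test_feature_against_ancestor(k, n, p)$p_value,
                 binom_tail_oracle(k, n, p), tolerance = 1e-12)
  }
  expect_error(test_feature_against_ancestor(5, 10, 0), "in \\(0, 1\\)")
  expect_error(test_feature_against_ancestor(11, 10, 0.5), "0 <= k <= n")
})

test_that("pseudo-count priors: root 1000, others exome-proportion x 1000", {
  bg <- uniform_bg()
  # a cohort of identical samples makes the bootstrap deterministic
  counts <- matrix(rep(2L, 96), 1, 96, dimnames = list("S", sbs96_contexts()))
  prof <- rbind_profiles <- counts[rep(1, 5), , drop = FALSE]
  pc <- bootstrap_pseudo_counts(prof, bg, n_boot = 10)
  expect_equal(pc[["TOTAL"]], 5 * 192 + 1000)
  # uniform bg: substitution prior = round(1/6 * 1000) = 167, plus 5*32 counts
  expect_equal(pc[["C>T"]], 160 + 167)
  # trinucleotide prior = round(1000/96) = 10
  expect_equal(pc[["A[C>A]A"]], 10 + 10)
  expect_error(bootstrap_pseudo_counts(prof, bg, n_boot = 0), "n_boot")
})

test_that("phase 1 keeps only features enriched against every ancestor", {
  bg <- uniform_bg()
  lat <- feature_lattice()
  # construct a pseudo-count table directly: start from the exact null
  null_pc <- round(vapply(lat$leaf_sets, function(ix) length(ix) / 96, 0) * 9600)
  names(null_pc) <- lat$names
  expect_identical(phase1_select(null_pc, bg), "TOTAL")

  # enrich [C>T]A against TOTAL but keep it exactly at expectation vs C>T:
  # inflate all of C>T uniformly so [C>T]A's conditional share stays 1/4
  pc <- null_pc
  pc["C>T"] <- null_pc[["C>T"]] * 3
  dinucs <- c("A[C>T]", "C[C>T]", "G[C>T]", "T[C>T]",
              "[C>T]A", "[C>T]C", "[C>T]G", "[C>T]T")
  pc[dinucs] <- null_pc[dinucs] * 3
  tri_ct <- lat$names[lat$level == 3 & grepl("[C>T]", lat$names, fixed = TRUE)]
  pc[tri_ct] <- null_pc[tri_ct] * 3
  pc["TOTAL"] <- null_pc[["TOTAL"]] + 2 * null_pc[["C>T"]]
  cand <- phase1_select(pc, bg)
  expect_true("C>T" %in% cand)
  expect_false("[C>T]A" %in% cand)   # inherited wealth only
  # any-ancestor sensitivity mode does admit it
  expect_true("[C>T]A" %in% phase1_select(pc, bg, mode = "any-ancestor"))
})

test_that("phase 1 finds a planted trinucleotide enrichment in a simulated cohort", {
  coh <- planted_cohort(n = 100, seed = 5)
  bg <- background_frequencies("exome")
  exposed <- coh[coh$meta$exposure == 1]
  pc <- withr::with_seed(7, bootstrap_pseudo_counts(exposed$counts, bg))
  cand <- phase1_select(pc, bg)
  expect_true("A[C>T]G" %in% cand)
})

test_that("phase 1 is monotone: raising a feature's count never drops it", {
  bg <- uniform_bg()
  lat <- feature_lattice()
  pc <- round(vapply(lat$leaf_sets, function(ix) length(ix) / 96, 0) * 9600)
  names(pc) <- lat$names
  pc["A[C>T]G"] <- 160  # enriched leaf
  base_in <- "A[C>T]G" %in% phase1_select(pc, bg)
  pc2 <- pc
  pc2["A[C>T]G"] <- 200  # larger count, ancestors fixed
  expect_true(!base_in || "A[C>T]G" %in% phase1_select(pc2, bg))
  # and the p-value itself is monotone in k
  pv <- vapply(c(120, 160, 200), function(k)
    test_feature_against_ancestor(k, 9600, 1 / 96)$p_value, 0)
  expect_true(all(diff(pv) < 0))
})

test_that("phase 2 drops parents fully explained by their selected children", {
  bg <- uniform_bg()
  lat <- feature_lattice()
  pc <- round(vapply(lat$leaf_sets, function(ix) length(ix) / 96, 0) * 9600)
  names(pc) <- lat$names
  # plant everything in A[C>T]: child explains the whole C>T excess
  boost <- 1200
  pc["A[C>T]"] <- pc["A[C>T]"] + boost
  pc[paste0("A[C>T]", c("A", "C", "G", "T"))] <-
    pc[paste0("A[C>T]", c("A", "C", "G", "T"))] + boost / 4
  pc["C>T"] <- pc["C>T"] + boost
  pc["TOTAL"] <- pc["TOTAL"] + boost
  cand <- phase1_select(pc, bg)
  expect_true(all(c("C>T", "A[C>T]") %in% cand))
  part <- phase2_prune(cand, pc, bg)
  expect_true("A[C>T]" %in% names(part))
  expect_false(any(grepl("^C>T$", names(part))))  # parent eliminated
  expect_true("remaining mutations" %in% names(part))
  # conservation: block pseudo-counts sum to the root pseudo count
  expect_equal(sum(attr(part, "block_counts")), pc[["TOTAL"]])
  # disjoint cover
  expect_setequal(unlist(part), 1:96)
})

test_that("a candidate with no candidate children passes phase 2 unchanged", {
  bg <- uniform_bg()
  lat <- feature_lattice()
  pc <- round(vapply(lat$leaf_sets, function(ix) length(ix) / 96, 0) * 9600)
  names(pc) <- lat$names
  pc["T>A"] <- pc["T>A"] * 3  # enrich the substitution alone
  pc["TOTAL"] <- pc["TOTAL"] + 2 * 1600
  cand <- phase1_select(pc, bg)
  expect_true("T>A" %in% cand)
  part <- phase2_prune(cand, pc, bg)
  expect_true("T>A" %in% names(part))
  expect_length(part[["T>A"]], 16)
  expect_equal(attr(part, "block_counts")[["T>A"]], pc[["T>A"]])
})

test_that("combining partitions produces the minimal common refinement", {
  lat <- feature_lattice()
  ct <- lat$leaf_sets[["C>T"]]
  act <- lat$leaf_sets[["A[C>T]"]]
  pA <- supersigr:::new_partition(list("C>T" = ct,
                                       "remaining mutations" = setdiff(1:96, ct)))
  pB <- supersigr:::new_partition(list("A[C>T]" = act,
                                       "remaining mutations" = setdiff(1:96, act)))
  comb <- combine_partitions(pA, pB)
  sizes <- as.integer(sort(lengths(comb)))
  expect_equal(sizes, c(4L, 12L, 80L))  # A[C>T], C>T minus A[C>T], the rest
  # every output block is a subset of exactly one block of each input
  for (blk in comb) {
    expect_equal(sum(vapply(pA, function(a) all(blk %in% a), NA)), 1L)
    expect_equal(sum(vapply(pB, function(b) all(blk %in% b), NA)), 1L)
  }
  # idempotence and identity
  expect_equal(lengths(combine_partitions(pA, pA)), lengths(pA))
  expect_equal(sort(lengths(combine_partitions(pA, trivial_partition()))),
               sort(lengths(pA)))
})

test_that("partition combination is commutative and associative on random partitions", {
  set.seed(33)
  rand_partition <- function() {
    k <- sample(2:6, 1)
    grp <- sample(k, 96, replace = TRUE)
    blocks <- split(1:96, grp)
    names(blocks) <- paste0("B", seq_along(blocks))
    supersigr:::new_partition(blocks)
  }
  canon <- function(p) unname(lapply(p, as.integer))
  for (i in 1:10) {
    p1 <- rand_partition(); p2 <- rand_partition(); p3 <- rand_partition()
    ab <- combine_partitions(p1, p2)
    ba <- combine_partitions(p2, p1)
    expect_equal(canon(ab), canon(ba))
    abc1 <- combine_partitions(combine_partitions(p1, p2), p3)
    abc2 <- combine_partitions(p1, combine_partitions(p2, p3))
    expect_equal(canon(abc1), canon(abc2))
  }
})

test_that("partition JSON round trip preserves blocks and metadata", {
  coh <- planted_cohort(n = 60, seed = 5)
  bg <- background_frequencies("exome")
  part <- context_matters(coh[coh$meta$exposure == 1], bg, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(part, path)
  back <- read_partition(path)
  expect_equal(unname(lapply(back, c)), unname(lapply(unclass(part), c)))
  expect_equal(attr(back, "meta")$seed, 3)
  expect_equal(attr(back, "meta")$divisor, 150)
})

test_that("under a pure-null cohort ContextMatters selects nothing beyond remaining mutations", {
  bg <- background_frequencies("exome")
  false_sel <- 0L
  n_rep <- 25L
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(cohort_spec(n_exposed = 0, n_unexposed = 60,
                                       seed = 1000 + i, bg = bg))
    part <- context_matters(coh, bg, seed = 2000 + i)
    if (length(part) > 1) false_sel <- false_sel + 1L
  }
  # Bonferroni guarantee: family-wise false-selection rate <= 0.05
  expect_lte(false_sel / n_rep, 0.05 + 1e-9)
})
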