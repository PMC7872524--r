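# ContextMatters: supervised feature engineering on the mutational family
# lattice. Phase 1 walks down from the root, keeping features whose
# pseudo-count-augmented cohort counts exceed every ancestor-conditional
# null (one-sided binomial, Bonferroni 0.05/150). Phase 2 walks back up,
# re-testing candidate parents after subtracting the counts of accepted
# candidate children, and always emits the "remaining mutations" block.

#' Bootstrap pseudo-count table
#'
#' For each of the 151 lattice features, resamples the cohort's samples
#' with replacement \code{n_boot} times; in each resample the feature's
#' cohort count is augmented by its pseudo-count prior (the root starts at
#' \code{root_start} = 1000; every other feature starts at its exome
#' proportion times 1000) and rounded; the per-feature median across
#' resamples is returned.
#'
#' @param counts Samples x 96 count matrix (or a \code{"mut_profiles"}).
#' @param bg Background frequencies (prior proportions).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param root_start Pseudo-count start of the root (default 1000).
#' @param lattice The feature lattice.
#' @return Named integer-valued vector over the 151 features.
#' @export
bootstrap_pseudo_counts <- function(counts, bg, n_boot = 100, root_start = 1000,
                                    lattice = feature_lattice()) {
  if (inherits(counts, "mut_profiles")) counts <- counts$counts
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (nrow(counts) == 0) stop("empty cohort")
  p0 <- leaf_null_probs(bg)
  prior <- round(vapply(lattice$leaf_sets, function(ix) sum(p0[ix]), 0) * root_start)
  prior[["TOTAL"]] <- root_start
  F <- counts %*% lattice$M  # samples x 151 feature counts
  n <- nrow(F)
  boots <- matrix(0, n_boot, ncol(F))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- round(colSums(F[idx, , drop = FALSE]) + prior)
  }
  stats::setNames(round(apply(boots, 2, stats::median)), lattice$names)
}

#' One-sided binomial enrichment test against an ancestor-conditional null
#'
#' Upper-tail test of observing \code{k} or more successes out of \code{n}
#' when each falls in the feature with null probability \code{p}.
#'
#' @param k Feature count (0 <= k <= n).
#' @param n Ancestor count.
#' @param p Expected proportion under the null, in (0, 1).
#' @param alpha_adj Bonferroni-adjusted significance level
#'   (default 0.05/150: 150 tests, the root is not tested against).
#' @return List with \code{p_value} = P(Bin(n, p) >= k) and
#'   \code{significant} (p_value < alpha_adj).
#' @export
test_feature_against_ancestor <- function(k, n, p, alpha_adj = 0.05 / 150) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  pv <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  list(p_value = pv, significant = pv < alpha_adj)
}

#' Phase 1: walk down the lattice
#'
#' A feature is a first-phase candidate iff the binomial enrichment test
#' rejects against every ancestor on every root path (\code{mode =
#' "all-ancestors"}; unless proven otherwise a feature's mutational wealth
#' is explained by inheritance). \code{mode = "any-ancestor"} is provided
#' for sensitivity analysis. The root is never tested and always retained.
#'
#' @param pseudo_counts Output of [bootstrap_pseudo_counts()].
#' @param bg Background frequencies.
#' @param alpha Significance level before correction (default 0.05).
#' @param divisor Bonferroni divisor, fixed at 150.
#' @param mode \code{"all-ancestors"} (default) or \code{"any-ancestor"}.
#' @param lattice The feature lattice.
#' @return Character vector of candidate feature names (root included).
#' @export
phase1_select <- function(pseudo_counts, bg, alpha = 0.05, divisor = 150,
                          mode = c("all-ancestors", "any-ancestor"),
                          lattice = feature_lattice()) {
  mode <- match.arg(mode)
  alpha_adj <- alpha / divisor
  p0 <- leaf_null_probs(bg)
  node_p0 <- vapply(lattice$leaf_sets, function(ix) sum(p0[ix]), 0)
  cand <- "TOTAL"
  for (f in lattice$names[lattice$level > 0]) {
    anc <- ancestors_of(f, lattice)
    hits <- vapply(anc, function(a) {
      k <- min(pseudo_counts[[f]], pseudo_counts[[a]])
      test_feature_against_ancestor(
        k, pseudo_counts[[a]], node_p0[[f]] / node_p0[[a]], alpha_adj)$significant
    }, NA)
    if ((mode == "all-ancestors" && all(hits)) ||
        (mode == "any-ancestor" && any(hits))) {
      cand <- c(cand, f)
    }
  }
  cand
}

#' Phase 2: walk back up and emit a partition
#'
#' Processes first-phase candidates deepest level first (trinucleotides,
#' then dinucleotides, then substitutions; canonical name order within a
#' level). A candidate with no accepted candidate descendants passes
#' through unchanged. Otherwise the accepted descendants' counts are
#' subtracted and the leftover is re-tested against its ancestors, with the
#' conditional null renormalized to the leftover context space (so the
#' leftover is tested against its own background). The leftover of the
#' root is always emitted as the \code{"remaining mutations"} block.
#'
#' @inheritParams phase1_select
#' @param candidates Character vector from [phase1_select()].
#' @return A \code{"mut_partition"}: named list of integer leaf-index
#'   blocks (disjoint, union = all 96 contexts), with attribute
#'   \code{"block_counts"} (pseudo-count mass per block, conserved: sums to
#'   the root pseudo count).
#' @export
phase2_prune <- function(candidates, pseudo_counts, bg, alpha = 0.05,
                         divisor = 150, lattice = feature_lattice()) {
  alpha_adj <- alpha / divisor
  p0 <- leaf_null_probs(bg)
  accepted <- list()   # name -> leaf indices (leftover block)
  acc_count <- numeric(0)
  acc_leaves_in <- function(ix) {
    # accepted blocks fully inside leaf set ix (blocks never straddle a
    # feature boundary: a block is a subset of its feature's leaf set)
    keep <- vapply(accepted, function(b) all(b %in% ix), NA)
    names(accepted)[keep]
  }
  for (lev in c(3L, 2L, 1L)) {
    feats <- sort(intersect(candidates, lattice$names[lattice$level == lev]))
    for (f in feats) {
      ix <- lattice$leaf_sets[[f]]
      inside <- acc_leaves_in(ix)
      taken <- unlist(accepted[inside], use.names = FALSE)
      B <- setdiff(ix, taken)
      k <- pseudo_counts[[f]] - sum(acc_count[inside])
      if (!length(inside)) {
        # no accepted candidate children: passes through unchanged
        accepted[[f]] <- ix
        acc_count[f] <- pseudo_counts[[f]]
        next
      }
      if (!length(B) || k <= 0) next  # nothing left to explain
      ok <- vapply(ancestors_of(f, lattice), function(a) {
        aix <- lattice$leaf_sets[[a]]
        a_in <- acc_leaves_in(aix)
        a_left <- setdiff(aix, unlist(accepted[a_in], use.names = FALSE))
        n_adj <- pseudo_counts[[a]] - sum(acc_count[a_in])
        p_adj <- sum(p0[B]) / sum(p0[a_left])
        if (n_adj <= 0 || p_adj <= 0 || p_adj >= 1) return(FALSE)
        test_feature_against_ancestor(min(k, n_adj), n_adj, p_adj, alpha_adj)$significant
      }, NA)
      if (all(ok)) {
        accepted[[f]] <- B
        acc_count[f] <- k
      }
    }
  }
  all_taken <- unlist(accepted, use.names = FALSE)
  blocks <- accepted
  cnts <- acc_count
  rest <- setdiff(seq_len(96), all_taken)
  blocks[["remaining mutations"]] <- rest
  cnts["remaining mutations"] <- pseudo_counts[["TOTAL"]] - sum(acc_count)
  new_partition(blocks, block_counts = cnts)
}

#' Run ContextMatters on a cohort
#'
#' Convenience wrapper: bootstrap pseudo counts, phase-1 selection, phase-2
#' pruning. Randomness (the bootstrap) is governed by \code{seed}.
#'
#' @inheritParams bootstrap_pseudo_counts
#' @inheritParams phase1_select
#' @param seed Integer seed for the pseudo-count bootstrap.
#' @return A \code{"mut_partition"} (see [phase2_prune()]); metadata
#'   attributes record seed, n_boot, alpha and divisor.
#' @export
context_matters <- function(counts, bg, n_boot = 100, seed = 1L, alpha = 0.05,
                            divisor = 150, mode = "all-ancestors",
                            lattice = feature_lattice()) {
  if (inherits(counts, "mut_profiles")) counts <- counts$counts
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pc <- bootstrap_pseudo_counts(counts, bg, n_boot = n_boot, lattice = lattice)
  cand <- phase1_select(pc, bg, alpha = alpha, divisor = divisor, mode = mode,
                        lattice = lattice)
  part <- phase2_prune(cand, pc, bg, alpha = alpha, divisor = divisor,
                       lattice = lattice)
  attr(part, "meta") <- list(seed = seed, n_boot = n_boot, alpha = alpha,
                             divisor = divisor, mode = mode)
  part
}

# Partitions --------------------------------------------------------------

new_partition <- function(blocks, block_counts = NULL) {
  blocks <- lapply(blocks, function(b) sort(unique(as.integer(b))))
  # deterministic order: by smallest member leaf
  ord <- order(vapply(blocks, min, 0L))
  blocks <- blocks[ord]
  all <- unlist(blocks, use.names = FALSE)
  if (length(all) != 96 || anyDuplicated(all) || !setequal(all, 1:96))
    stop("blocks must be disjoint and cover all 96 contexts")
  structure(blocks, class = "mut_partition",
            block_counts = if (!is.null(block_counts)) block_counts[names(blocks)])
}

#' The trivial one-block partition
#' @return A \code{"mut_partition"} whose single block covers all 96 contexts.
#' @export
trivial_partition <- function() {
  new_partition(list("remaining mutations" = 1:96))
}

#' @export
print.mut_partition <- function(x, ...) {
  cat("Mutation-space partition:", length(x), "blocks\n")
  for (nm in names(x)) cat(sprintf("  %-24s %3d contexts\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Combine two partitions into their minimal common refinement
#'
#' All non-empty pairwise intersections of the blocks of the two input
#' partitions: the coarsest partition refining both. Blocks keep the input
#' name when the intersection equals an input block, otherwise the two
#' names are joined with \code{" & "}.
#'
#' @param pA,pB \code{"mut_partition"} objects over the 96 contexts.
#' @return A \code{"mut_partition"}.
#' @export
combine_partitions <- function(pA, pB) {
  if (!inherits(pA, "mut_partition") || !inherits(pB, "mut_partition"))
    stop("inputs must be mut_partition objects")
  out <- list()
  for (a in names(pA)) {
    for (b in names(pB)) {
      sect <- intersect(pA[[a]], pB[[b]])
      if (!length(sect)) next
      nm <- if (setequal(sect, pA[[a]])) a
            else if (setequal(sect, pB[[b]])) b
            else paste(a, b, sep = " & ")
      while (nm %in% names(out)) nm <- paste0(nm, "'")
      out[[nm]] <- sect
    }
  }
  new_partition(out)
}

#' Per-sample feature values for a partition
#'
#' Each sample's value for a block is the sum of its counts over the
#' block's contexts, divided by age when \code{measure = "rate"}.
#'
#' @param profiles A \code{"mut_profiles"} object (or count matrix).
#' @param partition A \code{"mut_partition"}.
#' @param measure \code{"count"} (used for the age factor) or
#'   \code{"rate"} (counts/age, all other exposures).
#' @param age Ages; taken from \code{profiles$meta$age} when omitted.
#' @return Samples x blocks numeric matrix.
#' @export
partition_values <- function(profiles, partition, measure = c("count", "rate"),
                             age = NULL) {
  measure <- match.arg(measure)
  counts <- if (inherits(profiles, "mut_profiles")) profiles$counts else profiles
  if (is.null(age) && inherits(profiles, "mut_profiles")) age <- profiles$meta$age
  B <- matrix(0L, 96, length(partition),
              dimnames = list(sbs96_contexts(), names(partition)))
  for (nm in names(partition)) B[partition[[nm]], nm] <- 1L
  X <- counts %*% B
  if (measure == "rate") {
    if (is.null(age) || anyNA(age)) stop("rate measure requires ages for all samples")
    X <- X / age
  }
  X
}

#' Serialize / load a partition as JSON
#'
#' @param partition A \code{"mut_partition"}.
#' @param path Output (input) path.
#' @param meta Optional metadata list (seed, n_boot, alpha, divisor).
#' @return \code{write_partition} returns \code{path} invisibly;
#'   \code{read_partition} the partition.
#' @export
write_partition <- function(partition, path, meta = attr(partition, "meta")) {
  ctx <- sbs96_contexts()
  obj <- list(blocks = lapply(unclass(partition), function(ix) ctx[ix]),
              metadata = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctx <- sbs96_contexts()
  blocks <- lapply(obj$blocks, function(nm) match(nm, ctx))
  p <- new_partition(blocks)
  attr(p, "meta") <- obj$metadata
  p
}
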