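# The mutational family tree: 1 root + 6 substitutions + 48 dinucleotide
# features + 96 trinucleotides = 151 potential features. Trinucleotides
# have two dinucleotide parents (prefix and suffix), so the structure is a
# lattice, not a strict tree; all operations are defined on the DAG.

the <- new.env(parent = emptyenv())  # package-local cache

#' Enumerate the 151-feature mutational family lattice
#'
#' Level 0 is the root \code{"TOTAL"} (all mutations); level 1 the six
#' single-base substitutions (\code{"C>A"}, ...); level 2 the 48 features
#' pairing a substitution with one flanking base as prefix or suffix
#' (\code{"A[C>T]"}, \code{"[C>T]G"}); level 3 the 96 full trinucleotide
#' contexts. Edges connect features that share mutations: each
#' trinucleotide has exactly two dinucleotide parents, each dinucleotide
#' one substitution parent, each substitution the root.
#'
#' @return A \code{"feature_lattice"} object with components \code{names}
#'   (151 feature names), \code{level} (0-3), \code{leaf_sets} (per-feature
#'   integer indices into [sbs96_contexts()]), \code{parents},
#'   \code{children}, and \code{M} (96 x 151 leaf-membership indicator).
#' @export
#' @examples
#' lat <- feature_lattice()
#' length(lat$names)  # 151
feature_lattice <- function() {
  if (!is.null(the$lattice)) return(the$lattice)
  ctxs <- sbs96_contexts()
  names_ <- "TOTAL"
  level <- 0L
  leaf_sets <- list(seq_len(96))
  parents <- list(character(0))
  for (s in SUBSTITUTIONS) {
    names_ <- c(names_, s)
    level <- c(level, 1L)
    leaf_sets <- c(leaf_sets, list(which(grepl(paste0("[", s, "]"), ctxs, fixed = TRUE))))
    parents <- c(parents, list("TOTAL"))
  }
  for (s in SUBSTITUTIONS) {
    for (b in BASES) {  # prefix features b[s]
      names_ <- c(names_, paste0(b, "[", s, "]"))
      level <- c(level, 2L)
      leaf_sets <- c(leaf_sets, list(which(startsWith(ctxs, paste0(b, "[", s, "]")))))
      parents <- c(parents, list(s))
    }
    for (b in BASES) {  # suffix features [s]b
      names_ <- c(names_, paste0("[", s, "]", b))
      level <- c(level, 2L)
      leaf_sets <- c(leaf_sets, list(which(endsWith(ctxs, paste0("[", s, "]", b)))))
      parents <- c(parents, list(s))
    }
  }
  for (i in seq_along(ctxs)) {
    cx <- ctxs[i]
    f5 <- substr(cx, 1, 1)
    f3 <- substr(cx, nchar(cx), nchar(cx))
    s <- substr(cx, 3, 5)
    names_ <- c(names_, cx)
    level <- c(level, 3L)
    leaf_sets <- c(leaf_sets, list(i))
    parents <- c(parents, list(c(paste0(f5, "[", s, "]"), paste0("[", s, "]", f3))))
  }
  names(leaf_sets) <- names_
  names(parents) <- names_
  children <- stats::setNames(vector("list", length(names_)), names_)
  for (i in seq_along(names_)) children[[i]] <- character(0)
  for (f in names_) for (p in parents[[f]]) children[[p]] <- c(children[[p]], f)
  M <- matrix(0L, 96, length(names_), dimnames = list(ctxs, names_))
  for (f in names_) M[leaf_sets[[f]], f] <- 1L
  the$lattice <- structure(
    list(names = names_, level = stats::setNames(level, names_),
         leaf_sets = leaf_sets, parents = parents, children = children, M = M),
    class = "feature_lattice")
  the$lattice
}

#' @export
print.feature_lattice <- function(x, ...) {
  cat("Mutational family lattice:", length(x$names), "features",
      sprintf("(%d root + %d substitutions + %d dinucleotides + %d trinucleotides)\n",
              sum(x$level == 0), sum(x$level == 1), sum(x$level == 2), sum(x$level == 3)))
  invisible(x)
}

#' Parents, children, and leaf set of a lattice feature
#'
#' @param feature Canonical feature name (e.g. \code{"A[C>T]"}).
#' @param lattice A [feature_lattice()]; defaults to the cached one.
#' @return List with \code{parents}, \code{children} (character vectors)
#'   and \code{leaf_set} (character vector of trinucleotide contexts).
#' @export
relatives <- function(feature, lattice = feature_lattice()) {
  if (!feature %in% lattice$names) stop("unknown feature: ", feature)
  list(parents = lattice$parents[[feature]],
       children = lattice$children[[feature]],
       leaf_set = sbs96_contexts()[lattice$leaf_sets[[feature]]])
}

# All ancestors of a feature (transitively), root included; internal.
ancestors_of <- function(feature, lattice = feature_lattice()) {
  out <- character(0)
  frontier <- lattice$parents[[feature]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unique(unlist(lattice$parents[frontier], use.names = FALSE))
  }
  out
}

# Null mutation probability of each of the 96 leaves: background frequency
# of the trinucleotide times 1/3 (the three alternate bases are equally
# likely under the null). Sums to 1 over all 96 contexts.
leaf_null_probs <- function(bg) {
  cx <- split_context(sbs96_contexts())
  tri <- paste0(cx[, "f5"], cx[, "ref"], cx[, "f3"])
  stats::setNames(unname(bg$tri[tri]) / 3, sbs96_contexts())
}

#' Expected proportion of an ancestor's mutations falling in a feature
#'
#' Under the null, a feature's share of mutations is its background
#' probability: for a substitution given TOTAL this is the frequency of the
#' central base times 1/3 (three equally likely alternates); refining the
#' context multiplies by the conditional context frequency, e.g.
#' P([C>T]A | C>T) = freq(C followed by A) / freq(C). In general the
#' proportion is the ratio of the two features' null probabilities, which
#' makes the chain rule P(f | TOTAL) = P(f | parent) P(parent | TOTAL) hold
#' along any root path.
#'
#' @param feature,ancestor Canonical feature names; \code{ancestor} must be
#'   an ancestor of \code{feature} in the lattice (or equal to it).
#' @param bg A [background_frequencies()] object.
#' @param lattice A [feature_lattice()].
#' @return Probability in (0, 1].
#' @export
expected_proportion <- function(feature, ancestor, bg,
                                lattice = feature_lattice()) {
  if (!feature %in% lattice$names) stop("unknown feature: ", feature)
  if (!ancestor %in% lattice$names) stop("unknown feature: ", ancestor)
  if (ancestor != feature && !ancestor %in% ancestors_of(feature, lattice))
    stop(ancestor, " is not an ancestor of ", feature)
  p0 <- leaf_null_probs(bg)
  sum(p0[lattice$leaf_sets[[feature]]]) / sum(p0[lattice$leaf_sets[[ancestor]]])
}
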