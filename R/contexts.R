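# Canonical orders -------------------------------------------------------

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical 96 trinucleotide substitution contexts
#'
#' Returns the 96 single-base substitution classes in canonical (COSMIC)
#' order: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then the 5'
#' flanking base A < C < G < T, then the 3' flanking base A < C < G < T.
#' All classes are pyrimidine-stranded, e.g. \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_contexts())
sbs96_contexts <- function() {
  out <- character(96)
  i <- 1L
  for (s in SUBSTITUTIONS) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[i] <- paste0(f5, "[", s, "]", f3)
        i <- i + 1L
      }
    }
  }
  out
}

#' Pyrimidine-centered trinucleotide classes
#'
#' The 32 strand-collapsed trinucleotides with a central C or T, in the
#' order central C then T, 5' flank major, 3' flank minor. These index the
#' background-frequency vector.
#'
#' @return Character vector of length 32 (e.g. \code{"ACA"}, \code{"ACC"}).
#' @export
tri32_classes <- function() {
  out <- character(32)
  i <- 1L
  for (ctr in c("C", "T")) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[i] <- paste0(f5, ctr, f3)
        i <- i + 1L
      }
    }
  }
  out
}

revcomp <- function(x) {
  # reverse complement of short upstream/downstream strings, vectorized
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMPLEMENT[b])), collapse = ""), "")
}

#' Normalize a substitution to its pyrimidine-strand context name
#'
#' Single-base substitutions are named according to the pyrimidine of the
#' mutated Watson-Crick pair: when the reference base is a purine (A or G),
#' the substitution and both flanking bases are reverse-complemented (the
#' flanks swap and complement).
#'
#' @param ref,alt Reference and alternate bases (A/C/G/T), vectorized.
#' @param ctx5,ctx3 The 5' and 3' flanking bases. \code{"N"} in any
#'   position yields \code{NA} (undefined context; callers skip the record).
#' @return Character vector of canonical context names, e.g.
#'   \code{"T[C>T]A"}; \code{NA} where the context is undefined.
#' @export
#' @examples
#' normalize_substitution("G", "A", "T", "A")  # "T[C>T]A"
normalize_substitution <- function(ref, alt, ctx5, ctx3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(ctx5) == n, length(ctx3) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  ctx5 <- toupper(ctx5); ctx3 <- toupper(ctx3)
  if (any(ref == alt)) stop("invalid record: ref equals alt")
  ok_base <- function(x) x %in% BASES
  if (!all(ok_base(ref) & ok_base(alt))) stop("ref/alt must be one of A, C, G, T")
  undef <- !ok_base(ctx5) | !ok_base(ctx3)
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  f5 <- ifelse(flip, COMPLEMENT[ctx3], ctx5)
  f3 <- ifelse(flip, COMPLEMENT[ctx5], ctx3)
  out <- paste0(f5, "[", r, ">", a, "]", f3)
  out[undef] <- NA_character_
  out
}

# Decompose a context name "A[C>T]G" into its parts (internal)
split_context <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed context name: ", paste(x[bad], collapse = ", "))
  do.call(rbind, lapply(m, function(p) {
    c(f5 = p[2], ref = p[3], alt = p[4], f3 = p[5])
  }))
}

# Background frequencies --------------------------------------------------

#' Background trinucleotide frequencies
#'
#' Builds the 32-class pyrimidine-centered trinucleotide background from a
#' sequence source, a tabulated file, or the packaged synthetic tables.
#' Every window of three consecutive bases is counted on both strands
#' (strand-collapsed to the pyrimidine-centered class); windows containing
#' non-ACGT characters are skipped.
#'
#' @param source One of:
#'   \itemize{
#'     \item a character scalar naming a FASTA file or a two-column TSV
#'       (columns \code{trinucleotide}, \code{frequency});
#'     \item a character vector of raw sequence(s) (anything that is not an
#'       existing file path and looks like sequence);
#'     \item \code{"genome"} or \code{"exome"} for the packaged synthetic
#'       independence-model tables;
#'     \item a named numeric vector of length 32 over [tri32_classes()].
#'   }
#' @return Object of class \code{"mut_background"}: a named 32-vector
#'   \code{tri} summing to 1, with accessors [bg_aggregate()].
#' @seealso [synthetic_background()]
#' @export
background_frequencies <- function(source = "exome") {
  if (is.numeric(source)) {
    if (length(source) != 32 || is.null(names(source)))
      stop("numeric background must be a named 32-vector")
    tri <- source[tri32_classes()]
    if (anyNA(tri)) stop("background vector must name all 32 classes")
    return(new_background(tri))
  }
  stopifnot(is.character(source))
  if (length(source) == 1 && source %in% c("genome", "exome")) {
    path <- system.file("extdata", paste0("background_", source, "_synthetic.tsv"),
                        package = "supersigr")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tri <- stats::setNames(tab$frequency, tab$trinucleotide)[tri32_classes()]
    return(new_background(tri))
  }
  if (length(source) == 1 && file.exists(source)) {
    first <- readLines(source, n = 1L)
    if (startsWith(first, ">")) {
      seqs <- read_fasta(source)
      return(background_from_sequence(seqs))
    }
    tab <- utils::read.delim(source, stringsAsFactors = FALSE)
    need <- c("trinucleotide", "frequency")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("background table missing column: ", miss[1])
    tri <- stats::setNames(tab$frequency, tab$trinucleotide)[tri32_classes()]
    if (anyNA(tri)) stop("background table must cover all 32 trinucleotide classes")
    return(new_background(tri / sum(tri)))
  }
  # raw sequence(s)
  background_from_sequence(source)
}

new_background <- function(tri) {
  tri <- tri / sum(tri)
  structure(list(tri = tri), class = "mut_background")
}

background_from_sequence <- function(seqs) {
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 3)) stop("sequence shorter than 3 bases")
  counts <- stats::setNames(numeric(32), tri32_classes())
  for (s in seqs) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    tri <- paste0(b[1:(n - 2)], b[2:(n - 1)], b[3:n])
    tri <- tri[grepl("^[ACGT]{3}$", tri)]
    if (!length(tri)) next
    ctr <- substr(tri, 2, 2)
    pur <- ctr %in% c("A", "G")
    tri[pur] <- revcomp(tri[pur])
    t <- table(tri)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  if (sum(counts) == 0) stop("no valid ACGT trinucleotide windows in sequence")
  new_background(counts)
}

#' @export
print.mut_background <- function(x, ...) {
  cat("Background trinucleotide frequencies (32 pyrimidine-centered classes)\n")
  cat(sprintf("  freq(C) = %.4f, freq(T) = %.4f\n",
              bg_aggregate(x, "C"), bg_aggregate(x, "T")))
  invisible(x)
}

#' Aggregate background frequencies
#'
#' Sums the 32 trinucleotide classes down to a single-base aggregate
#' (\code{"C"}, \code{"T"}) or a dinucleotide aggregate given by a central
#' base plus one flank (e.g. \code{"CA"} = C followed by A summed over the
#' 5' flank; \code{"AC"} = A preceding C summed over the 3' flank).
#'
#' @param bg A [background_frequencies()] object.
#' @param what Aggregate name: one or two characters, pyrimidine central base.
#' @return Numeric proportion.
#' @export
bg_aggregate <- function(bg, what) {
  tri <- bg$tri
  cls <- tri32_classes()
  ctr <- substr(cls, 2, 2)
  if (nchar(what) == 1) {
    if (!what %in% c("C", "T")) stop("single-base aggregate must be C or T")
    return(sum(tri[ctr == what]))
  }
  if (nchar(what) == 2) {
    b <- strsplit(what, "")[[1]]
    if (b[1] %in% c("C", "T") && !b[2] %in% c("C", "T")) {
      # central base + 3' flank
      return(sum(tri[ctr == b[1] & substr(cls, 3, 3) == b[2]]))
    }
    if (b[2] %in% c("C", "T")) {
      # 5' flank + central base
      return(sum(tri[substr(cls, 1, 1) == b[1] & ctr == b[2]]))
    }
    stop("dinucleotide aggregate must contain a pyrimidine central base")
  }
  if (nchar(what) == 3) return(unname(tri[what]))
  stop("unknown aggregate: ", what)
}

#' Synthetic background model
#'
#' An independence-model background: each base drawn i.i.d. with the given
#' GC content, trinucleotide frequency the product of its base
#' probabilities, strand-collapsed. The packaged \code{"genome"} table uses
#' GC 0.41 (human-genome-like), the \code{"exome"} table GC 0.51. These are
#' synthetic stand-ins so that no reference genome needs to be shipped; any
#' FASTA or tabulated background may override them.
#'
#' @param gc GC content in (0, 1).
#' @return A \code{"mut_background"} object.
#' @export
synthetic_background <- function(gc = 0.41) {
  stopifnot(gc > 0, gc < 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cls <- tri32_classes()
  tri <- vapply(strsplit(cls, ""), function(b) {
    fwd <- p[b[1]] * p[b[2]] * p[b[3]]
    rc <- p[COMPLEMENT[b[3]]] * p[COMPLEMENT[b[2]]] * p[COMPLEMENT[b[1]]]
    unname(fwd + rc)  # both strands fold into the pyrimidine class
  }, 0)
  names(tri) <- cls
  new_background(tri)
}

# Minimal FASTA reader; uses Biostrings when available, base R otherwise.
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.character(Biostrings::readDNAStringSet(path)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], idx[!hdr], paste, collapse = "")
  nm <- sub("^>\\s*", "", lines[hdr])
  stats::setNames(as.character(seqs), vapply(strsplit(nm, "\\s+"), `[`, "", 1))
}
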