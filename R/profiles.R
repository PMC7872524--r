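# MAF-like mutation tables -> per-sample 96-context profiles

MAF_REQUIRED <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2")

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated table with MAF-compatible column names, keeps
#' single-nucleotide substitutions, and applies the variant-allele-frequency
#' filter: mutations with VAF strictly below \code{vaf_min} are removed
#' (records at exactly the threshold are retained). VAF is taken from a
#' \code{vaf} column when present, otherwise computed as
#' \code{t_alt_count / (t_alt_count + t_ref_count)}; if neither is
#' available all records pass the filter.
#'
#' @param path Path to the tab-separated file. Required columns:
#'   \code{Tumor_Sample_Barcode}, \code{Chromosome}, \code{Start_Position},
#'   \code{Reference_Allele}, \code{Tumor_Seq_Allele2}. Optional:
#'   \code{t_ref_count}/\code{t_alt_count} or \code{vaf}, and
#'   \code{CONTEXT} (a 3-mer centered on the reference base).
#' @param vaf_min Minimum variant allele frequency (default 0.05).
#' @return A data frame of mutation records with columns \code{sample_id},
#'   \code{chromosome}, \code{position}, \code{ref}, \code{alt}, \code{vaf},
#'   \code{context5}, \code{context3} (flanks are \code{NA} when no
#'   \code{CONTEXT} column is present); attribute \code{"dropped"} records
#'   how many rows were removed and why.
#' @export
read_mutation_table <- function(path, vaf_min = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read everything as character: allele columns like "T" must not be
  # parsed as logicals
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  miss <- setdiff(MAF_REQUIRED, names(tab))
  if (length(miss)) stop("missing required column: ", miss[1])
  n0 <- nrow(tab)
  if (n0 == 0) {
    out <- data.frame(sample_id = character(), chromosome = character(),
                      position = integer(), ref = character(), alt = character(),
                      vaf = numeric(), context5 = character(), context3 = character(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- c(non_snv = 0L, low_vaf = 0L)
    return(out)
  }
  ref <- toupper(tab$Reference_Allele)
  alt <- toupper(tab$Tumor_Seq_Allele2)
  # SNVs only: single-base A/C/G/T on both alleles, ref != alt
  snv <- ref %in% BASES & alt %in% BASES & ref != alt
  if ("vaf" %in% names(tab)) {
    vaf <- suppressWarnings(as.numeric(tab$vaf))
    if (anyNA(vaf[snv])) {
      stop("unparseable vaf at row ", which(snv & is.na(vaf))[1])
    }
  } else if (all(c("t_ref_count", "t_alt_count") %in% names(tab))) {
    a <- suppressWarnings(as.numeric(tab$t_alt_count))
    r <- suppressWarnings(as.numeric(tab$t_ref_count))
    bad <- snv & (is.na(a) | is.na(r))
    if (any(bad)) stop("unparseable allele counts at row ", which(bad)[1])
    vaf <- a / (a + r)
  } else {
    vaf <- rep(1, n0)  # no VAF information: nothing filtered
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stop("vaf outside [0, 1]")
  keep <- snv & vaf >= vaf_min
  dropped <- c(non_snv = sum(!snv), low_vaf = sum(snv & vaf < vaf_min))
  tab <- tab[keep, , drop = FALSE]
  ctx5 <- ctx3 <- rep(NA_character_, nrow(tab))
  if ("CONTEXT" %in% names(tab)) {
    cx <- toupper(tab$CONTEXT)
    ok <- !is.na(cx) & nchar(cx) == 3
    ctx5[ok] <- substr(cx[ok], 1, 1)
    ctx3[ok] <- substr(cx[ok], 3, 3)
  }
  out <- data.frame(sample_id = as.character(tab$Tumor_Sample_Barcode),
                    chromosome = as.character(tab$Chromosome),
                    position = as.integer(tab$Start_Position),
                    ref = toupper(tab$Reference_Allele),
                    alt = toupper(tab$Tumor_Seq_Allele2),
                    vaf = vaf[keep],
                    context5 = ctx5, context3 = ctx3,
                    stringsAsFactors = FALSE)
  if (sum(dropped) > 0) {
    message("read_mutation_table: removed ", dropped[["low_vaf"]],
            " low-VAF and ", dropped[["non_snv"]], " non-SNV records")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read a clinical annotation table
#'
#' TSV with header \code{sample_id}, \code{age}, \code{tissue}, plus one
#' column per etiological factor (binary 0/1 flags or numeric values such
#' as BMI).
#'
#' @param path Path to the TSV.
#' @return Data frame keyed by \code{sample_id}.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("sample_id", "age", "tissue"), names(tab))
  if (length(miss)) stop("missing required column: ", miss[1])
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in clinical table")
  tab
}

#' Build per-sample 96-context mutation profiles
#'
#' Resolves each record's trinucleotide context (from the record's flank
#' columns, or by FASTA lookup at position-1 and position+1), normalizes to
#' the pyrimidine strand, and tabulates one row of counts per sample in
#' canonical context order. Records whose context contains N (or cannot be
#' resolved) are skipped and counted in the log.
#'
#' @param records Data frame from [read_mutation_table()].
#' @param clinical Data frame from [read_clinical_table()] (or compatible).
#' @param fasta Optional FASTA path or named character vector of contig
#'   sequences used to look up missing flanks (1-based coordinates; records
#'   at contig boundaries are skipped with a warning).
#' @param include_missing If \code{TRUE}, samples present in \code{clinical}
#'   but absent from \code{records} get all-zero profiles.
#' @return A \code{"mut_profiles"} object: list with \code{counts} (samples
#'   x 96 integer matrix) and \code{meta} (clinical rows aligned to the
#'   count matrix). Samples missing from \code{clinical} get \code{NA}
#'   age/tissue with a warning.
#' @export
build_profile_matrix <- function(records, clinical, fasta = NULL,
                                 include_missing = FALSE) {
  ctx5 <- records$context5
  ctx3 <- records$context3
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
      read_fasta(fasta) else fasta
    need <- is.na(ctx5) | is.na(ctx3)
    if (any(need)) {
      looked <- lookup_context(records$chromosome[need], records$position[need], seqs)
      ctx5[need] <- looked$f5
      ctx3[need] <- looked$f3
    }
  }
  resolvable <- !is.na(ctx5) & !is.na(ctx3) &
    ctx5 %in% BASES & ctx3 %in% BASES
  n_skipped <- sum(!resolvable)
  if (n_skipped > 0) {
    message("build_profile_matrix: skipped ", n_skipped,
            " records with unresolvable or N context")
  }
  rec <- records[resolvable, , drop = FALSE]
  feat <- normalize_substitution(rec$ref, rec$alt, ctx5[resolvable], ctx3[resolvable])
  ctxs <- sbs96_contexts()
  samples <- unique(rec$sample_id)
  if (include_missing) samples <- union(samples, clinical$sample_id)
  counts <- matrix(0L, length(samples), 96,
                   dimnames = list(samples, ctxs))
  if (nrow(rec)) {
    t <- table(factor(rec$sample_id, levels = samples),
               factor(feat, levels = ctxs))
    counts <- matrix(as.integer(t), nrow(t), 96, dimnames = dimnames(counts))
  }
  idx <- match(samples, clinical$sample_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " sample(s) missing from clinical table; ",
            "age/tissue set to NA")
  }
  meta <- clinical[idx, , drop = FALSE]
  meta$sample_id <- samples
  rownames(meta) <- NULL
  if (is.null(meta$age)) meta$age <- NA_real_
  if (is.null(meta$tissue)) meta$tissue <- NA_character_
  new_profiles(counts, meta)
}

lookup_context <- function(chrom, pos, seqs) {
  f5 <- f3 <- rep(NA_character_, length(chrom))
  for (i in seq_along(chrom)) {
    s <- seqs[[chrom[i]]]
    if (is.null(s) || is.na(s)) next
    if (pos[i] <= 1 || pos[i] >= nchar(s)) {
      warning("record at contig boundary skipped (", chrom[i], ":", pos[i], ")")
      next
    }
    f5[i] <- toupper(substr(s, pos[i] - 1, pos[i] - 1))
    f3[i] <- toupper(substr(s, pos[i] + 1, pos[i] + 1))
  }
  list(f5 = f5, f3 = f3)
}

# mut_profiles container -------------------------------------------------

new_profiles <- function(counts, meta) {
  stopifnot(ncol(counts) == 96, nrow(counts) == nrow(meta))
  structure(list(counts = counts, meta = meta), class = "mut_profiles")
}

#' Construct a profile container from a count matrix and metadata
#'
#' @param counts Samples x 96 matrix, columns in [sbs96_contexts()] order
#'   (reordered by name if column names are present).
#' @param meta Data frame with at least \code{sample_id} and \code{age};
#'   additional columns are treated as exposure annotations.
#' @return A \code{"mut_profiles"} object.
#' @export
mut_profiles <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts))) {
    miss <- setdiff(sbs96_contexts(), colnames(counts))
    if (length(miss)) stop("count matrix missing context column: ", miss[1])
    counts <- counts[, sbs96_contexts(), drop = FALSE]
  } else {
    colnames(counts) <- sbs96_contexts()
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(meta$sample_id)) stop("meta must have a sample_id column")
  rownames(counts) <- meta$sample_id
  if (is.null(meta$age)) meta$age <- NA_real_
  new_profiles(counts, meta)
}

#' @export
print.mut_profiles <- function(x, ...) {
  cat("Mutation profiles: ", nrow(x$counts), " samples x 96 contexts\n", sep = "")
  tot <- rowSums(x$counts)
  cat(sprintf("  total mutations: median %.0f (range %.0f-%.0f)\n",
              stats::median(tot), min(tot), max(tot)))
  extra <- setdiff(names(x$meta), c("sample_id", "age", "tissue"))
  if (length(extra)) cat("  annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.mut_profiles` <- function(x, i, ...) {
  new_profiles(x$counts[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Number of samples in a profile container
#' @param x A \code{"mut_profiles"} object.
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$counts)

#' Per-sample total mutation counts
#' @param x A \code{"mut_profiles"} object.
#' @return Named integer vector.
#' @export
total_mutations <- function(x) rowSums(x$counts)

#' Write / read a profile matrix as TSV
#'
#' Rows are samples; the first columns carry the clinical metadata, then
#' the 96 context counts in canonical order.
#'
#' @param x A \code{"mut_profiles"} object.
#' @param path Output path.
#' @return \code{write_profiles} returns \code{path} invisibly;
#'   \code{read_profiles} returns a \code{"mut_profiles"} object.
#' @export
write_profiles <- function(x, path) {
  df <- cbind(x$meta, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ctx <- sbs96_contexts()
  miss <- setdiff(ctx, names(df))
  if (length(miss)) stop("profile TSV missing context column: ", miss[1])
  counts <- as.matrix(df[, ctx, drop = FALSE])
  meta <- df[, setdiff(names(df), ctx), drop = FALSE]
  mut_profiles(counts, meta)
}
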