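# Cohort assembly: sample-level filtering rules and exposed/unexposed
# group definitions for each etiological factor.

#' Filtering configuration
#'
#' @param hypermutator_multiplier Samples whose mutational load is strictly
#'   more than this multiple of the median load among unexposed samples are
#'   removed (default 3). Set \code{times_higher = TRUE} to read "3 times
#'   higher than the median" as median + 3*median = 4x instead.
#' @param min_total Samples with fewer total mutations are removed
#'   (default 1, i.e. zero-mutation samples go).
#' @param excluded_flags Clinical flag columns whose carriers are removed
#'   unless the flag is the factor under study (default MSI and the
#'   POLE/POLD family).
#' @param aml_min_age Minimum age for acute myeloid leukemia samples
#'   (tissue code \code{"LAML"}; default 40 -- adult AML only).
#' @param times_higher Interpretation switch for the hypermutator rule.
#' @return A \code{"filter_config"} list.
#' @export
filter_config <- function(hypermutator_multiplier = 3, min_total = 1,
                          excluded_flags = c("MSI", "POLE", "POLD"),
                          aml_min_age = 40, times_higher = FALSE) {
  stopifnot(hypermutator_multiplier > 0)
  structure(list(hypermutator_multiplier = hypermutator_multiplier,
                 min_total = min_total, excluded_flags = excluded_flags,
                 aml_min_age = aml_min_age, times_higher = times_higher),
            class = "filter_config")
}

# Exposure columns: clinical columns other than identifiers; binary-coded
# columns (0/1, yes/no, TRUE/FALSE) define "recorded exposure".
exposure_columns <- function(meta) {
  setdiff(names(meta), c("sample_id", "age", "tissue", "bmi", "BMI"))
}

exposure_matrix <- function(meta) {
  cols <- exposure_columns(meta)
  m <- matrix(FALSE, nrow(meta), length(cols), dimnames = list(NULL, cols))
  for (cc in cols) {
    v <- meta[[cc]]
    m[, cc] <- !is.na(v) & (v %in% c(1, "1", TRUE, "yes", "Yes", "Y", "exposed"))
  }
  m
}

#' Apply the cohort filtering rules
#'
#' Removes, in order: (i) samples with fewer than \code{min_total} exome
#' mutations (zero load suggests low neoplastic cell content); (ii)
#' samples flagged MSI or POLE/POLD-mutant, unless that flag is the factor
#' under study; (iii) AML (\code{"LAML"}) samples younger than
#' \code{aml_min_age}; (iv) exposed samples with more than one recorded
#' exposure; (v) hypermutators, i.e. samples whose load strictly exceeds
#' \code{hypermutator_multiplier} times the median load of the unexposed
#' samples (samples with no recorded exposure count as unexposed).
#'
#' Filtering is idempotent: running it on an already-filtered cohort
#' removes nothing.
#'
#' @param profiles A \code{"mut_profiles"} object.
#' @param factor Factor under study (its flag column, if any, is exempt
#'   from rule ii and does not count as an extra exposure in rule iv).
#' @param cfg A [filter_config()].
#' @return The retained \code{"mut_profiles"}; attribute
#'   \code{"exclusions"} is a data frame (sample_id, reason).
#' @export
filter_samples <- function(profiles, factor = NULL, cfg = filter_config()) {
  meta <- profiles$meta
  load <- total_mutations(profiles)
  n <- length(load)
  reason <- rep(NA_character_, n)

  mark <- function(ix, why) {
    new <- ix[is.na(reason[ix])]
    reason[new] <<- why
  }

  mark(which(load < cfg$min_total), "zero or below-minimum mutation load")

  flag_cols <- names(meta)[toupper(names(meta)) %in% toupper(cfg$excluded_flags) |
                             grepl("^POLE|^POLD", toupper(names(meta)))]
  flag_cols <- setdiff(flag_cols, factor)
  for (fc in flag_cols) {
    v <- meta[[fc]]
    flagged <- !is.na(v) & (v %in% c(1, "1", TRUE, "yes", "Yes", "Y"))
    mark(which(flagged), "MSI/POLE/POLD flag")
  }

  if (!is.null(meta$tissue) && !is.null(meta$age)) {
    mark(which(meta$tissue %in% c("LAML", "AML") & !is.na(meta$age) &
                 meta$age < cfg$aml_min_age), "AML younger than minimum age")
  }

  em_all <- exposure_matrix(meta)
  n_exposures <- if (ncol(em_all)) rowSums(em_all) else rep(0, n)
  mark(which(n_exposures > 1), "multiple recorded exposures")
  # unexposed = no recorded exposure at all
  unexposed <- n_exposures == 0 & is.na(reason)
  if (!any(unexposed)) stop("no unexposed samples: cannot compute median load")
  med <- stats::median(load[unexposed])
  mult <- if (cfg$times_higher) 1 + cfg$hypermutator_multiplier else cfg$hypermutator_multiplier
  mark(which(load > mult * med), "hypermutator (load above multiple of unexposed median)")

  keep <- is.na(reason)
  excl <- data.frame(sample_id = meta$sample_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  out <- profiles[keep]
  attr(out, "exclusions") <- excl
  out
}

#' Write the exclusion report
#' @param profiles Output of [filter_samples()].
#' @param path TSV output path.
#' @export
write_exclusion_report <- function(profiles, path) {
  excl <- attr(profiles, "exclusions")
  if (is.null(excl)) excl <- data.frame(sample_id = character(), reason = character())
  utils::write.table(excl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define exposed and unexposed groups for a factor
#'
#' Rules: \code{"age-tertile"} splits the age distribution at its
#' empirical 1/3 and 2/3 quantiles (type-7), labelling the middle tertile
#' \code{"excluded"} (ties at a cut-point go to the lower group);
#' \code{"bmi-threshold"} labels BMI >= 30 exposed (obese);
#' \code{"burden-percentile"} labels the lowest \code{floor(n * q)} samples
#' by total mutation count unexposed and the rest exposed (the UV proxy
#' uses q = 0.10, asbestos q = 0.33); \code{"binary-annotation"} reads the
#' factor's clinical column directly. \code{rule = "auto"} picks by factor
#' name (\code{age}, \code{bmi}/\code{obesity}, \code{uv},
#' \code{asbestos}, else binary).
#'
#' @param profiles A \code{"mut_profiles"} object.
#' @param factor Factor name.
#' @param rule One of \code{"auto"}, \code{"binary-annotation"},
#'   \code{"age-tertile"}, \code{"bmi-threshold"},
#'   \code{"burden-percentile"}.
#' @param q Percentile for the burden proxy (defaults by factor name).
#' @return A \code{"group_assignment"}: list with \code{factor},
#'   \code{labels} (named vector over samples:
#'   exposed/unexposed/excluded), and \code{rule}.
#' @export
assign_exposure_groups <- function(profiles, factor,
                                   rule = c("auto", "binary-annotation",
                                            "age-tertile", "bmi-threshold",
                                            "burden-percentile"),
                                   q = NULL) {
  rule <- match.arg(rule)
  meta <- profiles$meta
  lf <- tolower(factor)
  if (rule == "auto") {
    rule <- if (lf == "age") "age-tertile"
    else if (lf %in% c("bmi", "obesity")) "bmi-threshold"
    else if (lf %in% c("uv", "asbestos")) "burden-percentile"
    else "binary-annotation"
  }
  if (is.null(q)) q <- if (lf == "asbestos") 0.33 else 0.10
  n <- n_samples(profiles)
  labels <- rep("unexposed", n)

  if (rule == "age-tertile") {
    age <- meta$age
    if (anyNA(age)) stop("age-tertile rule requires age for every sample")
    cuts <- stats::quantile(age, c(1 / 3, 2 / 3), type = 7, names = FALSE)
    labels[age <= cuts[1]] <- "unexposed"            # younger
    labels[age > cuts[1] & age <= cuts[2]] <- "excluded"  # middle-aged
    labels[age > cuts[2]] <- "exposed"               # older
  } else if (rule == "bmi-threshold") {
    col <- if ("bmi" %in% names(meta)) "bmi" else if ("BMI" %in% names(meta)) "BMI"
    else stop("bmi-threshold rule requires a bmi column")
    bmi <- meta[[col]]
    if (anyNA(bmi)) stop("bmi-threshold rule requires BMI for every sample")
    labels <- ifelse(bmi >= 30, "exposed", "unexposed")
  } else if (rule == "burden-percentile") {
    load <- total_mutations(profiles)
    k <- floor(n * q)
    if (k < 1) stop("burden percentile leaves no unexposed samples")
    low <- order(load)[seq_len(k)]  # rank cut; ties broken by order stability
    labels <- rep("exposed", n)
    labels[low] <- "unexposed"
  } else {
    if (!factor %in% names(meta)) stop("no clinical column for factor: ", factor)
    v <- meta[[factor]]
    exposed <- !is.na(v) & v %in% c(1, "1", TRUE, "yes", "Yes", "Y", "exposed")
    labels <- ifelse(exposed, "exposed", "unexposed")
  }
  if (length(unique(labels[labels != "excluded"])) < 2)
    stop("degenerate design: all samples in one class")
  structure(list(factor = factor,
                 labels = stats::setNames(labels, meta$sample_id),
                 rule = rule),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment for '", x$factor, "' (rule: ", x$rule, ")\n", sep = "")
  print(table(x$labels))
  invisible(x)
}
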