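# Synthetic TCGA-like cohorts with known ground truth: per-sample
# 96-context counts are Poisson with mean age x per-year context rate,
# exposure effects multiply (or add to) the rates of chosen lattice
# features. Everything the tests and acceptance harness consume is
# generated here, no downloads involved.

#' Specify a synthetic cohort
#'
#' Defaults state a TCGA-exome-like world: 200 exposed and 200 unexposed
#' samples, ages uniform on 40-80 years, a total mutation rate of 4
#' mutations/year (so a 60-year-old carries ~240 exome mutations, in the
#' range of carcinogen-exposed TCGA exome cohorts) distributed over the 96
#' contexts proportionally to the background frequencies. The rate was
#' fixed by a design-stage power analysis: it is the regime in which a
#' single trinucleotide feature with a threefold rate elevation is
#' detectable (population AUC of the planted feature ~0.95), the canonical
#' validation scenario for the pipeline. Exposure effects are expressed per lattice feature: a
#' multiplicative factor elevates the rate of every leaf context the
#' feature covers in exposed samples.
#'
#' @param n_exposed,n_unexposed Cohort arm sizes.
#' @param age_range Uniform age range in years (or a fixed list of ages via
#'   \code{ages}).
#' @param total_rate Total mutations per year in unexposed samples.
#' @param baseline_rates Optional explicit 96-vector of per-year rates
#'   (overrides \code{total_rate}/\code{bg}).
#' @param bg Background used to apportion \code{total_rate} (defaults to
#'   the packaged exome-like table, matching the analysis null).
#' @param effects Named list: feature name -> multiplicative rate factor
#'   (e.g. \code{list("A[C>T]G" = 3)}); or a list of lists with fields
#'   \code{feature}, \code{factor} and/or \code{add} (additive rate).
#' @param label_noise Fraction of labels flipped after generation.
#' @param overdispersion Optional negative-binomial size parameter; NULL =
#'   Poisson counts.
#' @param ages Optional explicit ages (recycled per arm).
#' @param tissue Tissue code stamped on the samples.
#' @param seed Integer seed.
#' @return A \code{"cohort_spec"} list.
#' @export
cohort_spec <- function(n_exposed = 200, n_unexposed = 200,
                        age_range = c(40, 80), total_rate = 4,
                        baseline_rates = NULL,
                        bg = background_frequencies("exome"),
                        effects = list(), label_noise = 0,
                        overdispersion = NULL, ages = NULL,
                        tissue = "SYN", seed = 1L) {
  lat <- feature_lattice()
  effects <- normalize_effects(effects, lat)
  if (is.null(baseline_rates)) {
    baseline_rates <- leaf_null_probs(bg) * total_rate
  } else {
    stopifnot(length(baseline_rates) == 96)
    baseline_rates <- stats::setNames(as.numeric(baseline_rates), sbs96_contexts())
  }
  if (any(baseline_rates < 0)) stop("rates must be non-negative")
  stopifnot(label_noise >= 0, label_noise <= 1)
  structure(list(n_exposed = n_exposed, n_unexposed = n_unexposed,
                 age_range = age_range, ages = ages,
                 baseline_rates = baseline_rates, effects = effects,
                 label_noise = label_noise, overdispersion = overdispersion,
                 tissue = tissue, seed = seed),
            class = "cohort_spec")
}

normalize_effects <- function(effects, lat) {
  out <- list()
  if (!length(effects)) return(out)
  if (!is.null(names(effects)) && all(nzchar(names(effects))) &&
      all(vapply(effects, is.numeric, NA))) {
    for (nm in names(effects)) out[[length(out) + 1L]] <-
        list(feature = nm, factor = as.numeric(effects[[nm]]), add = 0)
  } else {
    for (e in effects) {
      out[[length(out) + 1L]] <- list(feature = e$feature,
                                      factor = if (is.null(e$factor)) 1 else e$factor,
                                      add = if (is.null(e$add)) 0 else e$add)
    }
  }
  for (e in out) {
    if (!e$feature %in% lat$names)
      stop("effect references unknown feature: ", e$feature)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Per sample: draw age, then per context j a count ~ Poisson(age x
#' rate_j), with rate_j elevated in exposed samples according to the
#' spec's effects (an effect on a non-leaf feature elevates all leaf
#' contexts it covers). The truth record (attribute \code{"truth"})
#' stores all parameters.
#'
#' @param spec A [cohort_spec()].
#' @return A \code{"mut_profiles"} object with meta columns
#'   \code{sample_id}, \code{age}, \code{tissue}, \code{exposure} (0/1).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  lat <- feature_lattice()
  n <- spec$n_exposed + spec$n_unexposed
  exposed <- c(rep(1L, spec$n_exposed), rep(0L, spec$n_unexposed))
  age <- if (!is.null(spec$ages)) rep_len(spec$ages, n)
  else stats::runif(n, spec$age_range[1], spec$age_range[2])
  rate_un <- spec$baseline_rates
  rate_ex <- rate_un
  for (e in spec$effects) {
    ix <- lat$leaf_sets[[e$feature]]
    rate_ex[ix] <- rate_ex[ix] * e$factor + e$add
  }
  counts <- matrix(0L, n, 96, dimnames = list(NULL, sbs96_contexts()))
  for (i in seq_len(n)) {
    mu <- age[i] * (if (exposed[i] == 1L) rate_ex else rate_un)
    counts[i, ] <- if (is.null(spec$overdispersion)) stats::rpois(96, mu)
    else stats::rnbinom(96, size = spec$overdispersion, mu = mu)
  }
  labels <- exposed
  if (spec$label_noise > 0) {
    labels <- perturb_labels(exposed, "mislabel", spec$label_noise)
  }
  meta <- data.frame(sample_id = sprintf("SYN-%04d", seq_len(n)),
                     age = age, tissue = spec$tissue, exposure = labels,
                     stringsAsFactors = FALSE)
  out <- mut_profiles(counts, meta)
  attr(out, "truth") <- list(spec = spec, true_exposure = exposed,
                             rate_unexposed = rate_un, rate_exposed = rate_ex)
  out
}

#' Write a cohort as MAF-like fixture files
#'
#' Emits \code{mutations.tsv} (MAF-compatible columns plus a CONTEXT
#' 3-mer; allele counts set so every VAF is 0.30, above the default
#' filter) and \code{clinical.tsv}, round-trippable through
#' [read_mutation_table()] / [build_profile_matrix()] with exact count
#' recovery. Mutations are placed at arbitrary positions on a synthetic
#' contig; roughly half are written on the purine strand so that
#' pyrimidine normalization is exercised.
#'
#' @param profiles A non-empty \code{"mut_profiles"} object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths.
#' @export
write_fixtures <- function(profiles, dir) {
  if (n_samples(profiles) == 0) stop("empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- sbs96_contexts()
  parts <- split_context(ctx)
  rows <- which(profiles$counts > 0, arr.ind = TRUE)
  idx <- rep(seq_len(nrow(rows)), profiles$counts[rows])
  samp <- rownames(profiles$counts)[rows[idx, 1]]
  cj <- rows[idx, 2]
  m <- length(cj)
  ref <- parts[cj, "ref"]
  alt <- parts[cj, "alt"]
  f5 <- parts[cj, "f5"]
  f3 <- parts[cj, "f3"]
  # write alternating records on the purine strand (reverse complement)
  flip <- seq_len(m) %% 2 == 0
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  tmp <- f5[flip]
  f5[flip] <- COMPLEMENT[f3[flip]]
  f3[flip] <- COMPLEMENT[tmp]
  maf <- data.frame(Tumor_Sample_Barcode = samp,
                    Chromosome = "chrSYN",
                    Start_Position = seq_len(m) * 10L,
                    Reference_Allele = ref,
                    Tumor_Seq_Allele2 = alt,
                    t_ref_count = 70L, t_alt_count = 30L,
                    CONTEXT = paste0(f5, ref, f3),
                    stringsAsFactors = FALSE)
  mut_path <- file.path(dir, "mutations.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  utils::write.table(maf, mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profiles$meta, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(mutations = mut_path, clinical = clin_path)
}
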