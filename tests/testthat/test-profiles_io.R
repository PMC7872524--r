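test_that("pyrimidine-strand normalization follows the reverse-complement convention", {
  expect_equal(normalize_substitution("C", "T", "A", "G"), "A[C>T]G")
  expect_equal(normalize_substitution("G", "A", "T", "A"), "T[C>T]A")
  expect_equal(normalize_substitution("A", "C", "T", "G"), "C[T>G]A")
  expect_error(normalize_substitution("C", "C", "A", "A"), "ref equals alt")
  expect_true(is.na(normalize_substitution("C", "T", "N", "G")))
})

test_that("normalization is involution-respecting: a record and its reverse-complement map to the same name", {
  set.seed(11)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:200) {
    b <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    ref <- b[1]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- normalize_substitution(ref, alt, b[2], b[3])
    rc <- normalize_substitution(comp[ref], comp[alt], comp[b[3]], comp[b[2]])
    expect_identical(fwd, rc)
  }
})

test_that("canonical context order is substitution-major with lexicographic flanks", {
  ctx <- sbs96_contexts()
  expect_length(ctx, 96)
  expect_identical(ctx[1], "A[C>A]A")
  expect_identical(ctx[2], "A[C>A]C")
  expect_identical(ctx[5], "C[C>A]A")
  expect_identical(ctx[17], "A[C>G]A")
  expect_identical(ctx[96], "T[T>G]T")
  expect_false(anyDuplicated(ctx) > 0)
})

test_that("the VAF filter removes strictly-below-threshold records only", {
  maf <- data.frame(Tumor_Sample_Barcode = c("S1", "S1", "S1"),
                    Chromosome = "chr1", Start_Position = c(100, 200, 300),
                    Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
                    t_ref_count = c(96, 95, 50), t_alt_count = c(4, 5, 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- suppressMessages(read_mutation_table(path))
  # vaf 0.04 excluded; vaf exactly 0.05 retained; order preserved
  expect_equal(recs$position, c(200, 300))
  expect_equal(attr(recs, "dropped")[["low_vaf"]], 1L)
})

test_that("mutation table edge cases: empty table, missing column, bad vaf", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- data.frame(Tumor_Sample_Barcode = character(), Chromosome = character(),
                    Start_Position = integer(), Reference_Allele = character(),
                    Tumor_Seq_Allele2 = character())
  write.table(hdr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_mutation_table(path)), 0L)

  bad <- data.frame(Tumor_Sample_Barcode = "S1", Chromosome = "chr1",
                    Start_Position = 1, Reference_Allele = "C")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "Tumor_Seq_Allele2")

  bad2 <- data.frame(Tumor_Sample_Barcode = "S1", Chromosome = "chr1",
                     Start_Position = 1, Reference_Allele = "C",
                     Tumor_Seq_Allele2 = "T", vaf = "oops")
  write.table(bad2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutation_table(path), "row 1")
})

test_that("profile building: single record, conservation, N-context skipping", {
  recs <- data.frame(sample_id = c("S", "S", "S"), chromosome = "c",
                     position = c(1, 2, 3) * 10, ref = c("C", "G", "C"),
                     alt = c("A", "A", "T"), vaf = 0.5,
                     context5 = c("T", "T", "N"), context3 = c("G", "A", "A"),
                     stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = "S", age = 50, tissue = "TST")
  prof <- suppressMessages(build_profile_matrix(recs, clinical))
  expect_equal(sum(prof$counts), 2)  # N-context record skipped
  expect_equal(unname(prof$counts[1, "T[C>A]G"]), 1L)
  expect_equal(unname(prof$counts[1, "T[C>T]A"]), 1L)  # G>A reverse-complemented
  expect_equal(unname(total_mutations(prof)), 2)
})

test_that("FASTA context lookup resolves flanks and skips contig boundaries", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrZ", "ACGTA"), fa)
  recs <- data.frame(sample_id = "S", chromosome = "chrZ",
                     position = c(2, 1), ref = "C", alt = "T", vaf = 0.5,
                     context5 = NA_character_, context3 = NA_character_,
                     stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = "S", age = 50, tissue = "TST")
  prof <- suppressWarnings(suppressMessages(
    build_profile_matrix(recs, clinical, fasta = fa)))
  # position 2 has flanks A and G; position 1 is at the boundary -> skipped
  expect_equal(sum(prof$counts), 1)
  expect_equal(unname(prof$counts[1, "A[C>T]G"]), 1L)
})

test_that("column sums of the profile matrix equal the multiset of normalized features", {
  coh <- planted_cohort(n = 20, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(coh, dir)
  recs <- suppressMessages(read_mutation_table(paths[["mutations"]]))
  feats <- normalize_substitution(recs$ref, recs$alt, recs$context5, recs$context3)
  prof <- suppressMessages(build_profile_matrix(
    recs, read_clinical_table(paths[["clinical"]])))
  tab <- table(factor(feats, levels = sbs96_contexts()))
  expect_equal(unname(colSums(prof$counts)), as.vector(tab))
})

test_that("background frequencies: degenerate, symmetric, and conservation cases", {
  all_c <- background_frequencies(strrep("C", 50))
  expect_equal(bg_aggregate(all_c, "C"), 1)
  expect_equal(bg_aggregate(all_c, "T"), 0)

  # all 64 trinucleotides equally frequent -> each pyrimidine class 1/32
  bg_u <- uniform_bg()
  expect_equal(unname(bg_u$tri), rep(1 / 32, 32))
  expect_equal(bg_aggregate(bg_u, "C"), 1 / 2)

  # conservation: freq(C) is the sum of the 16 central-C classes
  bgx <- background_frequencies("exome")
  ctr_c <- substr(tri32_classes(), 2, 2) == "C"
  expect_equal(bg_aggregate(bgx, "C"), sum(bgx$tri[ctr_c]))
  expect_equal(bg_aggregate(bgx, "C") + bg_aggregate(bgx, "T"), 1)
  expect_error(background_frequencies("CG"), "shorter than 3")
})

test_that("profile TSV round trip preserves counts and metadata", {
  coh <- planted_cohort(n = 10, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(coh, path)
  back <- read_profiles(path)
  expect_equal(back$counts, coh$counts)
  expect_equal(back$meta$age, coh$meta$age)
})
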