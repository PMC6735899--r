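test_that("index construction counts and validates", {
  ref <- make_test_ref(n_codons = 100, seed = 20)
  idx <- build_index(ref, k = 31)
  L <- nchar(amplicon(ref))
  expect_lte(sum(lengths(idx$map)), 2 * (L - 30))
  expect_error(build_index(ref, k = 0), ">= 1")
  expect_error(build_index(ref, k = L + 1), "exceeds")
  # degenerate reference: many-to-one map is still valid
  aaa <- orf_reference(strrep("AAA", 30))
  idx2 <- build_index(aaa, k = 5)
  expect_identical(length(idx2$map), 1L)
  expect_identical(length(idx2$map[[1]]), 86L)
})

test_that("single-read alignment honors the unique/<=1-mismatch contract", {
  ref <- make_test_ref(n_codons = 100, seed = 21)
  amp <- amplicon(ref)
  idx <- build_index(ref)

  exact <- substr(amp, 50, 149)
  a <- align_read(idx, exact)
  expect_identical(a$status, "unique")
  expect_identical(a$pos, 50L)
  expect_identical(a$strand, "+")
  expect_identical(a$n_mismatch, 0L)

  two <- exact
  substr(two, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(two, 10, 10))[1]
  substr(two, 70, 70) <- setdiff(c("A", "C", "G", "T"), substr(two, 70, 70))[1]
  expect_identical(align_read(idx, two)$status, "too_many_mismatches")

  short <- substr(amp, 1, 20)  # shorter than k: unmapped, not an error
  expect_identical(align_read(idx, short)$status, "unmapped")
  expect_identical(align_read(idx, strrep("ACGT", 25))$status, "unmapped")
})

test_that("reads from a duplicated segment are ambiguous, never unique", {
  ref <- make_dup_ref()
  idx <- build_index(ref)
  amp <- amplicon(ref)
  # a read wholly inside the duplicated block (ORF positions 34..153)
  read <- substr(amp, nchar(ref$flank5) + 40, nchar(ref$flank5) + 139)
  a <- align_read(idx, read)
  expect_identical(a$status, "ambiguous")
})

test_that("strand symmetry: a read and its reverse complement give the same call", {
  ref <- make_test_ref(n_codons = 100, seed = 22)
  amp <- amplicon(ref)
  idx <- build_index(ref)
  read <- substr(amp, 40, 139)
  mpos <- 30L
  substr(read, mpos, mpos) <- setdiff(c("A", "C", "G", "T"), substr(read, mpos, mpos))[1]
  fwd <- align_read(idx, read)
  rev <- align_read(idx, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read))))
  expect_identical(fwd$status, "unique")
  expect_identical(rev$status, "unique")
  expect_identical(fwd$pos, rev$pos)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "-")
  expect_identical(fwd$mismatches[, c("orf_pos", "ref_base", "read_base")],
                   rev$mismatches[, c("orf_pos", "ref_base", "read_base")])
})

test_that("a best 0-mismatch placement stays unique despite secondary 1-mismatch loci", {
  # amplicon contains a block and a 1-substitution copy of it: a read equal to
  # the original block has placements at 0 and 1 mismatches -> unique at 0
  set.seed(23)
  block <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  near <- block
  substr(near, 45, 45) <- setdiff(c("A", "C", "G", "T"), substr(near, 45, 45))[1]
  ref <- orf_reference(strrep("ATG", 30), flank5 = block, flank3 = near)
  a <- align_read(build_index(ref, k = 31), block)
  expect_identical(a$status, "unique")
  expect_identical(a$pos, 1L)
  expect_identical(a$n_mismatch, 0L)
})

test_that("N bases count as mismatches but are never reported as observations", {
  ref <- make_test_ref(n_codons = 100, seed = 24)
  amp <- amplicon(ref)
  idx <- build_index(ref)
  read <- substr(amp, 30, 129)
  substr(read, 50, 50) <- "N"
  a <- align_read(idx, read)
  expect_identical(a$status, "unique")
  expect_identical(a$n_mismatch, 1L)
  expect_identical(nrow(a$mismatches), 0L)
  # N plus a real substitution exceeds the mismatch budget
  substr(read, 80, 80) <- setdiff(c("A", "C", "G", "T"), substr(read, 80, 80))[1]
  expect_identical(align_read(idx, read)$status, "too_many_mismatches")
})

test_that("flank mismatches are counted but produce no ORF observation", {
  ref <- make_test_ref(n_codons = 100, seed = 25, flank = 40)
  amp <- amplicon(ref)
  idx <- build_index(ref)
  read <- substr(amp, 1, 100)          # starts inside flank5
  substr(read, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(read, 10, 10))[1]
  a <- align_read(idx, read)
  expect_identical(a$status, "unique")
  expect_identical(a$n_mismatch, 1L)
  expect_identical(nrow(a$mismatches), 0L)
})

test_that("batch alignment summarizes statuses and validates FASTQ", {
  ref <- make_test_ref(n_codons = 100, seed = 26)
  idx <- build_index(ref)

  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  s <- align_batch(idx, empty)$summary
  expect_identical(s$n_reads, 0L)
  expect_identical(s$n_unique, 0L)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-missing-at", "ACGT", "+", "IIII"), bad)
  expect_error(align_batch(idx, bad), "record 2")

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), trunc)
  expect_error(align_batch(idx, trunc), "record 1")

  q64 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "hhhh"), q64)  # Phred+64-style scores
  expect_error(align_batch(idx, q64), "Phred\\+33")
})

test_that("error-free reads from the reference allele alone carry no mismatches", {
  ref <- make_test_ref(n_codons = 100, seed = 27)
  pool <- structure(list(mutant_allele("wt")), class = "mutant_pool", ref_id = ref$id)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(ref, pool, read_sim_config(2000, read_length = 100,
                                            fragment_min = 120, fragment_max = 200,
                                            error_coupling = FALSE, seed = 28), fq)
  res <- align_batch(idx <- build_index(ref), fq)
  expect_identical(res$summary$n_unique, 2000L)
  expect_identical(res$summary$n_unique_with_mismatch, 0L)
  expect_identical(res$summary$frac_unique_with_mismatch, 0)
})

test_that("SAM and mismatch-file outputs are well-formed and round-trip", {
  ref <- make_test_ref(n_codons = 60, seed = 29)
  pool <- mutagenize(ref, mutagenesis_config(mean_mutations = 1, seed = 30), 30)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(ref, pool, read_sim_config(500, read_length = 80,
                                            fragment_min = 100, fragment_max = 150,
                                            error_coupling = FALSE, seed = 31), fq)
  mm <- withr::local_tempfile(fileext = ".tsv")
  sam <- withr::local_tempfile(fileext = ".sam")
  res <- align_batch(build_index(ref), fq, mismatch_out = mm, sam_out = sam)
  back <- res$mismatches
  rownames(back) <- NULL
  expect_identical(read_mismatches(mm), back)
  lines <- readLines(sam)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(startsWith(lines[2], "@SQ"))
  body <- strsplit(lines[-(1:2)], "\t")
  expect_true(all(lengths(body) >= 11L))
  flags <- as.integer(vapply(body, `[[`, "", 2L))
  expect_true(all(flags %in% c(0L, 4L, 16L)))
})

test_that("aligner agrees with the brute-force all-offset oracle", {
  ref <- make_dup_ref()
  reads <- make_random_reads(ref, 2000, len = 64, seed = 32, max_subs = 3)
  fq <- withr::local_tempfile(fileext = ".fastq")
  ids <- write_test_fastq(reads, fq)
  got <- align_batch(build_index(ref, k = 31), fq, keep_records = TRUE)$records
  want <- oracle_align(ref, reads, k = 31)
  expect_identical(got$status, want$status)
  u <- which(want$status == "unique")
  expect_gt(length(u), 200)
  expect_identical(got$pos[u], want$pos[u])
  expect_identical(got$strand[u], want$strand[u])
  expect_identical(got$n_mismatch[u], want$n_mismatch[u])
  # no false uniqueness anywhere
  expect_false(any(got$status == "unique" & want$status == "ambiguous"))
})
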