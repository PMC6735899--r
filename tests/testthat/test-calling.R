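test_that("Phred scores convert to base-calling confidence", {
  expect_identical(round(quality_confidence(38), 2), 99.98)
  expect_identical(quality_confidence(0), 0)
  expect_identical(quality_confidence(10), 90)
  expect_error(quality_confidence(-1), ">= 0")
})

test_that("quality filtering keeps exactly the at-threshold-and-above observations", {
  obs <- data.frame(orf_pos = 1:4, ref_base = "A", read_base = "G",
                    quality = c(37L, 38L, 39L, 0L),
                    read_id = paste0("r", 1:4), stringsAsFactors = FALSE)
  kept <- filter_mismatches(obs, 38)
  expect_identical(kept$quality, c(38L, 39L))
  expect_identical(filter_mismatches(obs, 0), obs)
  empty <- obs[0, ]
  expect_identical(nrow(filter_mismatches(empty, 38)), 0L)
})

test_that("supporting reads are counted per distinct read and ranked", {
  ref <- orf_reference("ATGGAAGCTCTGTGG")
  obs <- data.frame(
    orf_pos = c(4L, 4L, 4L, 4L, 8L),
    ref_base = c("G", "G", "G", "G", "C"),
    read_base = c("A", "A", "A", "A", "T"),
    quality = 40L,
    read_id = c("r1", "r2", "r3", "r3", "r5"),  # r3 duplicated on purpose
    stringsAsFactors = FALSE)
  tab <- call_and_rank(ref, obs, caller_config())
  expect_identical(tab$rank, 1:2)
  expect_identical(tab$supporting_reads, c(3L, 1L))  # r3 counted once
  expect_identical(tab$orf_pos, c(4L, 8L))
  expect_identical(attr(tab, "threshold_reads"), 1L)
  tot <- attr(tab, "totals")
  expect_identical(tot$mismatch_reads_in, 4L)
  expect_identical(tot$calls_passing_quality, 5L)
})

test_that("ties break deterministically by residue then alternate amino acid", {
  ref <- make_test_ref(n_codons = 60, seed = 40)
  obs <- make_random_obs(ref, 300, seed = 41)
  obs$quality <- 40L
  t1 <- call_and_rank(ref, obs, caller_config(top_n = 1000, include_synonymous = TRUE))
  t2 <- call_and_rank(ref, obs, caller_config(top_n = 1000, include_synonymous = TRUE))
  expect_identical(t1, t2)
  # within equal supporting counts, residues ascend
  for (s in unique(t1$supporting_reads)) {
    grp <- t1[t1$supporting_reads == s, ]
    expect_identical(grp$residue, sort(grp$residue))
  }
})

test_that("truncation, threshold and boundary ties behave as specified", {
  ref <- orf_reference(strrep("GAATGGCTT", 20))  # plenty of codons
  mk <- function(pos, alt, n_reads, offset) {
    data.frame(orf_pos = pos, ref_base = substr(ref$seq, pos, pos),
               read_base = alt, quality = 40L,
               read_id = sprintf("r%d_%d", offset, seq_len(n_reads)),
               stringsAsFactors = FALSE)
  }
  # supporting counts 5, 3, 3, 3 over four distinct substitutions
  obs <- rbind(mk(1L, "T", 5L, 1), mk(2L, "T", 3L, 2),
               mk(10L, "A", 3L, 3), mk(20L, "C", 3L, 4))
  tab <- call_and_rank(ref, obs, caller_config(top_n = 2, include_synonymous = TRUE))
  expect_identical(nrow(tab), 2L)
  expect_identical(attr(tab, "threshold_reads"), 3L)
  annex <- attr(tab, "boundary_ties")
  expect_identical(nrow(annex), 2L)
  expect_true(all(annex$supporting_reads == 3L))

  # top_n larger than the table: truncation is a no-op
  tab2 <- call_and_rank(ref, obs, caller_config(top_n = 100, include_synonymous = TRUE))
  expect_identical(nrow(tab2), 4L)
  expect_identical(attr(tab2, "threshold_reads"),
                   tab2$supporting_reads[nrow(tab2)])
  expect_null(attr(tab2, "boundary_ties"))
  expect_identical(tab2$rank, 1:4)
})

test_that("synonymous and stop handling follow the caller flags", {
  ref <- orf_reference("ATGGAAGCTCTGTGG")
  obs <- data.frame(
    orf_pos = c(12L, 15L), ref_base = c("G", "G"), read_base = c("A", "A"),
    quality = 40L, read_id = c("r1", "r2"), stringsAsFactors = FALSE)
  # CTG->CTA is synonymous; TGG->TGA is a stop gain
  def <- call_and_rank(ref, obs, caller_config())
  expect_identical(nrow(def), 1L)
  expect_identical(def$alt_aa, "*")
  with_syn <- call_and_rank(ref, obs, caller_config(include_synonymous = TRUE))
  expect_identical(nrow(with_syn), 2L)
  expect_true(any(with_syn$synonymous))
  no_stop <- call_and_rank(ref, obs, caller_config(include_stops = FALSE))
  expect_identical(nrow(no_stop), 0L)
})

test_that("corrupt observations are rejected with the position named", {
  ref <- orf_reference("ATGGAA")
  obs <- data.frame(orf_pos = 2L, ref_base = "C", read_base = "A",
                    quality = 40L, read_id = "r1", stringsAsFactors = FALSE)
  expect_error(call_and_rank(ref, obs), "position 2")
  out <- data.frame(orf_pos = 9L, ref_base = "A", read_base = "C",
                    quality = 40L, read_id = "r1", stringsAsFactors = FALSE)
  expect_error(call_and_rank(ref, out), "outside the ORF")
})

test_that("call tables round-trip through TSV and VCF export is well-formed", {
  ref <- make_test_ref(n_codons = 60, seed = 42)
  obs <- make_random_obs(ref, 400, seed = 43)
  tab <- call_and_rank(ref, obs, caller_config(min_quality = 20, top_n = 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(tab, path)
  back <- read_calls(path)
  as_plain <- function(d) {
    d <- as.data.frame(d)
    data.frame(d[seq_along(d)], stringsAsFactors = FALSE)
  }
  expect_identical(as_plain(back), as_plain(tab))
  expect_identical(attr(back, "ref_id"), attr(tab, "ref_id"))
  expect_identical(attr(back, "threshold_reads"), attr(tab, "threshold_reads"))
  expect_identical(back$rank, seq_len(nrow(back)))

  empty <- call_and_rank(ref, obs[0, ], caller_config())
  write_calls(empty, path)
  expect_identical(nrow(read_calls(path)), 0L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(tab, vcf)
  lines <- readLines(vcf)
  expect_identical(sum(!startsWith(lines, "#")), nrow(tab))
  expect_true(all(grepl("SR=\\d+", lines[!startsWith(lines, "#")])))
})

test_that("two nucleotide routes to one amino-acid change collapse correctly", {
  # TTT (F): both T->A and T->G at the third base give Leu
  ref <- orf_reference("ATGTTT")
  obs <- data.frame(orf_pos = 6L, ref_base = "T", read_base = c("A", "A", "G"),
                    quality = 40L, read_id = c("r1", "r2", "r3"),
                    stringsAsFactors = FALSE)
  tab <- call_and_rank(ref, obs, caller_config())
  expect_identical(nrow(tab), 2L)  # nt-level rows kept separate
  aa <- collapse_to_aa(tab)
  expect_identical(nrow(aa), 1L)
  expect_identical(aa$supporting_reads, 3L)
  expect_identical(aa$n_nt_routes, 2L)
  expect_identical(paste0(aa$ref_aa, aa$alt_aa), "FL")
})

test_that("raising the quality threshold shrinks calls monotonically", {
  ref <- make_test_ref(n_codons = 60, seed = 44)
  obs <- make_random_obs(ref, 600, seed = 45)
  lo <- call_and_rank(ref, obs, caller_config(min_quality = 20, top_n = 10000,
                                              include_synonymous = TRUE))
  hi <- call_and_rank(ref, obs, caller_config(min_quality = 35, top_n = 10000,
                                              include_synonymous = TRUE))
  key_lo <- paste(lo$orf_pos, lo$alt_base)
  key_hi <- paste(hi$orf_pos, hi$alt_base)
  expect_true(all(key_hi %in% key_lo))
  m <- match(key_hi, key_lo)
  expect_true(all(hi$supporting_reads <= lo$supporting_reads[m]))
  # conservation: nothing filtered + synonymous included => counts add up
  all_in <- call_and_rank(ref, obs, caller_config(min_quality = 0, top_n = 10000,
                                                  include_synonymous = TRUE))
  expect_identical(sum(all_in$supporting_reads),
                   attr(all_in, "totals")$mismatch_reads_in)
})
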