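# shared fixtures and the independent brute-force alignment oracle

TEST_BASES <- c("A", "C", "G", "T")

# random in-frame reference built from sense codons (ATG start, TAA end)
make_test_ref <- function(n_codons = 60, seed = 1, flank = 20, id = "testref") {
  set.seed(seed)
  cod <- apply(expand.grid(TEST_BASES, TEST_BASES, TEST_BASES), 1, paste, collapse = "")
  sense <- setdiff(cod, c("TAA", "TAG", "TGA"))
  body <- sample(sense, n_codons - 2, replace = TRUE)
  orf_reference(paste0("ATG", paste(body, collapse = ""), "TAA"), id = id,
                flank5 = paste(sample(TEST_BASES, flank, replace = TRUE), collapse = ""),
                flank3 = paste(sample(TEST_BASES, flank, replace = TRUE), collapse = ""))
}

# reference whose amplicon contains an exact internal duplication, so reads
# drawn from the duplicated block have two equally good placements
make_dup_ref <- function(seed = 7, block = 120, n_codons = 120) {
  set.seed(seed)
  cod <- apply(expand.grid(TEST_BASES, TEST_BASES, TEST_BASES), 1, paste, collapse = "")
  sense <- setdiff(cod, c("TAA", "TAG", "TGA"))
  body <- paste(sample(sense, n_codons - 2, replace = TRUE), collapse = "")
  seg <- substr(body, 31, 30 + block)
  # place the duplicate in the 3' flank
  orf_reference(paste0("ATG", body, "TAA"), id = "dupref",
                flank5 = paste(sample(TEST_BASES, 30, replace = TRUE), collapse = ""),
                flank3 = seg)
}

# reads sampled from the amplicon (both strands) with 0..max_subs injected
# substitutions at distinct offsets
make_random_reads <- function(ref, n, len, seed, max_subs = 3) {
  set.seed(seed)
  amp <- amplicon(ref)
  L <- nchar(amp)
  start <- sample.int(L - len + 1L, n, replace = TRUE)
  reads <- substring(amp, start, start + len - 1L)
  minus <- runif(n) < 0.5
  reads[minus] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[minus])))
  nsub <- sample(0:max_subs, n, replace = TRUE)
  for (i in which(nsub > 0)) {
    off <- sample.int(len, nsub[i])
    for (o in off) {
      cur <- substr(reads[i], o, o)
      substr(reads[i], o, o) <- sample(setdiff(TEST_BASES, cur), 1)
    }
  }
  reads
}

write_test_fastq <- function(reads, path, qual_char = "I") {
  ids <- sprintf("r%06d", seq_along(reads))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    strrep(qual_char, nchar(reads))), path)
  ids
}

# Brute-force oracle: scans every in-bounds offset on both strands, counting
# mismatches by direct character comparison. A read is anchored when some
# non-overlapping k-seed window is mismatch-free at an in-bounds placement.
# Status: best <= 1 and one best placement -> unique; best <= 1 and several ->
# ambiguous; anchored otherwise -> too_many_mismatches; else unmapped.
oracle_align <- function(ref, reads, k = 31L) {
  amp <- amplicon(ref)
  L <- nchar(amp)
  n <- length(reads)
  l <- unique(nchar(reads))
  stopifnot(length(l) == 1L)
  out <- data.frame(status = rep("unmapped", n), pos = NA_integer_,
                    strand = NA_character_, n_mismatch = NA_integer_,
                    stringsAsFactors = FALSE)
  if (l < k || l > L) return(out)
  offs <- 1L + k * (0:(l %/% k - 1L))
  readmat <- matrix(utf8ToInt(paste(reads, collapse = "")), ncol = l, byrow = TRUE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  rcmat <- matrix(utf8ToInt(paste(rc, collapse = "")), ncol = l, byrow = TRUE)
  refint <- utf8ToInt(amp)
  best <- rep(Inf, n); nbest <- integer(n)
  bpos <- rep(NA_integer_, n); bstr <- rep(NA_character_, n)
  anchored <- rep(FALSE, n)
  for (dir in c("+", "-")) {
    m <- if (dir == "+") readmat else rcmat
    for (p in seq_len(L - l + 1L)) {
      refw <- matrix(refint[p:(p + l - 1L)], n, l, byrow = TRUE)
      neq <- m != refw
      mm <- rowSums(neq)
      for (s in offs) {
        anchored <- anchored | rowSums(neq[, s:(s + k - 1L), drop = FALSE]) == 0
      }
      upd <- mm < best
      tie <- !upd & mm == best
      best[upd] <- mm[upd]; nbest[upd] <- 1L; bpos[upd] <- p; bstr[upd] <- dir
      nbest[tie] <- nbest[tie] + 1L
    }
  }
  uni <- is.finite(best) & best <= 1 & nbest == 1L
  amb <- is.finite(best) & best <= 1 & nbest >= 2L
  out$status[anchored] <- "too_many_mismatches"
  out$status[amb] <- "ambiguous"
  out$status[uni] <- "unique"
  out$pos[uni] <- bpos[uni]
  out$strand[uni] <- bstr[uni]
  out$n_mismatch[uni] <- as.integer(best[uni])
  out
}

# mismatch observations with unique read ids (one observation per read,
# matching the <=1-mismatch-per-read alignment contract)
make_random_obs <- function(ref, n, seed, qmax = 41L) {
  set.seed(seed)
  pos <- sample.int(nchar(ref$seq), n, replace = TRUE)
  rb <- substring(ref$seq, pos, pos)
  alt <- vapply(rb, function(b) sample(setdiff(TEST_BASES, b), 1), "",
                USE.NAMES = FALSE)
  data.frame(orf_pos = pos, ref_base = rb, read_base = alt,
             quality = sample.int(qmax + 1L, n, replace = TRUE) - 1L,
             read_id = sprintf("obs%07d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# pool of n_alleles plasmids, each carrying one of n_spike known
# non-synonymous substitutions (~90% GC->AT), log-normal colony abundances
make_spike_pool <- function(ref, n_alleles = 1000, n_spike = 30, seed = 101) {
  set.seed(seed)
  chars <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  cg <- which(chars %in% c("C", "G"))
  spikes <- NULL
  used <- integer(0)
  while (is.null(spikes) || nrow(spikes) < n_spike) {
    gcat <- runif(1) < 0.9
    p <- if (gcat) cg[sample.int(length(cg), 1)] else sample.int(length(chars), 1)
    if (p %in% used) next
    rb <- chars[p]
    ab <- if (gcat) {
      if (rb == "C") "T" else "A"
    } else {
      opts <- setdiff(TEST_BASES, rb)
      if (rb == "C") opts <- setdiff(opts, "T")
      if (rb == "G") opts <- setdiff(opts, "A")
      sample(opts, 1)
    }
    s <- substitution_from_mismatch(ref, p, ab)
    if (s$synonymous) next
    used <- c(used, p)
    spikes <- rbind(spikes, s)
  }
  alleles <- lapply(seq_len(n_alleles), function(i) {
    j <- (i - 1L) %% n_spike + 1L
    mutant_allele(sprintf("spike_%04d", i),
                  data.frame(orf_pos = spikes$orf_pos[j],
                             ref_base = spikes$ref_base[j],
                             alt_base = spikes$alt_base[j],
                             stringsAsFactors = FALSE),
                  abundance = rlnorm(1, 0, 1), phenotype = "resistant")
  })
  list(pool = structure(alleles, class = "mutant_pool", ref_id = ref$id),
       spikes = spikes)
}

# exact expected number of ORF bases per simulated read, by enumeration over
# fragment length, fragment start and strand (all uniform)
expected_orf_bases_per_read <- function(ref, fmin, fmax, rl) {
  amp_len <- nchar(amplicon(ref))
  f5 <- nchar(ref$flank5)
  orf_end <- f5 + nchar(ref$seq)
  tot <- 0
  cnt <- 0
  for (fl in fmin:fmax) {
    fstart <- seq_len(amp_len - fl + 1L)
    ov <- function(ws) pmax(0L, pmin(ws + rl - 1L, orf_end) - pmax(ws, f5 + 1L) + 1L)
    tot <- tot + sum(ov(fstart)) + sum(ov(fstart + fl - rl))
    cnt <- cnt + 2L * length(fstart)
  }
  tot / cnt
}
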