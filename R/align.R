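# ungapped read alignment: unique placements only, at most one mismatch

#' Build a k-mer seed index over the reference amplicon
#'
#' Exact k-mer -> position lookup over the amplicon. Reverse-strand placements
#' are found by looking up seeds of the reverse-complemented read in the same
#' forward table, so the index covers both strands. With non-overlapping seeds
#' and reads of length >= 2k, at least one seed of any placement with <= 1
#' mismatch is exact, so no such placement is ever missed.
#'
#' @param ref an [orf_reference()].
#' @param k seed length (default 31); must satisfy `1 <= k <= amplicon length`
#'   and, for full sensitivity, `k <= read_length / 2`.
#' @return list of class `kmer_index`.
#' @export
build_index <- function(ref, k = 31L) {
  stopifnot(inherits(ref, "orf_reference"))
  amp <- amplicon(ref)
  L <- nchar(amp)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) .config_error("seed length k must be >= 1")
  if (k > L) .config_error("seed length k (%d) exceeds the amplicon (%d nt)", k, L)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(amp, starts, starts + k - 1L)
  structure(list(map = split(starts, kmers), k = k, amp = amp,
                 amp_int = utf8ToInt(amp), L = L,
                 flank5_len = nchar(ref$flank5), orf_len = nchar(ref$seq),
                 ref_id = ref$id),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d over a %d-nt amplicon ('%s'), %d indexed positions\n",
              x$k, x$L, x$ref_id, sum(lengths(x$map))))
  invisible(x)
}

# non-overlapping seed offsets within a read of length len
.seed_offsets <- function(len, k) {
  if (len < k) return(integer(0))
  1L + k * (0:(len %/% k - 1L))
}

# core vectorized aligner over reads of possibly mixed lengths.
# Returns records (one row per read) and coding-strand ORF mismatch
# observations for unique single-mismatch placements.
.align_core <- function(idx, ids, seqs, quals) {
  n <- length(seqs)
  status <- rep("unmapped", n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  nmis <- rep(NA_integer_, n)
  obs <- list()
  if (n == 0L) {
    return(list(records = data.frame(read_id = character(0), status = character(0),
                                     pos = integer(0), strand = character(0),
                                     n_mismatch = integer(0), stringsAsFactors = FALSE),
                obs = .empty_obs()))
  }
  k <- idx$k
  lens <- nchar(seqs)
  for (l in unique(lens)) {
    sel <- which(lens == l)
    offs <- .seed_offsets(l, k)
    if (length(offs) == 0L || l > idx$L) next  # too short / too long => unmapped
    rc <- .revcomp(seqs[sel])

    # --- candidate placements from seed hits (both strands) --------------
    cand_read <- integer(0); cand_pos <- integer(0); cand_str <- character(0)
    for (dir in c("+", "-")) {
      src <- if (dir == "+") seqs[sel] else rc
      for (s in offs) {
        sd <- substring(src, s, s + k - 1L)
        hits <- idx$map[sd]
        nh <- lengths(hits)
        if (!any(nh > 0L)) next
        rix <- rep(seq_along(sel), nh)
        p <- unlist(hits, use.names = FALSE) - s + 1L
        keep <- p >= 1L & p + l - 1L <= idx$L
        cand_read <- c(cand_read, rix[keep])
        cand_pos <- c(cand_pos, p[keep])
        cand_str <- c(cand_str, rep(dir, sum(keep)))
      }
    }
    if (length(cand_read) == 0L) next
    dup <- duplicated(paste(cand_read, cand_pos, cand_str))
    cand_read <- cand_read[!dup]; cand_pos <- cand_pos[!dup]; cand_str <- cand_str[!dup]

    # --- verify candidates by full ungapped comparison --------------------
    mat_f <- matrix(utf8ToInt(paste(seqs[sel], collapse = "")), ncol = l, byrow = TRUE)
    mat_r <- matrix(utf8ToInt(paste(rc, collapse = "")), ncol = l, byrow = TRUE)
    nc <- length(cand_read)
    mm <- integer(nc)
    mmoff <- rep(NA_integer_, nc)
    for (dir in c("+", "-")) {
      cc <- which(cand_str == dir)
      if (length(cc) == 0L) next
      rm <- (if (dir == "+") mat_f else mat_r)[cand_read[cc], , drop = FALSE]
      refm <- matrix(idx$amp_int[rep(cand_pos[cc], each = l) + rep(0:(l - 1L), times = length(cc))],
                     ncol = l, byrow = TRUE)
      neq <- rm != refm
      mm[cc] <- as.integer(rowSums(neq))
      one <- which(mm[cc] == 1L)
      if (length(one)) mmoff[cc[one]] <- max.col(neq[one, , drop = FALSE], "first")
    }

    # --- best-stratum classification per read -----------------------------
    o <- order(cand_read, mm)
    cr <- cand_read[o]; cm <- mm[o]
    first <- !duplicated(cr)
    best <- rep(NA_integer_, length(sel))
    best[cr[first]] <- cm[first]
    is_best <- mm == best[cand_read]
    nbest <- tabulate(cand_read[is_best], nbins = length(sel))
    has_cand <- !is.na(best)
    status[sel[has_cand & best >= 2L]] <- "too_many_mismatches"
    amb <- has_cand & best <= 1L & nbest >= 2L
    status[sel[amb]] <- "ambiguous"
    uni <- which(has_cand & best <= 1L & nbest == 1L)
    if (length(uni) == 0L) next
    ubest <- which(is_best & cand_read %in% uni)
    stopifnot(!anyDuplicated(cand_read[ubest]))
    m <- match(cand_read[ubest], uni)
    gi <- sel[uni]                       # global read indices, aligned with uni
    status[gi] <- "unique"
    pos[gi[m]] <- cand_pos[ubest]
    strand[gi[m]] <- cand_str[ubest]
    nmis[gi[m]] <- mm[ubest]

    # --- mismatch observations for unique single-mismatch reads -----------
    mo <- which(mm[ubest] == 1L)
    if (length(mo)) {
      ub <- ubest[mo]
      j <- mmoff[ub]                      # offset in the compared sequence
      amp_pos <- cand_pos[ub] + j - 1L
      rdi <- cand_read[ub]
      read_base <- character(length(ub))
      plus <- cand_str[ub] == "+"
      read_base[plus] <- substring(seqs[sel][rdi[plus]], j[plus], j[plus])
      read_base[!plus] <- substring(rc[rdi[!plus]], j[!plus], j[!plus])
      qpos <- ifelse(plus, j, l - j + 1L) # position in the original read
      quality <- .phred_decode(paste(substring(quals[sel][rdi], qpos, qpos),
                                     collapse = ""))
      orf_pos <- amp_pos - idx$flank5_len
      in_orf <- orf_pos >= 1L & orf_pos <= idx$orf_len & read_base != "N"
      if (any(in_orf)) {
        obs[[length(obs) + 1L]] <- data.frame(
          orf_pos = orf_pos[in_orf],
          ref_base = substring(idx$amp, amp_pos[in_orf], amp_pos[in_orf]),
          read_base = read_base[in_orf],
          quality = quality[in_orf],
          read_id = ids[sel][rdi[in_orf]],
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- data.frame(read_id = ids, status = status, pos = pos,
                        strand = strand, n_mismatch = nmis,
                        stringsAsFactors = FALSE)
  obs <- if (length(obs)) do.call(rbind, obs) else .empty_obs()
  list(records = records, obs = obs)
}

.empty_obs <- function() {
  data.frame(orf_pos = integer(0), ref_base = character(0),
             read_base = character(0), quality = integer(0),
             read_id = character(0), stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Seed-and-verify ungapped alignment against the amplicon. Placements are
#' verified on both strands; a read is `unique` when exactly one placement
#' attains the minimal mismatch count and that count is at most 1 (a read with
#' one exact placement plus secondary 1-mismatch placements is unique at the
#' exact locus, matching best-stratum behavior). Reads anchoring to the
#' reference whose placements all carry >= 2 mismatches are
#' `too_many_mismatches`; reads with no exact seed anywhere (including reads
#' shorter than `k`) are `unmapped`. An `N` counts as a mismatch but is never
#' reported as an observation.
#'
#' @param index a [build_index()] object.
#' @param read read sequence over `{A,C,G,T,N}`.
#' @param qual Phred+33 quality string (defaults to Q40 everywhere).
#' @param read_id identifier used in the mismatch record.
#' @return list of class `alignment_record`: `read_id`, `status` (one of
#'   `unique`, `ambiguous`, `unmapped`, `too_many_mismatches`), 1-based `pos`,
#'   `strand`, `n_mismatch`, and `mismatches` (0- or 1-row data.frame of
#'   coding-strand ORF observations).
#' @export
align_read <- function(index, read, qual = NULL, read_id = "read") {
  stopifnot(inherits(index, "kmer_index"))
  read <- toupper(read)
  if (grepl("[^ACGTN]", read)) .data_error("read contains characters outside {A,C,G,T,N}")
  if (is.null(qual)) qual <- strrep("I", nchar(read))
  .phred_decode(qual)
  res <- .align_core(index, read_id, read, qual)
  r <- res$records[1L, ]
  structure(list(read_id = r$read_id, status = r$status, pos = r$pos,
                 strand = r$strand, n_mismatch = r$n_mismatch,
                 mismatches = res$obs),
            class = "alignment_record")
}

#' @export
print.alignment_record <- function(x, ...) {
  cat(sprintf("read '%s': %s", x$read_id, x$status))
  if (x$status == "unique") {
    cat(sprintf(" at %d (%s), %d mismatch(es)", x$pos, x$strand, x$n_mismatch))
  }
  cat("\n")
  invisible(x)
}

#' Align a FASTQ batch
#'
#' Streams a single-end Phred+33 FASTQ through the seed-and-verify aligner,
#' optionally writing minimal SAM records and the native tab-separated
#' mismatch file (`orf_pos` / `ref_base` / `read_base` / `quality` /
#' `read_id`). Only unique placements contribute mismatch observations;
#' mismatches falling in the amplicon flanks are counted but produce no ORF
#' observation.
#'
#' @param index a [build_index()] object.
#' @param fastq path to the input FASTQ.
#' @param mismatch_out optional path for the mismatch TSV.
#' @param sam_out optional path for SAM output.
#' @param keep_records also return the per-read alignment records
#'   (`read_id`, `status`, `pos`, `strand`, `n_mismatch`).
#' @param chunk_size reads per processing chunk (default 20000).
#' @return list with `summary` (class `alignment_summary`: totals per status
#'   and the fraction of unique alignments carrying a mismatch),
#'   `mismatches` (the observation data.frame) and, if requested, `records`.
#' @export
align_batch <- function(index, fastq, mismatch_out = NULL, sam_out = NULL,
                        keep_records = FALSE, chunk_size = 20000L) {
  stopifnot(inherits(index, "kmer_index"))
  fq <- read_fastq(fastq)
  n <- nrow(fq)
  counts <- c(unique = 0L, ambiguous = 0L, unmapped = 0L, too_many_mismatches = 0L)
  n_unique_mm <- 0L
  obs <- list()
  records <- list()
  sam_con <- NULL
  if (!is.null(sam_out)) {
    sam_con <- file(sam_out, open = "wt")
    on.exit(close(sam_con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", index$ref_id, index$L)), sam_con)
  }
  if (n > 0L) {
    for (lo in seq(1L, n, by = chunk_size)) {
      hi <- min(lo + chunk_size - 1L, n)
      res <- .align_core(index, fq$id[lo:hi], fq$seq[lo:hi], fq$qual[lo:hi])
      rec <- res$records
      tb <- table(rec$status)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
      n_unique_mm <- n_unique_mm +
        sum(rec$status == "unique" & rec$n_mismatch == 1L, na.rm = TRUE)
      if (nrow(res$obs)) obs[[length(obs) + 1L]] <- res$obs
      if (keep_records) records[[length(records) + 1L]] <- rec
      if (!is.null(sam_con)) {
        uniq <- rec$status == "unique"
        flag <- ifelse(uniq, ifelse(rec$strand == "-", 16L, 0L), 4L)
        posn <- ifelse(uniq, rec$pos, 0L)
        cigar <- ifelse(uniq, paste0(nchar(fq$seq[lo:hi]), "M"), "*")
        nm <- ifelse(uniq, paste0("\tNM:i:", rec$n_mismatch), "")
        writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                           rec$read_id, flag,
                           ifelse(uniq, index$ref_id, "*"), posn,
                           ifelse(uniq, 255L, 0L), cigar,
                           fq$seq[lo:hi], fq$qual[lo:hi], nm), sam_con)
      }
    }
  }
  obs <- if (length(obs)) do.call(rbind, obs) else .empty_obs()
  if (!is.null(mismatch_out)) {
    write.table(obs, mismatch_out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- structure(list(n_reads = n,
                            n_unique = counts[["unique"]],
                            n_ambiguous = counts[["ambiguous"]],
                            n_unmapped = counts[["unmapped"]],
                            n_too_many_mismatches = counts[["too_many_mismatches"]],
                            n_unique_with_mismatch = n_unique_mm,
                            frac_unique_with_mismatch =
                              if (counts[["unique"]] > 0L)
                                n_unique_mm / counts[["unique"]] else NA_real_),
                       class = "alignment_summary")
  out <- list(summary = summary, mismatches = obs)
  if (keep_records) {
    out$records <- if (length(records)) do.call(rbind, records) else
      data.frame(read_id = character(0), status = character(0),
                 pos = integer(0), strand = character(0),
                 n_mismatch = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf(paste0("Alignment summary: %d reads | unique %d | ambiguous %d | ",
                     "unmapped %d | >1 mismatch %d\n"),
              x$n_reads, x$n_unique, x$n_ambiguous, x$n_unmapped,
              x$n_too_many_mismatches))
  if (!is.na(x$frac_unique_with_mismatch)) {
    cat(sprintf("  %.2f%% of unique alignments carry a mismatch (%d reads)\n",
                100 * x$frac_unique_with_mismatch, x$n_unique_with_mismatch))
  }
  invisible(x)
}

#' Read a mismatch observation file written by [align_batch()]
#'
#' @param path path to the tab-separated mismatch file.
#' @return data.frame with columns `orf_pos`, `ref_base`, `read_base`,
#'   `quality`, `read_id`.
#' @export
read_mismatches <- function(path) {
  if (!file.exists(path)) .data_error("mismatch file not found: %s", path)
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(orf_pos = "integer", ref_base = "character",
                                 read_base = "character", quality = "integer",
                                 read_id = "character"))
  need <- c("orf_pos", "ref_base", "read_base", "quality", "read_id")
  miss <- setdiff(need, names(m))
  if (length(miss)) .data_error("mismatch file lacks column(s): %s", paste(miss, collapse = ", "))
  m
}
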