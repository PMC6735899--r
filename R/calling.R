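# quality filtering, amino-acid conversion, supporting-read ranking, top-N cutoff

#' Caller configuration
#'
#' Parameters of the mutation caller: the Phred threshold separating real
#' mismatches from sequencing error, the top-N cutoff applied to the ranked
#' mutation list, and flags controlling synonymous and stop-gain calls.
#'
#' @param min_quality minimum Phred score a mismatch must reach to be kept
#'   (default 38, i.e. 99.98% base-calling confidence).
#' @param top_n cutoff rank of the reported landscape (default 100).
#' @param include_synonymous keep synonymous calls in the ranking
#'   (default `FALSE`; they are always computed and flagged upstream).
#' @param include_stops keep stop-gain calls (default `TRUE`; nonsense alleles
#'   such as Trp->STOP changes are legitimate screen hits).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_quality = 38L, top_n = 100L,
                          include_synonymous = FALSE, include_stops = TRUE) {
  min_quality <- as.integer(min_quality)
  top_n <- as.integer(top_n)
  if (is.na(min_quality) || min_quality < 0L) .config_error("min_quality must be >= 0")
  if (is.na(top_n) || top_n < 1L) .config_error("top_n must be >= 1")
  structure(list(min_quality = min_quality, top_n = top_n,
                 include_synonymous = isTRUE(include_synonymous),
                 include_stops = isTRUE(include_stops)),
            class = "caller_config")
}

#' Base-calling confidence of a Phred score
#'
#' Converts a Phred quality score to the percent confidence that the base call
#' is correct: `100 * (1 - 10^(-q/10))`. A threshold of Q38 corresponds to
#' 99.98% confidence.
#'
#' @param q Phred score(s), `>= 0`.
#' @return percent confidence, same length as `q`.
#' @export
#' @examples
#' quality_confidence(38) # 99.98416
#' quality_confidence(10) # 90
quality_confidence <- function(q) {
  if (any(is.na(q)) || any(q < 0)) .config_error("Phred scores must be >= 0")
  100 * (1 - 10^(-q / 10))
}

#' Filter mismatch observations by base quality
#'
#' Keeps exactly the observations whose Phred score reaches `min_quality`;
#' order-preserving. A read whose single mismatch falls below the threshold
#' contributes nothing (the observation is dropped, the read is not
#' re-counted as wild type).
#'
#' @param obs mismatch observation data.frame (see [align_batch()]).
#' @param min_quality Phred threshold, or a [caller_config()].
#' @return the filtered data.frame.
#' @export
filter_mismatches <- function(obs, min_quality = 38L) {
  if (inherits(min_quality, "caller_config")) min_quality <- min_quality$min_quality
  obs[obs$quality >= min_quality, , drop = FALSE]
}

#' Call and rank amino-acid substitutions from mismatch observations
#'
#' The core screen computation: quality-filters the observations, groups them
#' by nucleotide change `(orf_pos, alt_base)`, counts supporting reads as
#' distinct read identifiers, converts each change to its amino-acid
#' substitution, sorts by supporting reads (descending) with a deterministic
#' tie-break (ascending residue, then alternate amino acid, then ORF position),
#' and truncates to the top N. Entries beyond rank N that tie with the rank-N
#' supporting count are kept in the `boundary_ties` attribute, never silently.
#'
#' Two nucleotide routes to the same amino-acid substitution are kept as
#' separate rows; use [collapse_to_aa()] for the residue-level view.
#'
#' @param ref an [orf_reference()].
#' @param obs mismatch observations (`orf_pos`, `ref_base`, `read_base`,
#'   `quality`, `read_id`). An observation whose `ref_base` disagrees with the
#'   reference raises an error naming the position.
#' @param cfg a [caller_config()].
#' @return data.frame of class `ranked_calls` with columns `rank`, `residue`,
#'   `ref_aa`, `alt_aa`, `orf_pos`, `ref_base`, `alt_base`,
#'   `supporting_reads`, `synonymous`; attributes `threshold_reads` (count at
#'   the last reported rank), `totals` (`mismatch_reads_in`,
#'   `calls_passing_quality`, `distinct_substitutions`), `boundary_ties`,
#'   `ref_id` and `cfg`.
#' @export
call_and_rank <- function(ref, obs, cfg = caller_config()) {
  stopifnot(inherits(ref, "orf_reference"), inherits(cfg, "caller_config"))
  need <- c("orf_pos", "ref_base", "read_base", "quality", "read_id")
  miss <- setdiff(need, names(obs))
  if (length(miss)) .config_error("observations lack column(s): %s", paste(miss, collapse = ", "))

  if (nrow(obs) > 0L) {
    bad <- which(obs$orf_pos < 1L | obs$orf_pos > nchar(ref$seq))
    if (length(bad)) {
      .data_error("observation at ORF position %d is outside the ORF [1, %d]",
                  obs$orf_pos[bad[1L]], nchar(ref$seq))
    }
    rb <- substring(ref$seq, obs$orf_pos, obs$orf_pos)
    bad <- which(rb != obs$ref_base)
    if (length(bad)) {
      .data_error("corrupt observation: ref_base '%s' at ORF position %d disagrees with the reference ('%s')",
                  obs$ref_base[bad[1L]], obs$orf_pos[bad[1L]], rb[bad[1L]])
    }
  }
  mismatch_reads_in <- length(unique(obs$read_id))
  kept <- filter_mismatches(obs, cfg$min_quality)
  calls_passing <- nrow(kept)

  if (calls_passing == 0L) {
    tab <- .empty_calls()
  } else {
    key <- paste(kept$orf_pos, kept$read_base)
    supporting <- vapply(split(kept$read_id, key), function(x) length(unique(x)), 0L)
    parts <- strsplit(names(supporting), " ", fixed = TRUE)
    gpos <- as.integer(vapply(parts, `[[`, "", 1L))
    galt <- vapply(parts, `[[`, "", 2L)
    tab <- substitution_from_mismatch(ref, gpos, galt)
    tab$supporting_reads <- as.integer(supporting)
  }
  distinct_subs <- nrow(tab)
  if (!cfg$include_synonymous) tab <- tab[!tab$synonymous, , drop = FALSE]
  if (!cfg$include_stops) tab <- tab[tab$alt_aa != "*", , drop = FALSE]

  o <- order(-tab$supporting_reads, tab$residue, tab$alt_aa, tab$orf_pos, tab$alt_base)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  n_keep <- min(cfg$top_n, nrow(tab))
  threshold_reads <- if (n_keep > 0L) tab$supporting_reads[n_keep] else NA_integer_
  annex <- tab[tab$rank > n_keep & tab$supporting_reads == threshold_reads, , drop = FALSE]
  main <- tab[seq_len(n_keep), , drop = FALSE]

  cols <- c("rank", "residue", "ref_aa", "alt_aa", "orf_pos", "ref_base",
            "alt_base", "supporting_reads", "synonymous")
  main <- main[, cols]
  rownames(main) <- NULL
  structure(main,
            class = c("ranked_calls", "data.frame"),
            threshold_reads = threshold_reads,
            totals = list(mismatch_reads_in = mismatch_reads_in,
                          calls_passing_quality = calls_passing,
                          distinct_substitutions = distinct_subs),
            boundary_ties = if (nrow(annex)) annex[, cols] else NULL,
            ref_id = ref$id,
            cfg = cfg)
}

.empty_calls <- function() {
  data.frame(orf_pos = integer(0), ref_base = character(0),
             alt_base = character(0), residue = integer(0),
             ref_aa = character(0), alt_aa = character(0),
             synonymous = logical(0), supporting_reads = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.ranked_calls <- function(x, n = 10L, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("Ranked mutation calls ('%s'): %d reported, read cutoff %s\n",
              attr(x, "ref_id") %||% "?", nrow(x),
              as.character(attr(x, "threshold_reads"))))
  if (!is.null(tot)) {
    cat(sprintf("  %d mismatch-bearing reads in, %d observations passed Q>=%d, %d distinct substitutions\n",
                tot$mismatch_reads_in, tot$calls_passing_quality,
                attr(x, "cfg")$min_quality %||% NA, tot$distinct_substitutions))
  }
  print.data.frame(head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  bt <- attr(x, "boundary_ties")
  if (!is.null(bt)) cat(sprintf("  (+%d boundary tie(s) at the cutoff, see attr 'boundary_ties')\n", nrow(bt)))
  invisible(x)
}

#' @export
summary.ranked_calls <- function(object, ...) {
  tot <- attr(object, "totals")
  out <- list(n_reported = nrow(object),
              threshold_reads = attr(object, "threshold_reads"),
              mismatch_reads_in = tot$mismatch_reads_in,
              calls_passing_quality = tot$calls_passing_quality,
              distinct_substitutions = tot$distinct_substitutions,
              n_stop_gains = sum(object$alt_aa == "*"),
              n_synonymous = sum(object$synonymous))
  class(out) <- "summary.ranked_calls"
  out
}

#' @export
print.summary.ranked_calls <- function(x, ...) {
  cat(sprintf(paste0("ranked_calls: %d reported (cutoff %s supporting reads); ",
                     "%d mismatch reads in, %d passed quality, %d distinct substitutions; ",
                     "%d stop gains, %d synonymous\n"),
              x$n_reported, as.character(x$threshold_reads), x$mismatch_reads_in,
              x$calls_passing_quality, x$distinct_substitutions,
              x$n_stop_gains, x$n_synonymous))
  invisible(x)
}

#' Landscape plot of a ranked call table
#'
#' Supporting-read counts along the residue axis, with optional domain
#' shading.
#'
#' @param x a `ranked_calls` table.
#' @param annotations optional domain annotation table for background shading.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ranked_calls <- function(x, annotations = NULL, ...) {
  if (nrow(x) == 0L) {
    plot(0, 0, type = "n", xlab = "residue", ylab = "supporting reads", ...)
    return(invisible(x))
  }
  xmax <- max(x$residue)
  plot(NA, xlim = c(1, xmax), ylim = c(0, max(x$supporting_reads) * 1.05),
       xlab = "residue", ylab = "supporting reads", ...)
  if (!is.null(annotations)) {
    top <- annotations[is.na(annotations$parent) | annotations$parent == "", , drop = FALSE]
    shade <- rep(c("grey92", "grey85"), length.out = nrow(top))
    usr <- par("usr")
    rect(top$start_res, usr[3], top$end_res, usr[4], col = shade, border = NA)
  }
  segments(x$residue, 0, x$residue, x$supporting_reads, lwd = 2)
  invisible(x)
}

#' Collapse a ranked call table to amino-acid level
#'
#' Degenerate codon positions allow two different nucleotide changes to yield
#' the same amino-acid substitution; this view sums their supporting reads by
#' `(residue, ref_aa, alt_aa)` and re-ranks with the same ordering rules.
#'
#' @param table a `ranked_calls` table.
#' @return data.frame with columns `rank`, `residue`, `ref_aa`, `alt_aa`,
#'   `supporting_reads`, `n_nt_routes`.
#' @export
collapse_to_aa <- function(table) {
  stopifnot(inherits(table, "ranked_calls"))
  if (nrow(table) == 0L) {
    return(data.frame(rank = integer(0), residue = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      supporting_reads = integer(0), n_nt_routes = integer(0)))
  }
  key <- paste(table$residue, table$ref_aa, table$alt_aa)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(table)), key), function(i) {
    data.frame(residue = table$residue[i[1L]], ref_aa = table$ref_aa[i[1L]],
               alt_aa = table$alt_aa[i[1L]],
               supporting_reads = sum(table$supporting_reads[i]),
               n_nt_routes = length(i), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$supporting_reads, agg$residue, agg$alt_aa), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg[, c("rank", "residue", "ref_aa", "alt_aa", "supporting_reads", "n_nt_routes")]
}

#' Write / read a ranked call table
#'
#' Lossless TSV round trip of the native schema (`rank` / `residue` /
#' `ref_aa` / `alt_aa` / `orf_pos` / `ref_base` / `alt_base` /
#' `supporting_reads` / `synonymous`), with the reference id and read cutoff
#' carried in a header comment.
#'
#' @param table a `ranked_calls` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(table, path) {
  stopifnot(inherits(table, "ranked_calls"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#ref_id=%s\tthreshold_reads=%s",
                     attr(table, "ref_id") %||% "NA",
                     as.character(attr(table, "threshold_reads") %||% NA)), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) .data_error("call table not found: %s", path)
  hdr <- readLines(path, n = 1L)
  ref_id <- NA_character_
  thr <- NA_integer_
  if (startsWith(hdr, "#")) {
    ref_id <- sub("^#ref_id=([^\t]*).*$", "\\1", hdr)
    thr <- suppressWarnings(as.integer(sub("^.*threshold_reads=([^\t]*)$", "\\1", hdr)))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = c(rank = "integer", residue = "integer",
                                   ref_aa = "character", alt_aa = "character",
                                   orf_pos = "integer", ref_base = "character",
                                   alt_base = "character",
                                   supporting_reads = "integer",
                                   synonymous = "logical"))
  structure(tab, class = c("ranked_calls", "data.frame"),
            threshold_reads = thr, ref_id = ref_id)
}

#' Export a ranked call table as VCF-flavored records
#'
#' CHROM is the ORF id, POS the 1-based ORF nucleotide position, and the INFO
#' field carries the residue, amino-acid change and supporting-read count.
#'
#' @param table a `ranked_calls` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(table, path) {
  stopifnot(inherits(table, "ranked_calls"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=RES,Number=1,Type=Integer,Description=\"1-based residue index\">",
               "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino-acid change\">",
               "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting reads\">",
               "##INFO=<ID=RANK,Number=1,Type=Integer,Description=\"Rank by supporting reads\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(table)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tRES=%d;AAC=%s%d%s;SR=%d;RANK=%d",
                       attr(table, "ref_id") %||% "orf", table$orf_pos,
                       table$ref_base, table$alt_base, table$residue,
                       table$ref_aa, table$residue,
                       ifelse(table$alt_aa == "*", "STOP", table$alt_aa),
                       table$supporting_reads, table$rank), con)
  }
  invisible(path)
}
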