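# landscape outputs: domain tallies, screen overlap, spectrum audit,
# selection-rate and phenotype-concordance bookkeeping

#' Tally ranked calls by protein domain
#'
#' Counts calls by the most deeply nested domain containing each residue
#' (`rollup = TRUE` instead attributes embedded-domain hits to their top-level
#' parent). Every annotated domain appears in the result, zero counts
#' included, plus an `unannotated` bin; the total always equals the table
#' size.
#'
#' @param table a `ranked_calls` table (or any data.frame with a `residue`
#'   column).
#' @param annotations domain annotation table (see
#'   [read_domain_annotations()]).
#' @param rollup count embedded-domain hits in their top-level parent.
#' @return named integer vector of counts.
#' @export
domain_tally <- function(table, annotations, rollup = FALSE) {
  if (is.null(annotations$depth)) annotations <- validate_annotations(annotations)
  labels <- if (rollup) {
    unique(domain_of(annotations,
                     annotations$start_res, rollup = TRUE))
  } else {
    annotations$name
  }
  labels <- c(labels, "unannotated")
  hits <- domain_of(annotations, table$residue, rollup = rollup)
  counts <- table(factor(hits, levels = labels))
  out <- as.integer(counts)
  names(out) <- labels
  out
}

#' Compare the ranked landscapes of two screens
#'
#' Partitions the union of two call tables into screen-specific and shared
#' substitutions. Membership identity is `(residue, alt_aa)` by default,
#' matching residue-level landscape comparisons; `by = "nt"` compares exact
#' nucleotide changes instead.
#'
#' @param table_a,table_b `ranked_calls` tables from the same reference
#'   (mismatched reference ids raise an error).
#' @param labels length-2 character vector naming the screens.
#' @param annotations optional domain table; when given, per-domain counts of
#'   each screen's calls are included.
#' @param by `"aa"` (residue + alternate amino acid) or `"nt"` (ORF position +
#'   alternate base).
#' @return list of class `screen_comparison`: `membership` (one row per union
#'   element with its class `A_only` / `B_only` / `shared`), `class_sizes`,
#'   and `domain_counts` (domain x screen matrix, or `NULL`).
#' @export
compare_screens <- function(table_a, table_b, labels = c("screen_A", "screen_B"),
                            annotations = NULL, by = c("aa", "nt")) {
  by <- match.arg(by)
  ra <- attr(table_a, "ref_id")
  rb <- attr(table_b, "ref_id")
  if (!is.null(ra) && !is.null(rb) && !is.na(ra) && !is.na(rb) && ra != rb) {
    .data_error("call tables come from different references ('%s' vs '%s')", ra, rb)
  }
  keyfun <- function(t) {
    if (by == "aa") paste(t$residue, t$alt_aa) else paste(t$orf_pos, t$alt_base)
  }
  ka <- unique(keyfun(table_a))
  kb <- unique(keyfun(table_b))
  all_keys <- union(ka, kb)
  cls <- ifelse(all_keys %in% ka & all_keys %in% kb, "shared",
                ifelse(all_keys %in% ka, "A_only", "B_only"))
  src <- rbind(table_a[, intersect(names(table_a), c("residue", "alt_aa", "orf_pos", "alt_base"))],
               table_b[, intersect(names(table_b), c("residue", "alt_aa", "orf_pos", "alt_base"))])
  src_key <- if (by == "aa") paste(src$residue, src$alt_aa) else paste(src$orf_pos, src$alt_base)
  m <- match(all_keys, src_key)
  membership <- data.frame(residue = src$residue[m], class = cls,
                           stringsAsFactors = FALSE)
  if (by == "aa") membership$alt_aa <- src$alt_aa[m]
  if (by == "nt") {
    membership$orf_pos <- src$orf_pos[m]
    membership$alt_base <- src$alt_base[m]
  }
  class_sizes <- c(A_only = sum(cls == "A_only"), B_only = sum(cls == "B_only"),
                   shared = sum(cls == "shared"))
  domain_counts <- NULL
  if (!is.null(annotations)) {
    ta <- domain_tally(table_a, annotations)
    tb <- domain_tally(table_b, annotations)
    domain_counts <- cbind(ta, tb)
    colnames(domain_counts) <- labels
  }
  structure(list(labels = labels, by = by, membership = membership,
                 class_sizes = class_sizes, domain_counts = domain_counts),
            class = "screen_comparison")
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat(sprintf("Screen comparison (%s vs %s, by %s): %d only in A, %d only in B, %d shared\n",
              x$labels[1L], x$labels[2L], x$by,
              x$class_sizes[["A_only"]], x$class_sizes[["B_only"]],
              x$class_sizes[["shared"]]))
  if (!is.null(x$domain_counts)) {
    cat("Per-domain counts:\n")
    print(x$domain_counts)
  }
  invisible(x)
}

#' Mutational-spectrum audit of a call table
#'
#' Reports the fraction of calls that are GC->AT transitions (C->T or G->A on
#' the coding strand) -- the signature expected of hydroxylamine mutagenesis --
#' together with per-class counts and the list of transversion calls for
#' inspection.
#'
#' @param table a `ranked_calls` table or any data.frame with `ref_base` and
#'   `alt_base` columns.
#' @return list of class `spectrum_audit`: `fraction_gc_to_at` (`NA` for an
#'   empty table), `n`, `class_counts` (named counts of `ref>alt` classes) and
#'   `transversions` (the subset of purine<->pyrimidine calls).
#' @export
spectrum_audit <- function(table) {
  n <- nrow(table)
  if (n == 0L) {
    return(structure(list(fraction_gc_to_at = NA_real_, n = 0L,
                          class_counts = integer(0),
                          transversions = table),
                     class = "spectrum_audit"))
  }
  gcat <- (table$ref_base == "C" & table$alt_base == "T") |
    (table$ref_base == "G" & table$alt_base == "A")
  purine <- c("A", "G")
  tv <- (table$ref_base %in% purine) != (table$alt_base %in% purine)
  cls <- paste0(table$ref_base, ">", table$alt_base)
  structure(list(fraction_gc_to_at = mean(gcat), n = n,
                 class_counts = sort(table(cls), decreasing = TRUE),
                 transversions = table[tv, , drop = FALSE]),
            class = "spectrum_audit")
}

#' @export
print.spectrum_audit <- function(x, ...) {
  if (x$n == 0L) {
    cat("Spectrum audit: empty table, fraction undefined\n")
    return(invisible(x))
  }
  cat(sprintf("Spectrum audit: %.1f%% GC->AT transitions (%d calls; %d transversions)\n",
              100 * x$fraction_gc_to_at, x$n, nrow(x$transversions)))
  print(x$class_counts)
  invisible(x)
}

#' Selection-rate summary
#'
#' Percent of plated transformants confirmed as resistant after re-patching,
#' reported to two decimal places.
#'
#' @param n_plated number of transformants plated (> 0).
#' @param n_confirmed number confirmed resistant (`0 <= n_confirmed <=
#'   n_plated`).
#' @return list of class `selection_summary` with `percent_confirmed`.
#' @export
#' @examples
#' selection_summary(28000, 363)$percent_confirmed # 1.30
selection_summary <- function(n_plated, n_confirmed) {
  if (!is.numeric(n_plated) || n_plated <= 0) .config_error("n_plated must be > 0")
  if (!is.numeric(n_confirmed) || n_confirmed < 0 || n_confirmed > n_plated) {
    .config_error("n_confirmed must lie in [0, n_plated]")
  }
  structure(list(n_plated = n_plated, n_confirmed = n_confirmed,
                 percent_confirmed = round(100 * n_confirmed / n_plated, 2)),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("Selection: %g of %g plated confirmed (%.2f%%)\n",
              x$n_confirmed, x$n_plated, x$percent_confirmed))
  invisible(x)
}

#' Classify validated-mutant phenotypes and score screen concordance
#'
#' Labels each (mutant, drug) record resistant when its log10 viable-count
#' fold-change reaches the threshold (default 2, i.e. a 100-fold increase),
#' stratifies resistant records into `weak` (fold change in `[2, 4)` log10
#' units, the 100-fold class) and `strong` (`>= 4`, the 10000-fold class),
#' and reports the fraction of records whose label matches the phenotype the
#' screen predicted.
#'
#' @param records data.frame with columns `mutant`, `drug`,
#'   `log10_fold_change`, `screen_expectation` (`resistant` / `sensitive`).
#' @param threshold_log10 resistance threshold in log10 fold-change units
#'   (default 2).
#' @return list of class `resistance_classification`: `records` (with added
#'   `label`, `stratum`, `concordant` columns), `concordance`,
#'   `n_concordant`, `n`, `threshold_log10`.
#' @export
classify_resistance <- function(records, threshold_log10 = 2) {
  if (threshold_log10 < 0) .config_error("threshold_log10 must be >= 0")
  need <- c("mutant", "drug", "log10_fold_change", "screen_expectation")
  miss <- setdiff(need, names(records))
  if (length(miss)) .config_error("phenotype records lack column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(records$log10_fold_change))) {
    .data_error("non-finite log10 fold change for mutant '%s'",
                records$mutant[which(!is.finite(records$log10_fold_change))[1L]])
  }
  lfc <- records$log10_fold_change
  label <- ifelse(lfc >= threshold_log10, "resistant", "sensitive")
  stratum <- ifelse(label != "resistant", NA_character_,
                    ifelse(lfc >= 4, "strong", "weak"))
  concordant <- label == records$screen_expectation
  out <- records
  out$label <- label
  out$stratum <- stratum
  out$concordant <- concordant
  structure(list(records = out, concordance = mean(concordant),
                 n_concordant = sum(concordant), n = nrow(records),
                 threshold_log10 = threshold_log10),
            class = "resistance_classification")
}

#' @export
print.resistance_classification <- function(x, ...) {
  cat(sprintf("Phenotype concordance: %d of %d records match the screen expectation (%.1f%%) at threshold %g log10\n",
              x$n_concordant, x$n, 100 * x$concordance, x$threshold_log10))
  invisible(x)
}

#' Read a validated-mutant phenotype table
#'
#' Tab-separated columns `mutant` / `drug` / `log10_fold_change` /
#' `screen_expectation`.
#'
#' @param path path to the TSV file.
#' @return data.frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .data_error("phenotype file not found: %s", path)
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mutant", "drug", "log10_fold_change", "screen_expectation")
  miss <- setdiff(need, names(p))
  if (length(miss)) .data_error("phenotype table lacks column(s): %s", paste(miss, collapse = ", "))
  p
}
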