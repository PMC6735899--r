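# ORF reference, genetic-code logic and domain annotations

#' ORF reference sequence
#'
#' Construct the reference object for a screened open reading frame (ORF):
#' the coding sequence plus any amplicon context outside the ORF. Reads are
#' aligned against the full amplicon (`flank5 + seq + flank3`), while mutations
#' are reported in 1-based ORF nucleotide coordinates and 1-based residue
#' numbers counted from the initiator methionine.
#'
#' @param seq ORF nucleotide sequence over `{A,C,G,T}`; its length must be a
#'   multiple of 3. Ambiguity codes (including `N`) are rejected.
#' @param id text label for the ORF (used as the SAM/VCF reference name).
#' @param flank5,flank3 amplicon sequence outside the ORF (may be empty).
#' @return An object of class `orf_reference` with fields `id`, `seq`,
#'   `flank5`, `flank3` and `codon_count`.
#' @seealso [read_reference()] to load a reference and its domain table from
#'   files, [translate_dna()], [substitution_from_mismatch()].
#' @export
#' @examples
#' ref <- orf_reference("ATGGAAGCTTGA", id = "toy")
#' ref$codon_count
orf_reference <- function(seq, id = "orf", flank5 = "", flank3 = "") {
  seq <- toupper(seq)
  flank5 <- toupper(flank5 %||% "")
  flank3 <- toupper(flank3 %||% "")
  .check_dna(seq, "ORF sequence")
  .check_dna(flank5, "flank5", allow_empty = TRUE)
  .check_dna(flank3, "flank3", allow_empty = TRUE)
  if (nchar(seq) %% 3L != 0L) {
    .data_error("ORF length %d is not divisible by 3", nchar(seq))
  }
  structure(list(id = as.character(id), seq = seq, flank5 = flank5,
                 flank3 = flank3, codon_count = nchar(seq) %/% 3L),
            class = "orf_reference")
}

#' @export
print.orf_reference <- function(x, ...) {
  cat(sprintf("ORF reference '%s': %d nt (%d codons), flanks %d/%d nt\n",
              x$id, nchar(x$seq), x$codon_count, nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

#' Full amplicon sequence of a reference
#'
#' @param ref an [orf_reference()].
#' @return `flank5 + seq + flank3` as a single string.
#' @export
amplicon <- function(ref) {
  stopifnot(inherits(ref, "orf_reference"))
  paste0(ref$flank5, ref$seq, ref$flank3)
}

# codon -> one-letter amino acid (stop = '*'); table comes from the standard
# genetic code shipped with Biostrings
.translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- NA_character_
  aa
}

#' Translate a nucleotide sequence
#'
#' Standard-genetic-code translation; stop codons are rendered as `*`.
#'
#' @param seq nucleotide string over `{A,C,G,T}` with length divisible by 3.
#' @return One-letter amino-acid string, one character per codon.
#' @export
#' @examples
#' translate_dna("ATGGAA") # "ME"
#' translate_dna("TGA")    # "*"
translate_dna <- function(seq) {
  seq <- toupper(seq)
  .check_dna(seq, "sequence")
  if (nchar(seq) %% 3L != 0L) {
    .data_error("sequence length %d is not divisible by 3", nchar(seq))
  }
  starts <- seq.int(1L, nchar(seq), by = 3L)
  paste(.translate_codons(substring(seq, starts, starts + 2L)), collapse = "")
}

#' Amino-acid substitution implied by a single-nucleotide mismatch
#'
#' Maps a single-base change at a 1-based ORF nucleotide position to the
#' amino-acid substitution it causes in the codon containing that position.
#' Synonymous changes are returned flagged, not dropped, so that callers can
#' keep an audit trail. Vectorized over `orf_pos`/`alt_base`.
#'
#' @param ref an [orf_reference()].
#' @param orf_pos 1-based ORF nucleotide index (vector allowed).
#' @param alt_base substituted base; must differ from the reference base.
#' @return data.frame with columns `orf_pos`, `ref_base`, `alt_base`,
#'   `residue` (1-based from the initiator Met), `ref_aa`, `alt_aa`
#'   (stop = `*`) and logical `synonymous`.
#' @export
#' @examples
#' ref <- orf_reference("ATGGAAGCTCTGTGG")
#' substitution_from_mismatch(ref, 4, "A")  # E2K
substitution_from_mismatch <- function(ref, orf_pos, alt_base) {
  stopifnot(inherits(ref, "orf_reference"))
  orf_pos <- as.integer(orf_pos)
  alt_base <- toupper(as.character(alt_base))
  if (length(alt_base) == 1L) alt_base <- rep(alt_base, length(orf_pos))
  if (length(alt_base) != length(orf_pos)) {
    .config_error("orf_pos and alt_base lengths differ")
  }
  bad <- which(is.na(orf_pos) | orf_pos < 1L | orf_pos > nchar(ref$seq))
  if (length(bad)) {
    .data_error("ORF position %s out of range [1, %d]",
                as.character(orf_pos[bad[1L]]), nchar(ref$seq))
  }
  bad <- which(!alt_base %in% DNA_BASES)
  if (length(bad)) .data_error("illegal substituted base '%s'", alt_base[bad[1L]])
  ref_base <- substring(ref$seq, orf_pos, orf_pos)
  bad <- which(alt_base == ref_base)
  if (length(bad)) {
    .data_error("substituted base equals the reference base at ORF position %d",
                orf_pos[bad[1L]])
  }
  residue <- (orf_pos - 1L) %/% 3L + 1L
  cstart <- (residue - 1L) * 3L + 1L
  codon <- substring(ref$seq, cstart, cstart + 2L)
  alt_codon <- codon
  off <- orf_pos - cstart + 1L
  substr(alt_codon, off, off) <- alt_base
  ref_aa <- .translate_codons(codon)
  alt_aa <- .translate_codons(alt_codon)
  data.frame(orf_pos = orf_pos, ref_base = ref_base, alt_base = alt_base,
             residue = residue, ref_aa = ref_aa, alt_aa = alt_aa,
             synonymous = ref_aa == alt_aa, stringsAsFactors = FALSE)
}

# depth of each annotation row (0 = top level), following parent pointers
.annotation_depth <- function(ann) {
  depth <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    d <- 0L
    p <- ann$parent[i]
    seen <- character(0)
    while (!is.na(p)) {
      if (p %in% seen) .data_error("domain annotation '%s' has a parent cycle", ann$name[i])
      seen <- c(seen, p)
      j <- match(p, ann$name)
      if (is.na(j)) .data_error("domain '%s' names unknown parent '%s'", ann$name[i], p)
      d <- d + 1L
      p <- ann$parent[j]
    }
    depth[i] <- d
  }
  depth
}

#' Validate a domain annotation table
#'
#' Checks 1-based inclusive residue intervals, containment of children within
#' their parents, and non-overlap of sibling intervals at the same nesting
#' level. Violations raise errors naming the offending record.
#'
#' @param ann data.frame with columns `name`, `start_res`, `end_res`,
#'   `parent` (`NA` or `""` for top level).
#' @param codon_count optional ORF length in codons; intervals must fit in
#'   `[1, codon_count]`.
#' @return The validated table (invisibly), with a `depth` column added.
#' @export
validate_annotations <- function(ann, codon_count = NULL) {
  need <- c("name", "start_res", "end_res", "parent")
  miss <- setdiff(need, names(ann))
  if (length(miss)) .data_error("annotation table lacks column(s): %s", paste(miss, collapse = ", "))
  ann$name <- as.character(ann$name)
  ann$parent <- as.character(ann$parent)
  ann$parent[!is.na(ann$parent) & ann$parent == ""] <- NA_character_
  ann$start_res <- as.integer(ann$start_res)
  ann$end_res <- as.integer(ann$end_res)
  if (anyDuplicated(ann$name)) {
    .data_error("duplicated domain name '%s'", ann$name[duplicated(ann$name)][1L])
  }
  bad <- which(is.na(ann$start_res) | is.na(ann$end_res) |
                 ann$start_res < 1L | ann$start_res > ann$end_res)
  if (length(bad)) {
    .data_error("domain '%s' has an invalid residue interval [%s, %s]",
                ann$name[bad[1L]], ann$start_res[bad[1L]], ann$end_res[bad[1L]])
  }
  if (!is.null(codon_count)) {
    bad <- which(ann$end_res > codon_count)
    if (length(bad)) {
      .data_error("domain '%s' ends at residue %d beyond the ORF (%d codons)",
                  ann$name[bad[1L]], ann$end_res[bad[1L]], codon_count)
    }
  }
  ann$depth <- .annotation_depth(ann)
  # child contained in parent
  for (i in seq_len(nrow(ann))) {
    p <- ann$parent[i]
    if (is.na(p)) next
    j <- match(p, ann$name)
    if (ann$start_res[i] < ann$start_res[j] || ann$end_res[i] > ann$end_res[j]) {
      .data_error("domain '%s' is not contained in its parent '%s'", ann$name[i], p)
    }
  }
  # siblings (same parent, NA included) must not overlap
  key <- ifelse(is.na(ann$parent), "<top>", ann$parent)
  for (grp in split(seq_len(nrow(ann)), key)) {
    if (length(grp) < 2L) next
    o <- grp[order(ann$start_res[grp])]
    for (k in seq_len(length(o) - 1L)) {
      if (ann$start_res[o[k + 1L]] <= ann$end_res[o[k]]) {
        .data_error("sibling domains '%s' and '%s' overlap",
                    ann$name[o[k]], ann$name[o[k + 1L]])
      }
    }
  }
  invisible(ann)
}

#' Read a domain annotation table
#'
#' Tab-separated columns `name` / `start_res` / `end_res` / `parent`
#' (1-based inclusive residue intervals; empty `parent` means top level).
#'
#' @param path path to the TSV file.
#' @param codon_count optional ORF length in codons used for bounds checking.
#' @return Validated annotation data.frame (with a computed `depth` column).
#' @export
read_domain_annotations <- function(path, codon_count = NULL) {
  if (!file.exists(path)) .data_error("annotation file not found: %s", path)
  ann <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = c(name = "character", start_res = "integer",
                                   end_res = "integer", parent = "character"))
  validate_annotations(ann, codon_count)
}

#' Deepest domain containing each residue
#'
#' Returns the name of the most deeply nested annotated interval containing
#' each residue; residues outside all annotations get `"unannotated"`.
#'
#' @param annotations validated annotation table (see
#'   [read_domain_annotations()]); a missing `depth` column is recomputed.
#' @param residue vector of 1-based residue indices.
#' @param rollup if `TRUE`, report the top-level ancestor instead of the
#'   deepest embedded domain.
#' @return Character vector of domain names, same length as `residue`.
#' @export
domain_of <- function(annotations, residue, rollup = FALSE) {
  if (is.null(annotations$depth)) annotations <- validate_annotations(annotations)
  residue <- as.integer(residue)
  out <- rep("unannotated", length(residue))
  if (nrow(annotations) == 0L) return(out)
  # ascend to top-level ancestors once, if rolling up
  top <- annotations$name
  if (rollup) {
    for (i in seq_len(nrow(annotations))) {
      p <- annotations$parent[i]
      while (!is.na(p)) {
        top[i] <- p
        p <- annotations$parent[match(p, annotations$name)]
      }
    }
  }
  ord <- order(annotations$depth)  # shallow first; deeper hits overwrite
  for (i in ord) {
    inside <- residue >= annotations$start_res[i] & residue <= annotations$end_res[i]
    out[inside] <- top[i]
  }
  out
}

#' Read an ORF reference (FASTA) and optional domain annotations
#'
#' The FASTA must contain exactly one ORF record; records named `flank5` /
#' `flank3` are treated as amplicon context outside the ORF. Both type
#' invariants (triplet ORF over `{A,C,G,T}`; consistent nested domains) are
#' validated on load.
#'
#' @param fasta_path path to the reference FASTA.
#' @param annotation_path optional path to the domain annotation TSV.
#' @return list with elements `ref` ([orf_reference()]) and `annotations`
#'   (data.frame or `NULL`).
#' @export
read_reference <- function(fasta_path, annotation_path = NULL) {
  if (!file.exists(fasta_path)) .data_error("FASTA file not found: %s", fasta_path)
  ss <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                 error = function(e) .data_error("malformed FASTA '%s': %s",
                                                 fasta_path, conditionMessage(e)))
  if (length(ss) == 0L) .data_error("empty FASTA: %s", fasta_path)
  nm <- sub("[ \t].*$", "", names(ss))
  is_flank <- nm %in% c("flank5", "flank3")
  if (sum(!is_flank) != 1L) {
    .data_error("FASTA must contain exactly one ORF record (found %d non-flank records)",
                sum(!is_flank))
  }
  orf_i <- which(!is_flank)
  f5 <- if ("flank5" %in% nm) as.character(ss[[match("flank5", nm)]]) else ""
  f3 <- if ("flank3" %in% nm) as.character(ss[[match("flank3", nm)]]) else ""
  ref <- orf_reference(as.character(ss[[orf_i]]), id = nm[orf_i],
                       flank5 = f5, flank3 = f3)
  ann <- if (!is.null(annotation_path)) {
    read_domain_annotations(annotation_path, ref$codon_count)
  }
  list(ref = ref, annotations = ann)
}

#' Paths to the packaged toy reference fixture
#'
#' A synthetic 300-codon ORF with 60-nt amplicon flanks, a nested 4-domain
#' annotation table, and a synthetic 23-record validated-mutant phenotype
#' table. All fixtures are generated, not biological sequences.
#'
#' @param file one of `"fasta"`, `"annotations"`, `"phenotypes"`; omit to get
#'   all three paths.
#' @return file path(s) under the installed package's `extdata/`.
#' @export
poolscreen_example <- function(file = c("fasta", "annotations", "phenotypes")) {
  file <- match.arg(file, several.ok = TRUE)
  p <- c(fasta = "toy_orf.fasta", annotations = "toy_domains.tsv",
         phenotypes = "phenotypes_synthetic.tsv")[file]
  out <- vapply(p, function(f) system.file("extdata", f, package = "poolscreen"), "")
  if (any(out == "")) .data_error("packaged fixture not found")
  if (length(out) == 1L) unname(out) else out
}
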