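# synthetic mutagenized plasmid pools and read simulation

#' Mutagenesis configuration
#'
#' Parameters of the chemical-mutagenesis model. Hydroxylamine predominantly
#' induces GC->AT transitions on plasmid DNA; `gc_to_at_fraction` is the
#' probability that an induced change is such a transition (C->T or G->A on
#' the coding strand), the remainder being uniform over all other
#' substitutions. Mutations per plasmid are Poisson distributed.
#'
#' @param mean_mutations Poisson mean number of substitutions per plasmid
#'   (default 1.5: functional selected alleles are dominated by one or two
#'   changes).
#' @param gc_to_at_fraction probability in `[0,1]` of a GC->AT transition
#'   (default 0.9: a strong bias that still permits transversion hits).
#' @param seed integer seed; mandatory for reproducible pools.
#' @return list of class `mutagenesis_config`.
#' @export
mutagenesis_config <- function(mean_mutations = 1.5, gc_to_at_fraction = 0.9,
                               seed = NULL) {
  if (!is.numeric(mean_mutations) || mean_mutations < 0) {
    .config_error("mean_mutations must be >= 0")
  }
  if (!is.numeric(gc_to_at_fraction) || gc_to_at_fraction < 0 ||
      gc_to_at_fraction > 1) {
    .config_error("gc_to_at_fraction must lie in [0, 1]")
  }
  structure(list(mean_mutations = mean_mutations,
                 gc_to_at_fraction = gc_to_at_fraction,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "mutagenesis_config")
}

#' Mutant allele
#'
#' One plasmid variant: a set of nucleotide substitutions relative to the ORF
#' reference, an abundance weight (relative colony size in the scraped pool)
#' and a ground-truth phenotype label.
#'
#' @param allele_id text identifier.
#' @param substitutions data.frame with columns `orf_pos`, `ref_base`,
#'   `alt_base` (0 rows for a wild-type plasmid). Positions must be unique
#'   within the allele.
#' @param abundance positive weight.
#' @param phenotype truth label (default `"sensitive"`).
#' @return list of class `mutant_allele`.
#' @export
mutant_allele <- function(allele_id, substitutions = NULL, abundance = 1,
                          phenotype = "sensitive") {
  if (is.null(substitutions)) {
    substitutions <- data.frame(orf_pos = integer(0), ref_base = character(0),
                                alt_base = character(0), stringsAsFactors = FALSE)
  }
  need <- c("orf_pos", "ref_base", "alt_base")
  if (!all(need %in% names(substitutions))) {
    .config_error("substitutions needs columns orf_pos/ref_base/alt_base")
  }
  if (anyDuplicated(substitutions$orf_pos)) {
    .data_error("allele '%s' has duplicated substitution positions", allele_id)
  }
  if (!is.numeric(abundance) || abundance <= 0) {
    .config_error("abundance must be a positive weight")
  }
  structure(list(allele_id = as.character(allele_id),
                 substitutions = substitutions,
                 abundance = as.numeric(abundance),
                 phenotype = as.character(phenotype)),
            class = "mutant_allele")
}

# check substitutions against the reference; corruption guard used by
# mutagenize() outputs and by user-constructed pools alike
validate_pool <- function(ref, alleles) {
  for (a in alleles) {
    s <- a$substitutions
    if (nrow(s) == 0L) next
    rb <- substring(ref$seq, s$orf_pos, s$orf_pos)
    bad <- which(rb != s$ref_base)
    if (length(bad)) {
      .data_error("allele '%s': ref_base '%s' at ORF position %d disagrees with the reference ('%s')",
                  a$allele_id, s$ref_base[bad[1L]], s$orf_pos[bad[1L]], rb[bad[1L]])
    }
    bad <- which(s$ref_base == s$alt_base)
    if (length(bad)) {
      .data_error("allele '%s': alt_base equals ref_base at ORF position %d",
                  a$allele_id, s$orf_pos[bad[1L]])
    }
  }
  invisible(alleles)
}

#' Simulate a hydroxylamine-mutagenized plasmid pool
#'
#' Draws `n_alleles` plasmid variants. Each carries a Poisson number of
#' substitutions; with probability `gc_to_at_fraction` a change is a GC->AT
#' transition at a uniformly chosen C/G site, otherwise it is a uniformly
#' chosen non-GC->AT substitution at a uniformly chosen site. Colony
#' abundances model the uneven sizes of pooled scraped colonies.
#'
#' @param ref an [orf_reference()]; only ORF positions are mutable.
#' @param cfg a [mutagenesis_config()].
#' @param n_alleles number of plasmids in the pool.
#' @param abundance_model `"lognormal"` (meanlog 0, `sdlog = abundance_sigma`)
#'   or `"uniform"` (all weights 1).
#' @param abundance_sigma log-normal sigma for colony-size skew (default 1).
#' @return list of [mutant_allele()] objects, class `mutant_pool`, with the
#'   reference id kept in `attr(, "ref_id")`.
#' @export
mutagenize <- function(ref, cfg, n_alleles,
                       abundance_model = c("lognormal", "uniform"),
                       abundance_sigma = 1) {
  stopifnot(inherits(ref, "orf_reference"), inherits(cfg, "mutagenesis_config"))
  abundance_model <- match.arg(abundance_model)
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L) .config_error("n_alleles must be >= 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  base_at <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  L <- length(base_at)
  cg <- which(base_at %in% c("C", "G"))
  if (length(cg) == 0L && cfg$gc_to_at_fraction > 0) {
    .data_error("reference has no C/G sites but gc_to_at_fraction > 0")
  }
  n_mut <- rpois(n_alleles, cfg$mean_mutations)
  abundance <- switch(abundance_model,
                      lognormal = rlnorm(n_alleles, 0, abundance_sigma),
                      uniform = rep(1, n_alleles))
  alleles <- vector("list", n_alleles)
  for (i in seq_len(n_alleles)) {
    pos <- integer(0)
    alt <- character(0)
    tries <- 0L
    while (length(pos) < n_mut[i]) {
      tries <- tries + 1L
      if (tries > 100L * (n_mut[i] + 1L)) {
        .data_error("cannot place %d distinct substitutions on this reference", n_mut[i])
      }
      gcat <- runif(1) < cfg$gc_to_at_fraction
      p <- if (gcat) cg[sample.int(length(cg), 1L)] else sample.int(L, 1L)
      if (p %in% pos) next
      rb <- base_at[p]
      ab <- if (gcat) {
        if (rb == "C") "T" else "A"
      } else {
        opts <- setdiff(DNA_BASES, rb)
        if (rb == "C") opts <- setdiff(opts, "T")
        if (rb == "G") opts <- setdiff(opts, "A")
        opts[sample.int(length(opts), 1L)]
      }
      pos <- c(pos, p)
      alt <- c(alt, ab)
    }
    o <- order(pos)
    alleles[[i]] <- mutant_allele(
      sprintf("allele_%05d", i),
      data.frame(orf_pos = pos[o], ref_base = base_at[pos[o]], alt_base = alt[o],
                 stringsAsFactors = FALSE),
      abundance = abundance[i])
  }
  structure(alleles, class = "mutant_pool", ref_id = ref$id)
}

#' @export
print.mutant_pool <- function(x, ...) {
  nm <- vapply(x, function(a) nrow(a$substitutions), 0L)
  cat(sprintf("Mutant pool: %d alleles, %d substitutions total (mean %.2f/allele)\n",
              length(x), sum(nm), mean(nm)))
  invisible(x)
}

#' Apply drug selection to a pool
#'
#' Assigns each allele a truth phenotype from a mutation->label map (alleles
#' carrying none of the listed mutations are `"sensitive"`), then retains the
#' alleles whose label is in `survival_labels`, plus a background escape
#' fraction of the others to model plating noise.
#'
#' @param pool a `mutant_pool` (list of [mutant_allele()]).
#' @param phenotype_map data.frame with columns `orf_pos`, `alt_base`,
#'   `label`; the first matching row (map order) labels an allele.
#' @param survival_labels labels that survive plating.
#' @param escape_fraction probability that a non-surviving allele escapes
#'   selection anyway (default 0).
#' @param seed optional seed for the escape draws.
#' @return the filtered `mutant_pool`, with `phenotype` fields set.
#' @export
apply_selection <- function(pool, phenotype_map, survival_labels,
                            escape_fraction = 0, seed = NULL) {
  known <- unique(c("sensitive", phenotype_map$label))
  bad <- setdiff(survival_labels, known)
  if (length(bad)) .config_error("unknown survival label '%s'", bad[1L])
  if (escape_fraction < 0 || escape_fraction > 1) {
    .config_error("escape_fraction must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  map_key <- paste(phenotype_map$orf_pos, phenotype_map$alt_base)
  labelled <- lapply(pool, function(a) {
    s <- a$substitutions
    hit <- match(paste(s$orf_pos, s$alt_base), map_key)
    hit <- hit[!is.na(hit)]
    a$phenotype <- if (length(hit)) phenotype_map$label[min(hit)] else "sensitive"
    a
  })
  keep <- vapply(labelled, function(a) a$phenotype %in% survival_labels, NA)
  if (escape_fraction > 0 && any(!keep)) {
    keep[!keep] <- runif(sum(!keep)) < escape_fraction
  }
  out <- labelled[keep]
  if (length(out) == 0L) warning("no alleles survive selection: empty pool")
  structure(out, class = "mutant_pool", ref_id = attr(pool, "ref_id"))
}

#' Read-simulation configuration
#'
#' Single-end Illumina-style reads from random fragments of the amplicon.
#' Fragment lengths are uniform on `[fragment_min, fragment_max]` (the
#' enzymatic fragmentation window of the library prep), the read is the first
#' `read_length` bases of a uniformly chosen strand of the fragment, and when
#' `error_coupling` is on every base is flipped to a uniformly chosen other
#' base with probability `10^(-Q/10)` for its drawn Phred score Q.
#'
#' @param n_reads number of reads to simulate.
#' @param read_length read length in nt (default 100).
#' @param fragment_min,fragment_max fragmentation bounds in nt
#'   (defaults 200 and 500).
#' @param quality_model per-base Phred distribution: `list(type = "constant",
#'   q = 38)`, `list(type = "discrete", q = ..., p = ...)` or `list(type =
#'   "normal", mean = , sd = , min = , max = )`. The default is a discrete
#'   Illumina-like mixture concentrated at Q40 with a low-quality tail.
#' @param error_coupling logical; couple the error channel to the drawn
#'   qualities (default `TRUE`).
#' @param seed integer seed; mandatory for reproducible FASTQ output.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads, read_length = 100L, fragment_min = 200L,
                            fragment_max = 500L,
                            quality_model = list(type = "discrete",
                                                 q = c(22, 27, 32, 37, 40),
                                                 p = c(0.03, 0.05, 0.12, 0.20, 0.60)),
                            error_coupling = TRUE, seed = NULL) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L) .config_error("n_reads must be positive")
  read_length <- as.integer(read_length)
  fragment_min <- as.integer(fragment_min)
  fragment_max <- as.integer(fragment_max)
  if (fragment_min > fragment_max) .config_error("fragment_min must be <= fragment_max")
  if (read_length > fragment_min) .config_error("read_length must be <= fragment_min")
  if (!is.list(quality_model) || is.null(quality_model$type)) {
    .config_error("quality_model must be a list with a 'type' field")
  }
  structure(list(n_reads = n_reads, read_length = read_length,
                 fragment_min = fragment_min, fragment_max = fragment_max,
                 quality_model = quality_model,
                 error_coupling = isTRUE(error_coupling),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "read_sim_config")
}

# draw an n x read_length matrix of Phred scores from a quality model
.sample_quals <- function(model, n, rl) {
  total <- n * rl
  q <- switch(model$type,
              constant = rep(as.integer(model$q), total),
              discrete = sample(as.integer(model$q), total, replace = TRUE,
                                prob = model$p),
              normal = {
                x <- round(rnorm(total, model$mean, model$sd))
                pmin(pmax(as.integer(x), as.integer(model$min %||% 2L)),
                     as.integer(model$max %||% 41L))
              },
              .config_error("unknown quality model type '%s'", model$type))
  matrix(as.integer(q), nrow = n, ncol = rl)
}

#' Simulate sequencing reads from a mutant pool
#'
#' Reads are drawn from alleles proportional to abundance; fragment starts are
#' uniform over the amplicon and fragment lengths uniform over the configured
#' window; each read is the first `read_length` bases of a uniformly chosen
#' strand of its fragment. When error coupling is on, each base is replaced by
#' a uniformly chosen other base with probability `10^(-Q/10)`.
#'
#' @param ref an [orf_reference()].
#' @param pool a non-empty `mutant_pool`.
#' @param cfg a [read_sim_config()].
#' @param fastq_out optional path for the Phred+33 FASTQ output.
#' @param truth_out optional path for the tab-separated truth table
#'   (`allele_id` / `orf_pos` / `ref_base` / `alt_base` / `ref_aa` /
#'   `residue` / `alt_aa` / `abundance`).
#' @return (invisibly) a list of class `read_sim_summary` with the realized
#'   per-substitution read coverage (`per_substitution`: reads drawn from a
#'   carrier allele whose window overlaps the site, before errors), the
#'   per-allele truth table (`truth`), and bookkeeping totals.
#' @export
simulate_reads <- function(ref, pool, cfg, fastq_out = NULL, truth_out = NULL) {
  stopifnot(inherits(ref, "orf_reference"), inherits(cfg, "read_sim_config"))
  if (length(pool) == 0L) .data_error("cannot simulate reads from an empty pool")
  validate_pool(ref, pool)
  amp <- amplicon(ref)
  amp_len <- nchar(amp)
  f5 <- nchar(ref$flank5)
  if (cfg$fragment_max > amp_len) {
    .config_error("fragment_max (%d) exceeds the amplicon length (%d)",
                  cfg$fragment_max, amp_len)
  }
  n <- cfg$n_reads
  rl <- cfg$read_length
  n_alleles <- length(pool)

  amp_chars <- strsplit(amp, "", fixed = TRUE)[[1]]
  allele_amp <- vapply(pool, function(a) {
    ch <- amp_chars
    s <- a$substitutions
    if (nrow(s)) ch[s$orf_pos + f5] <- s$alt_base
    paste(ch, collapse = "")
  }, "")
  abundance <- vapply(pool, `[[`, 0, "abundance")

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  aidx <- sample.int(n_alleles, n, replace = TRUE, prob = abundance)
  flen <- cfg$fragment_min +
    floor(runif(n) * (cfg$fragment_max - cfg$fragment_min + 1L))
  fstart <- 1L + floor(runif(n) * (amp_len - flen + 1L))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  ws <- as.integer(ifelse(strand == "+", fstart, fstart + flen - rl))
  we <- ws + rl - 1L
  seqs <- substring(allele_amp[aidx], ws, we)
  minus <- strand == "-"
  seqs[minus] <- .revcomp(seqs[minus])

  qmat <- .sample_quals(cfg$quality_model, n, rl)
  n_errors <- 0L
  if (cfg$error_coupling) {
    perr <- 10^(-qmat / 10)
    hit <- which(runif(length(perr)) < perr)  # column-major over n x rl
    n_errors <- length(hit)
    if (n_errors) {
      r <- (hit - 1L) %% n + 1L
      p <- (hit - 1L) %/% n + 1L
      for (e in seq_along(hit)) {
        cur <- substr(seqs[r[e]], p[e], p[e])
        substr(seqs[r[e]], p[e], p[e]) <-
          sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
  }
  ids <- sprintf("read_%07d", seq_len(n))
  quals <- vapply(seq_len(n), function(i) .phred_encode(qmat[i, ]), "")
  if (!is.null(fastq_out)) write_fastq(ids, seqs, quals, fastq_out)

  # truth table (per allele x substitution) and realized coverage
  truth <- do.call(rbind, lapply(pool, function(a) {
    s <- a$substitutions
    if (nrow(s) == 0L) return(NULL)
    aa <- substitution_from_mismatch(ref, s$orf_pos, s$alt_base)
    data.frame(allele_id = a$allele_id, orf_pos = s$orf_pos,
               ref_base = s$ref_base, alt_base = s$alt_base,
               ref_aa = aa$ref_aa, residue = aa$residue, alt_aa = aa$alt_aa,
               abundance = a$abundance, stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(allele_id = character(0), orf_pos = integer(0),
                        ref_base = character(0), alt_base = character(0),
                        ref_aa = character(0), residue = integer(0),
                        alt_aa = character(0), abundance = numeric(0),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(truth_out)) {
    write.table(truth, truth_out, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  per_sub <- NULL
  if (nrow(truth)) {
    reads_by_allele <- split(seq_len(n), aidx)
    site_amp <- truth$orf_pos + f5
    cov <- integer(nrow(truth))
    a_of_row <- match(truth$allele_id, vapply(pool, `[[`, "", "allele_id"))
    for (i in seq_len(nrow(truth))) {
      rr <- reads_by_allele[[as.character(a_of_row[i])]]
      cov[i] <- if (is.null(rr)) 0L else
        sum(ws[rr] <= site_amp[i] & we[rr] >= site_amp[i])
    }
    truth$reads_covering <- cov
    per_sub <- stats::aggregate(
      reads_covering ~ orf_pos + ref_base + alt_base + residue + ref_aa + alt_aa,
      data = truth, FUN = sum)
    per_sub <- per_sub[order(-per_sub$reads_covering, per_sub$orf_pos), ]
    rownames(per_sub) <- NULL
  }

  out <- structure(list(n_reads = n, n_alleles = n_alleles,
                        n_errors_injected = n_errors,
                        truth = truth, per_substitution = per_sub,
                        fastq = fastq_out, truth_path = truth_out),
                   class = "read_sim_summary")
  invisible(out)
}

#' @export
print.read_sim_summary <- function(x, ...) {
  cat(sprintf("Simulated %d reads from %d alleles (%d sequencing errors injected)\n",
              x$n_reads, x$n_alleles, x$n_errors_injected))
  if (!is.null(x$per_substitution)) {
    cat(sprintf("  %d distinct true substitutions; median site coverage %.0f reads\n",
                nrow(x$per_substitution),
                stats::median(x$per_substitution$reads_covering)))
  }
  invisible(x)
}
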