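# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poolscreen_config_error", "poolscreen_error",
                                "error", "condition")))
}

.data_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poolscreen_data_error", "poolscreen_error",
                                "error", "condition")))
}

.check_dna <- function(x, what, allow_empty = FALSE) {
  if (length(x) != 1L || is.na(x)) .data_error("%s must be a single string", what)
  if (!nzchar(x)) {
    if (allow_empty) return(invisible(x))
    .data_error("%s must be non-empty", what)
  }
  bad <- gsub("[ACGT]", "", x)
  if (nzchar(bad)) {
    .data_error("%s contains characters outside {A,C,G,T}: '%s'", what,
                substr(bad, 1L, 10L))
  }
  invisible(x)
}

# reverse complement for a character vector (may contain N)
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 decoding with fail-fast range check (rejects other dialects)
.phred_decode <- function(qual, record = NA_integer_) {
  q <- utf8ToInt(qual) - 33L
  if (any(q < 0L) || any(q > 62L)) {
    .data_error("quality string%s is not Phred+33 (score outside [0, 62])",
                if (is.na(record)) "" else sprintf(" in record %d", record))
  }
  q
}

.phred_encode <- function(q) intToUtf8(as.integer(q) + 33L)

# minimal 4-line-record FASTQ reader; errors name the offending record index
read_fastq <- function(path) {
  if (!file.exists(path)) .data_error("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    .data_error("malformed FASTQ: truncated record %d (line count %d not a multiple of 4)",
                length(lines) %/% 4L + 1L, length(lines))
  }
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) .data_error("malformed FASTQ: record %d header does not start with '@'", bad[1L])
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) .data_error("malformed FASTQ: record %d separator does not start with '+'", bad[1L])
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    .data_error("malformed FASTQ: record %d sequence and quality lengths differ", bad[1L])
  }
  bad <- which(grepl("[^ACGTN]", sq))
  if (length(bad)) .data_error("malformed FASTQ: record %d has bases outside {A,C,G,T,N}", bad[1L])
  bad <- which(grepl("[^!-_]", ql))  # Phred+33 scores 0..62 are '!'..'_'
  if (length(bad)) {
    .data_error("record %d quality string is not Phred+33 (score outside [0, 62])",
                bad[1L])
  }
  ids <- sub("^@", "", hd)
  ids <- sub("[ \t].*$", "", ids)
  data.frame(id = ids, seq = sq, qual = ql, stringsAsFactors = FALSE)
}

write_fastq <- function(id, seq, qual, path) {
  con <- file(path, open = "wb")  # fixed newline convention => byte-identical reruns
  on.exit(close(con))
  rec <- paste0("@", id, "\n", seq, "\n+\n", qual)
  writeLines(rec, con = con, sep = "\n")
  invisible(path)
}
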