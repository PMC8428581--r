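#' Sequence file input and output
#'
#' FASTA and FASTQ ingestion (optionally gzip-compressed, format auto-detected
#' from the first byte) via Biostrings, plus writers for the generator. Only
#' the sequences matter downstream: FASTQ quality lines are ignored, so FASTA
#' and FASTQ encodings of the same reads are interchangeable.
#'
#' @name sequence-io
NULL

.detect_format <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  first <- readChar(con, 1L, useBytes = TRUE)
  if (length(first) == 0L || !nzchar(first)) return(NA_character_)
  switch(first, ">" = "fasta", "@" = "fastq",
         stop("cannot detect FASTA/FASTQ format of ", path,
              " (first byte '", first, "')"))
}

#' Read sequences from FASTA/FASTQ files
#'
#' @param paths Character vector of file paths; each may be FASTA or FASTQ,
#'   plain or gzip-compressed. Multi-line FASTA is supported.
#' @return A tibble `read_id`, `sequence` in file order (files concatenated
#'   in the order given). An empty file yields a warning and zero rows.
#' @export
read_sequences <- function(paths) {
  stopifnot(all(file.exists(paths)))
  out <- lapply(paths, function(path) {
    fmt <- .detect_format(path)
    if (is.na(fmt)) {
      warning("empty input file: ", path)
      return(tibble::tibble(read_id = character(), sequence = character()))
    }
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = fmt),
      error = function(e) {
        stop("malformed ", fmt, " in ", path, ": ", conditionMessage(e))
      }
    )
    tibble::tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = unname(as.character(x))
    )
  })
  dplyr::bind_rows(out)
}

#' Write reads to a FASTA or FASTQ file
#'
#' @param reads A tibble `read_id`, `sequence`.
#' @param path Output path; a `.gz` suffix enables gzip compression.
#' @param format `"fasta"` or `"fastq"` (FASTQ gets uniform placeholder
#'   qualities, since no error model is simulated).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  }
  invisible(path)
}

# TSV writers: fixed column layouts per output type, tab-separated, with a
# header comment line where the metric definitions need stating.
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[, c("kmer", "count")], path)
  invisible(path)
}

write_histogram_tsv <- function(hist, path) {
  readr::write_tsv(hist, path)
  invisible(path)
}

write_binstats_tsv <- function(summaries, path) {
  readr::write_tsv(
    dplyr::rename(summaries, supermers = "n_supermers",
                  distinct = "n_distinct_kmers", total = "n_total_kmers"),
    path)
  invisible(path)
}

write_report_tsv <- function(report, path) {
  con <- file(path, "w")
  writeLines(paste0("# bin size = total k-mers per bin; stddev is the ",
                    "population standard deviation"), con)
  close(con)
  readr::write_tsv(
    dplyr::rename(report, bins = "n_bins", mean = "mean_bin",
                  max = "max_bin", max_mean = "max_mean_ratio",
                  stddev = "sd_bin", avg_supermer = "avg_supermer_kmers",
                  top0.5pct = "top_fraction_pct"),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_density_tsv <- function(points, path) {
  readr::write_tsv(points, path)
  invisible(path)
}
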