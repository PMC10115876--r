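#' Read a FASTQ file
#'
#' Gzip-transparent, four-line records.
#'
#' @param path FASTQ path.
#' @return data.frame with `id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ record count not a multiple of 4 in ", path, call. = FALSE)
  }
  i <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", lines[i]),
             sequence = lines[i + 1L],
             qualities = lines[i + 3L],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param ids,sequences,qualities Equal-length character vectors.
#' @param path Output path (plain text; byte-reproducible).
#' @export
write_fastq <- function(ids, sequences, qualities, path) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(qualities))
  con <- file(path, "wb")
  on.exit(close(con))
  out <- character(4L * length(ids))
  out[seq(1L, length(out), 4L)] <- paste0("@", ids)
  out[seq(2L, length(out), 4L)] <- sequences
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qualities
  writeLines(out, con, sep = "\n")
  invisible(path)
}
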