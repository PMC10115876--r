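#' A qPCR Ct record
#'
#' @param sample Sample id.
#' @param gene Gene id.
#' @param ct Numeric replicate Ct values (cycles); all positive and finite,
#'   at least one replicate.
#' @return Object of class `ct_record`.
#' @export
ct_record <- function(sample, gene, ct) {
  ct <- as.numeric(ct)
  if (!length(ct)) stop("at least one Ct replicate required", call. = FALSE)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  structure(list(sample = as.character(sample), gene = as.character(gene),
                 ct = ct), class = "ct_record")
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-((mean Ct_target - mean Ct_ref) - (mean Ct_target_cal -
#' mean Ct_ref_cal))`. Replicates are aggregated by the arithmetic mean of
#' Ct. Adding a constant to every Ct leaves the fold unchanged.
#'
#' @param target,reference Ct records for the gene of interest and the
#'   housekeeping reference in the test sample.
#' @param target_cal,reference_cal The same two genes in the calibrator
#'   sample.
#' @return Fold change (positive numeric).
#' @export
delta_delta_ct <- function(target, reference, target_cal, reference_cal) {
  recs <- list(target, reference, target_cal, reference_cal)
  ok <- vapply(recs, function(r) inherits(r, "ct_record") && length(r$ct) > 0,
               logical(1))
  if (!all(ok)) stop("all four arguments must be non-empty ct_records",
                     call. = FALSE)
  d_test <- mean(target$ct) - mean(reference$ct)
  d_cal <- mean(target_cal$ct) - mean(reference_cal$ct)
  2^(-(d_test - d_cal))
}

#' Beta/alpha-globin expression ratio
#'
#' @param beta_rel,alpha_rel Relative expression values (e.g. delta-delta-Ct
#'   folds) for beta- and alpha-globin.
#' @return `beta_rel / alpha_rel`.
#' @export
beta_alpha_ratio <- function(beta_rel, alpha_rel) {
  if (!is.finite(alpha_rel) || alpha_rel <= 0) {
    stop("alpha_rel must be positive", call. = FALSE)
  }
  beta_rel / alpha_rel
}

#' Read a Ct table from TSV
#'
#' Columns: `sample`, `gene`, then one column per replicate (`ct1`...).
#'
#' @param path TSV path.
#' @return List of [ct_record()]s keyed `sample|gene`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ct_cols <- grep("^ct", names(df), value = TRUE)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    ct_record(df$sample[i], df$gene[i],
              unlist(df[i, ct_cols], use.names = FALSE))
  })
  stats::setNames(recs, paste(df$sample, df$gene, sep = "|"))
}

#' Per-sample fold changes and beta/alpha ratios from a Ct table
#'
#' For each test sample, computes delta-delta-Ct folds for the target
#' genes against the reference gene, calibrated on `calibrator`, plus the
#' beta/alpha ratio.
#'
#' @param records List from [read_ct_table()].
#' @param samples Test sample ids.
#' @param calibrator Calibrator sample id (e.g. unedited control).
#' @param beta_gene,alpha_gene,reference_gene Gene ids.
#' @return data.frame with `sample`, `beta_fold`, `alpha_fold`, `ratio`.
#' @export
expression_summary <- function(records, samples, calibrator,
                               beta_gene = "HBB", alpha_gene = "HBA",
                               reference_gene = "RPL13A") {
  get <- function(sample, gene) {
    key <- paste(sample, gene, sep = "|")
    if (is.null(records[[key]])) stop("missing Ct record ", key, call. = FALSE)
    records[[key]]
  }
  rows <- lapply(samples, function(s) {
    bf <- delta_delta_ct(get(s, beta_gene), get(s, reference_gene),
                         get(calibrator, beta_gene),
                         get(calibrator, reference_gene))
    af <- delta_delta_ct(get(s, alpha_gene), get(s, reference_gene),
                         get(calibrator, alpha_gene),
                         get(calibrator, reference_gene))
    data.frame(sample = s, beta_fold = bf, alpha_fold = af,
               ratio = beta_alpha_ratio(bf, af), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
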