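#' Read and write screen tables
#'
#' All tables are tab-separated UTF-8 text with a header row.
#' `read_events()` expects columns `sgrna_id, gene, replicate, target_site,
#' kind, mh_length, donor_match, read_count`; `read_counts()` expects the
#' four key columns followed by count columns for the seven analysis
#' categories (a `WT` column, if present, is dropped: wild-type reads are
#' excluded from analysis spectra).
#'
#' @param path file path.
#' @return data frame in the package's event / count / spectra schema.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sgrna_id", "gene", "replicate", "target_site", "kind",
           "mh_length", "donor_match", "read_count")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols)) {
    stop("events file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ev$donor_match <- as.logical(ev$donor_match)
  ev
}

#' @rdname screen_io
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$WT <- NULL
  for (key in c("sgrna_id", "gene", "replicate", "target_site")) {
    if (key %in% names(tab)) tab[[key]] <- as.character(tab[[key]])
  }
  validate_count_table(tab)
}

#' @rdname screen_io
#' @param table data frame to write.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_spectra <- function(path) {
  sp <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "target_site", analysis_categories())
  missing_cols <- setdiff(req, names(sp))
  if (length(missing_cols)) {
    stop("spectra file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  sp
}

#' Read a term-to-gene annotation table
#'
#' Accepts either a two/three-column TSV (`term_id`, `gene`, optional
#' `term_name`) or GMT format (term, description, then member genes, one term
#' per line).
#'
#' @param path file path.
#' @param format `"auto"` (default; GMT if the extension is `.gmt`),
#'   `"tsv"`, or `"gmt"`.
#' @return data frame with columns `term_id`, `term_name`, `gene`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    lines <- lines[lengths(lines) >= 3]
    out <- do.call(rbind, lapply(lines, function(f) {
      data.frame(term_id = f[1], term_name = f[2], gene = f[-(1:2)],
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene") %in% names(ann))) {
    stop("annotation TSV needs columns term_id and gene")
  }
  if (is.null(ann$term_name)) ann$term_name <- ann$term_id
  ann[c("term_id", "term_name", "gene")]
}

#' Read a gene list (one gene id per line)
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
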