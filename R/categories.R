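#' Mutation outcome categories
#'
#' Repair outcomes at a CRISPR-induced double-strand break are aggregated into
#' eight higher-level categories: wild-type reads (`WT`), deletions stratified
#' by flanking microhomology length (`DEL_MH0`, `DEL_MH1`, `DEL_MH2`,
#' `DEL_MH3P` for 0, 1, 2 and 3+ bp), insertions (`INS`), combined
#' deletion-insertions (`DELINS`), and insertions matching the donor template
#' (`HDR`, homology-directed repair). Wild-type reads are excluded from
#' analysis spectra because changes in their abundance can reflect gene
#' essentiality or cutting efficiency rather than repair pathway choice, so
#' analysis spectra use exactly the seven non-WT categories, in the canonical
#' order returned by [analysis_categories()].
#'
#' @return `mutation_categories()` returns all eight category names;
#'   `analysis_categories()` returns the seven used in spectra.
#' @export
#' @examples
#' analysis_categories()
mutation_categories <- function() {
  c("WT", analysis_categories())
}

#' @rdname mutation_categories
#' @export
analysis_categories <- function() {
  c("DEL_MH0", "DEL_MH1", "DEL_MH2", "DEL_MH3P", "INS", "DELINS", "HDR")
}

.event_kinds <- c("wildtype", "deletion", "insertion", "deletion_insertion",
                  "substitution", "other")

#' Map called mutation events to outcome categories
#'
#' Assigns each called event its aggregate category: deletions are split by
#' microhomology length (0/1/2/3+ bp, the footprint used to distinguish
#' microhomology-mediated end joining from blunt end joining), insertions that
#' match the donor template are counted as HDR, and combined
#' deletion-insertions form their own class. Substitutions and other rare
#' event kinds are not typical double-strand break repair products and map to
#' `NA` (excluded); wild-type reads map to `WT` and are dropped later when
#' counts are tabulated.
#'
#' @param kind character vector of event kinds; one of `"wildtype"`,
#'   `"deletion"`, `"insertion"`, `"deletion_insertion"`, `"substitution"`,
#'   `"other"`.
#' @param mh_length integer vector of flanking microhomology lengths in bp;
#'   only consulted for deletions.
#' @param donor_match logical vector; whether an insertion matches the donor
#'   template. Only consulted for insertions.
#' @return character vector of category names (see [mutation_categories()]),
#'   `NA` for excluded events.
#' @export
#' @examples
#' categorize_event("deletion", mh_length = 2)     # "DEL_MH2"
#' categorize_event("insertion", donor_match = TRUE) # "HDR"
#' categorize_event("substitution")                # NA: excluded
categorize_event <- function(kind, mh_length = 0L, donor_match = FALSE) {
  kind <- as.character(kind)
  bad <- !(kind %in% .event_kinds)
  if (any(bad)) {
    stop("unknown event kind(s): ", paste(unique(kind[bad]), collapse = ", "))
  }
  n <- length(kind)
  mh_length <- rep_len(as.integer(mh_length), n)
  donor_match <- rep_len(as.logical(donor_match), n)
  if (any(mh_length < 0, na.rm = TRUE)) stop("mh_length must be >= 0")

  out <- rep(NA_character_, n)
  out[kind == "wildtype"] <- "WT"
  del <- kind == "deletion"
  out[del] <- paste0("DEL_MH", pmin(mh_length[del], 3L))
  out[del & mh_length >= 3L] <- "DEL_MH3P"
  ins <- kind == "insertion"
  out[ins] <- ifelse(donor_match[ins], "HDR", "INS")
  out[kind == "deletion_insertion"] <- "DELINS"
  # substitution / other stay NA (excluded)
  out
}

#' Tabulate categorized events into a count table
#'
#' Sums read counts per (sgRNA, gene, replicate, target site) row and analysis
#' category. Wild-type and excluded events contribute nothing; categories
#' never observed for a row are stored as 0.
#'
#' @param events data frame with columns `sgrna_id`, `gene`, `replicate`,
#'   `target_site`, `kind`, `mh_length`, `donor_match`, `read_count`.
#' @return a count table: data frame with the four key columns followed by the
#'   seven analysis-category count columns, one row per distinct key.
#' @seealso [read_events()], [preprocess_counts()]
#' @export
build_count_table <- function(events) {
  req <- c("sgrna_id", "gene", "replicate", "target_site", "kind",
           "mh_length", "donor_match", "read_count")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("events table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(events$read_count < 0)) stop("read_count must be >= 0")

  cats <- analysis_categories()
  events$category <- categorize_event(events$kind, events$mh_length,
                                      events$donor_match)
  keep <- !is.na(events$category) & events$category != "WT"
  keys <- unique(events[c("sgrna_id", "gene", "replicate", "target_site")])
  ev <- events[keep, , drop = FALSE]

  mat <- matrix(0, nrow = nrow(keys), ncol = length(cats),
                dimnames = list(NULL, cats))
  if (nrow(ev)) {
    key_id <- function(d) paste(d$sgrna_id, d$gene, d$replicate, d$target_site,
                                sep = "\r")
    row_idx <- match(key_id(ev), key_id(keys))
    col_idx <- match(ev$category, cats)
    for (i in seq_len(nrow(ev))) {
      mat[row_idx[i], col_idx[i]] <- mat[row_idx[i], col_idx[i]] +
        ev$read_count[i]
    }
  }
  out <- cbind(keys, as.data.frame(mat))
  rownames(out) <- NULL
  validate_count_table(out)
}

#' Validate a count table
#'
#' Checks the fixed column set (four key columns plus the seven analysis
#' categories), non-negative counts and uniqueness of row keys.
#'
#' @param table candidate count table.
#' @return the table, invisibly unchanged, or an error.
#' @export
validate_count_table <- function(table) {
  req <- c("sgrna_id", "gene", "replicate", "target_site",
           analysis_categories())
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  cnt <- as.matrix(table[analysis_categories()])
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    stop("counts must be finite and >= 0")
  }
  keys <- do.call(paste, c(table[c("sgrna_id", "gene", "replicate",
                                   "target_site")], sep = "\r"))
  if (anyDuplicated(keys)) stop("duplicate (sgRNA, gene, replicate, target) keys")
  table
}

count_matrix <- function(table) {
  as.matrix(table[analysis_categories()])
}
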