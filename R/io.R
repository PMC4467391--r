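# Reading and writing the tabular contracts: multi-sample event tables in the
# published layout (Mb coordinates, category tokens, per-sample/clonality
# presence columns), window counts and SNP tables.

#' Read a multi-sample copy-number event table
#'
#' Parses a TSV in the published event-table layout: columns `chrom`,
#' `start_mb`, `end_mb`, `length_mb` (2-decimal Mb), optional `cytobands`,
#' `type` (one of LOH, HL, OCL, CG, HCG, VHCG, EHCG), followed by one
#' presence column per sample/clonality combination (entries `x` or empty).
#' Presence columns named `<sample>_complete` / `<sample>_subclone` are
#' grouped per sample; an event is present in a sample when any of its
#' columns is marked. Rows with `end < start` or an unknown category token
#' are errors (naming the row); a printed length deviating from
#' `end - start` by more than `tolerance` Mb draws a warning per row.
#'
#' @param path TSV file.
#' @param tolerance allowed |length - (end - start)| in Mb.
#' @return list with `table` (the parsed data.frame), `sets` (named list of
#'   [sample_event_set()]s, bp coordinates) and `samples`.
#' @export
read_event_table <- function(path, tolerance = 0.011) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  need <- c("chrom", "start_mb", "end_mb", "length_mb", "type")
  stopifnot(all(need %in% names(d)))
  for (col in c("start_mb", "end_mb", "length_mb")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  bad <- which(d$end_mb < d$start_mb)
  if (length(bad)) {
    stop("row ", bad[1], ": end (", d$end_mb[bad[1]], ") < start (",
         d$start_mb[bad[1]], ")")
  }
  known <- c(LOSS_TYPES, GAIN_TYPES)
  bad <- which(!d$type %in% known)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown category token '", d$type[bad[1]], "'")
  }
  dev <- abs(d$end_mb - d$start_mb - d$length_mb)
  for (i in which(dev > tolerance)) {
    warning(sprintf("row %d (%s:%g-%g): length %.2f Mb deviates from span %.2f Mb",
                    i, d$chrom[i], d$start_mb[i], d$end_mb[i],
                    d$length_mb[i], d$end_mb[i] - d$start_mb[i]))
  }
  meta <- c(need, "cytobands")
  pres_cols <- setdiff(names(d), meta)
  samples <- unique(sub("_(complete|subclone)$", "", pres_cols))
  sets <- lapply(samples, function(s) {
    cols <- pres_cols[sub("_(complete|subclone)$", "", pres_cols) == s]
    pres <- apply(d[cols] == "x", 1, any)
    complete_col <- intersect(paste0(s, "_complete"), cols)
    clonality <- rep("complete", nrow(d))
    if (length(complete_col)) {
      clonality <- ifelse(d[[complete_col]] == "x", "complete", "subclonal")
    }
    ev <- data.frame(
      chrom = d$chrom, start = d$start_mb * 1e6, end = d$end_mb * 1e6,
      length_mb = d$length_mb, type = d$type,
      clonality = ifelse(d$type %in% GAIN_TYPES, "indeterminate", clonality),
      stringsAsFactors = FALSE)[pres, , drop = FALSE]
    sample_event_set(ev, s)
  })
  names(sets) <- samples
  list(table = d, sets = sets, samples = samples)
}

#' Write events in the published multi-sample layout
#'
#' Inverse of [read_event_table()]: one row per event, Mb coordinates at two
#' decimals, presence columns marked `x`.
#'
#' @param table a data.frame as returned in `read_event_table()$table`.
#' @param path output TSV.
#' @export
write_event_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write window count tables
#'
#' Window counts travel as TSV with columns
#' `chrom,start,end,n_normal,n_tumor` (bp, 0-based half-open).
#'
#' @param path TSV file.
#' @return data.frame of window counts.
#' @export
read_window_counts <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("chrom", "start", "end", "n_normal", "n_tumor") %in%
                  names(d)))
  d
}

#' @rdname read_window_counts
#' @param windows window count data.frame.
#' @export
write_window_counts <- function(windows, path) {
  utils::write.table(
    windows[, intersect(c("chrom", "start", "end", "n_normal", "n_tumor",
                          "underfilled"), names(windows))],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to the packaged four-stage breast cancer event table
#'
#' The bundled multi-sample copy-number event table from a documented
#' four-stage breast cancer progression case (two ductal carcinoma in situ
#' regions, primary tumor, asynchronous metastasis): 95 events with
#' per-sample complete/subclone presence marks.
#'
#' @return file path.
#' @export
progression_fixture_path <- function() {
  system.file("extdata", "breast_progression_events.tsv",
              package = "cnevolve", mustWork = TRUE)
}
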