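# Cross-sample event integration: Mb totals, pairwise concordance, retention,
# linear-vs-parallel classification and molecular-time ordering.

LOSS_TYPES <- c("LOH", "HL", "OCL")
GAIN_TYPES <- c("CG", "HCG", "VHCG", "EHCG")

event_class <- function(type) ifelse(type %in% LOSS_TYPES, "loss", "gain")

#' Bundle one sample's events into a sample event set
#'
#' @param events a `cn_events`-like data.frame (`chrom,start,end,length_mb,
#'   type`, optional `clonality`); `start`/`end` in bp.
#' @param sample sample id.
#' @return the events with class `sample_event_set` and a `sample` attribute.
#' @export
sample_event_set <- function(events, sample) {
  ev <- as.data.frame(events)
  stopifnot(all(c("chrom", "start", "end", "length_mb", "type") %in%
                  names(ev)))
  bad <- setdiff(ev$type, c(LOSS_TYPES, GAIN_TYPES))
  if (length(bad)) stop("unknown event category: ", paste(bad, collapse = ", "))
  ev <- ev[order(ev$chrom, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("sample_event_set", "data.frame"), sample = sample)
}

#' Per-sample Mb totals and event counts
#'
#' Sums the `length_mb` of loss- and gain-category rows (each row counted
#' once; overlaps between rows are not merged, matching the convention of
#' published per-sample event tables). Subclonal and complete events both
#' count as present.
#'
#' @param set a [sample_event_set()] (or plain events data.frame).
#' @return list `gained_mb, lost_mb, n_gain, n_loss`.
#' @export
totals <- function(set) {
  loss <- set$type %in% LOSS_TYPES
  list(gained_mb = sum(set$length_mb[!loss]),
       lost_mb = sum(set$length_mb[loss]),
       n_gain = sum(!loss), n_loss = sum(loss))
}

#' Match events between two samples
#'
#' Events correspond when they lie on the same chromosome, belong to the same
#' category class (loss vs gain), and both breakpoints agree within `bp_tol`
#' base pairs. Matching is greedy one-to-one in coordinate order.
#'
#' @param set_a,set_b event sets.
#' @param bp_tol breakpoint tolerance in bp (0 = exact, the right choice for
#'   pre-tabulated event tables; use about two window widths for
#'   pipeline-derived events).
#' @return list with `pairs` (data.frame of row indices `a`, `b`),
#'   `unmatched_a`, `unmatched_b` (row indices).
#' @export
match_events <- function(set_a, set_b, bp_tol = 0) {
  na <- nrow(set_a); nb <- nrow(set_b)
  used_b <- rep(FALSE, nb)
  pa <- integer(0); pb <- integer(0)
  cls_a <- event_class(set_a$type); cls_b <- event_class(set_b$type)
  for (i in seq_len(na)) {
    cand <- which(!used_b & set_b$chrom == set_a$chrom[i] &
                    cls_b == cls_a[i] &
                    abs(set_b$start - set_a$start[i]) <= bp_tol &
                    abs(set_b$end - set_a$end[i]) <= bp_tol)
    if (length(cand)) {
      j <- cand[which.min(abs(set_b$start[cand] - set_a$start[i]) +
                            abs(set_b$end[cand] - set_a$end[i]))]
      used_b[j] <- TRUE
      pa <- c(pa, i); pb <- c(pb, j)
    }
  }
  list(pairs = data.frame(a = pa, b = pb),
       unmatched_a = setdiff(seq_len(na), pa),
       unmatched_b = setdiff(seq_len(nb), pb))
}

# fraction of [start, end) covered by the union of intervals (each expanded
# by pad bp)
coverage_fraction <- function(start, end, ref_start, ref_end, pad = 0) {
  if (!length(ref_start)) return(0)
  s <- pmax(ref_start - pad, start); e <- pmin(ref_end + pad, end)
  keep <- s < e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  covered <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) { covered <- covered + cur_e - cur_s
      cur_s <- s[i]; cur_e <- e[i] } else cur_e <- max(cur_e, e[i])
  }
  covered <- covered + cur_e - cur_s
  covered / (end - start)
}

#' Mb concordance of one event set against a reference
#'
#' `100 * (Mb of query events present in the reference) / (Mb of all query
#' events)`. A query event counts as present in proportion to how much of its
#' interval is covered by reference territory of the same category class
#' (loss vs gain), each reference interval expanded by `bp_tol`. The measure
#' is therefore invariant to row order and to splitting an event into
#' abutting rows of the same total length, and retained events with identical
#' coordinates count in full.
#'
#' @param set_query,set_reference event sets.
#' @param bp_tol breakpoint tolerance in bp.
#' @return percentage in `[0, 100]`; `NA` (with a message) for an empty query.
#' @export
concordance <- function(set_query, set_reference, bp_tol = 0) {
  tot <- sum(set_query$length_mb)
  if (tot == 0) {
    message("empty query set: concordance undefined")
    return(NA_real_)
  }
  cls_q <- event_class(set_query$type)
  cls_r <- event_class(set_reference$type)
  matched <- vapply(seq_len(nrow(set_query)), function(i) {
    sel <- set_reference$chrom == set_query$chrom[i] & cls_r == cls_q[i]
    set_query$length_mb[i] * coverage_fraction(
      set_query$start[i], set_query$end[i],
      set_reference$start[sel], set_reference$end[sel], bp_tol)
  }, 0)
  100 * sum(matched) / tot
}

#' Classify progression as linear-consistent or parallel-evidence
#'
#' Linear progression predicts perfect nesting: every event of every earlier
#' stage is retained in every later stage, and no event is private to an
#' earlier sample. Any earlier-stage event missing from a later stage is
#' evidence for parallel progression and is listed. The report also carries
#' per-sample totals, the pairwise Mb-concordance matrix, and the
#' molecular-time acquisition table ([stage_acquisition()]).
#'
#' @param sets named list of event sets, ordered by progression stage.
#' @param bp_tol breakpoint tolerance in bp.
#' @return object of class `progression_report`.
#' @export
classify_progression <- function(sets, bp_tol = 0) {
  stopifnot(is.list(sets), length(sets) >= 1)
  stages <- names(sets)
  if (is.null(stages)) stages <- paste0("stage", seq_along(sets))
  n <- length(sets)
  viol <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m <- match_events(sets[[i]], sets[[j]], bp_tol)
      if (length(m$unmatched_a)) {
        v <- as.data.frame(sets[[i]])[m$unmatched_a, , drop = FALSE]
        v$stage <- stages[i]; v$missing_from <- stages[j]
        viol[[length(viol) + 1L]] <- v
      }
    }
  }
  violations <- if (length(viol))
    do.call(rbind, c(viol, list(make.row.names = FALSE))) else NULL
  conc <- matrix(NA_real_, n, n, dimnames = list(stages, stages))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    conc[i, j] <- if (sum(sets[[i]]$length_mb) > 0)
      concordance(sets[[i]], sets[[j]], bp_tol) else NA_real_
  }
  tot <- do.call(rbind, lapply(sets, function(s) as.data.frame(totals(s))))
  tot <- cbind(stage = stages, tot)
  rownames(tot) <- NULL
  structure(list(
    verdict = if (is.null(violations)) "linear-consistent"
    else "parallel-evidence",
    violations = violations,
    totals = tot,
    concordance = conc,
    acquisition = stage_acquisition(sets, bp_tol),
    stages = stages, bp_tol = bp_tol
  ), class = "progression_report")
}

#' Earliest acquisition stage per event and cumulative Mb per stage
#'
#' Each event is labeled with the first stage that carries it (molecular-time
#' ordering); the cumulative table gives, per stage, the Mb of gain and loss
#' territory acquired up to and including that stage -- the stepwise
#' acquisition picture of a linearly progressing genome.
#'
#' @param sets named list of event sets ordered by stage.
#' @param bp_tol breakpoint tolerance in bp.
#' @return list with `events` (unique events + `first_stage`) and
#'   `cumulative` (data.frame `stage, cum_gained_mb, cum_lost_mb`).
#' @export
stage_acquisition <- function(sets, bp_tol = 0) {
  stages <- names(sets)
  if (is.null(stages)) stages <- paste0("stage", seq_along(sets))
  uniq <- NULL
  for (k in seq_along(sets)) {
    ev <- as.data.frame(sets[[k]])
    if (!nrow(ev)) next
    ev$first_stage <- stages[k]
    if (is.null(uniq)) {
      uniq <- ev
    } else {
      m <- match_events(ev, uniq, bp_tol)
      if (length(m$unmatched_a)) {
        uniq <- rbind(uniq[, c("chrom", "start", "end", "length_mb", "type",
                               "first_stage")],
                      ev[m$unmatched_a, c("chrom", "start", "end",
                                          "length_mb", "type",
                                          "first_stage")])
      }
    }
    uniq <- uniq[, c("chrom", "start", "end", "length_mb", "type",
                     "first_stage")]
  }
  if (is.null(uniq)) {
    return(list(events = NULL,
                cumulative = data.frame(stage = stages, cum_gained_mb = 0,
                                        cum_lost_mb = 0)))
  }
  loss <- uniq$type %in% LOSS_TYPES
  stage_idx <- match(uniq$first_stage, stages)
  cum <- data.frame(
    stage = stages,
    cum_gained_mb = vapply(seq_along(stages), function(k)
      sum(uniq$length_mb[!loss & stage_idx <= k]), 0),
    cum_lost_mb = vapply(seq_along(stages), function(k)
      sum(uniq$length_mb[loss & stage_idx <= k]), 0))
  list(events = uniq, cumulative = cum)
}

#' @export
print.progression_report <- function(x, ...) {
  cat("Progression analysis over", length(x$stages), "stages:",
      paste(x$stages, collapse = " -> "), "\n")
  cat("Verdict:", x$verdict, "\n")
  if (!is.null(x$violations)) {
    cat("Events private to an earlier stage:\n")
    print.data.frame(x$violations[, c("chrom", "start", "end", "type",
                                      "stage", "missing_from")])
  }
  cat("\nPer-sample totals (Mb / event counts):\n")
  print.data.frame(x$totals, digits = 6)
  cat("\nPairwise Mb concordance (% of row sample present in column):\n")
  print(round(x$concordance, 2))
  invisible(x)
}

#' Export a progression report as JSON
#' @param report a `progression_report`.
#' @param path output file.
#' @export
write_progression_json <- function(report, path) {
  out <- list(
    verdict = report$verdict,
    stages = report$stages,
    totals = report$totals,
    concordance = report$concordance,
    cumulative = report$acquisition$cumulative,
    violations = if (is.null(report$violations)) list() else
      report$violations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
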