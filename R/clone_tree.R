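#' Construct a clone tree with per-sample cellular prevalences
#'
#' A clone tree describes the tumor cell populations present in one or more
#' sequenced samples. Each clone has a parent (the root clone's parent is the
#' germline, denoted `NA`) and, per sample, a *cellular prevalence*: the
#' fraction of tumor cells in that sample carrying the clone's somatic
#' genotype. Prevalences are cumulative over descent, so a clone's prevalence
#' is always at least the sum of its children's prevalences (pigeonhole
#' consistency), and the root clone of a sample that contains tumor cells has
#' prevalence 1. Normal-cell admixture is described separately by `purity`,
#' the fraction of all cells in the sample that are tumor cells.
#'
#' @param clones character vector of clone ids.
#' @param parent named character vector mapping each clone to its parent
#'   clone id; the root maps to `NA`.
#' @param prevalence numeric matrix, samples in rows (rownames = sample ids),
#'   clones in columns, entries in `[0, 1]`.
#' @param purity named numeric vector in `[0, 1]`, one entry per sample.
#' @return An object of class `clone_tree`.
#' @examples
#' tree <- clone_tree(
#'   clones = c("A", "B"),
#'   parent = c(A = NA, B = "A"),
#'   prevalence = matrix(c(1, 0.4), 1, 2,
#'     dimnames = list("tumor", c("A", "B"))),
#'   purity = c(tumor = 0.8)
#' )
#' @export
clone_tree <- function(clones, parent, prevalence, purity) {
  clones <- as.character(clones)
  stopifnot(length(clones) >= 1, !anyDuplicated(clones))
  parent <- parent[clones]
  if (sum(is.na(parent)) != 1) {
    stop("clone tree must have exactly one root (parent = NA)")
  }
  known <- is.na(parent) | as.character(parent) %in% clones
  if (!all(known)) stop("unknown parent clone: ", parent[!known][1])
  prevalence <- as.matrix(prevalence)
  if (is.null(rownames(prevalence)) || is.null(colnames(prevalence))) {
    stop("prevalence matrix needs sample rownames and clone colnames")
  }
  if (!setequal(colnames(prevalence), clones)) {
    stop("prevalence columns must match clone ids")
  }
  prevalence <- prevalence[, clones, drop = FALSE]
  samples <- rownames(prevalence)
  if (!setequal(names(purity), samples)) {
    stop("purity must be named by sample")
  }
  purity <- purity[samples]
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  tree <- structure(
    list(clones = clones, parent = parent, prevalence = prevalence,
         purity = purity, samples = samples),
    class = "clone_tree"
  )
  validate_clone_tree(tree)
  tree
}

#' Check clone-tree prevalence invariants
#'
#' Verifies, per sample, that every child's prevalence does not exceed its
#' parent's, and that the prevalences of sibling clones sum to at most their
#' parent's prevalence (at most 1 for the root's children plus the root).
#'
#' @param tree a [clone_tree()].
#' @return `tree`, invisibly; errors if an invariant fails.
#' @export
validate_clone_tree <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  prev <- tree$prevalence
  for (s in tree$samples) {
    for (cl in tree$clones) {
      kids <- tree$clones[!is.na(tree$parent) & tree$parent == cl]
      if (length(kids) && sum(prev[s, kids]) > prev[s, cl] + 1e-9) {
        stop(sprintf(
          "sample %s: children of clone %s have prevalence %.3f > parent %.3f",
          s, cl, sum(prev[s, kids]), prev[s, cl]))
      }
      pa <- tree$parent[[cl]]
      if (!is.na(pa) && prev[s, cl] > prev[s, pa] + 1e-9) {
        stop(sprintf("sample %s: clone %s prevalence exceeds parent %s",
                     s, cl, pa))
      }
    }
  }
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree:", length(x$clones), "clones,",
      length(x$samples), "samples\n")
  root <- x$clones[is.na(x$parent)]
  cat("  topology:", paste(
    ifelse(is.na(x$parent), paste0(x$clones, " (root)"),
           paste0(x$parent, " -> ", x$clones)), collapse = ", "), "\n")
  cat("  purity:", paste(sprintf("%s=%.2f", x$samples, x$purity),
                         collapse = ", "), "\n")
  cat("  prevalence (tumor-cell fractions):\n")
  print(round(x$prevalence, 3))
  invisible(x)
}

#' Clones descending from (and including) a clone
#' @param tree a [clone_tree()].
#' @param clone clone id.
#' @return character vector of clone ids.
#' @export
clone_descendants <- function(tree, clone) {
  out <- clone
  repeat {
    kids <- tree$clones[!is.na(tree$parent) & tree$parent %in% out &
                          !(tree$clones %in% out)]
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

#' Copy-number event specifications for a clone tree
#'
#' Builds the event table consumed by the simulator. Coordinates are 0-based
#' half-open base pairs. `kind` is one of `het_loss` (one haplotype lost,
#' per-event total copy 1), `hom_loss` (both lost, total copy 0) or `gain`
#' (total copy `copies >= 3`, extra copies on one haplotype). `allele` (1 or
#' 2) names the affected parental haplotype. Events are inherited by all
#' descendants of `clone`.
#'
#' @param chrom,start,end event interval (bp, 0-based half-open).
#' @param kind character, `het_loss`, `hom_loss` or `gain`.
#' @param clone clone id first acquiring the event.
#' @param copies integer total copy target; defaults follow `kind`.
#' @param allele affected haplotype, 1 or 2.
#' @return data.frame of class `cn_event_spec`.
#' @export
cn_event_spec <- function(chrom, start, end, kind, clone,
                          copies = NULL, allele = 1L) {
  kind <- match.arg(kind, c("het_loss", "hom_loss", "gain"),
                    several.ok = TRUE)
  n <- max(length(chrom), length(start), length(end), length(kind),
           length(clone))
  spec <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    kind = rep_len(kind, n),
    clone = rep_len(as.character(clone), n),
    allele = rep_len(as.integer(allele), n),
    stringsAsFactors = FALSE
  )
  spec$copies <- if (is.null(copies)) {
    ifelse(spec$kind == "het_loss", 1L, ifelse(spec$kind == "hom_loss", 0L, 3L))
  } else rep_len(as.integer(copies), n)
  bad <- (spec$kind == "het_loss" & spec$copies != 1L) |
    (spec$kind == "hom_loss" & spec$copies != 0L) |
    (spec$kind == "gain" & spec$copies < 3L)
  if (any(bad)) stop("copy target inconsistent with event kind")
  if (any(spec$start >= spec$end)) stop("event start must be < end")
  if (any(!spec$allele %in% c(1L, 2L))) stop("allele must be 1 or 2")
  class(spec) <- c("cn_event_spec", "data.frame")
  spec
}

#' Somatic SNV specifications for a clone tree
#'
#' @param chrom,pos position (bp, 0-based).
#' @param ref,alt reference and alternate base.
#' @param clone clone id first acquiring the mutation.
#' @return data.frame of class `snv_spec`.
#' @export
snv_spec <- function(chrom, pos, ref = "C", alt = "T", clone) {
  n <- max(length(chrom), length(pos), length(clone))
  spec <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.numeric(pos), n),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    clone = rep_len(as.character(clone), n),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("snv_spec", "data.frame")
  spec
}

# per-event change in total copy number relative to diploid
event_copy_delta <- function(spec) {
  ifelse(spec$kind == "het_loss", -1,
         ifelse(spec$kind == "hom_loss", -2, spec$copies - 2))
}

# reject events that overlap on the same haplotype within one clone lineage:
# with cumulative prevalences, copy effects are only additive when no two
# events touch the same haplotype of the same region in related clones
check_event_conflicts <- function(tree, events, genome) {
  if (!nrow(events)) return(invisible(events))
  if (!all(events$clone %in% tree$clones)) {
    stop("event assigned to unknown clone: ",
         paste(setdiff(events$clone, tree$clones), collapse = ", "))
  }
  if (!all(events$chrom %in% genome$chrom)) {
    stop("event on chromosome absent from genome")
  }
  len <- stats::setNames(genome$length, genome$chrom)
  if (any(events$end > len[events$chrom])) {
    stop("event extends past chromosome end")
  }
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(i - 1L)) {
      a <- events[i, ]; b <- events[j, ]
      if (a$chrom != b$chrom) next
      if (a$start >= b$end || b$start >= a$end) next
      hap_clash <- a$allele == b$allele ||
        a$kind == "hom_loss" || b$kind == "hom_loss"
      related <- a$clone %in% clone_descendants(tree, b$clone) ||
        b$clone %in% clone_descendants(tree, a$clone)
      if (hap_clash && related) {
        stop(sprintf(
          "conflicting events on %s: [%g,%g) (%s, clone %s) overlaps [%g,%g) (%s, clone %s) on the same haplotype lineage",
          a$chrom, a$start, a$end, a$kind, a$clone,
          b$start, b$end, b$kind, b$clone))
      }
    }
  }
  invisible(events)
}

#' A miniature multi-chromosome genome for simulation
#'
#' Five chromosomes totalling 200 Mb, enough territory for a realistic number
#' of well-separated megabase-scale events while keeping simulated tracks
#' small.
#'
#' @param n_chrom number of chromosomes (up to 8).
#' @return data.frame with columns `chrom`, `length` (bp).
#' @export
mini_genome <- function(n_chrom = 5L) {
  lengths <- c(60e6, 50e6, 40e6, 30e6, 20e6, 40e6, 30e6, 30e6)
  n_chrom <- min(as.integer(n_chrom), length(lengths))
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = lengths[seq_len(n_chrom)])
}
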