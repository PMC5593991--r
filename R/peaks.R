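# ---------------------------------------------------------------------------
# Consensus peak definition over replicate ChIP peak-call interval sets:
# per-base support via a boundary sweep, m-of-n thresholding, and
# input-control exclusion. Coordinates are 0-based half-open (BED).
# ---------------------------------------------------------------------------

#' Empty peak collection
#' @export
empty_peaks <- function() {
  data.frame(contig = character(), start = numeric(), end = numeric())
}

as_peaks <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(empty_peaks())
  stopifnot(is.data.frame(x), all(c("contig", "start", "end") %in% names(x)))
  data.frame(contig = as.character(x$contig), start = as.numeric(x$start),
             end = as.numeric(x$end))
}

#' Normalize a peak collection
#'
#' Sorts intervals and merges any that overlap or abut within a contig, so a
#' collection never covers a base twice. Intervals must satisfy start < end.
#'
#' @param peaks data.frame with `contig`, `start`, `end` (0-based half-open).
#' @return normalized data.frame of disjoint sorted intervals.
#' @export
normalize_peaks <- function(peaks) {
  peaks <- as_peaks(peaks)
  if (nrow(peaks) == 0) return(peaks)
  stopifnot(all(peaks$start < peaks$end))
  out <- lapply(split(peaks, peaks$contig), function(p) {
    p <- p[order(p$start, p$end), ]
    start <- p$start[1]; end <- p$end[1]
    res_s <- numeric(0); res_e <- numeric(0)
    if (nrow(p) > 1) for (i in 2:nrow(p)) {
      if (p$start[i] <= end) end <- max(end, p$end[i])
      else { res_s <- c(res_s, start); res_e <- c(res_e, end)
             start <- p$start[i]; end <- p$end[i] }
    }
    data.frame(contig = p$contig[1], start = c(res_s, start), end = c(res_e, end))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$contig, out$start), ]
}

#' Per-base support profile across replicate collections
#'
#' Boundary-sweep step function: for every contig, the number of samples whose
#' (normalized) intervals cover each base, represented as maximal runs of
#' constant support.
#'
#' @param collections list of peak data.frames (one per replicate sample).
#' @return data.frame `contig`, `start`, `end`, `support` covering all bases
#'   with support >= 1.
#' @export
support_profile <- function(collections) {
  stopifnot(length(collections) >= 1)
  collections <- lapply(collections, normalize_peaks)
  all <- do.call(rbind, collections)
  if (nrow(all) == 0) {
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      support = integer()))
  }
  out <- lapply(split(all, all$contig), function(p) {
    pos <- c(p$start, p$end)
    delta <- c(rep(1L, nrow(p)), rep(-1L, nrow(p)))
    o <- order(pos)
    pos <- pos[o]; delta <- delta[o]
    # collapse equal positions, then cumulative support between breakpoints
    agg <- rowsum(delta, group = pos)
    bp <- as.numeric(rownames(agg))
    supp <- cumsum(agg[, 1])
    k <- length(bp)
    seg <- data.frame(contig = p$contig[1], start = bp[-k], end = bp[-1],
                      support = as.integer(supp[-k]))
    seg <- seg[seg$support > 0, , drop = FALSE]
    # merge adjacent segments with equal support
    if (nrow(seg) > 1) {
      same <- c(FALSE, seg$support[-1] == seg$support[-nrow(seg)] &
                         seg$start[-1] == seg$end[-nrow(seg)])
      grp <- cumsum(!same)
      seg <- data.frame(contig = seg$contig[1],
                        start = tapply(seg$start, grp, min),
                        end = tapply(seg$end, grp, max),
                        support = tapply(seg$support, grp, unique))
    }
    seg
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

overlaps_any <- function(a, b) {
  # for each row of a: does it intersect any interval of b by >= 1 bp?
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    any(b$contig == a$contig[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

#' Call consensus peaks by the m-of-n rule with input exclusion
#'
#' A consensus region is a maximal run of bases covered by peak calls in at
#' least `m` of the replicate samples; any candidate sharing at least one base
#' with an input-control interval is moved to the excluded set ("no
#' simultaneous overlap with any input peak"). The defaults encode the
#' 14-of-18 rule. Sub-threshold gaps are not bridged unless `merge_gap` > 0.
#'
#' @param collections list of per-replicate peak data.frames.
#' @param input input-control peak data.frame (zero rows = no exclusion).
#' @param m minimum number of supporting samples per base.
#' @param merge_gap bridge candidate runs separated by at most this many bases
#'   (default 0: no merging).
#' @return a `consensus_set`: list with `regions` and `excluded` data.frames
#'   (`contig`, `start`, `end`, `support_min`, `support_max`, `status`), plus
#'   `m` and `n`.
#' @export
call_consensus <- function(collections, input = empty_peaks(), m = 14L,
                           merge_gap = 0) {
  if (length(collections) == 0) stop("no replicate collections supplied")
  stopifnot(m >= 1, m <= length(collections))
  prof <- support_profile(collections)
  cand <- prof[prof$support >= m, , drop = FALSE]
  regions <- empty_regions()
  if (nrow(cand)) {
    out <- lapply(split(cand, cand$contig), function(p) {
      p <- p[order(p$start), ]
      gap_to_prev <- c(Inf, p$start[-1] - p$end[-nrow(p)])
      grp <- cumsum(gap_to_prev > merge_gap)
      data.frame(contig = p$contig[1],
                 start = as.numeric(tapply(p$start, grp, min)),
                 end = as.numeric(tapply(p$end, grp, max)),
                 support_min = as.integer(tapply(p$support, grp, min)),
                 support_max = as.integer(tapply(p$support, grp, max)))
    })
    regions <- do.call(rbind, out)
    rownames(regions) <- NULL
  }
  input <- normalize_peaks(input)
  hit <- overlaps_any(regions, input)
  excluded <- regions[hit, , drop = FALSE]
  regions <- regions[!hit, , drop = FALSE]
  if (nrow(regions)) regions$status <- "consensus"
  if (nrow(excluded)) excluded$status <- "excluded"
  rownames(regions) <- rownames(excluded) <- NULL
  structure(list(regions = regions, excluded = excluded,
                 m = as.integer(m), n = length(collections)),
            class = "consensus_set")
}

empty_regions <- function() {
  data.frame(contig = character(), start = numeric(), end = numeric(),
             support_min = integer(), support_max = integer())
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d consensus regions (>= %d of %d samples), %d excluded by input overlap\n",
              nrow(x$regions), x$m, x$n, nrow(x$excluded)))
  invisible(x)
}

#' Annotate genes with consensus-peak presence
#'
#' @param consensus a `consensus_set` from [call_consensus()].
#' @param gene_regions data.frame with `contig`, `start`, `end`, `name`
#'   (promoter or gene intervals).
#' @return data.frame `gene`, `has_consensus_peak` (>= 1 bp intersection with
#'   a retained consensus region; excluded regions do not count).
#' @export
annotate_genes <- function(consensus, gene_regions) {
  stopifnot(inherits(consensus, "consensus_set"),
            all(c("contig", "start", "end", "name") %in% names(gene_regions)))
  hit <- overlaps_any(as_peaks(gene_regions), consensus$regions)
  data.frame(gene = gene_regions$name, has_consensus_peak = hit)
}

# ---- BED I/O (rtracklayer) -------------------------------------------------

peaks_to_granges <- function(peaks) {
  peaks <- as_peaks(peaks)
  GenomicRanges::GRanges(peaks$contig,
                         IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

granges_to_peaks <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

#' Read/write peak collections as BED3
#'
#' Thin wrappers over `rtracklayer` keeping the package's 0-based half-open
#' interval convention.
#'
#' @param peaks data.frame with `contig`, `start`, `end`.
#' @param path BED file path.
#' @rdname peaks_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  rtracklayer::export(peaks_to_granges(peaks), path, format = "BED")
  invisible(path)
}

#' @rdname peaks_bed
#' @export
read_peaks_bed <- function(path) {
  granges_to_peaks(rtracklayer::import(path, format = "BED"))
}
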