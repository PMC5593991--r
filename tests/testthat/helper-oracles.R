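# Independent oracles used across the suite.

# Naive per-base support counting on a single toy contig: literally fill an
# integer array, one cell per base.
per_base_support <- function(collections, contig_len) {
  counts <- integer(contig_len)
  for (p in collections) {
    covered <- logical(contig_len)
    for (i in seq_len(nrow(p))) {
      if (p$start[i] < contig_len) {
        covered[(p$start[i] + 1):min(p$end[i], contig_len)] <- TRUE
      }
    }
    counts <- counts + covered
  }
  counts
}

# Turn a support-profile data.frame back into a per-base vector.
profile_to_bases <- function(prof, contig_len) {
  counts <- integer(contig_len)
  for (i in seq_len(nrow(prof))) {
    counts[(prof$start[i] + 1):min(prof$end[i], contig_len)] <- prof$support[i]
  }
  counts
}

# Random interval collections on a small toy contig.
random_collections <- function(n_samples, contig_len, max_peaks = 8) {
  lapply(seq_len(n_samples), function(i) {
    k <- sample.int(max_peaks, 1)
    st <- sort(sample.int(contig_len - 50, k))
    data.frame(contig = "chrT", start = st,
               end = pmin(st + sample(10:60, k, replace = TRUE), contig_len))
  })
}

# Plain 1-bp-overlap test between two interval data.frames.
overlaps_any_regions <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$contig == a$contig[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Consensus regions recomputed from the per-base oracle.
oracle_consensus <- function(collections, input, m, contig_len) {
  counts <- per_base_support(collections, contig_len)
  ok <- counts >= m
  if (nrow(input)) {
    # mark input-covered bases to test region-level exclusion separately
    inp <- per_base_support(list(input), contig_len) > 0
  } else inp <- logical(contig_len)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             excluded = vapply(which(keep), function(i) {
               any(inp[(starts[i] + 1):ends[i]])
             }, logical(1)))
}
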