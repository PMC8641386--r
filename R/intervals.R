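# Interval helpers. All coordinates in this package are 0-based half-open
# [start, end); IRanges (1-based closed) appears only inside these wrappers.

iv_ranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Total length of the union of a set of intervals.
iv_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(iv_ranges(start, end))))
}

# Length of the intersection of interval [s, e) with the union of a set.
iv_cover_length <- function(s, e, start, end) {
  if (length(start) == 0 || e <= s) return(0L)
  hit <- IRanges::restrict(IRanges::reduce(iv_ranges(start, end)),
                           start = s + 1L, end = e)
  sum(IRanges::width(hit))
}

# Pairwise overlap length of two single intervals (0 when disjoint).
iv_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Merge overlapping/abutting intervals; returns tibble(start, end) sorted.
iv_reduce <- function(start, end) {
  if (length(start) == 0) return(tibble(start = integer(), end = integer()))
  r <- IRanges::reduce(iv_ranges(start, end))
  tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}
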