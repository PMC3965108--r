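#' Residue ranges
#'
#' A residue range is a closed interval of 1-based SEQRES indices. All
#' internal coordinates in this package are sequential SEQRES positions;
#' author numbering (with insertion codes) is an I/O-layer mapping only.
#' A set of ranges is represented as a data.frame with integer columns
#' `start` and `end`.
#'
#' @param start,end integer vectors of equal length; 1-based, inclusive.
#' @return A `residue_ranges` data.frame with columns `start`, `end`.
#' @examples
#' residue_ranges(c(2, 226), c(224, 544))
#' @export
residue_ranges <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length", call. = FALSE)
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop("residue ranges must not contain NA", call. = FALSE)
  }
  if (any(start < 1L)) stop("residue ranges are 1-based: start >= 1", call. = FALSE)
  if (any(end < start)) stop("residue range with end < start", call. = FALSE)
  structure(data.frame(start = start, end = end),
            class = c("residue_ranges", "data.frame"))
}

#' Merge ranges into sorted, non-overlapping form
#'
#' Adjacent (end + 1 == next start) and overlapping ranges are coalesced.
#'
#' @param ranges a `residue_ranges` data.frame.
#' @return A normalized `residue_ranges` data.frame.
#' @export
normalize_ranges <- function(ranges) {
  ranges <- as_residue_ranges(ranges)
  if (nrow(ranges) == 0L) return(ranges)
  o <- order(ranges$start, ranges$end)
  s <- ranges$start[o]
  e <- ranges$end[o]
  out_s <- s[1L]
  out_e <- e[1L]
  k <- 1L
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= out_e[k] + 1L) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]
      out_e[k] <- e[i]
    }
  }
  residue_ranges(out_s[seq_len(k)], out_e[seq_len(k)])
}

as_residue_ranges <- function(x) {
  if (inherits(x, "residue_ranges")) return(x)
  if (is.data.frame(x)) return(residue_ranges(x$start, x$end))
  stop("cannot interpret object as residue ranges", call. = FALSE)
}

#' Number of distinct residues in a union of ranges
#'
#' Counts distinct residue indices covered by a set of ranges; overlaps
#' are not double-counted. This is the coverage statistic used to rank
#' hit groups (total residues covered on the query chain).
#'
#' @param ranges a `residue_ranges` data.frame (possibly overlapping).
#' @return Integer count.
#' @examples
#' range_union_size(residue_ranges(c(1, 40), c(50, 100))) # 100
#' @export
range_union_size <- function(ranges) {
  r <- normalize_ranges(ranges)
  if (nrow(r) == 0L) return(0L)
  sum(r$end - r$start + 1L)
}

#' Expand ranges to the residue indices they cover
#' @param ranges a `residue_ranges` data.frame.
#' @return Sorted integer vector of covered indices.
#' @export
range_indices <- function(ranges) {
  r <- normalize_ranges(ranges)
  if (nrow(r) == 0L) return(integer())
  unlist(Map(seq.int, r$start, r$end), use.names = FALSE)
}

#' Build maximal contiguous ranges from a set of residue indices
#' @param idx integer vector of residue indices (any order, duplicates ok).
#' @return A `residue_ranges` data.frame.
#' @export
indices_to_ranges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) return(residue_ranges())
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  residue_ranges(idx[brk[-length(brk)] + 1L], idx[brk[-1L]])
}

#' Intersect a set of ranges with another
#' @param a,b `residue_ranges` data.frames.
#' @return Normalized `residue_ranges` covering the intersection.
#' @export
intersect_ranges <- function(a, b) {
  indices_to_ranges(intersect(range_indices(a), range_indices(b)))
}

#' Set difference of ranges (residues in `a` not in `b`)
#' @param a,b `residue_ranges` data.frames.
#' @return Normalized `residue_ranges`.
#' @export
setdiff_ranges <- function(a, b) {
  indices_to_ranges(setdiff(range_indices(a), range_indices(b)))
}

#' Format ranges as a "start-end,start-end" string
#' @param ranges a `residue_ranges` data.frame.
#' @return Character scalar ("" for empty).
#' @export
format_ranges <- function(ranges) {
  r <- as_residue_ranges(ranges)
  if (nrow(r) == 0L) return("")
  paste(sprintf("%d-%d", r$start, r$end), collapse = ",")
}

#' Parse a "start-end,start-end" string into ranges
#' @param x character scalar; "" yields empty ranges.
#' @return A `residue_ranges` data.frame.
#' @export
parse_ranges <- function(x) {
  if (is.na(x) || !nzchar(x)) return(residue_ranges())
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop(sprintf("malformed range segment '%s'", parts[bad][1L]), call. = FALSE)
  }
  residue_ranges(vapply(m, function(g) as.integer(g[2L]), 1L),
                 vapply(m, function(g) as.integer(g[3L]), 1L))
}
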