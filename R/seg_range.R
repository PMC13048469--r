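#' Segmented residue ranges
#'
#' A `seg_range` is an ordered set of 1-based inclusive residue segments
#' describing where a domain sits on its parent protein. Discontinuous
#' domains -- single folding units assembled from several sequence
#' segments -- carry more than one segment. Segments are kept sorted,
#' must not overlap, and must not abut (a gap of at least one residue
#' separates consecutive segments; abutting segments would denote a
#' single continuous segment and are rejected rather than silently
#' merged).
#'
#' @param starts,ends Integer vectors of equal length; `starts[i] <=
#'   ends[i]` for every segment.
#' @return An object of class `seg_range`.
#' @examples
#' r <- seg_range(c(5, 180), c(120, 230))
#' residue_count(r)
#' format_range_string(r)
#' @export
seg_range <- function(starts, ends) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) == 0) {
    stop("seg_range needs one or more (start, end) pairs", call. = FALSE)
  }
  if (anyNA(starts) || anyNA(ends)) stop("NA residue index", call. = FALSE)
  if (any(starts < 1L)) stop("residue indices are 1-based; start < 1", call. = FALSE)
  bad <- which(starts > ends)
  if (length(bad)) {
    stop(sprintf("segment %d-%d has start > end", starts[bad[1]], ends[bad[1]]),
         call. = FALSE)
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  if (length(starts) > 1L) {
    gap <- starts[-1L] - ends[-length(ends)]
    if (any(gap < 1L)) {
      stop("segments overlap", call. = FALSE)
    }
    if (any(gap == 1L)) {
      stop("segments abut; write them as a single segment", call. = FALSE)
    }
  }
  structure(list(starts = starts, ends = ends), class = "seg_range")
}

#' @export
print.seg_range <- function(x, ...) {
  cat("<seg_range> ", format_range_string(x), "  (", residue_count(x),
      " residues)\n", sep = "")
  invisible(x)
}

#' Number of residues covered by a segmented range
#' @param r A `seg_range`.
#' @return Integer residue count.
#' @export
residue_count <- function(r) {
  stopifnot(inherits(r, "seg_range"))
  sum(r$ends - r$starts + 1L)
}

#' Number of segments in a segmented range
#' @param r A `seg_range`.
#' @return Integer segment count.
#' @export
n_segments <- function(r) {
  stopifnot(inherits(r, "seg_range"))
  length(r$starts)
}

#' Residue indices covered by a segmented range
#' @param r A `seg_range`.
#' @return Sorted integer vector of residue indices.
#' @export
range_residues <- function(r) {
  stopifnot(inherits(r, "seg_range"))
  unlist(mapply(seq.int, r$starts, r$ends, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Parse a range string into a `seg_range`
#'
#' Range strings are comma-separated `"a-b"` tokens with 1-based
#' inclusive bounds, e.g. `"5-120,180-230"`. Whitespace around tokens is
#' tolerated on read and never written.
#'
#' @param s A single character string.
#' @return A canonical `seg_range`.
#' @export
parse_range_string <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(trimws(s))) {
    stop("empty range string", call. = FALSE)
  }
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  m <- regmatches(toks, regexec("^([0-9]+)-([0-9]+)$", toks))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    stop(sprintf("malformed range token '%s'", toks[bad[1]]), call. = FALSE)
  }
  starts <- vapply(m, function(x) as.integer(x[2]), integer(1))
  ends <- vapply(m, function(x) as.integer(x[3]), integer(1))
  tryCatch(seg_range(starts, ends), error = function(e) {
    stop(sprintf("invalid range string '%s': %s", s, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Format a `seg_range` as its canonical range string
#' @param r A `seg_range`.
#' @return A character string such as `"5-120,180-230"`.
#' @export
format_range_string <- function(r) {
  stopifnot(inherits(r, "seg_range"))
  paste(sprintf("%d-%d", r$starts, r$ends), collapse = ",")
}

#' Residue overlap between two segmented ranges
#'
#' @param a,b `seg_range` objects on the same protein.
#' @return Integer count of residues shared by `a` and `b`.
#' @export
range_overlap <- function(a, b) {
  length(intersect(range_residues(a), range_residues(b)))
}

#' Are two segmented ranges identical up to boundary jitter?
#'
#' Ranges are "near-identical" when they have the same number of
#' segments and every corresponding boundary differs by at most `tol`
#' residues. With `tol = 0` this is exact equality of the canonical
#' ranges.
#'
#' @param a,b `seg_range` objects.
#' @param tol Non-negative integer boundary tolerance.
#' @return Logical scalar.
#' @export
range_near_identical <- function(a, b, tol = 0L) {
  if (n_segments(a) != n_segments(b)) return(FALSE)
  all(abs(a$starts - b$starts) <= tol) && all(abs(a$ends - b$ends) <= tol)
}

# Vectorised helpers over character range strings (used by table verbs).
ranges_parse <- function(s) lapply(s, parse_range_string)

ranges_nres <- function(s) {
  vapply(ranges_parse(s), residue_count, integer(1))
}

ranges_nseg <- function(s) {
  vapply(ranges_parse(s), n_segments, integer(1))
}
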