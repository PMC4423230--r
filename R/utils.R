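# Shared interval arithmetic and coordinate conventions.
#
# All coordinates inside the package are 0-based, half-open [start, end),
# the BED convention. Converters below are the only places where the
# 1-based inclusive convention (GFF/Ensembl style) is touched.

#' Convert 0-based half-open intervals to 1-based inclusive
#'
#' @param x data.frame with `start` and `end` columns in 0-based half-open
#'   coordinates.
#' @return the same data.frame with `start`/`end` in 1-based inclusive
#'   coordinates.
#' @export
interval_0to1 <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  x$start <- x$start + 1L
  x
}

#' Convert 1-based inclusive intervals to 0-based half-open
#'
#' Inverse of [interval_0to1()].
#' @param x data.frame with 1-based inclusive `start`/`end` columns.
#' @return data.frame in 0-based half-open coordinates.
#' @export
interval_1to0 <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  x$start <- x$start - 1L
  x
}

# IRanges view of 0-based half-open coordinates (IRanges is 1-based closed).
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# Edge-to-edge gap between two half-open intervals; 0 when they overlap
# or abut. Vectorised over the second interval.
.edge_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

# Which 0-based positions fall inside any interval of `iv` on the matching
# chromosome. `chrom` is scalar, `pos` a vector (NA allowed, returns FALSE).
.pos_in_intervals <- function(chrom, pos, iv) {
  hit <- rep(FALSE, length(pos))
  if (is.null(iv) || nrow(iv) == 0L) return(hit)
  sel <- iv$chrom == chrom
  if (!any(sel)) return(hit)
  ok <- !is.na(pos)
  if (!any(ok)) return(hit)
  q <- .as_iranges(pos[ok], pos[ok] + 1L)
  s <- .as_iranges(iv$start[sel], iv$end[sel])
  hit[ok] <- IRanges::overlapsAny(q, s)
  hit
}

# Union (in bp) of the parts of [s, e) covered by intervals iv (same chrom
# assumed already filtered). Used for covered_fraction.
.covered_bp <- function(s, e, iv_start, iv_end) {
  if (length(iv_start) == 0L) return(0L)
  cs <- pmax(iv_start, s)
  ce <- pmin(iv_end, e)
  keep <- cs < ce
  if (!any(keep)) return(0L)
  r <- IRanges::reduce(.as_iranges(cs[keep], ce[keep]))
  sum(IRanges::width(r))
}

# Stable text connection reader; file() transparently decompresses gzip.
.read_lines <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Run a block of code with the global RNG state restored afterwards.
.with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}
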