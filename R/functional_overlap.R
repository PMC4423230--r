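# Coverage-weighted overlap between elements and functional signal
# tracks (DHS, histone marks, TF binding, p300 ...), and the
# linkage-score-binned enrichment curves built from it.

#' Coverage-weighted functional score of one element
#'
#' Every peak overlapping the element by at least 1 bp contributes its
#' signal value weighted by the fraction of the element it covers:
#' a 100-bp element overlapped over 40 bp by a peak of value 12 scores
#' 12 * (40/100) = 4.8. Contributions of distinct peaks are additive.
#'
#' @param element list or single-row data.frame with `chrom`, `start`,
#'   `end`.
#' @param peaks data.frame of valued intervals (`chrom`, `start`, `end`,
#'   `value` >= 0).
#' @return list with `score` (weighted signal value, 0 when nothing
#'   overlaps) and `covered_fraction` (union of overlapping peak bases
#'   over element length, in [0, 1]).
#' @export
weighted_overlap <- function(element, peaks) {
  len <- element$end - element$start
  stopifnot(len > 0)
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(list(score = 0, covered_fraction = 0))
  sel <- peaks$chrom == element$chrom
  ov <- pmax(0, pmin(element$end, peaks$end[sel]) -
               pmax(element$start, peaks$start[sel]))
  score <- sum(peaks$value[sel] * ov / len)
  covered <- .covered_bp(element$start, element$end,
                         peaks$start[sel][ov > 0], peaks$end[sel][ov > 0])
  list(score = score, covered_fraction = covered / len)
}

#' Functional scores for a table of elements
#'
#' Vectorised [weighted_overlap()] over a whole element table against one
#' signal track.
#'
#' @param elements data.frame with `chrom`, `start`, `end` and an id
#'   column (`cne_id` or `reg_id`; the first one found is used).
#' @param peaks valued-interval data.frame.
#' @param track_name label stored in the output.
#' @return data.frame with `element_id`, `track`, `score`,
#'   `covered_fraction`.
#' @export
functional_scores <- function(elements, peaks, track_name = "track") {
  idcol <- intersect(c("cne_id", "reg_id", "element_id"), names(elements))[1]
  if (is.na(idcol)) stop("no id column (cne_id / reg_id / element_id)")
  out <- data.frame(element_id = elements[[idcol]], track = track_name,
                    score = 0, covered_fraction = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(elements))) {
    w <- weighted_overlap(list(chrom = elements$chrom[i],
                               start = elements$start[i],
                               end = elements$end[i]), peaks)
    out$score[i] <- w$score
    out$covered_fraction[i] <- w$covered_fraction
  }
  out
}

#' Element-level score from constituent CNE scores
#'
#' A regulatory element overlaps a track when at least one of its
#' constituent CNEs has a positive functional score; its score is the sum
#' over constituents.
#'
#' @param reg_elements table from [fuse_reg_elements()] (uses the
#'   `cne_ids` list-column).
#' @param cne_scores data.frame from [functional_scores()] computed on
#'   the constituent CNEs.
#' @return data.frame with `reg_id`, `score`, `overlaps` (logical).
#' @export
element_score_from_cnes <- function(reg_elements, cne_scores) {
  sc <- stats::setNames(cne_scores$score, cne_scores$element_id)
  score <- vapply(reg_elements$cne_ids, function(ids) {
    v <- sc[ids]
    sum(v[!is.na(v)])
  }, numeric(1))
  data.frame(reg_id = reg_elements$reg_id, score = score,
             overlaps = score > 0, stringsAsFactors = FALSE)
}

#' Enrichment of functional overlap along the linkage score
#'
#' Elements are ranked by S_A into equal-count quantile bins; each bin
#' reports the proportion of elements with a positive functional score.
#' Empty bins report NA, not 0. An optional stratification (for example
#' by conservation-score class) computes the curve per stratum so the
#' score-enrichment relationship can be examined controlling for
#' conservation.
#'
#' @param sa numeric vector of element S_A scores.
#' @param positive logical vector: does the element overlap the track
#'   (score > 0)?
#' @param bins number of quantile bins (default 10).
#' @param strata optional factor of the same length; curves are computed
#'   within each level.
#' @return data.frame with `bin`, `n`, `n_positive`, `proportion`,
#'   `sa_min`, `sa_max` (plus `stratum` when stratified), classed
#'   `enrichment_curve`.
#' @export
enrichment_by_score <- function(sa, positive, bins = 10L, strata = NULL) {
  stopifnot(length(sa) == length(positive))
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(sa))
    parts <- split(seq_along(sa), strata)
    out <- do.call(rbind, lapply(names(parts), function(sname) {
      ix <- parts[[sname]]
      cv <- enrichment_by_score(sa[ix], positive[ix], bins = bins)
      cv$stratum <- sname
      cv
    }))
    class(out) <- c("enrichment_curve", "data.frame")
    return(out)
  }
  n <- length(sa)
  bin <- integer(0)
  if (n > 0L) {
    bin <- ceiling(bins * rank(sa, ties.method = "first") / n)
    bin[bin < 1L] <- 1L
  }
  out <- data.frame(bin = seq_len(bins), n = 0L, n_positive = 0L,
                    proportion = NA_real_, sa_min = NA_real_,
                    sa_max = NA_real_)
  for (b in seq_len(bins)) {
    ix <- which(bin == b)
    out$n[b] <- length(ix)
    if (length(ix) == 0L) next
    out$n_positive[b] <- sum(positive[ix])
    out$proportion[b] <- mean(positive[ix])
    out$sa_min[b] <- min(sa[ix])
    out$sa_max[b] <- max(sa[ix])
  }
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Fold change between the extreme bins of an enrichment curve
#'
#' Ratio of the top (highest-score) bin proportion to the bottom bin
#' proportion, both taken over non-empty bins. Undefined (NA, with a
#' warning) when the bottom proportion is 0.
#'
#' @param curve an `enrichment_curve` (unstratified).
#' @return a single fold-change value.
#' @export
fold_change <- function(curve) {
  ok <- which(curve$n > 0L)
  if (length(ok) < 2L) {
    warning("fewer than two non-empty bins; fold change undefined")
    return(NA_real_)
  }
  bottom <- curve$proportion[ok[1]]
  top <- curve$proportion[ok[length(ok)]]
  if (bottom == 0) {
    warning("bottom-bin proportion is 0; fold change undefined")
    return(NA_real_)
  }
  top / bottom
}

#' Fisher 2x2 association helper
#'
#' Plain two-sided Fisher exact test on a 2x2 contingency table, provided
#' as generic plumbing for overlap-vs-annotation contrasts.
#'
#' @param n11,n12,n21,n22 the four cell counts.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_overlap <- function(n11, n12, n21, n22) {
  ft <- stats::fisher.test(matrix(c(n11, n21, n12, n22), nrow = 2))
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
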