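# Consistency between score-based target predictions and promoter
# interaction pairs (ChIA-PET style), with a window-resampling
# permutation null.

#' Consistency of target predictions with interaction pairs
#'
#' An element counts as overlapping when it intersects (>= 1 bp) at least
#' one anchor of an interaction pair; it is consistent when at least one
#' of its best-scoring target genes equals one of the genes those
#' interactions involve (any-match rule).
#'
#' @param elements data.frame with an id column (`reg_id` or `cne_id`),
#'   `chrom`, `start`, `end` and a `targets` list-column of best-target
#'   gene sets.
#' @param interactions interaction pairs from
#'   [read_intervals()] with `format = "bedpe"`: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `gene_id`.
#' @return list with `n_overlapping`, `n_consistent`, `fraction`, and
#'   `per_element` (data.frame `element_id`, `overlapping`, `consistent`,
#'   list-column `interacting` of gene sets).
#' @export
consistency <- function(elements, interactions) {
  idcol <- intersect(c("reg_id", "cne_id", "element_id"), names(elements))[1]
  if (is.na(idcol)) stop("no id column (reg_id / cne_id / element_id)")
  n <- nrow(elements)
  overlapping <- logical(n)
  consistent <- logical(n)
  interacting <- vector("list", n)
  for (i in seq_len(n)) {
    hit1 <- interactions$chrom1 == elements$chrom[i] &
      interactions$start1 < elements$end[i] &
      interactions$end1 > elements$start[i]
    hit2 <- interactions$chrom2 == elements$chrom[i] &
      interactions$start2 < elements$end[i] &
      interactions$end2 > elements$start[i]
    genes <- unique(interactions$gene_id[hit1 | hit2])
    interacting[[i]] <- genes
    overlapping[i] <- length(genes) > 0L
    consistent[i] <- length(intersect(elements$targets[[i]], genes)) > 0L
  }
  per_element <- data.frame(element_id = elements[[idcol]],
                            overlapping = overlapping,
                            consistent = consistent,
                            stringsAsFactors = FALSE)
  per_element$interacting <- I(interacting)
  list(n_overlapping = sum(overlapping),
       n_consistent = sum(consistent & overlapping),
       fraction = if (any(overlapping))
         sum(consistent & overlapping) / sum(overlapping) else NA_real_,
       per_element = per_element)
}

# deterministic per-element RNG stream seed from (seed, element id), so
# that subsetting or reordering elements never shifts other elements'
# draws
.element_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Permutation test of prediction/interaction consistency
#'
#' The observed consistency count is compared with a null in which every
#' overlapping element keeps its number of best-scoring targets k but
#' draws them uniformly without replacement from the genes present in a
#' window (default 2 Mb) centred on the element. Per element and
#' resample, the number of interacting genes hit by such a draw follows a
#' hypergeometric law in (m matching genes, g window genes, k draws),
#' which is how the draws are realised; the marginal distribution of the
#' consistency indicator is identical to explicit gene-set sampling. Each
#' element has its own RNG stream derived from (`seed`, element id).
#'
#' The empirical bound is p = (r + 1) / (n_resamples + 1) with r the
#' number of resamples whose null consistency count reaches the observed
#' count; when r = 0 the result is reported as p < 1 / n_resamples.
#'
#' @inheritParams consistency
#' @param genes data.frame of gene placements in the reference:
#'   `family_id` (or `gene_id`), `chrom`, `start`, `end`.
#' @param n_resamples number of resamplings (default 10000).
#' @param window window width in bp centred on the element (default
#'   2 Mb).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `consistency_result` list: the [consistency()] fields plus
#'   `null_counts`, `r`, `p_bound`, `at_floor`, `n_resamples`,
#'   `n_skipped`.
#' @export
permutation_test <- function(elements, interactions, genes,
                             n_resamples = 10000L, window = 2e6,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  idcol <- intersect(c("reg_id", "cne_id", "element_id"), names(elements))[1]
  gene_ids <- if (!is.null(genes$family_id)) genes$family_id else
    genes$gene_id
  obs <- consistency(elements, interactions)
  ov <- which(obs$per_element$overlapping)
  null_counts <- integer(n_resamples)
  n_skipped <- 0L
  .with_preserved_rng({
    for (i in ov) {
      center <- (elements$start[i] + elements$end[i]) / 2
      lo <- center - window / 2
      hi <- center + window / 2
      in_win <- genes$chrom == elements$chrom[i] &
        genes$start < hi & genes$end > lo
      g <- sum(in_win)
      if (g == 0L) {
        warning("element ", elements[[idcol]][i],
                " has no gene in its window; skipped")
        n_skipped <- n_skipped + 1L
        next
      }
      m <- length(intersect(obs$per_element$interacting[[i]],
                            gene_ids[in_win]))
      k <- min(length(elements$targets[[i]]), g)
      if (k == 0L || m == 0L) next  # this element can never match
      set.seed(.element_seed(seed, elements[[idcol]][i]))
      hits <- stats::rhyper(n_resamples, m, g - m, k) >= 1L
      null_counts <- null_counts + hits
    }
  })
  r <- sum(null_counts >= obs$n_consistent)
  res <- c(obs, list(null_counts = null_counts, r = r,
                     p_bound = (r + 1) / (n_resamples + 1),
                     at_floor = r == 0L, n_resamples = n_resamples,
                     n_skipped = n_skipped))
  class(res) <- "consistency_result"
  res
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("consistency: %d of %d overlapping elements (%.1f%%)\n",
              x$n_consistent, x$n_overlapping, 100 * x$fraction))
  if (x$at_floor) {
    cat(sprintf("no resample reached the observed count: p < %g (%d resamplings)\n",
                1 / x$n_resamples, x$n_resamples))
  } else {
    cat(sprintf("permutation p-bound: %.4g (%d resamplings)\n",
                x$p_bound, x$n_resamples))
  }
  invisible(x)
}
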