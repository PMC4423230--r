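# CNE calling from alignment blocks: column-wise conservation with exon /
# repeat masking, 10-bp core windows, bidirectional extension across short
# non-conserved runs, fusion of nearby same-pattern elements, and the
# per-phylogenetic-group conservation score.

#' Scanner parameters
#'
#' @param min_species_beyond_ref minimum number of aligned species in
#'   addition to the reference for a column to count as conserved
#'   (default 7).
#' @param column_mismatch_fraction substitution threshold per column; a
#'   column with n aligned rows (reference included) is conserved when its
#'   mismatches do not exceed `ceiling(column_mismatch_fraction * n)`.
#'   At the default 0.12 this allows exactly one substitution in the
#'   minimal 8-row situation.
#' @param core_window width (bp) of the seeding window (default 10).
#' @param core_min_conserved_fraction fraction of conserved columns a core
#'   window must contain (default 0.90, i.e. 9 of 10).
#' @param max_nonconserved_run longest run of non-conserved columns the
#'   extension step may cross (default 3).
#' @param fuse_max_gap elements closer than this (bp, reference) with the
#'   same species pattern are fused (default 100).
#' @return a `scan_params` list.
#' @export
scan_params <- function(min_species_beyond_ref = 7L,
                        column_mismatch_fraction = 0.12,
                        core_window = 10L,
                        core_min_conserved_fraction = 0.90,
                        max_nonconserved_run = 3L,
                        fuse_max_gap = 100L) {
  p <- list(min_species_beyond_ref = as.integer(min_species_beyond_ref),
            column_mismatch_fraction = column_mismatch_fraction,
            core_window = as.integer(core_window),
            core_min_conserved_fraction = core_min_conserved_fraction,
            max_nonconserved_run = as.integer(max_nonconserved_run),
            fuse_max_gap = as.integer(fuse_max_gap))
  stopifnot(p$min_species_beyond_ref > 0, p$core_window > 0,
            p$max_nonconserved_run >= 0, p$fuse_max_gap > 0,
            p$column_mismatch_fraction > 0, p$column_mismatch_fraction < 1,
            p$core_min_conserved_fraction > 0,
            p$core_min_conserved_fraction <= 1)
  structure(p, class = "scan_params")
}

# character matrix of a block, one row per species, upper case
.block_matrix <- function(block) {
  m <- do.call(rbind, strsplit(toupper(block$rows$seq), "", fixed = TRUE))
  rownames(m) <- block$rows$species
  m
}

# 0-based reference position of each alignment column; NA at reference gaps
.ref_positions <- function(block, mat = NULL) {
  if (is.null(mat)) mat <- .block_matrix(block)
  ri <- match(block$ref, block$rows$species)
  refrow <- mat[ri, ]
  nongap <- refrow != "-"
  pos <- rep(NA_integer_, length(refrow))
  pos[nongap] <- block$rows$start[ri] + seq_len(sum(nongap)) - 1L
  pos
}

#' Mask alignment columns covered by exons or repeats
#'
#' A column is masked when its reference base falls inside any exon or
#' repeat interval (reference coordinates), or when the reference row is
#' gapped at that column.
#'
#' @param block a `maf_block`.
#' @param exon_intervals,repeat_intervals data.frames with `chrom`,
#'   `start`, `end` (0-based half-open), or NULL.
#' @return logical vector over alignment columns; TRUE = masked.
#' @export
mask_columns <- function(block, exon_intervals = NULL,
                         repeat_intervals = NULL) {
  mat <- .block_matrix(block)
  pos <- .ref_positions(block, mat)
  ri <- match(block$ref, block$rows$species)
  chrom <- block$rows$chrom[ri]
  masked <- is.na(pos)
  masked <- masked | .pos_in_intervals(chrom, pos, exon_intervals)
  masked | .pos_in_intervals(chrom, pos, repeat_intervals)
}

#' Is a single alignment column conserved?
#'
#' A column is conserved when (i) at least `min_species_beyond_ref`
#' non-reference rows are aligned (non-gap) at it, and (ii) the number of
#' bases differing from the reference does not exceed
#' `ceiling(column_mismatch_fraction * n)` where n counts all aligned rows
#' including the reference. Gapped rows are not counted.
#'
#' @param column character vector of bases, the reference base first;
#'   `"-"` marks a gap.
#' @param params a [scan_params()] list.
#' @return TRUE/FALSE.
#' @export
column_conserved <- function(column, params = scan_params()) {
  ref <- toupper(column[1])
  if (ref == "-") return(FALSE)
  others <- toupper(column[-1])
  aligned <- others[others != "-"]
  if (length(aligned) < params$min_species_beyond_ref) return(FALSE)
  n <- length(aligned) + 1L
  sum(aligned != ref) <= ceiling(params$column_mismatch_fraction * n)
}

#' Column conservation mask of a block
#'
#' Vectorised form of [column_conserved()] over every alignment column,
#' with masked columns forced to non-conserved.
#'
#' @inheritParams mask_columns
#' @param params a [scan_params()] list.
#' @param masked optional logical mask from [mask_columns()].
#' @return logical vector over columns; TRUE = conserved.
#' @export
conserved_columns <- function(block, params = scan_params(), masked = NULL) {
  mat <- .block_matrix(block)
  ri <- match(block$ref, block$rows$species)
  refrow <- mat[ri, ]
  others <- mat[-ri, , drop = FALSE]
  aligned <- others != "-"
  n_aligned <- colSums(aligned)
  refmat <- matrix(refrow, nrow = nrow(others), ncol = ncol(others),
                   byrow = TRUE)
  mism <- colSums(aligned & (others != refmat))
  cons <- refrow != "-" &
    n_aligned >= params$min_species_beyond_ref &
    mism <= ceiling(params$column_mismatch_fraction * (n_aligned + 1L))
  if (!is.null(masked)) cons <- cons & !masked
  cons
}

# columns belonging to a barrier: a non-conserved run that extension can
# never cross, i.e. one longer than max_nonconserved_run or containing a
# masked column
.barrier_columns <- function(conserved_mask, masked, params) {
  n <- length(conserved_mask)
  if (is.null(masked)) masked <- rep(FALSE, n)
  bad <- !conserved_mask | masked
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- logical(n)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    if (r$lengths[i] > params$max_nonconserved_run ||
        any(masked[starts[i]:ends[i]]))
      out[starts[i]:ends[i]] <- TRUE
  }
  out
}

#' Find core seeding windows
#'
#' Slides a `core_window`-wide window over the conservation mask and keeps
#' windows with at least `ceiling(core_min_conserved_fraction *
#' core_window)` conserved columns; overlapping windows are unioned into
#' seeds. A window never intersects a barrier (a masked column, or a
#' non-conserved run too long for the extension step to cross): a seed is
#' genuinely conserved sequence and may not swallow the edge of a run
#' that terminates extension.
#'
#' @param conserved_mask logical vector from [conserved_columns()].
#' @param params a [scan_params()] list.
#' @param masked optional logical mask from [mask_columns()].
#' @return data.frame of seeds with 1-based inclusive column indices
#'   `start`, `end`.
#' @export
find_cores <- function(conserved_mask, params = scan_params(),
                       masked = NULL) {
  n <- length(conserved_mask)
  w <- params$core_window
  empty <- data.frame(start = integer(), end = integer())
  if (n < w) return(empty)
  need <- ceiling(params$core_min_conserved_fraction * w)
  cs <- cumsum(as.integer(conserved_mask))
  wsum <- cs[w:n] - c(0L, cs[seq_len(n - w)])
  ok <- wsum >= need
  barrier <- .barrier_columns(conserved_mask, masked, params)
  bs <- cumsum(as.integer(barrier))
  wbar <- bs[w:n] - c(0L, bs[seq_len(n - w)])
  ok <- ok & wbar == 0L
  starts <- which(ok)
  if (length(starts) == 0L) return(empty)
  r <- IRanges::reduce(IRanges::IRanges(start = starts, width = w))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

#' Extend a seed across short non-conserved runs
#'
#' Walks outward from a seed, crossing runs of up to
#' `max_nonconserved_run` non-conserved columns, stopping at the first
#' longer run or at a masked column, and trimming the ends back to
#' conserved columns.
#'
#' @param seed integer vector `c(start, end)` (or a one-row data.frame
#'   from [find_cores()]), 1-based inclusive column indices.
#' @param conserved_mask logical vector from [conserved_columns()].
#' @param params a [scan_params()] list.
#' @param masked optional logical mask.
#' @return integer vector `c(start, end)` of the extended, trimmed
#'   element.
#' @export
extend_seed <- function(seed, conserved_mask, params = scan_params(),
                        masked = NULL) {
  if (is.data.frame(seed)) seed <- c(seed$start[1], seed$end[1])
  n <- length(conserved_mask)
  if (is.null(masked)) masked <- rep(FALSE, n)
  maxrun <- params$max_nonconserved_run
  # rightward
  right <- seed[2]
  run <- 0L
  j <- seed[2] + 1L
  while (j <= n && !masked[j]) {
    if (conserved_mask[j]) {
      right <- j
      run <- 0L
    } else {
      run <- run + 1L
      if (run > maxrun) break
    }
    j <- j + 1L
  }
  # leftward
  left <- seed[1]
  run <- 0L
  j <- seed[1] - 1L
  while (j >= 1L && !masked[j]) {
    if (conserved_mask[j]) {
      left <- j
      run <- 0L
    } else {
      run <- run + 1L
      if (run > maxrun) break
    }
    j <- j - 1L
  }
  # trim ends onto conserved columns
  while (left <= right && !conserved_mask[left]) left <- left + 1L
  while (right >= left && !conserved_mask[right]) right <- right - 1L
  c(left, right)
}

#' Called segments of a block from its conservation and mask vectors
#'
#' The closed form of core-seeding plus extension: masked columns and
#' non-conserved runs longer than `max_nonconserved_run` split the block
#' into stretches; each stretch is trimmed to conserved end columns and
#' reported when it still contains a qualifying core window.
#'
#' @inheritParams find_cores
#' @return data.frame of elements with 1-based inclusive column indices
#'   `start`, `end`.
#' @export
segments_from_masks <- function(conserved_mask, masked = NULL,
                                params = scan_params()) {
  n <- length(conserved_mask)
  empty <- data.frame(start = integer(), end = integer())
  if (n == 0L) return(empty)
  if (is.null(masked)) masked <- rep(FALSE, n)
  barrier_cols <- .barrier_columns(conserved_mask, masked, params)
  cutpoints <- sort(unique(c(0L, which(barrier_cols), n + 1L)))
  out <- list()
  for (i in seq_len(length(cutpoints) - 1L)) {
    lo <- cutpoints[i] + 1L
    hi <- cutpoints[i + 1L] - 1L
    if (lo > hi) next
    seg <- .trim_segment(lo, hi, conserved_mask)
    if (is.null(seg)) next
    if (.has_core(seg[1], seg[2], conserved_mask, params))
      out[[length(out) + 1L]] <- seg
  }
  if (length(out) == 0L) return(empty)
  data.frame(start = vapply(out, `[`, integer(1), 1L),
             end = vapply(out, `[`, integer(1), 2L))
}

.trim_segment <- function(lo, hi, cons) {
  while (lo <= hi && !cons[lo]) lo <- lo + 1L
  while (hi >= lo && !cons[hi]) hi <- hi - 1L
  if (lo > hi) return(NULL)
  c(lo, hi)
}

.has_core <- function(lo, hi, cons, params) {
  w <- params$core_window
  len <- hi - lo + 1L
  if (len < w) return(FALSE)
  need <- ceiling(params$core_min_conserved_fraction * w)
  v <- as.integer(cons[lo:hi])
  cs <- cumsum(v)
  wsum <- cs[w:len] - c(0L, cs[seq_len(len - w)])
  any(wsum >= need)
}

#' Call CNEs in alignment blocks
#'
#' Runs masking, column conservation and segment calling on every block
#' and assembles per-element records: reference interval, the set of
#' species aligned over the element, per-species orthologous locations
#' (forward-strand native coordinates) and per-species identity counts.
#' A species belongs to the element's species set when it is aligned
#' (non-gap) over at least half of the element's columns. Elements are
#' confined to single blocks; blocks are never stitched.
#'
#' @param blocks list of `maf_block` objects.
#' @param exon_intervals,repeat_intervals optional mask interval
#'   data.frames (`chrom`, `start`, `end`).
#' @param params a [scan_params()] list.
#' @return data.frame with columns `cne_id`, `chrom`, `start`, `end`,
#'   `length`, `n_species`, and list-columns `species_set`, `locations`
#'   (per-species data.frame `species`, `chrom`, `start`, `end`),
#'   `n_match`, `n_comp` (named per-species identity counts).
#' @export
call_cnes <- function(blocks, exon_intervals = NULL,
                      repeat_intervals = NULL, params = scan_params()) {
  recs <- list()
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    mat <- .block_matrix(block)
    pos <- .ref_positions(block, mat)
    masked <- mask_columns(block, exon_intervals, repeat_intervals)
    cons <- conserved_columns(block, params, masked)
    segs <- segments_from_masks(cons, masked, params)
    if (nrow(segs) == 0L) next
    ri <- match(block$ref, block$rows$species)
    chrom <- block$rows$chrom[ri]
    for (si in seq_len(nrow(segs))) {
      s <- segs$start[si]
      e <- segs$end[si]
      recs[[length(recs) + 1L]] <-
        .cne_record(block, mat, pos, ri, chrom, s, e, bi)
    }
  }
  .cne_table(recs)
}

# assemble the per-species bookkeeping of one called segment
.cne_record <- function(block, mat, pos, ri, chrom, s, e, block_index) {
  cols <- s:e
  ncol_seg <- length(cols)
  refsub <- mat[ri, cols]
  ref_nongap <- refsub != "-"
  start0 <- pos[s]
  end0 <- pos[e] + 1L
  species <- block$rows$species[-ri]
  idx <- seq_len(nrow(block$rows))[-ri]
  set <- character(0)
  loc <- list()
  n_match <- numeric(0)
  n_comp <- numeric(0)
  for (k in seq_along(idx)) {
    i <- idx[k]
    sub <- mat[i, cols]
    nongap <- sub != "-"
    ncov <- sum(nongap)
    if (ncov < ncol_seg / 2) next
    sp <- species[k]
    set <- c(set, sp)
    both <- nongap & ref_nongap
    n_comp[sp] <- sum(both)
    n_match[sp] <- sum(sub[both] == refsub[both])
    full <- mat[i, ]
    before <- sum(full[seq_len(s - 1L)] != "-")
    nat_start <- block$rows$start[i] + before
    nat_end <- nat_start + ncov
    if (block$rows$strand[i] == "-") {
      fwd_start <- block$rows$src_size[i] - nat_end
      fwd_end <- block$rows$src_size[i] - nat_start
    } else {
      fwd_start <- nat_start
      fwd_end <- nat_end
    }
    loc[[sp]] <- list(chrom = block$rows$chrom[i], start = fwd_start,
                      end = fwd_end)
  }
  locdf <- if (length(loc)) {
    data.frame(species = names(loc),
               chrom = vapply(loc, `[[`, character(1), "chrom"),
               start = vapply(loc, function(x) as.numeric(x$start),
                              numeric(1)),
               end = vapply(loc, function(x) as.numeric(x$end), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(species = character(), chrom = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  }
  list(chrom = chrom, start = start0, end = end0, block = block_index,
       species_set = set, locations = locdf, n_match = n_match,
       n_comp = n_comp)
}

.cne_table <- function(recs) {
  if (length(recs) == 0L) {
    return(data.frame(cne_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_species = integer(),
                      species_set = I(list()), locations = I(list()),
                      n_match = I(list()), n_comp = I(list()),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    cne_id = sprintf("CNE%05d", seq_along(recs)),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, function(r) as.integer(r$start), integer(1)),
    end = vapply(recs, function(r) as.integer(r$end), integer(1)),
    stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$n_species <- vapply(recs, function(r) length(r$species_set), integer(1))
  df$species_set <- I(lapply(recs, `[[`, "species_set"))
  df$locations <- I(lapply(recs, `[[`, "locations"))
  df$n_match <- I(lapply(recs, `[[`, "n_match"))
  df$n_comp <- I(lapply(recs, `[[`, "n_comp"))
  df
}

#' Fuse nearby CNEs with an identical species pattern
#'
#' Two consecutive elements are fused when they share an identical species
#' set, their reference gap is below `fuse_max_gap`, and in every shared
#' species their orthologous locations sit on the same chromosome with no
#' third called element between them. Fusion is applied transitively along
#' chains and is idempotent; identity counts are summed so the fused
#' percent identities are exact.
#'
#' @param cnes data.frame from [call_cnes()].
#' @param params a [scan_params()] list.
#' @return data.frame of the same shape, ids reassigned.
#' @export
fuse_cnes <- function(cnes, params = scan_params()) {
  if (nrow(cnes) <= 1L) return(cnes)
  ord <- order(cnes$chrom, cnes$start)
  cnes <- cnes[ord, , drop = FALSE]
  n <- nrow(cnes)
  # species-location index: per species, all element locations
  loc_by_species <- .species_location_index(cnes)
  group <- integer(n)
  group[1] <- 1L
  for (i in 2:n) {
    fuse <- .can_fuse(cnes, i - 1L, i, params, loc_by_species)
    group[i] <- if (fuse) group[i - 1L] else group[i - 1L] + 1L
  }
  merged <- lapply(split(seq_len(n), group), function(ix) {
    if (length(ix) == 1L) return(.row_as_record(cnes, ix))
    .merge_rows(cnes, ix)
  })
  .cne_table(unname(merged))
}

.species_location_index <- function(cnes) {
  rows <- list()
  for (i in seq_len(nrow(cnes))) {
    l <- cnes$locations[[i]]
    if (nrow(l) == 0L) next
    l$elem <- i
    rows[[length(rows) + 1L]] <- l
  }
  if (length(rows) == 0L) return(list())
  all <- do.call(rbind, rows)
  split(all, all$species)
}

.can_fuse <- function(cnes, a, b, params, loc_by_species) {
  if (cnes$chrom[a] != cnes$chrom[b]) return(FALSE)
  gap <- cnes$start[b] - cnes$end[a]
  if (gap >= params$fuse_max_gap) return(FALSE)
  sa <- cnes$species_set[[a]]
  sb <- cnes$species_set[[b]]
  if (length(sa) != length(sb) || !setequal(sa, sb)) return(FALSE)
  la <- cnes$locations[[a]]
  lb <- cnes$locations[[b]]
  for (sp in sa) {
    ra <- la[la$species == sp, ]
    rb <- lb[lb$species == sp, ]
    if (nrow(ra) == 0L || nrow(rb) == 0L) return(FALSE)
    if (ra$chrom != rb$chrom) return(FALSE)
    lo <- min(ra$end, rb$end)
    hi <- max(ra$start, rb$start)
    if (hi <= lo) next  # locations overlap or abut: adjacent
    others <- loc_by_species[[sp]]
    others <- others[others$elem != a & others$elem != b &
                       others$chrom == ra$chrom, , drop = FALSE]
    if (nrow(others) > 0L &&
        any(others$start < hi & others$end > lo)) return(FALSE)
  }
  TRUE
}

.row_as_record <- function(cnes, i) {
  list(chrom = cnes$chrom[i], start = cnes$start[i], end = cnes$end[i],
       block = NA_integer_, species_set = cnes$species_set[[i]],
       locations = cnes$locations[[i]], n_match = cnes$n_match[[i]],
       n_comp = cnes$n_comp[[i]])
}

.merge_rows <- function(cnes, ix) {
  set <- cnes$species_set[[ix[1]]]
  nm <- numeric(0)
  nc <- numeric(0)
  locs <- list()
  for (i in ix) {
    mi <- cnes$n_match[[i]]
    ci <- cnes$n_comp[[i]]
    for (sp in names(ci)) {
      nm[sp] <- (if (sp %in% names(nm)) nm[sp] else 0) + mi[sp]
      nc[sp] <- (if (sp %in% names(nc)) nc[sp] else 0) + ci[sp]
    }
    l <- cnes$locations[[i]]
    for (j in seq_len(nrow(l))) {
      sp <- l$species[j]
      if (is.null(locs[[sp]])) {
        locs[[sp]] <- list(chrom = l$chrom[j], start = l$start[j],
                           end = l$end[j])
      } else {
        locs[[sp]]$start <- min(locs[[sp]]$start, l$start[j])
        locs[[sp]]$end <- max(locs[[sp]]$end, l$end[j])
      }
    }
  }
  locdf <- data.frame(species = names(locs),
                      chrom = vapply(locs, `[[`, character(1), "chrom"),
                      start = vapply(locs, function(x) as.numeric(x$start),
                                     numeric(1)),
                      end = vapply(locs, function(x) as.numeric(x$end),
                                   numeric(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(chrom = cnes$chrom[ix[1]], start = min(cnes$start[ix]),
       end = max(cnes$end[ix]), block = NA_integer_, species_set = set,
       locations = locdf, n_match = nm, n_comp = nc)
}

#' Conservation score of one element
#'
#' Per-species percent identity (matches over columns where both the
#' reference and the species are ungapped, 0-100, rounded to the nearest
#' integer) is summarised per phylogenetic group by its maximum; the score
#' is the sum of the group maxima, groups with no aligned species
#' contributing 0.
#'
#' @param pct_id named numeric vector of per-species percent identities,
#'   or a single-row slice of a [call_cnes()] table.
#' @param species_meta species metadata (see [read_species_meta()]).
#' @return the summed percent identity (one number).
#' @examples
#' meta <- data.frame(
#'   species_id = c("hsap", "ptro", "lafr", "mdom", "ggal", "olat"),
#'   phylo_group = c("Reference", "Boreoeutheria", "Atlantogenata",
#'                   "MonotremesMarsupials", "SauropsidsAmphibians",
#'                   "Teleosts"),
#'   genome_size = 1e9, C_e = 1, excluded = FALSE)
#' conservation_score(
#'   c(ptro = 97, lafr = 68, mdom = 62, ggal = 54, olat = 49), meta)
#' @export
conservation_score <- function(pct_id, species_meta) {
  if (is.data.frame(pct_id)) {
    stopifnot(nrow(pct_id) == 1L)
    pct_id <- .pct_id_of(pct_id$n_match[[1]], pct_id$n_comp[[1]])
  }
  grp <- species_meta$phylo_group[match(names(pct_id),
                                        species_meta$species_id)]
  if (anyNA(grp))
    stop("species without metadata: ",
         paste(names(pct_id)[is.na(grp)], collapse = ", "))
  keep <- grp %in% phylo_groups() & !is.na(pct_id)
  if (!any(keep)) return(0)
  sum(tapply(pct_id[keep], grp[keep], max))
}

.pct_id_of <- function(n_match, n_comp) {
  ok <- n_comp > 0
  out <- round(100 * n_match[ok] / n_comp[ok])
  names(out) <- names(n_comp)[ok]
  out
}

#' Conservation scores for a table of elements
#'
#' @param cnes data.frame from [call_cnes()] or [fuse_cnes()].
#' @param species_meta species metadata.
#' @return `cnes` with `pct_id` (list-column) and `score` columns added.
#' @export
conservation_scores <- function(cnes, species_meta) {
  pid <- lapply(seq_len(nrow(cnes)), function(i)
    .pct_id_of(cnes$n_match[[i]], cnes$n_comp[[i]]))
  cnes$pct_id <- I(pid)
  cnes$score <- vapply(pid, conservation_score, numeric(1),
                       species_meta = species_meta)
  cnes
}

#' Merge scanner output with an externally derived element set
#'
#' Takes the interval union per chromosome of the native elements and an
#' external BED-style set. Merged elements that include at least one
#' native element inherit the union of their species data; elements
#' arising purely from the external set carry an empty species set and
#' are flagged `external_only`.
#'
#' @param cnes data.frame from [call_cnes()] / [fuse_cnes()].
#' @param external_bed data.frame with `chrom`, `start`, `end`.
#' @return element table with an `external_only` logical column.
#' @export
merge_external <- function(cnes, external_bed) {
  ivs <- rbind(
    data.frame(chrom = cnes$chrom, start = cnes$start, end = cnes$end,
               native = seq_len(nrow(cnes)), stringsAsFactors = FALSE),
    data.frame(chrom = external_bed$chrom, start = external_bed$start,
               end = external_bed$end, native = NA_integer_,
               stringsAsFactors = FALSE))
  out <- list()
  ext_only <- logical(0)
  for (ch in unique(ivs$chrom)) {
    sub <- ivs[ivs$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(.as_iranges(sub$start, sub$end))
    ms <- IRanges::start(r) - 1L
    me <- IRanges::end(r)
    hit <- IRanges::findOverlaps(.as_iranges(sub$start, sub$end), r)
    for (k in seq_along(ms)) {
      members <- sub$native[S4Vectors::queryHits(hit)[
        S4Vectors::subjectHits(hit) == k]]
      members <- members[!is.na(members)]
      if (length(members) == 0L) {
        out[[length(out) + 1L]] <- list(
          chrom = ch, start = ms[k], end = me[k], block = NA_integer_,
          species_set = character(0),
          locations = data.frame(species = character(),
                                 chrom = character(), start = numeric(),
                                 end = numeric(), stringsAsFactors = FALSE),
          n_match = numeric(0), n_comp = numeric(0))
        ext_only <- c(ext_only, TRUE)
      } else {
        rec <- .merge_rows(cnes, members)
        rec$species_set <- Reduce(union, cnes$species_set[members])
        rec$start <- ms[k]
        rec$end <- me[k]
        out[[length(out) + 1L]] <- rec
        ext_only <- c(ext_only, FALSE)
      }
    }
  }
  tab <- .cne_table(out)
  tab$external_only <- ext_only
  tab[order(tab$chrom, tab$start), , drop = FALSE]
}

#' One-call scanner: call, fuse and score CNEs
#'
#' @inheritParams call_cnes
#' @param species_meta species metadata used for conservation scoring.
#' @return fused, scored element table.
#' @export
scan_cnes <- function(blocks, exon_intervals = NULL,
                      repeat_intervals = NULL, params = scan_params(),
                      species_meta = NULL) {
  x <- call_cnes(blocks, exon_intervals, repeat_intervals, params)
  x <- fuse_cnes(x, params)
  if (!is.null(species_meta)) x <- conservation_scores(x, species_meta)
  x
}
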