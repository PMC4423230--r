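# Evolutionary linkage scoring: per-species status of each candidate
# target gene relative to the orthologous CNE, synteny-level and
# coverage-weighted evidence accumulation, sigmoid normalisation to the
# S_A score, target selection and fusion of co-targeting CNEs into
# regulatory elements.

#' Scale the linkage radius to a genome's size
#'
#' The search radius in species e is the reference radius scaled by the
#' ratio of genome sizes, so that a genome at 80% of the reference size
#' gets a 0.8 Mb radius from a 1 Mb reference radius.
#'
#' @param d_ref reference radius in bp (default 1 Mb).
#' @param genome_size_e,genome_size_ref genome sizes in bp, both > 0.
#' @return scaled radius in bp.
#' @export
scaled_radius <- function(d_ref, genome_size_e, genome_size_ref) {
  if (any(genome_size_e <= 0) || any(genome_size_ref <= 0))
    stop("genome sizes must be > 0")
  d_ref * genome_size_e / genome_size_ref
}

#' Candidate target families of a CNE
#'
#' Families whose reference gene lies within `d_ref` of the element
#' (closest-edge gap, 0 when overlapping) on the same chromosome.
#'
#' @param cne list or single-row data.frame with `chrom`, `start`, `end`.
#' @param ref_genes data.frame of reference gene placements with
#'   `family_id`, `chrom`, `start`, `end`.
#' @param d_ref radius in bp (default 1 Mb).
#' @return character vector of family ids (possibly empty:
#'   an unassociated element).
#' @export
candidate_families <- function(cne, ref_genes, d_ref = 1e6) {
  if (nrow(ref_genes) == 0L) return(character(0))
  same <- ref_genes$chrom == cne$chrom
  gap <- .edge_gap(cne$start, cne$end, ref_genes$start, ref_genes$end)
  unique(ref_genes$family_id[same & gap < d_ref])
}

#' Status of a family in one species relative to the orthologous CNE
#'
#' `S0`: no gene record in the species (absent or mis-annotated);
#' `S3`: records exist but none on the chromosome/scaffold of the
#' orthologous CNE; `S1`: the nearest same-chromosome record is within
#' the scaled radius `d_e`; `S2`: same chromosome but beyond `d_e`.
#' With paralogs the most favourable status (S1 > S2 > S3) applies.
#'
#' @param cne_loc list with `chrom`, `start`, `end`: the element's
#'   orthologous location in the species.
#' @param records data.frame of the family's gene records in that species
#'   (`chrom`, `start`, `end`); zero rows mean absent.
#' @param d_e scaled radius in bp.
#' @return one of `"S0"`, `"S1"`, `"S2"`, `"S3"`.
#' @export
classify_status <- function(cne_loc, records, d_e) {
  if (is.null(records) || nrow(records) == 0L) return("S0")
  same <- records$chrom == cne_loc$chrom
  if (!any(same)) return("S3")
  gap <- .edge_gap(cne_loc$start, cne_loc$end,
                   records$start[same], records$end[same])
  if (min(gap) < d_e) "S1" else "S2"
}

#' Synteny level of a species against the reference gene order
#'
#' The fraction R_e = P_e / H, where H is the number of adjacent gene
#' pairs in the reference gene order and P_e the number of those pairs
#' whose orthologs are direct neighbours (same chromosome, consecutive in
#' the species' gene order, orientation ignored) in species e. The
#' reference against itself gives 1; a genome with every ortholog
#' isolated on its own scaffold gives 0.
#'
#' @param ref_genes data.frame of reference placements (`family_id`,
#'   `chrom`, `start`, `end`), one or more rows per family.
#' @param species_genes data.frame of the species' placements, same
#'   columns.
#' @return R_e in [0, 1].
#' @export
synteny_level <- function(ref_genes, species_genes) {
  ro <- ref_genes[order(ref_genes$chrom, ref_genes$start), , drop = FALSE]
  H <- 0L
  ref_pairs <- character(0)
  if (nrow(ro) >= 2L) {
    adj <- ro$chrom[-nrow(ro)] == ro$chrom[-1]
    a <- ro$family_id[-nrow(ro)][adj]
    b <- ro$family_id[-1][adj]
    keep <- a != b
    ref_pairs <- unique(paste(pmin(a[keep], b[keep]),
                              pmax(a[keep], b[keep]), sep = "\r"))
    H <- length(ref_pairs)
  }
  if (H == 0L) stop("reference gene order has no adjacent gene pairs")
  if (nrow(species_genes) < 2L) return(0)
  so <- species_genes[order(species_genes$chrom, species_genes$start), ,
                      drop = FALSE]
  adj <- so$chrom[-nrow(so)] == so$chrom[-1]
  a <- so$family_id[-nrow(so)][adj]
  b <- so$family_id[-1][adj]
  keep <- a != b
  sp_pairs <- unique(paste(pmin(a[keep], b[keep]),
                           pmax(a[keep], b[keep]), sep = "\r"))
  sum(ref_pairs %in% sp_pairs) / H
}

#' Synteny levels for every species in an ortholog table
#'
#' @param orthologs ortholog table (see [read_ortholog_table()]).
#' @param species_meta species metadata; the `Reference` species supplies
#'   the reference gene order.
#' @return `species_meta` with an `R_e` column filled (reference = 1,
#'   excluded species = NA).
#' @export
compute_synteny_levels <- function(orthologs, species_meta) {
  ref_sp <- species_meta$species_id[species_meta$phylo_group == "Reference"]
  ref_genes <- orthologs[orthologs$species_id == ref_sp, , drop = FALSE]
  if (nrow(ref_genes) == 0L) stop("no reference gene placements")
  species_meta$R_e <- NA_real_
  for (i in seq_len(nrow(species_meta))) {
    sp <- species_meta$species_id[i]
    if (species_meta$excluded[i]) next
    if (sp == ref_sp) {
      species_meta$R_e[i] <- 1
      next
    }
    sg <- orthologs[orthologs$species_id == sp, , drop = FALSE]
    species_meta$R_e[i] <- synteny_level(ref_genes, sg)
  }
  species_meta
}

#' Weight scheme for the raw linkage score
#'
#' Per-species contributions: a gene still linked within the scaled
#' radius (S1) is rewarded in proportion to how rearranged the genome is,
#' `s1 * (1 - R_e)` -- maintained linkage in a highly rearranged genome is
#' strong evidence, while the reference genome itself (R_e = 1)
#' contributes nothing. Absence evidence is penalised proportionally to
#' the sequencing-coverage factor `C_e`, which discounts genomes whose
#' annotations cannot be trusted: `s2 * C_e` for same-chromosome beyond
#' the radius, `s3 * C_e` for another chromosome, `s0 * C_e` for a
#' missing annotation. The defaults keep the contract that the raw score
#' strictly increases along S3 -> S2 -> S1 whenever C_e > 0.
#'
#' @param s1,s2,s3,s0 status coefficients.
#' @return a `linkage_weights` list.
#' @export
linkage_weights <- function(s1 = 1, s2 = -0.5, s3 = -1, s0 = -0.25) {
  structure(list(s1 = s1, s2 = s2, s3 = s3, s0 = s0),
            class = "linkage_weights")
}

.status_weight <- function(status, R_e, C_e, weights) {
  switch(status,
         S1 = weights$s1 * (1 - R_e),
         S2 = weights$s2 * C_e,
         S3 = weights$s3 * C_e,
         S0 = weights$s0 * C_e,
         stop("unknown status: ", status))
}

#' Raw linkage score from a status trail
#'
#' @param statuses named character vector, one status (`"S0"`..`"S3"`)
#'   per species in the element's species set.
#' @param species_meta species metadata with `R_e` filled.
#' @param weights a [linkage_weights()] scheme.
#' @return the summed raw score.
#' @export
raw_linkage <- function(statuses, species_meta, weights = linkage_weights()) {
  idx <- match(names(statuses), species_meta$species_id)
  if (anyNA(idx))
    stop("species missing from metadata: ",
         paste(names(statuses)[is.na(idx)], collapse = ", "))
  total <- 0
  for (k in seq_along(statuses)) {
    i <- idx[k]
    total <- total + .status_weight(statuses[[k]], species_meta$R_e[i],
                                    species_meta$C_e[i], weights)
  }
  total
}

#' Sigmoid normalisation of raw linkage scores
#'
#' S_A = 1 / (1 + exp(-k (raw - m))). Strictly monotone, so the ranking
#' of candidates is exactly the ranking of raw scores, and every output
#' lies in (0, 1). By default the midpoint m is the median raw score of
#' the run.
#'
#' @param raw numeric vector of raw scores.
#' @param k slope (default 1).
#' @param midpoint m; default `median(raw)`.
#' @return numeric vector of S_A values in (0, 1).
#' @export
normalize_scores <- function(raw, k = 1, midpoint = NULL) {
  if (length(raw) == 0L) return(numeric(0))
  if (is.null(midpoint)) midpoint <- stats::median(raw)
  1 / (1 + exp(-k * (raw - midpoint)))
}

#' Select the best-scoring targets of one element
#'
#' All families attaining the maximal S_A are kept (ties mean multiple
#' targets). The relative score is the gap between the top and the
#' second-highest distinct S_A; it is undefined (NA) when there is no
#' second distinct value, in particular for single-candidate elements.
#'
#' @param assignments data.frame with `family_id` and `S_A` for one
#'   element.
#' @return list with `targets` (character vector), `max_SA`, `relative`.
#' @export
rank_and_select <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(list(targets = character(0), max_SA = NA_real_,
                relative = NA_real_))
  top <- max(assignments$S_A)
  targets <- assignments$family_id[assignments$S_A == top]
  uniq <- sort(unique(assignments$S_A), decreasing = TRUE)
  relative <- if (length(uniq) >= 2L) top - uniq[2] else NA_real_
  list(targets = targets, max_SA = top, relative = relative)
}

#' Score the evolutionary linkage of every CNE to its candidate genes
#'
#' For each element, candidate families within `d_ref` of the reference
#' interval are classified per species of the element's species set
#' (excluded species skipped), the weighted evidence is summed into a raw
#' score, and all raw scores of the run are sigmoid-normalised into S_A.
#'
#' @param cnes element table from [call_cnes()] / [fuse_cnes()].
#' @param orthologs ortholog table.
#' @param species_meta species metadata; `R_e` is computed from the
#'   ortholog table when not already present.
#' @param d_ref reference radius in bp (default 1 Mb).
#' @param weights a [linkage_weights()] scheme.
#' @param k,midpoint sigmoid constants, see [normalize_scores()].
#' @return list with `assignments` (one row per element x candidate:
#'   `cne_id`, `family_id`, `raw`, `S_A`, `status` trail string),
#'   `selections` (one row per element: `cne_id`, `chrom`, `start`,
#'   `end`, `n_candidates`, `max_SA`, `relative`, list-column `targets`),
#'   and the `species_meta` with `R_e` filled.
#' @export
score_linkage <- function(cnes, orthologs, species_meta, d_ref = 1e6,
                          weights = linkage_weights(), k = 1,
                          midpoint = NULL) {
  if (is.null(species_meta$R_e) || anyNA(species_meta$R_e[
    !species_meta$excluded]))
    species_meta <- compute_synteny_levels(orthologs, species_meta)
  ref_sp <- species_meta$species_id[species_meta$phylo_group == "Reference"]
  ref_genes <- orthologs[orthologs$species_id == ref_sp, , drop = FALSE]
  usable <- species_meta$species_id[!species_meta$excluded &
                                      species_meta$species_id != ref_sp]
  meta_idx <- match(species_meta$species_id, species_meta$species_id)
  size_ref <- species_meta$genome_size[species_meta$phylo_group ==
                                         "Reference"]
  d_e_all <- scaled_radius(d_ref, species_meta$genome_size, size_ref)
  names(d_e_all) <- species_meta$species_id
  R_all <- stats::setNames(species_meta$R_e, species_meta$species_id)
  C_all <- stats::setNames(species_meta$C_e, species_meta$species_id)
  # fast (species, family) -> records lookup
  recs <- .family_record_index(orthologs)
  rows <- list()
  sel <- list()
  for (i in seq_len(nrow(cnes))) {
    cne <- list(chrom = cnes$chrom[i], start = cnes$start[i],
                end = cnes$end[i])
    cands <- candidate_families(cne, ref_genes, d_ref)
    trail_sp <- intersect(cnes$species_set[[i]], usable)
    locs <- cnes$locations[[i]]
    fam_rows <- list()
    for (fam in cands) {
      statuses <- character(length(trail_sp))
      names(statuses) <- trail_sp
      raw <- 0
      for (sp in trail_sp) {
        li <- which(locs$species == sp)
        loc <- list(chrom = locs$chrom[li], start = locs$start[li],
                    end = locs$end[li])
        rr <- recs[[sp]][[fam]]
        st <- classify_status(loc, rr, d_e_all[[sp]])
        statuses[[sp]] <- st
        raw <- raw + .status_weight(st, R_all[[sp]], C_all[[sp]], weights)
      }
      fam_rows[[fam]] <- list(
        cne_id = cnes$cne_id[i], family_id = fam, raw = raw,
        status = paste(sprintf("%s:%s", trail_sp, statuses),
                       collapse = ";"))
    }
    rows <- c(rows, unname(fam_rows))
    sel[[i]] <- list(cne_id = cnes$cne_id[i], cne = cne,
                     n_candidates = length(cands))
  }
  assignments <- if (length(rows)) {
    data.frame(cne_id = vapply(rows, `[[`, character(1), "cne_id"),
               family_id = vapply(rows, `[[`, character(1), "family_id"),
               raw = vapply(rows, `[[`, numeric(1), "raw"),
               status = vapply(rows, `[[`, character(1), "status"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cne_id = character(), family_id = character(),
               raw = numeric(), status = character(),
               stringsAsFactors = FALSE)
  }
  assignments$S_A <- normalize_scores(assignments$raw, k = k,
                                      midpoint = midpoint)
  selections <- data.frame(
    cne_id = cnes$cne_id, chrom = cnes$chrom, start = cnes$start,
    end = cnes$end,
    n_candidates = vapply(sel, `[[`, integer(1), "n_candidates"),
    max_SA = NA_real_, relative = NA_real_, stringsAsFactors = FALSE)
  selections$targets <- I(vector("list", nrow(selections)))
  for (i in seq_len(nrow(selections))) {
    sub <- assignments[assignments$cne_id == selections$cne_id[i], ,
                       drop = FALSE]
    r <- rank_and_select(sub)
    selections$targets[[i]] <- r$targets
    selections$max_SA[i] <- r$max_SA
    selections$relative[i] <- r$relative
  }
  list(assignments = assignments, selections = selections,
       species_meta = species_meta)
}

.family_record_index <- function(orthologs) {
  out <- list()
  by_sp <- split(seq_len(nrow(orthologs)), orthologs$species_id)
  for (sp in names(by_sp)) {
    ix <- by_sp[[sp]]
    sub <- orthologs[ix, c("family_id", "chrom", "start", "end"),
                     drop = FALSE]
    out[[sp]] <- split(sub[, c("chrom", "start", "end")], sub$family_id)
  }
  out
}

#' Fuse co-targeting CNEs into regulatory elements
#'
#' Chain-fusion of consecutive elements (reference order) whose selected
#' target sets are identical and whose gap is below `max_gap`. Idempotent;
#' the element interval spans its constituents.
#'
#' @param selections selection table from [score_linkage()].
#' @param max_gap fusion distance in bp (default 100).
#' @return data.frame of regulatory elements: `reg_id`, `chrom`, `start`,
#'   `end`, `n_cnes`, `max_SA`, list-columns `cne_ids` and `targets`.
#' @export
fuse_reg_elements <- function(selections, max_gap = 100L) {
  if (nrow(selections) == 0L) {
    return(data.frame(reg_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cnes = integer(), max_SA = numeric(),
                      cne_ids = I(list()), targets = I(list()),
                      stringsAsFactors = FALSE))
  }
  s <- selections[order(selections$chrom, selections$start), , drop = FALSE]
  n <- nrow(s)
  group <- integer(n)
  group[1] <- 1L
  if (n > 1L) for (i in 2:n) {
    same_chrom <- s$chrom[i] == s$chrom[i - 1L]
    gap <- s$start[i] - s$end[i - 1L]
    same_targets <- setequal(s$targets[[i]], s$targets[[i - 1L]])
    group[i] <- if (same_chrom && gap < max_gap && same_targets)
      group[i - 1L] else group[i - 1L] + 1L
  }
  parts <- split(seq_len(n), group)
  out <- data.frame(
    reg_id = sprintf("RegEl%05d", seq_along(parts)),
    chrom = vapply(parts, function(ix) s$chrom[ix[1]], character(1)),
    start = vapply(parts, function(ix) min(s$start[ix]), numeric(1)),
    end = vapply(parts, function(ix) max(s$end[ix]), numeric(1)),
    n_cnes = lengths(parts),
    max_SA = vapply(parts, function(ix) {
      v <- s$max_SA[ix]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$cne_ids <- I(lapply(parts, function(ix) s$cne_id[ix]))
  out$targets <- I(lapply(parts, function(ix) s$targets[[ix[1]]]))
  out
}
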