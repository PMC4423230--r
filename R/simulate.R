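# Synthetic data generator: an ancestral (reference) gene/CNE layout,
# descendant genomes rearranged by inversions, transpositions and
# translocations, multi-species alignment blocks with per-group
# divergence, ortholog tables with coverage-dependent annotation
# dropout, planted signal peaks and promoter interaction pairs -- all
# with full ground truth, so every module of the pipeline can be tested
# offline. Linkage between a planted enhancer and its true target is
# protected from breakpoints (except in a configurable violation
# fraction of species), emulating negative selection against
# rearrangements that would dissociate an enhancer from its target.

.GROUP_ABBREV <- c(Boreoeutheria = "bor", Atlantogenata = "atl",
                   MonotremesMarsupials = "mar",
                   SauropsidsAmphibians = "sau", Teleosts = "tel")

#' Simulation configuration
#'
#' Defaults define the package's standard study conditions: 20 species
#' beyond the reference spread over the five phylogenetic groups, a
#' 6-Mb reference chromosome with 60 genes and 100 CNEs (half of them
#' enhancers with a planted target among their flanking genes), two
#' rearrangement operations per Mb per species, coverage-dependent gene
#' annotation dropout, group-specific sequence divergence and signal
#' peaks enriched on true enhancers.
#'
#' @param seed integer seed (mandatory).
#' @param n_species named integer vector: species count per phylogenetic
#'   group.
#' @param n_genes,genome_length,gene_length reference layout: gene count,
#'   chromosome length (bp) and gene body length (bp).
#' @param n_cnes,cne_length CNE count and length range (bp).
#' @param fraction_enhancers fraction of CNEs given a planted true
#'   target.
#' @param rearrangement_rate expected rearrangement operations per Mb per
#'   species.
#' @param violation_fraction probability that a species is allowed to
#'   break a given enhancer-target linkage.
#' @param op_weights named weights over `inversion`, `transposition`,
#'   `translocation`.
#' @param fraction_low_coverage fraction of species emulating ~2x draft
#'   assemblies (coverage factor `coverage_factors["low"]`, more
#'   annotation dropout).
#' @param coverage_factors named vector with `high` and `low` C_e values.
#' @param gene_loss_base,gene_loss_coverage gene annotation dropout
#'   probability: `base + coverage * (1 - C_e)`.
#' @param group_identity named vector: expected percent identity of each
#'   group's aligned sequence over CNE columns.
#' @param flank_identity expected percent identity of the non-conserved
#'   flanks around each planted CNE.
#' @param flank_width flank width (alignment columns) on each side.
#' @param gap_rate,flank_gap_rate per-column gap probabilities.
#' @param presence_prob probability that a species is aligned at a CNE
#'   (at least `min_aligned` species are forced).
#' @param min_aligned minimal number of non-reference species aligned at
#'   every CNE.
#' @param peak_prob_enhancer,peak_prob_background probability of a
#'   planted signal peak on true enhancers vs other CNEs.
#' @param interaction_fraction fraction of enhancers given an
#'   interaction pair.
#' @param interaction_consistent probability that such a pair names the
#'   true target (otherwise a random non-target gene within 1 Mb).
#' @param size_factor_range range of genome-size factors relative to the
#'   reference.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_species = c(Boreoeutheria = 7L,
                                     Atlantogenata = 3L,
                                     MonotremesMarsupials = 3L,
                                     SauropsidsAmphibians = 4L,
                                     Teleosts = 3L),
                       n_genes = 60L, genome_length = 6e6,
                       gene_length = 5000L,
                       n_cnes = 100L, cne_length = c(60L, 120L),
                       fraction_enhancers = 0.5,
                       rearrangement_rate = 2,
                       violation_fraction = 0.05,
                       op_weights = c(inversion = 0.4,
                                      transposition = 0.3,
                                      translocation = 0.3),
                       fraction_low_coverage = 0.25,
                       coverage_factors = c(high = 1, low = 0.5),
                       gene_loss_base = 0.02, gene_loss_coverage = 0.3,
                       group_identity = c(Boreoeutheria = 96,
                                          Atlantogenata = 92,
                                          MonotremesMarsupials = 90,
                                          SauropsidsAmphibians = 87,
                                          Teleosts = 83),
                       flank_identity = 55, flank_width = 25L,
                       gap_rate = 0.02, flank_gap_rate = 0.08,
                       presence_prob = 0.92, min_aligned = 7L,
                       peak_prob_enhancer = 0.85,
                       peak_prob_background = 0.05,
                       interaction_fraction = 0.7,
                       interaction_consistent = 0.9,
                       size_factor_range = c(0.7, 1.05)) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(fraction_enhancers, violation_fraction, fraction_low_coverage,
             gene_loss_base, gene_loss_coverage, gap_rate, flank_gap_rate,
             presence_prob, peak_prob_enhancer, peak_prob_background,
             interaction_fraction, interaction_consistent)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(names(n_species) %in% phylo_groups()),
            all(n_species >= 0), n_genes >= 2, n_cnes >= 1,
            genome_length > n_genes * (gene_length + 4000))
  # feasibility: intergenic room for the requested CNEs
  spacing <- floor(genome_length / n_genes)
  room <- spacing - gene_length - 3000 - max(cne_length)
  if (room < 400 || n_cnes > (n_genes - 1) * floor(room / 300))
    stop("infeasible config: not enough intergenic room for n_cnes")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete data bundle
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, the bundle is also written
#'   to disk via [write_bundle()].
#' @return a `sim_bundle` list with elements `config`, `blocks` (MAF
#'   blocks), `orthologs`, `species_meta`, `ref_genes`, `exons`,
#'   `repeats`, `peaks`, `interactions` and `truth` (ground-truth
#'   bookkeeping: per-CNE targets and peak labels, per-species operation
#'   counts and preserved-adjacency counts, per-species CNE locations,
#'   violator map).
#' @export
simulate_bundle <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bundle <- .with_preserved_rng({
    set.seed(config$seed)
    .simulate_impl(config)
  })
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

.simulate_impl <- function(cfg) {
  L <- cfg$genome_length
  nG <- cfg$n_genes
  spacing <- floor(L / nG)
  gene_start <- (seq_len(nG) - 1L) * spacing + floor(0.15 * spacing)
  gene_end <- gene_start + cfg$gene_length
  gene_ids <- sprintf("g%03d", seq_len(nG))

  # --- CNE placement in intergenic regions
  lens <- cfg$cne_length[1] +
    floor(stats::runif(cfg$n_cnes) * (diff(cfg$cne_length) + 1))
  region <- sample(nG - 1L, cfg$n_cnes, replace = TRUE)
  cne_start <- integer(cfg$n_cnes)
  for (i in seq_len(cfg$n_cnes)) {
    placed <- FALSE
    for (try in 1:200) {
      r <- if (try == 1L) region[i] else sample(nG - 1L, 1L)
      lo <- gene_end[r] + 1500L
      hi <- gene_start[r + 1L] - 1500L - lens[i]
      if (hi <= lo) next
      pos <- lo + sample.int(hi - lo, 1L)
      if (i == 1L || all(abs(pos - cne_start[seq_len(i - 1L)]) >= 300L)) {
        cne_start[i] <- pos
        region[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place CNE ", i, "; config too dense")
  }
  ord <- order(cne_start)
  cne_start <- cne_start[ord]
  lens <- lens[ord]
  region <- region[ord]
  cne_end <- cne_start + lens
  cne_ids <- sprintf("cne%04d", seq_len(cfg$n_cnes))
  n_enh <- round(cfg$fraction_enhancers * cfg$n_cnes)
  enhancer <- logical(cfg$n_cnes)
  enhancer[sample(cfg$n_cnes, n_enh)] <- TRUE
  # one target side per intergenic region: co-located enhancers share a
  # target (a genome regulatory block), so protected chains of one region
  # never cross each other
  side_of_region <- stats::runif(nG - 1L) < 0.5
  true_target <- rep(NA_character_, cfg$n_cnes)
  target_gidx <- ifelse(enhancer, region + side_of_region[region], NA)
  true_target[enhancer] <- gene_ids[target_gidx[enhancer]]

  # --- reference locus order (genes + CNEs interleaved)
  loci <- data.frame(
    id = c(gene_ids, cne_ids),
    type = rep(c("gene", "cne"), c(nG, cfg$n_cnes)),
    start = c(gene_start, cne_start),
    end = c(gene_end, cne_end), stringsAsFactors = FALSE)
  loci <- loci[order(loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci$len <- loci$end - loci$start
  loci$gap_before <- c(loci$start[1], loci$start[-1] - loci$end[-nrow(loci)])
  nL <- nrow(loci)
  locus_of <- stats::setNames(seq_len(nL), loci$id)

  # protected reference adjacencies: the chain between an enhancer CNE
  # and its true target gene
  protected_of_enh <- list()
  for (i in which(enhancer)) {
    a <- locus_of[[cne_ids[i]]]
    b <- locus_of[[true_target[i]]]
    lohi <- sort(c(a, b))
    protected_of_enh[[cne_ids[i]]] <-
      paste(lohi[1]:(lohi[2] - 1L), (lohi[1] + 1L):lohi[2], sep = "-")
  }

  # --- species table
  sp_ids <- character(0)
  sp_grp <- character(0)
  for (g in names(cfg$n_species)) {
    k <- cfg$n_species[[g]]
    if (k > 0)
      sp_ids <- c(sp_ids, sprintf("%s%d", .GROUP_ABBREV[[g]], seq_len(k)))
    sp_grp <- c(sp_grp, rep(g, k))
  }
  nS <- length(sp_ids)
  size_factor <- stats::runif(nS, cfg$size_factor_range[1],
                              cfg$size_factor_range[2])
  low_cov <- stats::runif(nS) < cfg$fraction_low_coverage
  C_e <- ifelse(low_cov, cfg$coverage_factors[["low"]],
                cfg$coverage_factors[["high"]])
  species_meta <- data.frame(
    species_id = c("hsap", sp_ids),
    phylo_group = c("Reference", sp_grp),
    genome_size = c(L, round(size_factor * L)),
    C_e = c(1, C_e), excluded = FALSE, stringsAsFactors = FALSE)

  violator <- matrix(stats::runif(nS * n_enh) < cfg$violation_fraction,
                     nrow = nS, dimnames = list(sp_ids,
                                                cne_ids[enhancer]))

  # --- per-species rearranged layouts
  layouts <- list()   # species -> data.frame(id, chrom, start, end, strand)
  n_ops_applied <- stats::setNames(integer(nS), sp_ids)
  for (s in seq_len(nS)) {
    sp <- sp_ids[s]
    protected <- unique(unlist(lapply(names(protected_of_enh), function(e) {
      if (violator[s, e]) character(0) else protected_of_enh[[e]]
    })))
    st <- .rearrange(nL, protected, cfg)
    n_ops_applied[sp] <- st$n_ops
    layouts[[sp]] <- .layout_positions(st, loci, size_factor[s])
  }

  # --- gene presence and ortholog table
  loss_p <- cfg$gene_loss_base + cfg$gene_loss_coverage * (1 - C_e)
  present <- matrix(TRUE, nrow = nS, ncol = nG,
                    dimnames = list(sp_ids, gene_ids))
  for (s in seq_len(nS))
    present[s, ] <- stats::runif(nG) >= loss_p[s]
  orow <- list()
  for (g in seq_len(nG)) {
    orow[[length(orow) + 1L]] <- data.frame(
      family_id = gene_ids[g], species_id = "hsap",
      gene_id = paste0(gene_ids[g], "_hsap"), chrom = "chrX",
      start = gene_start[g], end = gene_end[g], strand = "+",
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(nS)) {
    sp <- sp_ids[s]
    lay <- layouts[[sp]]
    for (g in seq_len(nG)) {
      if (!present[s, g]) next
      li <- lay[lay$id == gene_ids[g], ]
      orow[[length(orow) + 1L]] <- data.frame(
        family_id = gene_ids[g], species_id = sp,
        gene_id = paste0(gene_ids[g], "_", sp), chrom = li$chrom,
        start = li$start, end = li$end, strand = li$strand,
        stringsAsFactors = FALSE)
    }
  }
  orthologs <- do.call(rbind, orow)

  # --- alignment presence
  aligned <- matrix(stats::runif(nS * cfg$n_cnes) < cfg$presence_prob,
                    nrow = nS, dimnames = list(sp_ids, cne_ids))
  for (i in seq_len(cfg$n_cnes)) {
    while (sum(aligned[, i]) < cfg$min_aligned) {
      off <- which(!aligned[, i])
      aligned[off[sample.int(length(off), 1L)], i] <- TRUE
    }
  }

  # --- MAF blocks
  bases <- c("A", "C", "G", "T")
  fw <- cfg$flank_width
  blocks <- vector("list", cfg$n_cnes)
  cne_locs <- list()  # species -> data.frame per cne
  for (i in seq_len(cfg$n_cnes)) {
    len <- lens[i]
    ncol <- len + 2L * fw
    refseq <- sample(bases, ncol, replace = TRUE)
    in_cne <- seq_len(ncol) > fw & seq_len(ncol) <= fw + len
    rows <- data.frame(
      species = "hsap", chrom = "chrX",
      start = cne_start[i] - fw, length = ncol, strand = "+",
      src_size = L, seq = paste(refseq, collapse = ""),
      stringsAsFactors = FALSE)
    for (s in seq_len(nS)) {
      sp <- sp_ids[s]
      if (!aligned[s, i]) next
      pid <- cfg$group_identity[[sp_grp[s]]] / 100
      sub_p <- ifelse(in_cne, 1 - pid, 1 - cfg$flank_identity / 100)
      gap_p <- ifelse(in_cne, cfg$gap_rate, cfg$flank_gap_rate)
      sq <- refseq
      mut <- stats::runif(ncol) < sub_p
      if (any(mut)) {
        sq[mut] <- vapply(sq[mut], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      gp <- stats::runif(ncol) < gap_p
      sq[gp] <- "-"
      nongap <- sq != "-"
      lc <- sum(nongap & seq_len(ncol) <= fw)
      ccov <- sum(nongap & in_cne)
      rc <- sum(nongap & seq_len(ncol) > fw + len)
      li <- layouts[[sp]]
      lrow <- li[li$id == cne_ids[i], ]
      fwd_start <- lrow$start - lc
      fwd_end <- lrow$start + ccov + rc
      src <- species_meta$genome_size[species_meta$species_id == sp]
      maf_start <- if (lrow$strand == "-") src - fwd_end else fwd_start
      rows <- rbind(rows, data.frame(
        species = sp, chrom = lrow$chrom, start = maf_start,
        length = lc + ccov + rc, strand = lrow$strand, src_size = src,
        seq = paste(sq, collapse = ""), stringsAsFactors = FALSE))
      cne_locs[[sp]] <- rbind(cne_locs[[sp]], data.frame(
        cne_id = cne_ids[i], chrom = lrow$chrom, start = lrow$start,
        end = lrow$end, strand = lrow$strand, stringsAsFactors = FALSE))
    }
    blocks[[i]] <- structure(list(ref = "hsap", rows = rows),
                             class = "maf_block")
  }

  # --- masks, peaks, interactions
  exons <- data.frame(chrom = "chrX", start = gene_start, end = gene_end,
                      name = gene_ids, stringsAsFactors = FALSE)
  rep_pos <- gene_start[seq(2, nG, by = max(1L, floor(nG / 5)))] - 1200L
  repeats <- data.frame(chrom = "chrX", start = rep_pos,
                        end = rep_pos + 400L,
                        name = sprintf("rep%02d", seq_along(rep_pos)),
                        stringsAsFactors = FALSE)

  peak_p <- ifelse(enhancer, cfg$peak_prob_enhancer,
                   cfg$peak_prob_background)
  has_peak <- stats::runif(cfg$n_cnes) < peak_p
  prow <- list()
  for (i in which(has_peak)) {
    off <- sample.int(max(1L, floor(lens[i] / 4)), 1L) - 1L
    wid <- max(10L, floor(lens[i] * stats::runif(1, 0.4, 1)))
    prow[[length(prow) + 1L]] <- data.frame(
      chrom = "chrX", start = cne_start[i] + off,
      end = min(cne_start[i] + off + wid, cne_end[i] + 30L),
      name = sprintf("peak_%s", cne_ids[i]),
      value = round(stats::rlnorm(1, meanlog = 2, sdlog = 0.5), 2),
      stringsAsFactors = FALSE)
  }
  for (j in 1:5) {  # background peaks away from any CNE (inside genes)
    g <- sample.int(nG, 1L)
    prow[[length(prow) + 1L]] <- data.frame(
      chrom = "chrX", start = gene_start[g] + 500L,
      end = gene_start[g] + 900L, name = sprintf("peak_bg%02d", j),
      value = round(stats::rlnorm(1, meanlog = 2, sdlog = 0.5), 2),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, prow)

  irow <- list()
  for (i in which(enhancer)) {
    if (stats::runif(1) >= cfg$interaction_fraction) next
    gene <- true_target[i]
    if (stats::runif(1) >= cfg$interaction_consistent) {
      gi <- which(gene_ids != gene &
                    .edge_gap(cne_start[i], cne_end[i], gene_start,
                              gene_end) < 1e6)
      if (length(gi)) gene <- gene_ids[gi[sample.int(length(gi), 1L)]]
    }
    g <- match(gene, gene_ids)
    irow[[length(irow) + 1L]] <- data.frame(
      chrom1 = "chrX", start1 = cne_start[i] - 50L,
      end1 = cne_end[i] + 50L, chrom2 = "chrX",
      start2 = gene_start[g] - 500L, end2 = gene_start[g] + 500L,
      gene_id = gene, stringsAsFactors = FALSE)
  }
  interactions <- if (length(irow)) do.call(rbind, irow) else
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer(),
               gene_id = character(), stringsAsFactors = FALSE)

  # --- ground-truth bookkeeping
  H <- nG - 1L
  P_e <- stats::setNames(integer(nS), sp_ids)
  for (s in seq_len(nS)) {
    lay <- layouts[[sp_ids[s]]]
    lay <- lay[lay$id %in% gene_ids[present[s, ]], , drop = FALSE]
    lay <- lay[order(lay$chrom, lay$start), , drop = FALSE]
    adj <- character(0)
    if (nrow(lay) >= 2L) {
      same <- lay$chrom[-nrow(lay)] == lay$chrom[-1]
      a <- lay$id[-nrow(lay)][same]
      b <- lay$id[-1][same]
      adj <- paste(pmin(a, b), pmax(a, b), sep = "-")
    }
    ref_pairs <- paste(gene_ids[-nG], gene_ids[-1], sep = "-")
    P_e[s] <- sum(ref_pairs %in% adj)
  }

  truth <- list(
    cnes = data.frame(cne_id = cne_ids, chrom = "chrX",
                      start = cne_start, end = cne_end, length = lens,
                      enhancer = enhancer, true_target = true_target,
                      peak = has_peak, stringsAsFactors = FALSE),
    species = data.frame(species_id = sp_ids, n_ops = unname(n_ops_applied),
                         P_e = unname(P_e), H = H,
                         size_factor = size_factor,
                         stringsAsFactors = FALSE),
    cne_locations = cne_locs,
    violator = violator,
    aligned = aligned,
    present = present)

  structure(list(config = cfg, blocks = blocks, orthologs = orthologs,
                 species_meta = species_meta,
                 ref_genes = data.frame(family_id = gene_ids,
                                        chrom = "chrX",
                                        start = gene_start,
                                        end = gene_end,
                                        stringsAsFactors = FALSE),
                 exons = exons, repeats = repeats, peaks = peaks,
                 interactions = interactions, truth = truth),
            class = "sim_bundle")
}

# apply random rearrangement operations to the locus order; `protected`
# holds "i-j" keys of reference adjacencies that must never be cut.
# Operations pick either chromosome (weighted by locus count) so
# translocated regions stay breakable; translocations insert the segment
# at a random allowed position of the other chromosome.
.rearrange <- function(nL, protected, cfg) {
  chrs <- list(seq_len(nL), integer(0))
  strand <- rep("+", nL)
  n_ops <- stats::rpois(1, cfg$rearrangement_rate *
                          cfg$genome_length / 1e6)
  applied <- 0L
  allowed_gaps <- function(ord) {
    n <- length(ord)
    if (n < 2L) return(c(0L, n))
    inner <- seq_len(n - 1L)
    keys <- paste(pmin(ord[inner], ord[inner + 1L]),
                  pmax(ord[inner], ord[inner + 1L]), sep = "-")
    c(0L, inner[!keys %in% protected], n)
  }
  for (op in seq_len(n_ops)) {
    sizes <- lengths(chrs)
    eligible <- which(sizes >= 4L)
    if (length(eligible) == 0L) break
    ci <- if (length(eligible) == 1L) eligible else
      sample(eligible, 1L, prob = sizes[eligible])
    ord <- chrs[[ci]]
    n1 <- length(ord)
    allowed <- allowed_gaps(ord)
    if (length(allowed) < 3L) next
    b <- sort(sample(allowed, 2L))
    if (b[1] == b[2]) next
    seg <- (b[1] + 1L):b[2]
    if (length(seg) >= n1) next
    type <- sample(names(cfg$op_weights), 1L, prob = cfg$op_weights)
    if (type == "inversion") {
      segl <- ord[seg]
      ord[seg] <- rev(segl)
      strand[segl] <- ifelse(strand[segl] == "+", "-", "+")
      chrs[[ci]] <- ord
    } else if (type == "transposition") {
      segl <- ord[seg]
      rest <- ord[-seg]
      allowed_r <- allowed_gaps(rest)
      ins <- allowed_r[sample.int(length(allowed_r), 1L)]
      chrs[[ci]] <- append(rest, segl, after = ins)
    } else {  # translocation to the other chromosome
      oi <- if (ci == 1L) 2L else 1L
      segl <- ord[seg]
      chrs[[ci]] <- ord[-seg]
      other <- chrs[[oi]]
      allowed_o <- allowed_gaps(other)
      ins <- allowed_o[sample.int(length(allowed_o), 1L)]
      chrs[[oi]] <- append(other, segl, after = ins)
    }
    applied <- applied + 1L
  }
  list(chr1 = chrs[[1]], chr2 = chrs[[2]], strand = strand, n_ops = applied)
}

# lay the rearranged locus order back onto coordinates; gaps and locus
# lengths both carry the genome-size factor, so distances scale exactly
# the way the linkage radius does
.layout_positions <- function(st, loci, f) {
  place <- function(order_idx, chrom, offset) {
    if (length(order_idx) == 0L)
      return(NULL)
    gaps <- pmax(50L, round(loci$gap_before[order_idx] * f))
    lens <- pmax(1L, round(loci$len[order_idx] * f))
    starts <- offset + cumsum(as.numeric(gaps)) +
      c(0, cumsum(as.numeric(lens))[-length(lens)])
    data.frame(id = loci$id[order_idx], chrom = chrom,
               start = as.integer(starts),
               end = as.integer(starts + lens),
               strand = st$strand[order_idx], stringsAsFactors = FALSE)
  }
  rbind(place(st$chr1, "chr1", 0L), place(st$chr2, "chr2", 10000L))
}

#' Write a simulated bundle to disk
#'
#' Emits `alignment.maf`, `orthologs.tsv`, `species_meta.tsv`,
#' `genes.bed`, `exons.bed`, `repeats.bed`, `peaks.bedgraph`,
#' `interactions.bedpe` and `truth.json` into `dir`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_maf(bundle$blocks, p("alignment.maf"))
  write_ortholog_table(bundle$orthologs, p("orthologs.tsv"))
  write_species_meta(bundle$species_meta, p("species_meta.tsv"))
  g <- bundle$ref_genes
  g$name <- g$family_id
  write_intervals(g, p("genes.bed"), "bed")
  write_intervals(bundle$exons, p("exons.bed"), "bed")
  write_intervals(bundle$repeats, p("repeats.bed"), "bed")
  write_intervals(bundle$peaks, p("peaks.bedgraph"), "bedgraph")
  write_intervals(bundle$interactions, p("interactions.bedpe"), "bedpe")
  truth <- bundle$truth
  truth$violator <- as.data.frame(truth$violator)
  truth$aligned <- as.data.frame(truth$aligned)
  truth$present <- as.data.frame(truth$present)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a bundle back from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return list with the same components as a `sim_bundle` (minus
#'   `config`); `truth` is re-assembled from `truth.json`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$cnes <- as.data.frame(truth$cnes, stringsAsFactors = FALSE)
  truth$species <- as.data.frame(truth$species, stringsAsFactors = FALSE)
  genes <- read_intervals(p("genes.bed"), "bed")
  list(blocks = read_maf(p("alignment.maf")),
       orthologs = read_ortholog_table(p("orthologs.tsv")),
       species_meta = read_species_meta(p("species_meta.tsv")),
       ref_genes = data.frame(family_id = genes$name, chrom = genes$chrom,
                              start = genes$start, end = genes$end,
                              stringsAsFactors = FALSE),
       exons = read_intervals(p("exons.bed"), "bed"),
       repeats = read_intervals(p("repeats.bed"), "bed"),
       peaks = read_intervals(p("peaks.bedgraph"), "bedgraph"),
       interactions = read_intervals(p("interactions.bedpe"), "bedpe"),
       truth = truth)
}

#' Audit a simulated bundle against its own ground truth
#'
#' Writes the bundle to disk (or uses `dir`), reads every file back
#' through the package readers and re-derives the ground-truth summaries:
#' block counts and round-trip identity, family counts, synteny levels
#' against the planted preserved-adjacency counts, peak labels against
#' positive coverage-weighted scores, and -- for every non-violating
#' species -- the protected enhancer-target linkage within the scaled
#' radius.
#'
#' @param bundle a `sim_bundle`.
#' @param dir optional directory to use; defaults to a temporary one.
#' @return list with `ok` (logical) and `issues` (character vector).
#' @export
audit_bundle <- function(bundle, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bundle")
    on.exit(unlink(dir, recursive = TRUE))
  }
  write_bundle(bundle, dir)
  back <- read_bundle(dir)
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)

  if (length(back$blocks) != length(bundle$blocks))
    note("MAF block count changed on round trip")
  for (i in seq_along(bundle$blocks)) {
    if (!isTRUE(all.equal(back$blocks[[i]]$rows, bundle$blocks[[i]]$rows)))
      note(sprintf("MAF block %d not identical after round trip", i))
  }
  fams <- unique(back$orthologs$family_id)
  if (length(fams) != bundle$config$n_genes)
    note("ortholog family count != planted gene count")
  ref_sp <- back$species_meta$species_id[
    back$species_meta$phylo_group == "Reference"]
  no_ref <- setdiff(fams, back$orthologs$family_id[
    back$orthologs$species_id == ref_sp])
  if (length(no_ref))
    note(paste("families without reference gene:",
               paste(no_ref, collapse = ",")))

  meta <- compute_synteny_levels(back$orthologs, back$species_meta)
  tr <- bundle$truth
  for (i in seq_len(nrow(tr$species))) {
    sp <- tr$species$species_id[i]
    want <- tr$species$P_e[i] / tr$species$H[i]
    got <- meta$R_e[meta$species_id == sp]
    if (abs(got - want) > 1e-12)
      note(sprintf("synteny level mismatch for %s: %.4f vs %.4f", sp,
                   got, want))
  }

  for (i in seq_len(nrow(tr$cnes))) {
    w <- weighted_overlap(list(chrom = tr$cnes$chrom[i],
                               start = tr$cnes$start[i],
                               end = tr$cnes$end[i]), back$peaks)
    if ((w$score > 0) != tr$cnes$peak[i])
      note(sprintf("peak label mismatch for %s", tr$cnes$cne_id[i]))
  }

  L <- bundle$species_meta$genome_size[
    bundle$species_meta$phylo_group == "Reference"]
  enh <- which(tr$cnes$enhancer)
  for (i in enh) {
    cid <- tr$cnes$cne_id[i]
    tgt <- tr$cnes$true_target[i]
    for (sp in tr$species$species_id) {
      if (isTRUE(tr$violator[sp, cid])) next
      if (!isTRUE(tr$aligned[sp, cid])) next
      if (!isTRUE(tr$present[sp, tgt])) next
      locs <- tr$cne_locations[[sp]]
      cl <- locs[locs$cne_id == cid, ]
      gr <- back$orthologs[back$orthologs$species_id == sp &
                             back$orthologs$family_id == tgt, ]
      d_e <- scaled_radius(1e6, bundle$species_meta$genome_size[
        bundle$species_meta$species_id == sp], L)
      if (nrow(gr) == 0L || gr$chrom[1] != cl$chrom ||
          .edge_gap(cl$start, cl$end, gr$start[1], gr$end[1]) >= d_e)
        note(sprintf("protected linkage broken: %s / %s in %s", cid,
                     tgt, sp))
    }
  }
  list(ok = length(issues) == 0L, issues = issues)
}

#' Run the full pipeline on a bundle
#'
#' Scan, fuse and score the CNEs, compute linkage assignments and target
#' selections, and fuse co-targeting CNEs into regulatory elements.
#'
#' @param bundle a `sim_bundle` (or the list from [read_bundle()]).
#' @param params a [scan_params()] list.
#' @param d_ref linkage radius in bp.
#' @return list with `cnes`, `link` (see [score_linkage()]) and
#'   `reg_elements`.
#' @export
run_pipeline <- function(bundle, params = scan_params(), d_ref = 1e6) {
  cnes <- scan_cnes(bundle$blocks, bundle$exons, bundle$repeats, params,
                    bundle$species_meta)
  link <- score_linkage(cnes, bundle$orthologs, bundle$species_meta,
                        d_ref = d_ref)
  reg <- fuse_reg_elements(link$selections)
  list(cnes = cnes, link = link, reg_elements = reg)
}

#' Match called CNEs to planted elements
#'
#' Assigns every called element to the planted CNE its reference
#' interval overlaps (planted elements are spaced far enough apart that
#' the assignment is unique).
#'
#' @param cnes called element table (with `chrom`, `start`, `end`).
#' @param truth_cnes the `truth$cnes` table of a bundle.
#' @return `cnes` with `planted_id`, `enhancer` and `true_target`
#'   columns added (NA when a called element overlaps nothing planted).
#' @export
match_planted <- function(cnes, truth_cnes) {
  planted_id <- rep(NA_character_, nrow(cnes))
  for (i in seq_len(nrow(cnes))) {
    hit <- which(truth_cnes$chrom == cnes$chrom[i] &
                   truth_cnes$start < cnes$end[i] &
                   truth_cnes$end > cnes$start[i])
    if (length(hit)) planted_id[i] <- truth_cnes$cne_id[hit[1]]
  }
  m <- match(planted_id, truth_cnes$cne_id)
  cnes$planted_id <- planted_id
  cnes$enhancer <- truth_cnes$enhancer[m]
  cnes$true_target <- truth_cnes$true_target[m]
  cnes
}
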