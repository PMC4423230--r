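# Independent reference implementations (oracles) and small fixture
# builders used across the suite. The oracles deliberately use naive
# scalar loops so they share no code path with the package.

# --- fixture builders ------------------------------------------------------

toy_meta <- function(species, groups, genome_size = 1e9, C_e = 1,
                     excluded = FALSE, ref = "hsap") {
  rbind(
    data.frame(species_id = ref, phylo_group = "Reference",
               genome_size = genome_size[1], C_e = 1, excluded = FALSE,
               stringsAsFactors = FALSE),
    data.frame(species_id = species, phylo_group = groups,
               genome_size = genome_size, C_e = C_e, excluded = excluded,
               stringsAsFactors = FALSE))
}

# build a maf_block from named gapped sequences (reference first)
toy_block <- function(seqs, start = 1000L, chrom = "chrX",
                      src_size = 1e6, ref = names(seqs)[1]) {
  rows <- data.frame(
    species = names(seqs), chrom = chrom,
    start = as.integer(start),
    length = nchar(gsub("-", "", seqs, fixed = TRUE)),
    strand = "+", src_size = as.integer(src_size),
    seq = unname(seqs), stringsAsFactors = FALSE)
  structure(list(ref = ref, rows = rows), class = "maf_block")
}

# random alignment block: a reference row plus `nsp` species rows whose
# per-column substitution and gap probabilities vary along the block
random_block <- function(ncols, nsp = 9, seed = NULL, chrom = "chrX",
                         start = 0L) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  refseq <- sample(bases, ncols, replace = TRUE)
  # alternating easy/hard stretches to create core + extension structure
  sub_p <- rep(runif(max(1, ncols %/% 25), 0.02, 0.6),
               each = 25, length.out = ncols)
  rows <- character(nsp)
  for (s in seq_len(nsp)) {
    sq <- refseq
    mut <- runif(ncols) < sub_p
    sq[mut] <- vapply(sq[mut], function(b) sample(setdiff(bases, b), 1),
                      character(1))
    gp <- runif(ncols) < 0.05
    sq[gp] <- "-"
    rows[s] <- paste(sq, collapse = "")
  }
  seqs <- c(hsap = paste(refseq, collapse = ""),
            stats::setNames(rows, sprintf("sp%02d", seq_len(nsp))))
  toy_block(seqs, start = start, chrom = chrom)
}

# --- oracles ---------------------------------------------------------------

# scalar per-column conservation, independent of the package's
# vectorised implementation
oracle_conserved <- function(block, min_sp = 7, frac = 0.12) {
  chars <- strsplit(toupper(block$rows$seq), "")
  ri <- match(block$ref, block$rows$species)
  n <- nchar(block$rows$seq[1])
  out <- logical(n)
  for (j in seq_len(n)) {
    ref <- chars[[ri]][j]
    if (ref == "-") next
    others <- vapply(chars[-ri], `[`, character(1), j)
    aligned <- others[others != "-"]
    if (length(aligned) < min_sp) next
    out[j] <- sum(aligned != ref) <=
      ceiling(frac * (length(aligned) + 1))
  }
  out
}

# scalar scan for barrier columns: non-conserved runs that extension
# can never cross (longer than maxrun, or holding a masked column)
oracle_barriers <- function(cons, masked, maxrun = 3) {
  n <- length(cons)
  bar <- logical(n)
  j <- 1
  while (j <= n) {
    if (cons[j] && !masked[j]) { j <- j + 1; next }
    k <- j
    while (k < n && (!cons[k + 1] || masked[k + 1])) k <- k + 1
    if ((k - j + 1) > maxrun || any(masked[j:k])) bar[j:k] <- TRUE
    j <- k + 1
  }
  bar
}

# exhaustive core-window enumeration; windows may not touch a barrier
oracle_cores <- function(cons, masked = rep(FALSE, length(cons)),
                         w = 10, min_frac = 0.9, maxrun = 3) {
  need <- ceiling(min_frac * w)
  bar <- oracle_barriers(cons, masked, maxrun)
  hits <- integer(0)
  n <- length(cons)
  if (n >= w) for (i in 1:(n - w + 1)) {
    win <- i:(i + w - 1)
    if (sum(cons[win]) >= need && !any(bar[win])) hits <- c(hits, i)
  }
  hits  # window start positions
}

# independent scalar walk extension of one core window
oracle_extend <- function(from, to, cons, masked, maxrun = 3) {
  n <- length(cons)
  j <- to + 1; run <- 0; right <- to
  while (j <= n && !masked[j]) {
    if (cons[j]) { right <- j; run <- 0 } else {
      run <- run + 1
      if (run > maxrun) break
    }
    j <- j + 1
  }
  j <- from - 1; run <- 0; left <- from
  while (j >= 1 && !masked[j]) {
    if (cons[j]) { left <- j; run <- 0 } else {
      run <- run + 1
      if (run > maxrun) break
    }
    j <- j - 1
  }
  while (left <= right && !cons[left]) left <- left + 1
  while (right >= left && !cons[right]) right <- right - 1
  c(left, right)
}

# brute-force segment enumerator: every qualifying core, extended, then
# de-duplicated -- the maximal valid segments of the mask pair
oracle_segments <- function(cons, masked = rep(FALSE, length(cons)),
                            w = 10, min_frac = 0.9, maxrun = 3) {
  cores <- oracle_cores(cons, masked, w, min_frac, maxrun)
  if (length(cores) == 0)
    return(data.frame(start = integer(), end = integer()))
  segs <- list()
  last <- c(-1, -1)
  for (i in cores) {
    # a core starting inside the previous extended segment extends to the
    # same barriers, so the walk can be skipped
    if (i >= last[1] && i <= last[2]) next
    last <- oracle_extend(i, i + w - 1, cons, masked, maxrun)
    segs[[length(segs) + 1]] <- last
  }
  segs <- unique(do.call(rbind, segs))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  data.frame(start = as.integer(segs[, 1]), end = as.integer(segs[, 2]))
}

# sweep-line interval union count (per chromosome)
oracle_union <- function(df) {
  total <- 0L
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur_end <- -Inf
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] > cur_end) total <- total + 1L
      cur_end <- max(cur_end, sub$end[i])
    }
  }
  total
}

# analytic per-element null match probability for the permutation test:
# drawing k of g window genes, m of which match
oracle_match_prob <- function(g, m, k) {
  if (k >= g) return(as.numeric(m > 0))
  1 - choose(g - m, k) / choose(g, k)
}

# minimal element table wrapper for interval-level tests
.fake_cnes <- function(iv) {
  df <- data.frame(cne_id = sprintf("X%03d", seq_len(nrow(iv))),
                   chrom = iv$chrom, start = iv$start, end = iv$end,
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$n_species <- 0L
  df$species_set <- I(rep(list(character(0)), nrow(df)))
  df$locations <- I(rep(list(data.frame(species = character(),
                                        chrom = character(),
                                        start = numeric(),
                                        end = numeric())), nrow(df)))
  df$n_match <- I(rep(list(numeric(0)), nrow(df)))
  df$n_comp <- I(rep(list(numeric(0)), nrow(df)))
  df
}

# a small, fast simulation configuration shared by several tests
small_config <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 20L, genome_length = 2e6,
             n_cnes = 24L, ...)
}
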