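# Linkage scoring: scaled radius, candidate search, per-species status,
# synteny level, weighted evidence, sigmoid normalisation, target
# selection and regulatory-element fusion.

test_that("the radius scales linearly with genome size", {
  expect_equal(scaled_radius(1e6, 0.8e9, 1e9), 0.8e6)
  expect_equal(scaled_radius(1e6, 3.2e9, 3.2e9), 1e6)
  expect_equal(scaled_radius(1e6, 1.37e9, 1e9), 1.37e6)
  expect_error(scaled_radius(1e6, 0, 1e9), "> 0")
})

test_that("candidate families are the genes within the edge-gap radius", {
  cne <- list(chrom = "chrX", start = 5e6, end = 5.0001e6)
  genes <- data.frame(
    family_id = c("near", "far", "otherchrom", "overlap"),
    chrom = c("chrX", "chrX", "chr2", "chrX"),
    start = c(5.5e6, 6.2e6, 5.1e6, 4.9999e6),
    end = c(5.51e6, 6.21e6, 5.11e6, 5.00005e6))
  expect_setequal(candidate_families(cne, genes), c("near", "overlap"))
  # a gene 1.2 Mb away with nothing closer: unassociated element
  lonely <- genes[genes$family_id == "far", ]
  expect_length(candidate_families(cne, lonely), 0)
  # random layouts against the brute-force distance oracle
  set.seed(31)
  for (rep in 1:30) {
    g <- data.frame(family_id = sprintf("f%02d", 1:40),
                    chrom = sample(c("chrX", "chr7"), 40, replace = TRUE),
                    start = sample.int(1e7, 40))
    g$end <- g$start + sample.int(5e4, 40)
    el <- list(chrom = "chrX", start = 4e6, end = 4.001e6)
    want <- character(0)
    for (i in 1:40) {
      if (g$chrom[i] != el$chrom) next
      gap <- max(0, max(el$start, g$start[i]) - min(el$end, g$end[i]))
      if (gap < 1e6) want <- c(want, g$family_id[i])
    }
    expect_setequal(candidate_families(el, g), want)
  }
})

test_that("status classification follows the four-state rule with paralog favour", {
  loc <- list(chrom = "chr5", start = 2e6, end = 2.0001e6)
  near <- data.frame(chrom = "chr5", start = 2.1e6, end = 2.11e6)
  far <- data.frame(chrom = "chr5", start = 3.5e6, end = 3.51e6)
  other <- data.frame(chrom = "scaffold_12", start = 100, end = 200)
  expect_equal(classify_status(loc, near, 0.8e6), "S1")
  expect_equal(classify_status(loc, far, 0.8e6), "S2")
  expect_equal(classify_status(loc, other, 0.8e6), "S3")
  expect_equal(classify_status(loc, near[0, ], 0.8e6), "S0")
  # paralogs: one S3 and one S1 -> S1 (checked against enumeration)
  expect_equal(classify_status(loc, rbind(other, near), 0.8e6), "S1")
  expect_equal(classify_status(loc, rbind(other, far), 0.8e6), "S2")
  both <- rbind(near, far)
  states <- vapply(seq_len(nrow(both)), function(i)
    classify_status(loc, both[i, ], 0.8e6), character(1))
  expect_equal(classify_status(loc, both, 0.8e6),
               c("S1", "S2", "S3")[min(match(states, c("S1", "S2", "S3")))])
})

test_that("synteny level is 1 against self and 0 for isolated orthologs", {
  ref <- data.frame(family_id = sprintf("f%02d", 1:12), chrom = "chrX",
                    start = (1:12) * 1e5)
  ref$end <- ref$start + 5e4
  expect_equal(synteny_level(ref, ref), 1)
  shattered <- ref
  shattered$chrom <- sprintf("scaf%02d", 1:12)
  expect_equal(synteny_level(ref, shattered), 0)
  # a simple half-preserved case: break the order in the middle
  sp <- ref
  sp$start[7:12] <- sp$start[12:7]   # reverse a tail block
  expect_lt(synteny_level(ref, sp), 1)
  expect_error(synteny_level(ref[1, ], ref), "adjacent gene pairs")
})

test_that("synteny recovered from the generator equals planted adjacency counts", {
  b <- simulate_bundle(small_config(seed = 13))
  meta <- compute_synteny_levels(b$orthologs, b$species_meta)
  tr <- b$truth$species
  for (i in seq_len(nrow(tr))) {
    got <- meta$R_e[meta$species_id == tr$species_id[i]]
    expect_equal(got, tr$P_e[i] / tr$H[i])
  }
  expect_equal(meta$R_e[meta$phylo_group == "Reference"], 1)
})

test_that("default weights give the documented per-status contributions", {
  meta <- toy_meta("mmus", "Boreoeutheria")
  meta$R_e <- c(1, 0.4)
  # one species, R_e = 0.4, S1 -> +0.6
  expect_equal(raw_linkage(c(mmus = "S1"), meta), 0.6)
  # same species S3 with C_e = 1 -> -1
  expect_equal(raw_linkage(c(mmus = "S3"), meta), -1)
  expect_equal(raw_linkage(c(mmus = "S2"), meta), -0.5)
  expect_equal(raw_linkage(c(mmus = "S0"), meta), -0.25)
  # reference-like genomes (all S1 at R_e = 1) carry no evidence
  meta3 <- toy_meta(c("a", "b"), rep("Boreoeutheria", 2))
  meta3$R_e <- 1
  expect_equal(raw_linkage(c(a = "S1", b = "S1"), meta3), 0)
  expect_error(raw_linkage(c(zz = "S1"), meta), "missing from metadata")
})

test_that("improving any species' status never decreases the raw score", {
  set.seed(17)
  for (rep in 1:1000) {
    nsp <- sample(3:12, 1)
    ids <- sprintf("s%02d", seq_len(nsp))
    meta <- toy_meta(ids, rep("Boreoeutheria", nsp),
                     C_e = runif(nsp, 0.3, 1))
    meta$R_e <- c(1, runif(nsp, 0, 0.99))
    st <- sample(c("S1", "S2", "S3"), nsp, replace = TRUE)
    names(st) <- ids
    worse <- which(st != "S1")
    if (length(worse) == 0) next
    i <- worse[sample.int(length(worse), 1)]
    st2 <- st
    st2[i] <- c(S2 = "S1", S3 = "S2")[st[i]]
    expect_gt(raw_linkage(st2, meta), raw_linkage(st, meta))
  }
})

test_that("sigmoid normalisation is monotone, bounded and centred", {
  expect_equal(normalize_scores(3, midpoint = 3), 0.5)
  expect_equal(normalize_scores(1e4, midpoint = 0), 1)
  set.seed(5)
  raw <- rnorm(200, sd = 4)
  sa <- normalize_scores(raw)
  expect_true(all(sa > 0 & sa < 1))
  expect_equal(order(sa), order(raw))
  # default midpoint is the run median
  expect_equal(sa[which.min(abs(raw - median(raw)))],
               normalize_scores(raw)[which.min(abs(raw - median(raw)))])
})

test_that("target selection keeps ties and defines the relative score by distinct values", {
  a <- data.frame(family_id = c("A", "B", "C"), S_A = c(0.9, 0.9, 0.4))
  r <- rank_and_select(a)
  expect_setequal(r$targets, c("A", "B"))
  expect_equal(r$relative, 0.5)
  single <- data.frame(family_id = "A", S_A = 0.7)
  r2 <- rank_and_select(single)
  expect_equal(r2$targets, "A")
  expect_true(is.na(r2$relative))
  r3 <- rank_and_select(a[0, ])
  expect_length(r3$targets, 0)
})

test_that("co-targeting elements fuse into regulatory elements like a union-find oracle", {
  mk_sel <- function(starts, ends, targets) {
    df <- data.frame(cne_id = sprintf("c%03d", seq_along(starts)),
                     chrom = "chrX", start = starts, end = ends,
                     n_candidates = 1L, max_SA = 0.9, relative = NA_real_,
                     stringsAsFactors = FALSE)
    df$targets <- I(targets)
    df
  }
  # 3 CNEs, same target, gaps 40 and 60 -> one element
  s <- mk_sel(c(0, 140, 300), c(100, 240, 380),
              list("g1", "g1", "g1"))
  r <- fuse_reg_elements(s)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_cnes, 3L)
  expect_equal(r$start, 0)
  expect_equal(r$end, 380)
  # middle element with a different target splits the chain
  s2 <- mk_sel(c(0, 140, 300), c(100, 240, 380),
               list("g1", "g2", "g1"))
  expect_equal(nrow(fuse_reg_elements(s2)), 3)
  # random layouts vs an independent union-find over the adjacency relation
  set.seed(23)
  for (rep in 1:30) {
    n <- 30
    starts <- cumsum(sample(c(20, 80, 150), n, replace = TRUE,
                            prob = c(0.5, 0.3, 0.2)))
    ends <- starts + 15
    tg <- lapply(sample(1:4, n, replace = TRUE), function(k)
      sprintf("g%d", k))
    s3 <- mk_sel(starts, ends, tg)
    got <- fuse_reg_elements(s3)
    # oracle: union-find over consecutive pairs
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; as.integer(x) }
    for (i in 2:n) {
      if (starts[i] - ends[i - 1] < 100 &&
          setequal(tg[[i]], tg[[i - 1]]))
        parent[find(i)] <- find(i - 1)
    }
    expect_equal(nrow(got), length(unique(vapply(1:n, find, integer(1)))))
    expect_equal(fuse_reg_elements(s3)$n_cnes, got$n_cnes)  # idempotent input
  }
})

test_that("fusion and selection commute with gene id relabeling", {
  b <- simulate_bundle(small_config(seed = 19))
  res <- run_pipeline(b)
  relabel <- function(x) paste0("Z_", x)
  ortho2 <- b$orthologs
  ortho2$family_id <- relabel(ortho2$family_id)
  cnes <- res$cnes
  link2 <- score_linkage(cnes, ortho2, b$species_meta)
  reg2 <- fuse_reg_elements(link2$selections)
  reg1 <- res$reg_elements
  expect_equal(nrow(reg1), nrow(reg2))
  expect_equal(reg1$start, reg2$start)
  for (i in seq_len(nrow(reg1)))
    expect_setequal(relabel(reg1$targets[[i]]), reg2$targets[[i]])
})

test_that("removing a species never changes the status of other species", {
  b <- simulate_bundle(small_config(seed = 21))
  res <- run_pipeline(b)
  A1 <- res$link$assignments
  # drop one species from every element's species set and rescore
  drop_sp <- "bor1"
  cnes2 <- res$cnes
  for (i in seq_len(nrow(cnes2))) {
    cnes2$species_set[[i]] <- setdiff(cnes2$species_set[[i]], drop_sp)
  }
  A2 <- score_linkage(cnes2, b$orthologs, b$species_meta)$assignments
  parse_trail <- function(s) {
    kv <- strsplit(strsplit(s, ";")[[1]], ":")
    stats::setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
  }
  key1 <- paste(A1$cne_id, A1$family_id)
  key2 <- paste(A2$cne_id, A2$family_id)
  common <- intersect(key1, key2)
  for (k in sample(common, 40)) {
    t1 <- parse_trail(A1$status[match(k, key1)])
    t2 <- parse_trail(A2$status[match(k, key2)])
    t1 <- t1[names(t1) != drop_sp]
    expect_equal(t2[names(t1)], t1)
  }
})

test_that("excluded species are skipped entirely", {
  b <- simulate_bundle(small_config(seed = 25))
  meta <- b$species_meta
  meta$excluded[meta$species_id == "bor1"] <- TRUE
  cnes <- scan_cnes(b$blocks, b$exons, b$repeats)
  link <- score_linkage(cnes, b$orthologs, meta)
  expect_false(any(grepl("bor1:", link$assignments$status)))
})
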