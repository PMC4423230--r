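# Scanner: column conservation, core windows, extension, segment
# calling, fusion, conservation score, external merge.

five_group_meta <- function() {
  toy_meta(c("ptro", "mmus", "lafr", "dnov", "mdom", "ggal", "xtro",
             "drer", "olat"),
           c("Boreoeutheria", "Boreoeutheria", "Atlantogenata",
             "Atlantogenata", "MonotremesMarsupials",
             "SauropsidsAmphibians", "SauropsidsAmphibians", "Teleosts",
             "Teleosts"))
}

test_that("the minimal 8-row column tolerates exactly one substitution", {
  col8 <- c("A", rep("A", 6), "C")           # ref + 7 aligned, 1 mismatch
  expect_true(column_conserved(col8))
  col8b <- c("A", rep("A", 5), "C", "G")     # 2 mismatches
  expect_false(column_conserved(col8b))
  col7 <- c("A", rep("A", 6))                # only 6 species beyond ref
  expect_false(column_conserved(col7))
  # gapped rows are not aligned rows
  colg <- c("A", rep("A", 7), "-", "-")
  expect_true(column_conserved(colg))
})

test_that("vectorised column conservation agrees with the scalar oracle", {
  for (seed in 1:10) {
    blk <- random_block(200, nsp = 9, seed = seed)
    got <- conserved_columns(blk)
    want <- oracle_conserved(blk)
    expect_equal(unname(got), want)
  }
})

test_that("core windows require 9 of 10 conserved columns", {
  p <- scan_params()
  cons <- rep(TRUE, 10)
  expect_equal(find_cores(cons, p), data.frame(start = 1L, end = 10L))
  cons2 <- c(rep(TRUE, 4), FALSE, rep(TRUE, 3), FALSE, TRUE)  # 8 of 10
  expect_equal(nrow(find_cores(cons2, p)), 0)
})

test_that("core finding equals exhaustive window enumeration on random masks", {
  p <- scan_params()
  set.seed(4)
  for (rep in 1:50) {
    cons <- runif(200) < runif(1, 0.5, 0.95)
    got <- find_cores(cons, p)
    starts <- oracle_cores(cons)
    if (length(starts) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      # reduce oracle windows to unions
      r <- IRanges::reduce(IRanges::IRanges(starts, width = 10))
      expect_equal(got$start, IRanges::start(r))
      expect_equal(got$end, IRanges::end(r))
    }
  }
})

test_that("extension crosses runs of three non-conserved columns but not four", {
  p <- scan_params()
  cons <- c(TRUE, rep(FALSE, 3), rep(TRUE, 12), rep(FALSE, 4), TRUE)
  seed <- c(5, 16)  # the 12 conserved columns
  expect_equal(extend_seed(seed, cons, p), c(1L, 16L))
  # left: crosses the 3-gap to reach column 1; right: stops before the 4-run
})

test_that("extension equals the independent scalar walk on random masks", {
  p <- scan_params()
  set.seed(9)
  for (rep in 1:80) {
    n <- 500
    cons <- runif(n) < 0.7
    masked <- runif(n) < 0.03
    cons[masked] <- FALSE
    starts <- oracle_cores(cons, masked)
    if (length(starts) == 0) next
    i <- starts[sample.int(length(starts), 1)]
    got <- extend_seed(c(i, i + 9L), cons, p, masked)
    want <- oracle_extend(i, i + 9L, cons, masked)
    expect_equal(got, as.integer(want))
  }
})

test_that("mask_columns marks reference gaps and masked reference positions", {
  blk <- toy_block(c(hsap = "AC-GTACGTA", mmus = "ACCGTACGTA"),
                   start = 100L)
  m0 <- mask_columns(blk)
  expect_equal(which(m0), 3L)   # only the reference gap
  # reference spans 100..108 (one gap column); 104..109 covers 5 bases
  exon <- data.frame(chrom = "chrX", start = 104L, end = 109L)
  m1 <- mask_columns(blk, exon)
  expect_equal(sum(m1 & !m0), 5)
  # an exon covering the whole block kills every column
  all_exon <- data.frame(chrom = "chrX", start = 0L, end = 1000L)
  cons <- conserved_columns(blk, scan_params(min_species_beyond_ref = 1L),
                            mask_columns(blk, all_exon))
  expect_false(any(cons))
})

test_that("the conservation score sums the per-group maxima", {
  meta <- five_group_meta()
  pid <- c(ptro = 97, mmus = 91, lafr = 68, mdom = 62, ggal = 54,
           xtro = 40, olat = 49)
  expect_equal(conservation_score(pid, meta), 330)
  # single aligned group
  expect_equal(conservation_score(c(ptro = 97), meta), 97)
  # invariant to species order and duplicated species entries
  expect_equal(conservation_score(rev(pid), meta), 330)
  expect_equal(conservation_score(c(pid, ptro = 97), meta), 330)
})

test_that("scores recomputed from simulated alignments match hand-derived identities", {
  b <- simulate_bundle(small_config(seed = 3))
  cnes <- scan_cnes(b$blocks, b$exons, b$repeats,
                    species_meta = b$species_meta)
  expect_gt(nrow(cnes), 0)
  meta <- b$species_meta
  for (i in sample.int(nrow(cnes), 5)) {
    # hand-compute per-species identity over the element from raw counts
    pid <- round(100 * cnes$n_match[[i]] / cnes$n_comp[[i]])
    grp <- meta$phylo_group[match(names(pid), meta$species_id)]
    want <- sum(tapply(pid, grp, max))
    expect_equal(cnes$score[i], want)
    # bounded by 100 x number of represented groups
    expect_lte(cnes$score[i], 100 * length(unique(grp)))
  }
})

test_that("same-pattern elements under 100 bp apart fuse; distant ones do not", {
  seqs_cons <- function() paste(rep("A", 30), collapse = "")
  mk <- function(ref_start, sp_start) {
    toy_block(c(hsap = seqs_cons(), sp1 = seqs_cons(), sp2 = seqs_cons(),
                sp3 = seqs_cons(), sp4 = seqs_cons(), sp5 = seqs_cons(),
                sp6 = seqs_cons(), sp7 = seqs_cons()),
              start = ref_start)
  }
  # two blocks 50 bp apart in the reference; species locations adjacent
  b1 <- mk(1000L)
  b2 <- mk(1080L)
  cnes <- call_cnes(list(b1, b2))
  expect_equal(nrow(cnes), 2)
  fused <- fuse_cnes(cnes)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$start, 1000L)
  expect_equal(fused$end, 1110L)
  # identity counts add up exactly
  expect_equal(unname(fused$n_comp[[1]]["sp1"]), 60)
  # 150 bp apart: not fused
  b3 <- mk(1260L)
  cnes2 <- call_cnes(list(b1, b3))
  expect_equal(nrow(fuse_cnes(cnes2)), 2)
  # different species sets never fuse
  b4 <- toy_block(c(hsap = seqs_cons(), sp1 = seqs_cons(),
                    sp2 = seqs_cons(), sp3 = seqs_cons(),
                    sp4 = seqs_cons(), sp5 = seqs_cons(),
                    sp6 = seqs_cons(), sp7 = seqs_cons(),
                    sp8 = seqs_cons()), start = 1080L)
  cnes3 <- call_cnes(list(b1, b4))
  expect_equal(nrow(fuse_cnes(cnes3)), 2)
})

test_that("fusion is idempotent on simulator output", {
  b <- simulate_bundle(small_config(seed = 5))
  cnes <- call_cnes(b$blocks, b$exons, b$repeats)
  f1 <- fuse_cnes(cnes)
  f2 <- fuse_cnes(f1)
  expect_equal(f1[, c("chrom", "start", "end", "n_species")],
               f2[, c("chrom", "start", "end", "n_species")])
})

test_that("merging with an external set is an interval union", {
  b <- simulate_bundle(small_config(seed = 6))
  cnes <- call_cnes(b$blocks, b$exons, b$repeats)
  # disjoint external set -> concatenation
  ext <- data.frame(chrom = "chrX", start = c(5L, 105L),
                    end = c(30L, 140L))
  merged <- merge_external(cnes, ext)
  expect_equal(nrow(merged), nrow(cnes) + 2)
  expect_true(any(merged$external_only))
  # overlapping external element -> union semantics
  ext2 <- data.frame(chrom = cnes$chrom[1],
                     start = cnes$start[1] - 10L,
                     end = cnes$start[1] + 5L)
  merged2 <- merge_external(cnes, ext2)
  expect_equal(nrow(merged2), nrow(cnes))
  expect_equal(min(merged2$start), cnes$start[1] - 10L)
  # random sets: count equals the sweep-line union oracle
  set.seed(2)
  for (rep in 1:20) {
    a <- data.frame(chrom = "chrX",
                    start = sort(sample.int(1000, 15)) * 10L)
    a$end <- a$start + sample(5:80, 15, replace = TRUE)
    b2 <- data.frame(chrom = "chrX",
                     start = sort(sample.int(1000, 10)) * 10L)
    b2$end <- b2$start + sample(5:80, 10, replace = TRUE)
    fake <- .fake_cnes(a)
    got <- merge_external(fake, b2)
    expect_equal(nrow(got), oracle_union(rbind(a, b2)))
  }
})

test_that("every called element contains a core and avoids masked columns", {
  b <- simulate_bundle(small_config(seed = 8))
  params <- scan_params()
  for (bi in seq_along(b$blocks)[1:10]) {
    blk <- b$blocks[[bi]]
    masked <- mask_columns(blk, b$exons, b$repeats)
    cons <- conserved_columns(blk, params, masked)
    segs <- segments_from_masks(cons, masked, params)
    for (si in seq_len(nrow(segs))) {
      cols <- segs$start[si]:segs$end[si]
      expect_false(any(masked[cols]))
      # re-check the 9/10 rule post hoc
      expect_gt(length(oracle_cores(cons[cols], masked[cols])), 0)
    }
  }
})
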