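# Consistency statistic against interaction pairs and its
# window-resampling permutation null.

mk_elements <- function(n, targets, chrom = "c1", spacing = 1e4,
                        width = 500) {
  df <- data.frame(reg_id = sprintf("E%03d", seq_len(n)), chrom = chrom,
                   start = (seq_len(n) - 1) * spacing,
                   end = (seq_len(n) - 1) * spacing + width,
                   stringsAsFactors = FALSE)
  df$targets <- I(targets)
  df
}

mk_interaction <- function(el_row, gene) {
  # promoter anchor far away so only anchor1 can overlap an element
  data.frame(chrom1 = el_row$chrom, start1 = el_row$start,
             end1 = el_row$end, chrom2 = "cprom", start2 = 1,
             end2 = 2, gene_id = gene, stringsAsFactors = FALSE)
}

test_that("consistency follows the any-match rule", {
  els <- mk_elements(3, list("A", c("A", "B"), "C"))
  ints <- rbind(mk_interaction(els[1, ], "A"),
                mk_interaction(els[2, ], "B"),
                mk_interaction(els[3, ], "D"))
  r <- consistency(els, ints)
  expect_equal(r$n_overlapping, 3)
  expect_equal(r$n_consistent, 2)
  expect_equal(r$per_element$consistent, c(TRUE, TRUE, FALSE))
  # an element overlapping no anchor is not counted
  els2 <- mk_elements(1, list("A"))
  els2$start <- 9e8
  els2$end <- 9e8 + 10
  r2 <- consistency(els2, ints)
  expect_equal(r2$n_overlapping, 0)
})

test_that("consistency counts equal a brute-force set-intersection oracle", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:12)
  for (rep in 1:25) {
    n <- 15
    targets <- lapply(seq_len(n), function(i)
      sample(genes, sample(1:3, 1)))
    els <- mk_elements(n, targets)
    ints <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (runif(1) < 0.3) return(NULL)
      mk_interaction(els[i, ], sample(genes, 1))
    }))
    r <- consistency(els, ints)
    want_ov <- 0L
    want_cons <- 0L
    for (i in seq_len(n)) {
      hits <- ints$gene_id[ints$start1 == els$start[i]]
      if (length(hits)) {
        want_ov <- want_ov + 1L
        if (length(intersect(targets[[i]], hits)) > 0)
          want_cons <- want_cons + 1L
      }
    }
    expect_equal(r$n_overlapping, want_ov)
    expect_equal(r$n_consistent, want_cons)
  }
})

test_that("permutation results are bit-reproducible and order-invariant at fixed seed", {
  set.seed(11)
  genes <- data.frame(family_id = sprintf("g%02d", 1:30), chrom = "c1",
                      start = (1:30) * 2e4, end = (1:30) * 2e4 + 1000,
                      stringsAsFactors = FALSE)
  n <- 12
  targets <- lapply(seq_len(n), function(i)
    sample(genes$family_id, 2))
  els <- mk_elements(n, targets, spacing = 4e4)
  ints <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_interaction(els[i, ], sample(genes$family_id, 1))))
  r1 <- permutation_test(els, ints, genes, n_resamples = 300, seed = 5)
  r2 <- permutation_test(els, ints, genes, n_resamples = 300, seed = 5)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$p_bound, r2$p_bound)
  # shuffle element order: null distribution identical element-wise sums
  perm <- sample(n)
  r3 <- permutation_test(els[perm, ], ints, genes, n_resamples = 300,
                         seed = 5)
  expect_identical(sort(r3$null_counts), sort(r1$null_counts))
  expect_identical(r1$null_counts, r3$null_counts)
  expect_equal(r3$p_bound, r1$p_bound)
  # different seed, different draws
  r4 <- permutation_test(els, ints, genes, n_resamples = 300, seed = 6)
  expect_false(identical(r1$null_counts, r4$null_counts))
})

test_that("the null matches the analytic hypergeometric match probabilities", {
  # one element, one matching gene of g in the window, k draws:
  # P(hit) = k / g exactly
  genes <- data.frame(family_id = sprintf("g%02d", 1:10), chrom = "c1",
                      start = (0:9) * 1e5, end = (0:9) * 1e5 + 1000,
                      stringsAsFactors = FALSE)
  el <- mk_elements(1, list(c("g01", "g02", "g03")))
  el$start <- 4e5
  el$end <- 4e5 + 500   # 2-Mb window covers all 10 genes
  ints <- mk_interaction(el[1, ], "g05")
  r <- permutation_test(el, ints, genes, n_resamples = 4000, seed = 2)
  phat <- mean(r$null_counts)
  p <- oracle_match_prob(10, 1, 3)
  expect_equal(p, 3 / 10)
  expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / 4000))
  # several elements: mean of the Poisson-binomial null
  els <- mk_elements(4, list("g01", c("g02", "g03"),
                             c("g04", "g05", "g06"), "g07"),
                     spacing = 1e5)
  ints4 <- do.call(rbind, lapply(1:4, function(i)
    mk_interaction(els[i, ], c("g05", "g01", "g09", "g02")[i])))
  r4 <- permutation_test(els, ints4, genes, n_resamples = 4000, seed = 3)
  want_mean <- sum(vapply(1:4, function(i)
    oracle_match_prob(10, 1, length(els$targets[[i]])), numeric(1)))
  sd_null <- sqrt(sum(vapply(1:4, function(i) {
    p <- oracle_match_prob(10, 1, length(els$targets[[i]]))
    p * (1 - p)
  }, numeric(1))))
  expect_lt(abs(mean(r4$null_counts) - want_mean),
            4 * sd_null / sqrt(4000))
})

test_that("a fully consistent toy set drives the p-value to its floor", {
  # 20 elements, every observed target matches, window holds 10 genes of
  # which 1 matches: null count is Bin(20, 0.1)-like, so P(null >= 20)
  # is astronomically small and no resample can reach the observed count
  genes <- data.frame(family_id = sprintf("g%02d", 1:10), chrom = "c1",
                      start = (0:9) * 1e5, end = (0:9) * 1e5 + 1000,
                      stringsAsFactors = FALSE)
  n <- 20
  els <- mk_elements(n, as.list(rep("g05", n)), spacing = 0)
  els$start <- 4e5
  els$end <- 4e5 + 500
  els$reg_id <- sprintf("E%03d", 1:n)
  ints <- do.call(rbind, lapply(seq_len(n), function(i)
    mk_interaction(els[i, ], "g05")))
  r <- permutation_test(els, ints, genes, n_resamples = 1000, seed = 9)
  expect_equal(r$n_consistent, n)
  expect_true(r$at_floor)
  expect_equal(r$p_bound, 1 / 1001)
  expect_output(print(r), "p < 0.001")
})

test_that("elements with an empty gene window are skipped with a warning", {
  genes <- data.frame(family_id = "g1", chrom = "c1", start = 1e8,
                      end = 1e8 + 1000, stringsAsFactors = FALSE)
  els <- mk_elements(1, list("g1"))
  ints <- mk_interaction(els[1, ], "g1")
  expect_warning(r <- permutation_test(els, ints, genes,
                                       n_resamples = 50, seed = 1),
                 "skipped")
  expect_equal(r$n_skipped, 1L)
})
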