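# Target selection, pairing and fragment-swap decoy generation.

test_that("target selection applies S/N and relative-intensity rules", {
  f <- make_feature(sn = 20, height = 1000,
                    frag_int = c(900, 500, 12, 5))
  kept <- select_targets(list(f))
  expect_length(kept, 1)
  # 5 counts < 1% of the 1000-count precursor is dropped
  expect_equal(sort(kept[[1]]$fragments$intensity), c(12, 500, 900))

  expect_length(select_targets(list(make_feature(sn = 14.9))), 0)
  expect_length(select_targets(list(make_feature(sn = 15))), 1)

  # intensity band is inclusive at both ends (1% .. 130%)
  f2 <- make_feature(height = 1000, frag_int = c(1300, 10, 100, 1301, 9.9))
  expect_equal(sort(select_targets(list(f2))[[1]]$fragments$intensity),
               c(10, 100, 1300))

  # fewer than 3 in-band fragments -> not a target
  f3 <- make_feature(height = 1000, frag_int = c(500, 300, 5, 4))
  expect_length(select_targets(list(f3)), 0)
})

test_that("top 16 most intense fragments are kept per target", {
  f <- make_feature(height = 1000, frag_int = seq(950, 100, length.out = 20))
  kept <- select_targets(list(f))[[1]]
  expect_equal(nrow(kept$fragments), 16)
  expect_equal(min(kept$fragments$rank), 1)
  expect_equal(max(kept$fragments$rank), 16)
  expect_equal(sort(kept$fragments$intensity, decreasing = TRUE),
               sort(f$fragments$intensity, decreasing = TRUE)[1:16])
})

test_that("pairing respects m/z window, RT gap and fragment count", {
  t1 <- make_feature("T1", mz = 300, rt = 1.0,
                     frag_int = c(900, 700, 500, 300, 200))
  t2 <- make_feature("T2", mz = 320, rt = 6.0,
                     frag_int = c(800, 600, 400, 250, 150))
  t3 <- make_feature("T3", mz = 700, rt = 6.5,
                     frag_int = c(850, 650, 450, 280, 180))
  pr <- pair_targets(list(t1, t2, t3))
  expect_length(pr$pairs, 1)
  ids <- sort(c(pr$pairs[[1]]$a$feature_id, pr$pairs[[1]]$b$feature_id))
  expect_equal(ids, c("T1", "T2"))
  expect_equal(pr$unpaired, "T3")  # outside the 50 Th window

  # RT gap below 3 min -> both unpaired
  pr2 <- pair_targets(list(make_feature("A", rt = 1.0),
                           make_feature("B", mz = 305, rt = 3.9)))
  expect_length(pr2$pairs, 0)
  expect_length(pr2$unpaired, 2)

  # partner with the largest RT difference wins
  a <- make_feature("A", rt = 1.0, height = 5000)
  b <- make_feature("B", mz = 310, rt = 4.5)
  c2 <- make_feature("C", mz = 320, rt = 5.2)
  pr3 <- pair_targets(list(a, b, c2))
  top <- pr3$pairs[[1]]
  expect_setequal(c(top$a$feature_id, top$b$feature_id), c("A", "C"))

  # mismatched fragment counts cannot pair
  d <- make_feature("D", rt = 1.0, frag_int = c(900, 500, 100, 50))
  e <- make_feature("E", mz = 310, rt = 6.0, frag_int = c(900, 500, 100))
  expect_length(pair_targets(list(d, e))$pairs, 0)
})

test_that("pairing happens within the representative run", {
  run1 <- lapply(1:3, function(i)
    make_feature(paste0("R1_", i), run = "run1", mz = 300 + i,
                 rt = c(1, 5, 8)[i]))
  run2 <- list(make_feature("R2_1", run = "run2", mz = 300, rt = 1))
  pr <- pair_targets(c(run1, run2))
  in_pairs <- unlist(lapply(pr$pairs, function(p)
    c(p$a$run_id, p$b$run_id)))
  expect_true(all(in_pairs == "run1"))
})

test_that("swap count honours the 40-60% band", {
  mk <- function(n, tag) {
    list(a = make_feature(paste0("A", tag), rt = 1,
                          frag_int = seq(1000, 100, length.out = n),
                          frag_mz = seq(100, by = 17.3, length.out = n)),
         b = make_feature(paste0("B", tag), mz = 310, rt = 6,
                          frag_int = seq(990, 110, length.out = n),
                          frag_mz = seq(95, by = 19.1, length.out = n)))
  }
  # n = 6: only k = 3 is admissible (ceil(2.4) = floor(3.6) = 3)
  dec6 <- generate_decoys(list(mk(6, "x")), seed = 1)
  expect_equal(dec6$pairs[[1]]$n_swap, 3)
  swapped <- sum(dec6$decoys[[1]]$fragments$mz !=
                   dec6$pairs[[1]]$a$fragments$mz)
  expect_equal(swapped, 3)

  # n = 10: k in {4, 5, 6}
  ks <- vapply(1:20, function(s)
    generate_decoys(list(mk(10, s)), seed = s)$pairs[[1]]$n_swap, 0)
  expect_true(all(ks %in% 4:6))
  expect_gt(length(unique(ks)), 1)

  # n = 3 and n = 1 admit no integer in the band -> pair rejected
  expect_length(generate_decoys(list(mk(3, "y")), seed = 1)$decoys, 0)
  expect_equal(length(generate_decoys(list(mk(3, "y")),
                                      seed = 1)$rejected), 2)
})

test_that("decoys keep precursor properties and swap only fragment m/z", {
  p <- list(a = make_feature("A", rt = 1, ccs = 151, sn = 44,
                             frag_int = c(900, 700, 500, 300, 200, 100),
                             frag_mz = seq(100, by = 17.3,
                                           length.out = 6)),
            b = make_feature("B", mz = 340, rt = 7, ccs = 158, sn = 31,
                             frag_int = c(880, 680, 480, 290, 190, 90),
                             frag_mz = seq(98, by = 21.7,
                                           length.out = 6)))
  dec <- generate_decoys(list(p), seed = 5)
  da <- dec$decoys[[1]]; db <- dec$decoys[[2]]
  for (fld in c("precursor_mz", "rt", "ccs", "sn", "height")) {
    expect_equal(da[[fld]], p$a[[fld]])
    expect_equal(db[[fld]], p$b[[fld]])
  }
  expect_equal(da$fragments$intensity, p$a$fragments$intensity)
  # swapped m/z values come from the partner at matching intensity rank
  expect_true(all(da$fragments$mz %in% c(p$a$fragments$mz,
                                         p$b$fragments$mz)))
  ranks <- attr(da, "swap_ranks")
  expect_equal(da$fragments$mz[match(ranks, da$fragments$rank)],
               p$b$fragments$mz[match(ranks, p$b$fragments$rank)])
  # both decoys mirror the same positions
  expect_equal(attr(db, "swap_ranks"), ranks)
  expect_equal(da$feature_id, "DECOY_A")
  expect_equal(attr(da, "partner_id"), "A")
})

test_that("decoy generation is deterministic under a seed", {
  cfg <- simulation_config(n_true_groups = 60, n_false_groups = 60,
                           n_runs = 1, seed = 42)
  sim <- simulate_peakgroups(cfg, tempfile())
  feats <- read_feature_alignment(sim$alignment)
  tg <- select_targets(feats)
  pr <- pair_targets(tg)
  d1 <- generate_decoys(pr$pairs, seed = 9)
  d2 <- generate_decoys(pr$pairs, seed = 9)
  expect_identical(d1, d2)
  d3 <- generate_decoys(pr$pairs, seed = 10)
  mz1 <- unlist(lapply(d1$decoys, function(d) d$fragments$mz))
  mz3 <- unlist(lapply(d3$decoys, function(d) d$fragments$mz))
  expect_false(identical(mz1, mz3))
})

test_that("decoy marginals equal the paired targets' exactly", {
  cfg <- simulation_config(n_true_groups = 150, n_false_groups = 150,
                           n_runs = 1, seed = 8)
  sim <- simulate_peakgroups(cfg, tempfile())
  tg <- select_targets(read_feature_alignment(sim$alignment))
  dec <- generate_decoys(pair_targets(tg)$pairs, seed = 8)
  paired <- unlist(lapply(dec$pairs, function(p) list(p$a, p$b)),
                   recursive = FALSE)
  expect_gt(length(dec$decoys), 20)
  expect_equal(length(dec$decoys), length(paired))
  fld <- function(xs, f) sort(vapply(xs, `[[`, 0, f))
  for (f in c("precursor_mz", "rt", "ccs"))
    expect_equal(fld(dec$decoys, f), fld(paired, f))
  nf <- function(xs) sort(vapply(xs, function(x) nrow(x$fragments), 0L))
  expect_equal(nf(dec$decoys), nf(paired))
  # fragment m/z values are drawn from the pair's union (swap permutes)
  for (i in seq_along(dec$pairs)) {
    p <- dec$pairs[[i]]
    un <- c(p$a$fragments$mz, p$b$fragments$mz)
    expect_true(all(dec$decoys[[2 * i - 1]]$fragments$mz %in% un))
  }
})
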