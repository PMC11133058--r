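test_that("configuration validity rules use the configuration-window names", {
  expect_error(generation_config(3, 10, 8, 3, 3), "Close Space Items")
  expect_error(generation_config(3, 12, 6, 7, 2), "Target Items")
  expect_error(generation_config(0, 12, 6, 3, 2), "Number of Lists")
  expect_error(generation_config(3, 12, 6, 3, 0), "Critical Lures")
  expect_error(generation_config(3, 12, 6, 3, 2, -1), "Unrelated Lures")
  cfg <- generation_config(3, 12, 6, 3, 2, 2)
  expect_s3_class(cfg, "fmg_config")
  expect_identical(cfg$method, "random")
})

test_that("accepted studied sets place their farthest member at rank N_CS exactly", {
  sp <- clustered_space(seed = 41)
  cfg <- small_config(seed = 5)
  seeds <- find_list_seeds(sp, 1, rng = 5)
  bs <- build_study_set(sp, seeds$seeds[1], cfg, rng = 9)
  # independent brute-force re-ranking against the returned centroid
  oracle <- brute_rank(sp, bs$centroid)
  ranks <- match(bs$studied, oracle$label)
  expect_identical(max(ranks), cfg$close_space_items)
  expect_length(bs$studied, cfg$studied_items)
  expect_identical(oracle$label[seq_len(cfg$close_space_items)],
                   bs$close_space)
  expect_equal(bs$close_radius,
               oracle$distance[cfg$close_space_items], tolerance = 1e-12)
  # classical criterion: the rank-1 neighbor is not studied
  expect_false(oracle$label[1] %in% bs$studied)
  # studied set is ordered by ascending distance to the centroid
  expect_true(all(diff(bs$studied_distance) >= 0))
})

test_that("a close space exactly filled by studied items accepts immediately", {
  # boundary of the close-space construction step on its own: with
  # N_CS = N_S and the classical flag off, the accepted studied set is the
  # whole close space
  sp <- clustered_space(3, 40, 8, 0.35, seed = 51)
  cfg <- generation_config(1, 7, 6, 2, 1, 1, "random",
                           classical_critical_lure = FALSE, seed = 3)
  cfg$close_space_items <- 6L  # exercise the op below the full-run invariant
  seeds <- find_list_seeds(sp, 1, rng = 4)
  bs <- build_study_set(sp, seeds$seeds[1], cfg, rng = 4)
  expect_setequal(bs$studied, bs$close_space)
})

test_that("random-method lures respect the close/far boundary (brute force)", {
  sp <- clustered_space(seed = 61)
  for (classical in c(TRUE, FALSE)) {
    lists <- generate_lists(sp, small_config(classical = classical, seed = 17))
    for (l in lists) {
      dc <- brute_dist_to_centroid(sp, l$critical_lures, l$centroid)
      du <- brute_dist_to_centroid(sp, l$unrelated_lures, l$centroid)
      expect_true(all(dc <= l$close_radius + 1e-12))
      expect_true(all(du > l$close_radius))
      expect_true(all(l$critical_lures %in% l$close_space))
      expect_false(any(l$critical_lures %in% l$studied))
      if (classical) {
        expect_true(l$close_space[1] %in% l$critical_lures)
      }
    }
  }
})

test_that("N_CS = N_S + N_CL forces the critical lures exactly", {
  sp <- clustered_space(3, 40, 8, 0.35, seed = 71)
  cfg <- generation_config(1, 8, 6, 3, 2, 1, "random",
                           classical_critical_lure = FALSE, seed = 23)
  lists <- generate_lists(sp, cfg)
  l <- lists[[1]]
  expect_setequal(l$critical_lures, setdiff(l$close_space, l$studied))
})

test_that("a single critical lure with the classical flag is the rank-1 neighbor", {
  sp <- clustered_space(seed = 81)
  cfg <- small_config(ncl = 1, nul = 2, classical = TRUE, seed = 31)
  lists <- generate_lists(sp, cfg)
  for (l in lists) {
    # eligibility when this list was built: items of earlier lists that were
    # already committed (studied sets and their reserved classical lures)
    earlier <- unlist(lapply(lists, function(x) {
      if (x$list_id < l$list_id) c(x$studied, x$critical_lures) else NULL
    }))
    oracle <- brute_rank(sp, l$centroid, excluded = earlier)
    expect_identical(l$critical_lures, oracle$label[1])
  }
})

test_that("distributed bins form one geometric progression across the boundary", {
  sp <- clustered_space(seed = 91)
  lists <- generate_lists(sp, small_config(method = "distributed", seed = 37))
  for (l in lists) {
    b <- l$bins
    expect_identical(nrow(b), 4L)  # 2 close + 2 far
    ratios <- b$width[-1] / b$width[-nrow(b)]
    expect_equal(ratios, rep(b$ratio[1], 3), tolerance = 1e-9)
    # tiling is exact: close bins end at the radius, far at the horizon
    expect_equal(b$upper[2], l$close_radius, tolerance = 1e-12)
    # each critical lure occupies a distinct close bin
    dc <- brute_dist_to_centroid(sp, l$critical_lures, l$centroid)
    bins_hit <- vapply(dc, function(z) {
      which(z <= b$upper[b$region == "close"] + 1e-9)[1]
    }, integer(1))
    expect_identical(sort(unname(bins_hit)), 1:2)
    # unrelated lures occupy distinct far bins
    du <- brute_dist_to_centroid(sp, l$unrelated_lures, l$centroid)
    far_upper <- b$upper[b$region == "far"]
    fbins <- vapply(du, function(z) which(z <= far_upper + 1e-9)[1], integer(1))
    expect_identical(sort(unname(fbins)), 1:2)
  }
})

test_that("single close and far bins span the whole occupied intervals", {
  sp <- clustered_space(seed = 101)
  cfg <- small_config(method = "distributed", ncl = 1, nul = 1,
                      classical = FALSE, seed = 43)
  lists <- generate_lists(sp, cfg)
  for (l in lists) {
    expect_identical(nrow(l$bins), 2L)
    expect_equal(l$bins$upper[1], l$close_radius, tolerance = 1e-12)
    expect_length(l$critical_lures, 1L)
    expect_length(l$unrelated_lures, 1L)
  }
})

test_that("the distributed Exp-2 shape yields three lures of each kind per list", {
  sp <- clustered_space(6, 60, 16, seed = 111)
  cfg <- small_config(method = "distributed", ncs = 15, ncl = 3, nul = 3,
                      seed = 47)
  lists <- generate_lists(sp, cfg)
  for (l in lists) {
    expect_length(l$critical_lures, 3L)
    expect_length(l$unrelated_lures, 3L)
    b <- l$bins
    ratios <- b$width[-1] / b$width[-nrow(b)]
    expect_equal(ratios, rep(b$ratio[1], 5), tolerance = 1e-9)
  }
})

test_that("no item appears in two lists in any role", {
  sp <- clustered_space(seed = 121)
  for (m in c("random", "distributed")) {
    lists <- generate_lists(sp, small_config(method = m, seed = 53))
    all_items <- unlist(lapply(lists, function(l) {
      c(l$studied, l$critical_lures, l$unrelated_lures)
    }))
    expect_identical(anyDuplicated(all_items), 0L)
    cfg <- attr(lists, "config")
    expect_length(all_items, cfg$n_lists *
                    (cfg$studied_items + cfg$critical_lures +
                       cfg$unrelated_lures))
  }
})

test_that("generation is deterministic per master seed", {
  sp <- clustered_space(seed = 131)
  pick <- function(l) l[c("studied", "targets", "critical_lures",
                          "unrelated_lures")]
  for (m in c("random", "distributed")) {
    a <- generate_lists(sp, small_config(method = m, seed = 59))
    b <- generate_lists(sp, small_config(method = m, seed = 59))
    expect_identical(lapply(a, pick), lapply(b, pick))
    c <- generate_lists(sp, small_config(method = m, seed = 60))
    expect_false(identical(lapply(a, pick), lapply(c, pick)))
  }
})

test_that("targets are a subset of studied items of the requested size", {
  sp <- clustered_space(seed = 141)
  lists <- generate_lists(sp, small_config(seed = 61))
  for (l in lists) {
    expect_length(l$targets, 3L)
    expect_true(all(l$targets %in% l$studied))
  }
})

test_that("near-noiseless clusters are recovered: studied sets are mono-cluster", {
  sp <- make_synthetic_space(12, 30, 24, 0.02, seed = 5)
  cl <- attr(sp, "clusters")
  cfg <- generation_config(12, 10, 5, 2, 2, 2, "random",
                           classical_critical_lure = FALSE, seed = 67)
  lists <- generate_lists(sp, cfg)
  owners <- vapply(lists, function(l) {
    k <- unique(cl[l$studied])
    expect_length(k, 1L)
    k[1]
  }, integer(1))
  expect_length(unique(owners), 12L)
})

test_that("feasibility reports counting shortfalls with suggested edits", {
  sp <- clustered_space(2, 15, 8, 0.3, seed = 151)  # 30 items
  cfg <- small_config(n_lists = 4, ncs = 12, seed = 71)
  rep <- check_feasibility(sp, cfg)
  expect_identical(nrow(rep), 2L)
  expect_false(any(rep$feasible))
  expect_match(rep$limiting_constraint[1], "vocabulary size")
  expect_match(rep$suggestion[1], "Number of Lists|larger vector space")
})

test_that("feasibility passes on a generous space and leaves real runs alone", {
  sp <- clustered_space(seed = 161)
  cfg <- small_config(seed = 73)
  rep <- check_feasibility(sp, cfg)
  expect_true(all(rep$feasible))
  # the simulation draws from an independent substream: a real run after a
  # feasibility check is identical to one without it
  a <- generate_lists(sp, cfg)
  invisible(check_feasibility(sp, cfg))
  b <- generate_lists(sp, cfg)
  pick <- function(l) l[c("studied", "targets", "critical_lures",
                          "unrelated_lures")]
  expect_identical(lapply(a, pick), lapply(b, pick))
})

test_that("generating from a too-small vocabulary fails fast", {
  sp <- clustered_space(2, 10, 8, 0.3, seed = 171)
  expect_error(generate_lists(sp, small_config(n_lists = 4, seed = 79)),
               "infeasible")
})
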