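test_that("plain and headered embedding files parse to the same space", {
  body <- c("a 1 0", "b 0 1", "c 1 1")
  plain <- write_space_file(body)
  headered <- write_space_file(c("3 2", body))

  sp <- load_vector_space(plain)
  expect_s3_class(sp, "fmg_space")
  expect_identical(sp$labels, c("a", "b", "c"))
  expect_identical(ncol(sp$vectors), 2L)
  expect_equal(unname(sp$vectors["c", ]), c(1, 1))

  sp2 <- load_vector_space(headered)
  expect_identical(sp$labels, sp2$labels)
  expect_equal(unname(sp$vectors), unname(sp2$vectors))
  expect_true(attr(sp2, "header"))
  expect_false(attr(sp, "header"))
})

test_that("malformed embedding files are rejected with the offending line", {
  expect_error(load_vector_space(write_space_file(c("a 1 0", "a 0 1"))),
               "duplicate label: a")
  expect_error(load_vector_space(write_space_file(c("a 1 0", "b 1 0 3"))),
               "line 2")
  expect_error(load_vector_space(write_space_file(c("3 2", "a 1 0", "b 1"))),
               "line 3")
  expect_error(load_vector_space(write_space_file(c("a 1 0", "b 0 0"))),
               "zero-norm.*b")
  expect_error(load_vector_space(write_space_file(c("a 1 0", "b x 1"))),
               "line 2")
  expect_error(load_vector_space(tempfile()), "not found")
})

test_that("save/load round-trips labels exactly and values to printed precision", {
  sp <- clustered_space(3, 10, 8, 0.2, seed = 3)
  f <- tempfile()
  save_vector_space(sp, f)
  back <- load_vector_space(f)
  expect_identical(back$labels, sp$labels)
  expect_equal(unname(back$vectors), unname(sp$vectors), tolerance = 1e-9)

  # dialect mirroring: header attribute survives a round trip
  save_vector_space(sp, f, header = TRUE)
  back2 <- load_vector_space(f)
  expect_true(attr(back2, "header"))
  expect_identical(back2$labels, sp$labels)

  # one-item space writes a single line of 1 + d tokens
  one <- vector_space(matrix(c(1, 2, 3), 1, 3, dimnames = list("only", NULL)))
  save_vector_space(one, f, header = FALSE)
  ln <- readLines(f)
  expect_length(ln, 1L)
  expect_length(strsplit(ln, " ")[[1]], 4L)
})

test_that("degenerate construction inputs error", {
  expect_error(vector_space(matrix(1:4, 2, 2)), "labels")
  expect_error(vector_space(matrix(1:2, 1, 2, dimnames = list("a b", NULL))),
               "whitespace")
  expect_error(vector_space(matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL))),
               "at least 2")
  expect_error(vector_space(matrix(c(1, 0, NA, 1), 2, 2,
                                   dimnames = list(c("a", "b"), NULL))),
               "finite")
})

test_that("synthetic spaces are deterministic and respect the noise limit", {
  s1 <- make_synthetic_space(4, 5, 6, 0.3, seed = 11)
  s2 <- make_synthetic_space(4, 5, 6, 0.3, seed = 11)
  expect_identical(s1$vectors, s2$vectors)
  expect_identical(attr(s1, "clusters"), attr(s2, "clusters"))

  # zero spread collapses each cluster to one point: within-cluster cosine 1
  s0 <- make_synthetic_space(3, 4, 5, 0, seed = 2)
  cl <- attr(s0, "clusters")
  for (k in 1:3) {
    v <- s0$vectors[cl == k, , drop = FALSE]
    expect_equal(max(abs(sweep(v, 2, v[1, ]))), 0)
  }
  # all vectors unit length
  expect_equal(unname(rowSums(s1$vectors^2)), rep(1, 20), tolerance = 1e-12)
})

test_that("each synthetic item is nearest its own cluster direction (brute force)", {
  sp <- make_synthetic_space(12, 40, 50, 0.08, seed = 9)
  cl <- attr(sp, "clusters")
  # recover the directions as per-cluster centroids of the near-noiseless items
  dirs <- t(vapply(1:12, function(k) {
    colMeans(sp$vectors[cl == k, , drop = FALSE])
  }, numeric(50)))
  for (l in sample(sp$labels, 60)) {
    sims <- vapply(1:12, function(k) brute_cosine(sp$vectors[l, ], dirs[k, ]),
                   numeric(1))
    expect_identical(which.max(sims), unname(cl[[l]]))
  }
})

test_that("well-separated clusters: within-cluster similarity exceeds between", {
  sp <- clustered_space(5, 25, 16, seed = 21)
  cl <- attr(sp, "clusters")
  S <- sp$vectors %*% t(sp$vectors)
  same <- outer(cl, cl, "==")
  ut <- upper.tri(S)
  expect_gt(mean(S[same & ut]), mean(S[!same & ut]))
})
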