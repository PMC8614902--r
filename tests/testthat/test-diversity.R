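test_that("nei_li matches hand-enumerated band classes and handles edge cases", {
  expect_identical(nei_li(c(1, 0, 1, 1), c(1, 0, 1, 1)), 0)
  expect_identical(nei_li(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # Nx = 3, Ny = 3, Nxy = 2 -> 1 - 4/6
  expect_equal(nei_li(c(1, 1, 0, 1), c(1, 0, 1, 1)), 1 / 3)
  expect_error(nei_li(c(1, 0), c(1, 0, 1)), "length")
  expect_warning(z <- nei_li(c(0, 0), c(0, 0)), "all-zero")
  expect_identical(z, 0)
})

test_that("nei_li is symmetric, bounded, zero iff identical presence sets", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(x) + sum(y) == 0) next
    d <- nei_li(x, y)
    expect_identical(d, nei_li(y, x))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_identical(d == 0, all(x == y))
    expect_equal(d, nei_li_oracle(x, y))
    # invariance under a shared column permutation and shared-absent padding
    p <- sample.int(n)
    expect_equal(nei_li(x[p], y[p]), d)
    expect_equal(nei_li(c(x, 0, 0), c(y, 0, 0)), d)
  }
})

test_that("appending a shared band weakly decreases Gd, a private band weakly increases it", {
  set.seed(102)
  for (rep in 1:25) {
    x <- rbinom(20, 1, 0.5)
    y <- rbinom(20, 1, 0.5)
    if (sum(x) + sum(y) == 0) next
    d <- nei_li(x, y)
    expect_lte(nei_li(c(x, 1), c(y, 1)), d)
    expect_gte(nei_li(c(x, 1), c(y, 0)), d)
  }
})

test_that("pairwise_gd equals the double-loop oracle across sizes", {
  expect_identical(pairwise_gd(rbind(a = c(1, 0, 1), b = c(1, 0, 1))),
                   matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  v <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  d <- pairwise_gd(v)
  expect_equal(sort(d[upper.tri(d)]), c(0, 1, 1))
  set.seed(103)
  for (n in c(5, 17, 50)) {
    m <- random_matrix(n, 12)
    expect_equal(suppressWarnings(pairwise_gd(m)), pairwise_oracle(m$values))
  }
  expect_error(pairwise_gd(matrix(1, 1, 3, dimnames = list("a", NULL))),
               "at least 2")
})

test_that("consensus profile takes the majority, honouring the tie rule", {
  v <- matrix(0, 10, 3)
  v[1:7, 1] <- 1            # 7/10 -> present
  v[1:5, 2] <- 1            # 5/10 -> tie
  rownames(v) <- sprintf("s%d", 1:10)
  m <- make_matrix(v)
  expect_identical(unname(consensus_profile(m)), c(1L, 0L, 0L))
  expect_identical(unname(consensus_profile(m, tie = "present")), c(1L, 1L, 0L))
  one <- make_matrix(rbind(c(1, 0, 1)))
  expect_identical(unname(consensus_profile(one)), c(1L, 0L, 1L))
  # identical rows reproduce the row
  same <- make_matrix(matrix(rep(c(1, 0, 1, 1), each = 6), 6))
  expect_identical(unname(consensus_profile(same)), c(1L, 0L, 1L, 1L))
})

test_that("between-population Gd equals consensus-then-nei_li done by hand", {
  set.seed(104)
  m <- random_matrix(18, 40)
  tab <- make_table(sample_ids(m), rep(c("A", "B", "C"), each = 6))
  got <- between_population_gd(m, tab)
  prof <- sapply(c("A", "B", "C"), function(p) {
    v <- m$values[tab$population == p, ]
    as.integer(colSums(v) > nrow(v) / 2)
  })
  for (p in c("A", "B", "C")) for (q in c("A", "B", "C")) {
    expect_equal(got[p, q], nei_li_oracle(prof[, p], prof[, q]))
  }
  # identical consensus -> 0
  twin <- make_matrix(rbind(a1 = c(1, 0, 1), a2 = c(1, 0, 1),
                            b1 = c(1, 0, 1), b2 = c(1, 0, 1)))
  ttab <- make_table(sample_ids(twin), rep(c("A", "B"), each = 2))
  expect_identical(between_population_gd(twin, ttab)["A", "B"], 0)
  # pooled units
  pooled <- between_population_gd(m, tab, units = list(AB = c("A", "B"), C = "C"))
  expect_identical(rownames(pooled), c("AB", "C"))
})

test_that("within-unit summary equals the explicit pair list", {
  twin <- make_matrix(rbind(a1 = c(1, 0, 1), a2 = c(1, 0, 1)))
  tab <- make_table(sample_ids(twin), "A")
  s <- within_population_gd(twin, tab, "A")
  expect_equal(c(s$min_gd, s$mean_gd, s$max_gd), c(0, 0, 0))
  set.seed(105)
  m <- random_matrix(9, 30)
  tab <- make_table(sample_ids(m), rep(c("A", "B", "C"), each = 3))
  s <- within_population_gd(m, tab, c("A", "C"), name = "pool")
  v <- m$values[tab$population %in% c("A", "C"), ]
  pairs <- utils::combn(nrow(v), 2)
  gds <- apply(pairs, 2, function(ij) nei_li_oracle(v[ij[1], ], v[ij[2], ]))
  expect_identical(s$n_pairs, ncol(pairs))
  expect_equal(s$min_gd, min(gds))
  expect_equal(s$mean_gd, mean(gds))
  expect_equal(s$max_gd, max(gds))
  one <- make_matrix(rbind(x = c(1, 0, 1)), ids = "x")
  expect_error(within_population_gd(one, make_table("x", "X"), "X"),
               "at least 2")
})

test_that("gd_range summarizes the strict upper triangle", {
  d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  r <- gd_range(d)
  expect_equal(unlist(r), c(min = .4, mean = .4, max = .4, n_pairs = 1))
})

test_that("diversity ratios round half-up to one decimal", {
  expect_identical(diversity_ratio(0.294, 0.194), 1.5)
  expect_identical(diversity_ratio(0.294, 0.248), 1.2)
  expect_identical(diversity_ratio(0.322, 0.234), 1.4)
  expect_identical(diversity_ratio(0.3, 0.3), 1)
  expect_identical(diversity_ratio(0.25, 0.2), 1.3)  # 1.25 rounds up
  expect_error(diversity_ratio(0.3, 0), "zero")
})

test_that("summary aggregation averages columns and differences against a reference", {
  s <- data.frame(unit = c("u1", "u2"), n_samples = c(5L, 6L),
                  n_pairs = c(10L, 15L),
                  min_gd = c(0.2, 0.3), mean_gd = c(0.4, 0.5),
                  max_gd = c(0.6, 0.7))
  ref <- data.frame(unit = "native", n_samples = 7L, n_pairs = 21L,
                    min_gd = 0.25, mean_gd = 0.55, max_gd = 0.75)
  out <- aggregate_gd_summaries(s, ref)
  avg <- out[out$unit == "average", ]
  expect_equal(avg$mean_gd, 0.45)
  expect_equal(out$gd_difference[out$unit == "u1"], 0.15)
  expect_equal(avg$gd_difference, 0.1)
  # single summary aggregates to itself
  one <- aggregate_gd_summaries(s[1, ])
  expect_equal(one$mean_gd, c(0.4, 0.4))
})

test_that("Gd matrix CSV and PHYLIP writers round-trip / emit valid files", {
  set.seed(106)
  d <- pairwise_gd(random_matrix(5, 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_gd_matrix(d, f)
  expect_equal(read_gd_matrix(f), d, tolerance = 1e-12)
  p <- withr::local_tempfile(fileext = ".phy")
  write_gd_phylip(d, p)
  lines <- readLines(p)
  expect_identical(lines[1], "5")
  expect_length(lines, 6L)
})
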