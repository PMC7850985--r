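test_that("dense rank implements the 1223 tie scheme in both directions", {
  v <- c(a = 5, b = 5, c = 3)
  expect_equal(dense_rank(v, "higher"), c(a = 1L, b = 1L, c = 2L))
  expect_equal(dense_rank(v, "lower"), c(a = 2L, b = 2L, c = 1L))
  expect_error(dense_rank(c(a = 1, b = NaN)), "b")
})

test_that("dense rank is permutation-equivariant", {
  set.seed(11)
  for (i in 1:10) {
    v <- setNames(sample(1:6, 12, replace = TRUE), paste0("n", 1:12))
    r <- dense_rank(v, "higher")
    perm <- sample(names(v))
    expect_equal(dense_rank(v[perm], "higher"), r[perm])
  }
})

test_that("aggregation reproduces the published shortlist arithmetic", {
  t1 <- table1_fixture()
  ranks <- function(col) setNames(as.integer(t1[[col]]), t1$protein)
  agg <- aggregate_ranks(ranks("hub_rank"), ranks("perturbation_rank"),
                         ranks("disruption_rank"))
  m <- merge(t1, agg, by.x = "protein", by.y = "node")
  expect_equal(nrow(m), 20L)
  expect_equal(m$average_rank, m$average)
  expect_equal(m$cumulative_rank, m$cumulative)
  # spot checks: exact tie detection on thirds, dense cumulative sequence
  expect_equal(agg$average_rank[agg$node == "HSPA5"], 10.33)
  expect_equal(agg$cumulative_rank[agg$node == "HSPA5"], 7L)
  expect_equal(agg$cumulative_rank[agg$node == "TPI1"],
               agg$cumulative_rank[agg$node == "VCP"])
  expect_equal(sort(unique(agg$cumulative_rank)), 1:16)
})

test_that("aggregation rejects mismatched node sets, names the difference", {
  h <- c(a = 1L, b = 2L)
  p <- c(a = 1L, b = 2L)
  d <- c(a = 1L, c = 2L)
  expect_error(aggregate_ranks(h, p, d), "b.*c|c.*b")
})

test_that("average ranking uses exact sums, not rounded averages", {
  # sums 28 and 28 tie; 28/3 and 29/3 round to different displays but the
  # near-tie 28 vs 29 must not collapse
  h <- c(x = 10L, y = 9L, z = 1L)
  p <- c(x = 9L, y = 10L, z = 1L)
  d <- c(x = 9L, y = 10L, z = 1L)
  agg <- aggregate_ranks(h, p, d)
  expect_equal(agg$cumulative_rank[agg$node == "x"], 2L)
  expect_equal(agg$cumulative_rank[agg$node == "y"], 3L)
  expect_equal(agg$average_rank[agg$node == "x"], 9.33)
  expect_equal(agg$average_rank[agg$node == "y"], 9.67)
})

test_that("rounding for display is half-up at 2 decimals", {
  expect_equal(round_half_up(28 / 3, 2), 9.33)
  expect_equal(round_half_up(26 / 3, 2), 8.67)
  expect_equal(round_half_up(9.335, 2), 9.34)
  expect_equal(round_half_up(10, 2), 10)
})

test_that("shortlisting keeps whole tie classes and the prefix property", {
  t1 <- table1_fixture()
  ranks <- function(col) setNames(as.integer(t1[[col]]), t1$protein)
  agg <- aggregate_ranks(ranks("hub_rank"), ranks("perturbation_rank"),
                         ranks("disruption_rank"))

  # fraction covering 3 of 20 -> ceiling is 1 class beyond GAPDH, HSPA8
  top <- shortlist_top_fraction(agg, 0.15)   # need 3; class {3} has 2 members
  expect_equal(top$node, c("GAPDH", "HSPA8", "HSP90AA1", "HSPA4"))

  # prefix property on a synthetic table
  set.seed(3)
  n <- 60
  h <- dense_rank(setNames(sample(1:20, n, TRUE), paste0("g", 1:n)), "higher")
  p <- dense_rank(setNames(sample(1:20, n, TRUE), paste0("g", 1:n)), "higher")
  d <- dense_rank(setNames(sample(1:20, n, TRUE), paste0("g", 1:n)), "higher")
  tab <- aggregate_ranks(h, p, d)
  short <- shortlist_top_fraction(tab, 0.1)
  included <- tab$cumulative_rank[tab$node %in% short$node]
  excluded <- tab$cumulative_rank[!(tab$node %in% short$node)]
  expect_true(max(included) < min(excluded))
  # tie-class atomicity
  cut <- max(included)
  expect_equal(sum(tab$cumulative_rank <= cut), nrow(short))
  # monotonicity in the fraction
  for (f in c(0.2, 0.5, 1)) {
    bigger <- shortlist_top_fraction(tab, f)
    expect_true(all(short$node %in% bigger$node))
  }
  expect_error(shortlist_top_fraction(tab, 0), "fraction")
  expect_error(shortlist_top_fraction(tab, 1.2), "fraction")
})

test_that("all-tied tables shortlist everything", {
  h <- setNames(rep(1L, 5), letters[1:5])
  tab <- aggregate_ranks(h, h, h)
  expect_equal(nrow(shortlist_top_fraction(tab, 0.05)), 5L)
})

test_that("aggregating ranks of ranks preserves the ordering", {
  t1 <- table1_fixture()
  ranks <- function(col) setNames(as.integer(t1[[col]]), t1$protein)
  agg <- aggregate_ranks(ranks("hub_rank"), ranks("perturbation_rank"),
                         ranks("disruption_rank"))
  cum <- setNames(agg$cumulative_rank, agg$node)
  again <- aggregate_ranks(cum, cum, cum)
  m <- merge(agg, again, by = "node", suffixes = c("", ".again"))
  expect_equal(m$cumulative_rank.again, m$cumulative_rank)
})

test_that("rank_nodes excludes the bait by default but can include it", {
  net <- generate_network(30, "preferential_attachment", seed = 6)
  sc <- score_nodes(net)
  bait <- sc$node[1]
  tab <- rank_nodes(sc, bait = bait)
  expect_false(bait %in% tab$node)
  tab2 <- rank_nodes(sc, bait = bait, include_bait = TRUE)
  expect_true(bait %in% tab2$node)
})
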