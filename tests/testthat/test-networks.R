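test_that("two-species worked example reproduces degrees and redundancies", {
  fx <- two_species_example()
  m <- function_metrics(fx$paired)
  red <- m[m$function_id == "red", ]
  expect_equal(red$k_gcn, 2L)
  expect_equal(red$k_pcn, 1L)
  expect_identical(network_degree(fx$gcn, "green"), c(green = 2L))
  expect_identical(network_degree(fx$pcn, "green"), c(green = 2L))
  ## niche protein: owned by both (FR_g = 2 p1 p2) but expressed by one (FR_p = 0)
  expect_equal(unname(functional_redundancy(fx$gcn, fx$profile, "red")), 0.5)
  expect_equal(unname(functional_redundancy(fx$pcn, fx$profile, "red")), 0)
  ## essential protein: no reduction
  expect_equal(m$fr_g[m$function_id == "green"], m$fr_p[m$function_id == "green"])
  ## specialist: zero at both levels
  blue <- m[m$function_id == "blue", ]
  expect_equal(c(blue$fr_g, blue$fr_p), c(0, 0))
  got <- as.data.frame(m)[, names(fx$expected)]
  rownames(got) <- NULL
  expect_equal(got, fx$expected, tolerance = 1e-12)
})

test_that("uneven profile shrinks redundancy but not degree", {
  fx <- two_species_example(c(0.9, 0.1))
  m <- function_metrics(fx$paired)
  expect_equal(m$fr_g[m$function_id == "red"], 2 * 0.9 * 0.1)
  expect_equal(m$k_gcn, c(1L, 2L, 2L))
  expect_equal(m$nfr_g[m$function_id == "green"], 1)  # fully shared
})

test_that("pair distance is 0 only when both taxa own the function", {
  fx <- two_species_example()
  expect_identical(pair_distance(fx$gcn, "red", "T1", "T2"), 0)
  expect_identical(pair_distance(fx$pcn, "red", "T1", "T2"), 1)
  none <- content_network(matrix(0, 2, 1, dimnames = list(c("T1", "T2"), "f")),
                          "protein")
  expect_identical(pair_distance(none, "f", "T1", "T2"), 1)  # neither owns
  expect_error(pair_distance(fx$gcn, "red", "T1", "T9"), "unknown taxon")
  expect_error(pair_distance(fx$gcn, "pink", "T1", "T2"), "unknown function")
})

test_that("redundancy equals the literal pair-sum oracle on random instances", {
  for (seed in 1:5) {
    n_taxa <- sample(3:50, 1)
    pd <- random_paired(n_taxa, sample(2:8, 1), seed)
    p <- as.numeric(pd$profile)
    for (net in list(pd$gcn, pd$pcn)) {
      expect_equal(unname(functional_redundancy(net, pd$profile)),
                   fr_oracle(net$incidence, p), tolerance = 1e-12)
    }
  }
})

test_that("redundancy obeys its structural bounds and invariances", {
  for (seed in 1:5) {
    pd <- random_paired(12, 6, seed)
    td <- taxonomic_diversity(pd$profile)
    fr_g <- functional_redundancy(pd$gcn, pd$profile)
    fr_p <- functional_redundancy(pd$pcn, pd$profile)
    expect_true(all(fr_g >= 0 & fr_g <= td + 1e-12))
    ## PCN is a subset of GCN by construction here
    expect_true(all(fr_p <= fr_g + 1e-12))
    expect_true(all(network_degree(pd$pcn) <= network_degree(pd$gcn)))
    ## permutation invariance
    perm <- sample(rownames(pd$gcn$incidence))
    g2 <- content_network(pd$gcn$incidence[perm, ], "gene")
    p2 <- taxonomic_profile(as.numeric(pd$profile)[match(perm, names(pd$profile))],
                            perm)
    expect_equal(functional_redundancy(g2, p2), fr_g, tolerance = 1e-12)
  }
})

test_that("fully shared functions reach TD exactly; rare ones are zero", {
  taxa <- c("a", "b", "c")
  inc <- matrix(c(1, 1, 1,   # shared by all
                  1, 0, 0,   # single owner
                  0, 0, 0),  # unowned
                3, 3, dimnames = list(taxa, c("all", "one", "none")))
  prof <- taxonomic_profile(c(0.2, 0.3, 0.5), taxa)
  fr <- functional_redundancy(content_network(inc, "gene"), prof)
  expect_equal(unname(fr), c(0.62, 0, 0))
  expect_equal(unname(fr["all"]), taxonomic_diversity(prof))
})

test_that("for a fully shared function the uniform profile maximizes FR", {
  one_fun <- function(p, n) {
    inc <- matrix(1, n, 1, dimnames = list(sprintf("t%d", 1:n), "f"))
    functional_redundancy(content_network(inc, "gene"),
                          taxonomic_profile(p, sprintf("t%d", 1:n)))
  }
  ## 2-taxon simplex grid
  grid2 <- seq(0.01, 0.99, by = 0.01)
  vals2 <- vapply(grid2, function(q) one_fun(c(q, 1 - q), 2), numeric(1))
  expect_equal(grid2[which.max(vals2)], 0.5)
  ## 3-taxon simplex grid: the uniform profile dominates every grid point and
  ## the grid argmax sits next to it
  step <- seq(0.02, 0.96, by = 0.02)
  best <- c(0, 0, -1)
  for (q1 in step) for (q2 in step) {
    q3 <- 1 - q1 - q2
    if (q3 <= 0) next
    v <- one_fun(c(q1, q2, q3), 3)
    if (v > best[3]) best <- c(q1, q2, v)
  }
  expect_lte(best[3], one_fun(rep(1/3, 3), 3))
  expect_lt(max(abs(best[1:2] - 1/3)), 0.02 + 1e-9)
})

test_that("taxonomic diversity and normalization behave on edge cases", {
  expect_equal(taxonomic_diversity(taxonomic_profile(c(0.5, 0.5), c("a", "b"))), 0.5)
  expect_equal(taxonomic_diversity(taxonomic_profile(1, "a")), 0)
  expect_equal(taxonomic_diversity(taxonomic_profile(c(0.9, 0.1), c("a", "b"))), 0.18)
  expect_equal(normalized_redundancy(0.5, 0.5), 1)
  expect_equal(normalized_redundancy(0, 0.42), 0)
  expect_equal(normalized_redundancy(0, 0), 0)     # single-taxon community
  expect_error(normalized_redundancy(0.6, 0.5), "exceed")
})

test_that("connectance counts realized edges", {
  fx <- two_species_example()
  expect_equal(connectance(fx$gcn), 5 / 6)
  ones <- content_network(matrix(1, 2, 2, dimnames = list(c("a","b"), c("x","y"))),
                          "gene")
  expect_equal(connectance(ones), 1)
  zeros <- content_network(matrix(0, 2, 2, dimnames = list(c("a","b"), c("x","y"))),
                           "gene")
  expect_equal(connectance(zeros), 0)
})

test_that("NODF matches hand-worked and perfectly nested cases", {
  stair <- rbind(c(1,1,1,1), c(1,1,1,0), c(1,1,0,0), c(1,0,0,0))
  expect_equal(nodf(stair), 1)
  expect_equal(nodf(diag(4)), 0)  # equal marginals: every pair contributes 0
  ## hand-worked 4x4: row pairs contribute 1,1,1,1,1,0; column pairs
  ## 1,1,1,0,1,1 -> (5 + 5) / 12
  m <- rbind(c(1,1,1,1), c(1,1,1,0), c(1,1,0,0), c(1,0,1,0))
  expect_equal(nodf(m), 10 / 12)
  expect_error(nodf(matrix(1, 1, 1)), "at least two")
})

test_that("NODF and connectance are bounded and NODF is transpose-symmetric", {
  skip_if_not_installed("vegan")
  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(rbinom(48, 1, 0.45), 6, 8)
    v <- nodf(m)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(nodf(t(m)), v, tolerance = 1e-12)
    ## independent oracle: vegan (after its marginal-total sort, which the
    ## order-invariant definition used here makes implicit) on the 0-100 scale
    ref <- unname(vegan::nestednodf(m, order = TRUE)$statistic["NODF"])
    expect_equal(v, ref / 100, tolerance = 1e-10)
  }
})

test_that("network alignment intersects functions and unions taxa", {
  g <- content_network(matrix(c(1, 0, 1, 1), 2, 2,
                              dimnames = list(c("t1", "t2"), c("a", "b"))), "gene")
  p <- content_network(matrix(c(1, 1, 0, 1), 2, 2,
                              dimnames = list(c("t2", "t3"), c("b", "c"))), "protein")
  prof <- taxonomic_profile(c(t1 = 0.5, t2 = 0.3, t3 = 0.2))
  pd <- paired_networks(g, p, prof)
  expect_identical(colnames(pd$gcn$incidence), "b")        # intersection
  expect_identical(rownames(pd$gcn$incidence), c("t1", "t2", "t3"))  # union
  expect_equal(sum(pd$profile), 1)
  ## taxa absent from one network own/express nothing there
  expect_equal(unname(pd$pcn$incidence["t1", "b"]), 0)
  ## identical inputs round-trip
  fx <- two_species_example()
  pd2 <- paired_networks(fx$gcn, fx$pcn, fx$profile)
  expect_equal(pd2$gcn$incidence["T1", c("red", "green", "blue")],
               fx$gcn$incidence["T1", c("red", "green", "blue")])
  ## failure modes
  q <- content_network(matrix(1, 1, 1, dimnames = list("t9", "z")), "protein")
  expect_error(paired_networks(g, q, prof), "share no functions")
  prof_far <- taxonomic_profile(c(x1 = 1))
  expect_error(paired_networks(g, p, prof_far), "disjoint")
})

test_that("profile abundances are re-normalized over retained taxa", {
  g <- content_network(matrix(1, 2, 1, dimnames = list(c("t1", "t2"), "a")), "gene")
  p <- content_network(matrix(1, 2, 1, dimnames = list(c("t1", "t2"), "a")), "protein")
  prof <- taxonomic_profile(c(t1 = 0.25, t2 = 0.25, ghost = 0.5))
  pd <- paired_networks(g, p, prof)
  expect_equal(as.numeric(pd$profile), c(0.5, 0.5))
})

test_that("metrics table flags FR_p > FR_g rather than clamping", {
  ## PCN deliberately NOT a subset of the GCN (detection-depth artifact)
  g <- content_network(matrix(c(1, 0), 2, 1, dimnames = list(c("t1","t2"), "f")),
                       "gene")
  p <- content_network(matrix(c(1, 1), 2, 1, dimnames = list(c("t1","t2"), "f")),
                       "protein")
  pd <- paired_networks(g, p, taxonomic_profile(c(t1 = 0.5, t2 = 0.5)))
  m <- function_metrics(pd)
  expect_true(m$flag_frp_gt_frg)
  expect_gt(m$fr_p, m$fr_g)
  ## PCN == GCN means equal redundancy everywhere
  pd2 <- random_paired(8, 5, seed = 11, p_expr = 1)
  m2 <- function_metrics(pd2)
  expect_equal(m2$fr_p, m2$fr_g)
  expect_false(any(m2$flag_frp_gt_frg))
})
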