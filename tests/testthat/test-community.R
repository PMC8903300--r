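# Hill diversity, Bray-Curtis/NMDS composition, PERMANOVA, seasonal models.

test_that("Hill numbers match direct formula evaluation", {
  # uniform community: all orders equal richness
  expect_equal(sapply(c(0, 1, 2), hill_number, counts = rep(25, 4)),
               c(4, 4, 4))
  # single taxon: 1 at every order
  expect_equal(sapply(c(0, 1, 2), hill_number, counts = c(0, 42, 0)),
               c(1, 1, 1))
  # dominance-structured sample against the brute-force oracle
  cts <- c(63, 28, 7, 1, 1)
  for (q in c(0, 0.5, 1, 2, 3)) {
    expect_equal(hill_number(cts, q), brute_force_hill(cts, q),
                 tolerance = 1e-12)
  }
  expect_equal(hill_number(cts, 0), 5)
  expect_gt(hill_number(cts, 0), hill_number(cts, 1))
  expect_gt(hill_number(cts, 1), hill_number(cts, 2))
  expect_error(hill_number(c(0, 0), 1), "empty")
  expect_error(hill_number(c(1, 2), -1), "q must be")
})

test_that("diversity is non-increasing in q and scale invariant", {
  set.seed(61)
  for (i in 1:100) {
    cts <- rmultinom(1, rpois(1, 150) + 1,
                     prop.table(rgamma(8, shape = 0.5)))[, 1]
    d <- sapply(c(0, 1, 2), hill_number, counts = cts)
    expect_true(all(diff(d) <= 1e-10))
    expect_gte(d[3], 1)
    # doubling all counts changes nothing
    expect_equal(sapply(c(0, 1, 2), hill_number, counts = 2 * cts), d,
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis distances match hand evaluation", {
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(2, 1, 0),
             d = c(0, 0, 5))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)        # identical rows
  expect_equal(d["a", "d"], 1)        # disjoint support
  expect_equal(d, t(d))
  # ratio invariance under count doubling
  expect_equal(as.matrix(bray_curtis(2 * m)), d, tolerance = 1e-12)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("NMDS embeds exact configurations and separates clusters", {
  set.seed(62)
  pts <- matrix(rnorm(20 * 2), ncol = 2)
  # vegan warns that near-zero stress may indicate too-easy data -- here it
  # is the point of the check
  nm <- suppressWarnings(
    nmds_communities(dist(pts), k = 2, restarts = 5, seed = 3))
  expect_lt(nm$stress, 0.01)  # perfectly embeddable
  expect_lt(max(abs(colMeans(nm$coordinates))), 1e-8)

  # identical seed, identical stress
  nm2 <- suppressWarnings(
    nmds_communities(dist(pts), k = 2, restarts = 5, seed = 3))
  expect_identical(nm$stress, nm2$stress)

  # two well-separated simulated communities: axis 1 recovers the split
  base1 <- c(40, 5, 5, 1, 1, 0, 0, 0)
  base2 <- c(0, 0, 1, 1, 5, 5, 40, 10)
  cts <- rbind(t(sapply(1:8, function(i) rpois(8, base1 + 0.5))),
               t(sapply(1:8, function(i) rpois(8, base2 + 0.5))))
  nmc <- suppressWarnings(
    nmds_communities(bray_curtis(cts), k = 2, restarts = 10, seed = 4))
  ax1 <- nmc$coordinates[, 1]
  lab <- rep(c(1, 2), each = 8)
  sep <- abs(mean(ax1[lab == 1]) - mean(ax1[lab == 2])) /
    (sd(ax1[lab == 1]) + sd(ax1[lab == 2]))
  expect_gt(sep, 1)
})

test_that("stratified PERMANOVA restricts permutations and matches oracles", {
  # permutations never cross strata
  set.seed(63)
  g <- rep(c("x", "y"), 6)
  st <- rep(1:3, each = 4)
  for (i in 1:50) {
    p <- soundsoil:::permute_within_strata(g, st)
    for (s in 1:3) {
      expect_equal(sort(p[st == s]), sort(g[st == s]))
    }
  }

  # Monte-Carlo p matches full enumeration on n = 6 paired strata
  set.seed(64)
  m <- matrix(rnorm(6 * 3), ncol = 3)
  d <- dist(m)
  g6 <- rep(c("x", "y"), 3)
  st6 <- rep(1:3, each = 2)
  exact <- exact_strata_permanova_p(d, g6, st6)
  mc <- permanova_strata(d, g6, strata = st6, n_perm = 1000, seed = 1)
  expect_lt(abs(mc$p - exact), 2 / sqrt(1000) + 1e-9)

  # maximal separation: p is near the attainable minimum 1/(n_perm + 1);
  # random permutations occasionally reproduce the same binary partition,
  # so only those ties can push it above the floor
  m2 <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + rnorm(20, sd = 0.01)
  pm <- permanova_strata(dist(m2), rep(c("a", "b"), each = 5),
                         n_perm = 199, seed = 2)
  expect_gte(pm$p, 1 / 200)
  expect_lt(pm$p, 0.05)
  expect_error(permanova_strata(dist(m2), rep("a", 10)), "two groups")

  # unstratified statistic agrees with the standard implementation
  set.seed(65)
  mm <- matrix(rpois(12 * 6, 8), ncol = 6)
  gg <- rep(c("a", "b", "c"), 4)
  ours <- permanova_strata(vegan::vegdist(mm), gg, n_perm = 99, seed = 3)
  ref <- vegan::adonis2(vegan::vegdist(mm) ~ gg, permutations = 99)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("seasonal mixed models detect planted effects with honest nulls", {
  cfg <- community_config(seed = 66, season_shift = list())
  seasons <- rep(c("winter", "spring", "summer", "fall"), each = 6)
  sensors <- rep(paste0("S", 1:6), 4)
  # null: no seasonal structure planted
  tab0 <- generate_community(cfg, 24, seasons, sensors)
  f0 <- season_lmm(tab0, "shannon")
  row0 <- f0$anova[f0$anova$term == "season", ]
  expect_equal(row0$numDF, 3)
  expect_gt(row0$p, 0.001)  # planted null rarely yields extreme p

  # strong dominance shift: Simpson diversity responds
  cfg1 <- community_config(seed = 67,
                           season_shift = list(summer = c(Acari = 0.15),
                                               winter = c(Acari = 3)))
  tab1 <- generate_community(cfg1, 24, seasons, sensors)
  f1 <- season_lmm(tab1, "simpson")
  expect_lt(f1$anova[f1$anova$term == "season", "p"], 0.05)
  expect_gte(f1$r2_conditional, f1$r2_marginal)
  expect_error(season_lmm(tab1, "nope"))
})
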