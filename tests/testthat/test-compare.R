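# Two-group inference: Welch/Holm regional tests, subject-relabeling
# permutation on metric AUCs, and the seed-edge contrast.

test_that("identical groups give t = 0 and p = 1 everywhere", {
  tab <- tiny_table()
  x <- simulate_uptake(tab, 10, coupling_spec(), seed = 51)
  res <- regional_ttests(x, x)
  expect_true(all(abs(res$t) < 1e-12))
  expect_true(all(res$p > 1 - 1e-12))
  expect_false(any(res$significant))
})

test_that("Holm adjustment follows the step-down rule and is monotone", {
  # hand-applied Holm on raw p = (0.001, 0.02, 0.04):
  # adjusted = (0.003, 0.04, 0.04), all significant at 0.05
  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.04), method = "holm"),
               c(0.003, 0.04, 0.04))
  tab <- make_region_table(10, 2, 2)
  a <- simulate_uptake(tab, 15, coupling_spec(), seed = 52)
  b <- simulate_uptake(tab, 12, coupling_spec(), seed = 53)
  res <- regional_ttests(a, b)
  expect_true(all(res$p_holm >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_holm[ord]) >= -1e-15))
  # rejection at rank j implies rejection at all smaller ranks
  rej <- res$significant[ord]
  if (any(rej)) expect_true(all(rej[seq_len(max(which(rej)))]))
})

test_that("injected shifts are detected with high power and no false flags", {
  tab <- make_region_table(16, 2, 2)
  nodes <- mcnet:::region_nodes(tab)$name
  shifted <- nodes[2:6]
  # Welch t with a 0.5 SD shift at n = 200/200 and a Holm cut near
  # alpha / 20 has per-region power about 0.98; assert floors below that
  per_region <- stats::setNames(numeric(length(shifted)), shifted)
  all_five <- 0; false_flags <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    a <- simulate_uptake(tab, 200, coupling_spec(), seed = 5400 + rep)
    b <- simulate_uptake(tab, 200,
                         coupling_spec(mean_shift = stats::setNames(
                           rep(0.5, 5), shifted)), seed = 5600 + rep)
    res <- regional_ttests(a, b)
    hit <- res$significant[match(shifted, res$region)]
    per_region <- per_region + hit
    all_five <- all_five + all(hit)
    false_flags <- false_flags + sum(res$significant[!res$region %in% shifted])
  }
  expect_true(all(per_region / n_rep >= 0.9))
  expect_gte(all_five / n_rep, 0.6)
  expect_lte(false_flags / n_rep, 0.25)
})

test_that("misaligned or degenerate inputs are rejected", {
  tab <- tiny_table()
  a <- simulate_uptake(tab, 8, coupling_spec(), seed = 55)
  b <- a[, rev(colnames(a))]
  expect_error(regional_ttests(a, b), class = "mcnet_alignment_error")
  const_a <- a; const_a[, 1] <- 1
  const_b <- a[1:5, ]; const_b[, 1] <- 2
  expect_error(regional_ttests(const_a, const_b),
               class = "mcnet_degenerate_error")
})

test_that("permutation p is deterministic under a fixed seed", {
  tab <- make_region_table(6, 2, 2)
  a <- simulate_uptake(tab, 10, coupling_spec(), seed = 56)
  b <- simulate_uptake(tab, 9, coupling_spec(), seed = 57)
  grid <- seq(0.1, 0.4, by = 0.1)
  r1 <- permute_network_metric(a, b, metrics = "Cp", grid = grid,
                               n_perm = 99, seed = 58)
  r2 <- permute_network_metric(a, b, metrics = "Cp", grid = grid,
                               n_perm = 99, seed = 58)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$observed, r2$observed)
  expect_true(r1$p > 0 && r1$p <= 1)
})

test_that("swapping group labels flips the observed sign, not the p-value", {
  tab <- make_region_table(6, 2, 2)
  a <- simulate_uptake(tab, 4, epileptic_coupling(tab), seed = 59)
  b <- simulate_uptake(tab, 4, coupling_spec(), seed = 60)
  grid <- seq(0.1, 0.4, by = 0.1)
  # exhaustive enumeration (all C(8,4) relabelings) makes the label-exchange
  # invariance exact: the relabeling set is closed under swapping the groups
  r_ab <- suppressMessages(permute_network_metric(
    a, b, metrics = "Cp", grid = grid, n_perm = 99, seed = 61))
  r_ba <- suppressMessages(permute_network_metric(
    b, a, metrics = "Cp", grid = grid, n_perm = 99, seed = 61))
  expect_true(r_ab$exact && r_ba$exact)
  expect_equal(r_ab$observed, -r_ba$observed, tolerance = 1e-12)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-12)
})

test_that("small cohorts trigger exact enumeration of all relabelings", {
  tab <- tiny_table()
  a <- simulate_uptake(tab, 4, coupling_spec(), seed = 62)
  b <- simulate_uptake(tab, 4, coupling_spec(), seed = 63)
  expect_message(
    r <- permute_network_metric(a, b, metrics = "Cp",
                                grid = seq(0.2, 0.4, by = 0.1),
                                n_perm = 100, seed = 64),
    "exhaustively")
  expect_true(r$exact)
  expect_equal(r$n_perm, choose(8, 4))
  # exact p is seed-free
  r2 <- suppressMessages(permute_network_metric(
    a, b, metrics = "Cp", grid = seq(0.2, 0.4, by = 0.1),
    n_perm = 100, seed = 999))
  expect_equal(r$p, r2$p)
})

test_that("seed-edge contrast flags disease-specific connections", {
  tab <- make_region_table()
  a <- simulate_uptake(tab, 17, epileptic_coupling(tab), seed = 65)
  b <- simulate_uptake(tab, 14, control_coupling(tab), seed = 66)
  sa <- seed_correlations(a, "Insula")
  sb <- seed_correlations(b, "Insula")
  ct <- seed_edge_contrast(sa, sb)
  expect_equal(sum(ct$a_not_b), sum(sa$significant & !sb$significant))
  # self-contrast has no flags
  self <- seed_edge_contrast(sa, sa)
  expect_equal(sum(self$a_not_b), 0)
  # permuted region order is an alignment error
  sb_perm <- sb[rev(seq_len(nrow(sb))), ]
  expect_error(seed_edge_contrast(sa, sb_perm),
               class = "mcnet_alignment_error")
})
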