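# community_profile: relative abundance, EF and its permutation test,
# Bray-Curtis, PCoA, PERMANOVA.

test_that("count_table validates counts and metadata", {
  counts <- matrix(1:4, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), donor = "D1",
                     treatment = "none", fraction = "bulk", timepoint_h = 0)
  expect_s3_class(count_table(counts, meta), "count_table")
  expect_error(count_table(-counts, meta), "non-negative")
  expect_error(count_table(counts + 0.5, meta), "non-negative integers")
  expect_error(count_table(counts, meta[, -2]), "lacks column")
  expect_error(count_table(counts, rbind(meta, meta[1, ])), "duplicate")
  bad <- meta; bad$sample_id <- c("s1", "sX")
  expect_error(count_table(counts, bad), "do not match")
})

test_that("relative_abundance normalizes columns and flags empty samples", {
  expect_equal(relative_abundance(matrix(c(2, 2), 2, 1,
                                         dimnames = list(c("a", "b"), "s1")))[, 1],
               c(a = 0.5, b = 0.5))
  expect_equal(relative_abundance(matrix(c(0, 5), 2, 1,
                                         dimnames = list(c("a", "b"), "s1")))[, 1],
               c(a = 0, b = 1))
  set.seed(31)
  m <- matrix(rpois(60, 20), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  expect_true(all(abs(colSums(relative_abundance(m)) - 1) < 1e-12))
  m[, 3] <- 0
  expect_error(relative_abundance(m), "s3")
})

test_that("enrichment_factor: arithmetic, antisymmetry, bounds, domain", {
  expect_equal(enrichment_factor(0.05, 0.05), 0)
  expect_equal(enrichment_factor(0.08, 0), 1)
  expect_equal(enrichment_factor(0.06, 0.02), 0.5)
  expect_equal(enrichment_factor(0, 0), 0)
  expect_error(enrichment_factor(-0.1, 0.2), "non-negative")
  set.seed(37)
  a <- runif(100); b <- runif(100)
  ef <- enrichment_factor(a, b)
  expect_equal(ef, -enrichment_factor(b, a))
  expect_true(all(ef >= -1 & ef <= 1))
})

test_that("ef_table: null contrast, planted doubling, single donor", {
  # identical treat and ref counts -> all EF 0
  ct <- toy_count_table()
  ef0 <- ef_table(ct, treat_sel(), ref_sel())
  expect_equal(ef0$ef, rep(0, 3))

  # one genus doubled in every treat sample -> largest positive cohort EF
  ct2 <- toy_count_table(count_fun = function(donor, group) {
    if (group == "treat") c(20L, 20L, 30L) else c(10L, 20L, 30L)
  })
  ef2 <- ef_table(ct2, treat_sel(), ref_sel())
  expect_equal(ef2$genus[which.max(ef2$ef)], "gA")
  expect_gt(ef2$ef[ef2$genus == "gA"], 0)
  expect_true(all(ef2$ef[ef2$genus != "gA"] < 0))  # others rescaled down

  # single-donor cohort EF equals that donor's EF
  ct1 <- toy_count_table(donors = "D1", count_fun = function(donor, group) {
    if (group == "treat") c(30L, 10L, 10L) else c(10L, 10L, 30L)
  })
  ef1 <- ef_table(ct1, treat_sel(), ref_sel())
  expect_equal(ef1$ef, ef1$ef_D1)

  expect_error(ef_table(ct, list(fraction = "nope"), ref_sel()),
               "matches no samples")
})

test_that("ef_permutation_test matches the brute-force enumeration oracle", {
  set.seed(43)
  ct <- toy_count_table(count_fun = function(donor, group) {
    base <- c(10L, 20L, 30L)
    bump <- if (group == "treat") c(15L, 0L, 0L) else c(0L, 0L, 0L)
    as.integer(base + bump + rpois(3, 3))
  })
  oracle <- oracle_ef_perm(ct, n_rep_treat = 2)
  got <- ef_permutation_test(ct, treat_sel(), ref_sel(), n_perm = 999)
  expect_true(attr(got, "exhaustive"))
  expect_equal(attr(got, "n_permutations"), oracle$n)  # 6 * 6 = 36
  expect_equal(got$ef, unname(oracle$ef), tolerance = 1e-12)
  expect_equal(got$p, unname(oracle$p), tolerance = 1e-12)

  # sampled branch converges to the enumeration p
  got_s <- ef_permutation_test(ct, treat_sel(), ref_sel(), n_perm = 4000,
                               seed = 7, method = "sample")
  tol <- 3 * sqrt(pmax(oracle$p * (1 - oracle$p), 0.25 / 36) / 4000) +
    2 / 4001
  expect_true(all(abs(got_s$p - oracle$p) < tol))
})

test_that("ef_permutation_test: identical samples give p = 1, BH is step-up", {
  ct <- toy_count_table()  # every sample identical
  got <- ef_permutation_test(ct, treat_sel(), ref_sel(), n_perm = 999)
  expect_equal(got$p, rep(1, 3))
  expect_equal(got$p_adj, rep(1, 3))

  # BH oracle: step-up formula computed directly
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(47)
  praw <- runif(20)
  bh <- p.adjust(praw, "BH")
  o <- order(praw)
  manual <- rev(cummin(rev(praw[o] * 20 / seq_len(20))))
  expect_equal(bh[o], pmin(manual, 1))
  expect_true(all(bh >= praw))
  expect_true(all(diff(bh[o]) >= -1e-15))
})

test_that("bray_curtis: trivial pairs, hand value, vegan oracle", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(bray_curtis(m)[1, 2], 0)
  m2 <- cbind(s1 = c(1, 0, 2), s2 = c(0, 3, 0))
  expect_equal(bray_curtis(m2)[1, 2], 1)
  m3 <- cbind(x = c(2, 0, 1), y = c(1, 1, 1))
  expect_equal(bray_curtis(m3)[1, 2], 1 / 3)

  set.seed(53)
  m4 <- matrix(rpois(50, 10) + 1, 5, 10)
  colnames(m4) <- paste0("s", 1:10)
  d <- bray_curtis(m4)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0) && all(d >= 0 & d <= 1))
  skip_if_not_installed("vegan")
  ref <- as.matrix(vegan::vegdist(t(m4), method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)

  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "all zero")
})

test_that("pcoa: analytic geometries and Euclidean self-consistency", {
  # two points at distance d -> axis-1 coordinates +/- d/2
  d <- matrix(c(0, 3, 3, 0), 2, 2)
  ord <- pcoa(d)
  expect_equal(sort(ord$coordinates[, 1]), c(-1.5, 1.5))

  # three mutually equidistant points -> two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- pcoa(d3)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # Euclidean distances are reproduced exactly
  set.seed(59)
  xy <- matrix(rnorm(16), 8, 2)
  de <- euclid_dist(xy)
  orde <- pcoa(de)
  expect_equal(euclid_dist(orde$coordinates), de, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(orde$n_negative, 0)
  expect_true(all(diff(orde$eigenvalues) <= 1e-9))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("permanova: sampled vs exhaustive on an n = 6 toy, separation limit", {
  d <- matrix(5, 6, 6)
  d[1:3, 1:3] <- matrix(c(0, 1, 1.2, 1, 0, 0.8, 1.2, 0.8, 0), 3, 3)
  d[4:6, 4:6] <- matrix(c(0, 0.9, 1.1, 0.9, 0, 1.0, 1.1, 1.0, 0), 3, 3)
  g <- rep(c("a", "b"), each = 3)

  exh <- permanova(d, g, n_perm = 10000, method = "auto")
  expect_true(exh$exhaustive)
  samp <- permanova(d, g, n_perm = 10000, seed = 61, method = "sample")
  tol <- 3 * sqrt(exh$p * (1 - exh$p) / 10000) + 2 / 10001
  expect_lt(abs(samp$p - exh$p), tol)

  # tight separated clusters: minimal attainable p, R^2 > 0.9
  expect_equal(exh$p, 2 / 20)  # 2 of the 20 distinct splits tie the max F
  expect_gt(exh$r2, 0.9)

  expect_error(permanova(d, rep("a", 6), 99), "2 groups")
  expect_error(permanova(d, c("a", "b", "c", "d", "e", "f"), 99),
               "degenerate")
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  set.seed(67)
  m <- matrix(rpois(120, 15) + 1, 8, 15)
  colnames(m) <- paste0("s", 1:15)
  g <- rep(c("x", "y", "z"), each = 5)
  d <- bray_curtis(relative_abundance(m))
  mine <- permanova(d, g, n_perm = 99, seed = 1, method = "sample")
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(mine$f, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("count table TSV round-trips through read/write", {
  sim <- generate_count_table(community_spec(n_donors = 2, n_genera = 8,
                                             reads_per_sample = 500),
                              seed = 71)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(sim$table, cpath, mpath)
  back <- read_count_table(cpath, mpath)
  expect_equal(back$counts, sim$table$counts)
  expect_equal(back$meta$donor, sim$table$meta$donor)
})
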