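# Fixtures and independent oracles shared across test files. Oracles here
# are deliberately naive (loops, direct formulas) so they stay independent
# of the implementation paths they check.

# Independent trapezoid oracle on raw arrays.
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  s
}

default_grid <- function() seq(400, 3200, by = 1)

flat_spectrum <- function(value = 1, grid = default_grid(), id = "flat") {
  raman_spectrum(grid, rep(value, length(grid)), cell_id = id)
}

# Gaussian band of given area on an optional linear baseline.
gauss_spectrum <- function(area, center, sigma, offset = 0, slope = 0,
                           grid = default_grid(), id = "gauss") {
  y <- offset + slope * (grid - min(grid)) + area * dnorm(grid, center, sigma)
  raman_spectrum(grid, y, cell_id = id)
}

# Small donor-paired count table built by hand: `n_rep` treat and ref
# samples per donor, counts supplied per genus as a function(donor, group).
toy_count_table <- function(donors = c("D1", "D2"), n_rep = 2,
                            genera = c("gA", "gB", "gC"),
                            count_fun = function(donor, group) {
                              c(10L, 20L, 30L)
                            }) {
  meta <- expand.grid(replicate = seq_len(n_rep),
                      fraction = c("boncat_pos", "dapi_neg"),
                      donor = donors, stringsAsFactors = FALSE)
  meta$treatment <- ifelse(meta$fraction == "boncat_pos", "lactulose", "none")
  meta$timepoint_h <- 6
  meta$sample_id <- sprintf("%s_%s_r%d", meta$donor, meta$fraction,
                            meta$replicate)
  counts <- sapply(seq_len(nrow(meta)), function(i) {
    count_fun(meta$donor[i],
              if (meta$fraction[i] == "boncat_pos") "treat" else "ref")
  })
  rownames(counts) <- genera
  colnames(counts) <- meta$sample_id
  count_table(counts, meta)
}

treat_sel <- function() list(fraction = "boncat_pos", treatment = "lactulose")
ref_sel <- function() list(fraction = "dapi_neg", treatment = "none")

# Brute-force cohort-EF permutation oracle: enumerates every within-donor
# reassignment directly from the count matrix with plain loops.
oracle_ef_perm <- function(ct, n_rep_treat) {
  ra <- sweep(ct$counts, 2, colSums(ct$counts), "/")
  meta <- ct$meta
  donors <- unique(meta$donor)
  pools <- lapply(donors, function(d) which(meta$donor == d))
  cohort_ef <- function(treat_cols_by_donor) {
    efs <- sapply(seq_along(donors), function(i) {
      tr <- treat_cols_by_donor[[i]]
      rf <- setdiff(pools[[i]], tr)
      mt <- rowMeans(ra[, tr, drop = FALSE])
      mr <- rowMeans(ra[, rf, drop = FALSE])
      ifelse(mt + mr == 0, 0, (mt - mr) / (mt + mr))
    })
    rowMeans(efs)
  }
  obs_treat <- lapply(donors, function(d) {
    which(meta$donor == d & meta$fraction == "boncat_pos")
  })
  obs <- cohort_ef(obs_treat)
  combos <- lapply(pools, function(p) combn(p, n_rep_treat, simplify = FALSE))
  grid <- expand.grid(lapply(combos, seq_along))
  exceed <- rep(0, nrow(ra))
  for (r in seq_len(nrow(grid))) {
    assign <- lapply(seq_along(combos), function(i) combos[[i]][[grid[r, i]]])
    exceed <- exceed + (abs(cohort_ef(assign)) >= abs(obs) - 1e-12)
  }
  list(ef = obs, p = exceed / nrow(grid), n = nrow(grid))
}

# Euclidean distance matrix from a coordinate matrix (rows = points).
euclid_dist <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
  }
  rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  d
}
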