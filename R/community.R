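# Sorted-fraction community statistics: count tables, relative abundance,
# the signed enrichment factor (EF) with within-donor permutation inference
# and BH correction, Bray-Curtis dissimilarity, classical PCoA and
# PERMANOVA implemented from the distance-partitioning definition.

#' Construct a genus x sample count table
#'
#' @param counts Non-negative integer matrix, taxa in rows, samples in
#'   columns; rownames are genus labels, colnames sample ids.
#' @param meta data.frame of per-sample metadata with columns `sample_id`,
#'   `donor`, `treatment`, `fraction`, `timepoint_h` (and optionally
#'   `replicate`); one row per sample, complete (no NA) in those columns.
#' @return A `count_table` object (list with `counts`, `meta`).
#' @export
count_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_table: counts needs row (genus) and column (sample) names")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("count_table: counts must be non-negative integers")
  }
  required <- c("sample_id", "donor", "treatment", "fraction", "timepoint_h")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop(sprintf("count_table: metadata lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) stop("count_table: duplicate sample ids")
  if (anyNA(meta[required])) stop("count_table: incomplete sample metadata")
  if (!setequal(colnames(counts), meta$sample_id)) {
    stop("count_table: sample ids in counts and metadata do not match")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table: %d genera x %d samples, %d donors>\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$donor))))
  invisible(x)
}

#' Relative abundance
#'
#' @param table A `count_table` or a non-negative matrix (taxa x samples).
#' @return Matrix of fractions; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[which(tot == 0)[1L]]
    stop(sprintf("relative_abundance: sample '%s' has zero total count", bad))
  }
  sweep(m, 2L, tot, "/")
}

#' Signed enrichment factor
#'
#' `EF = (ra_treat - ra_ref) / (ra_treat + ra_ref)`, the symmetric bounded
#' contrast of two relative abundances: +1 means present only under
#' treatment, -1 only in the reference, 0 no change. Defined as 0 when both
#' abundances are 0 (an absent genus carries no signal). Vectorized.
#'
#' @param ra_treat,ra_ref Non-negative relative abundances.
#' @return EF in \[-1, 1\].
#' @export
enrichment_factor <- function(ra_treat, ra_ref) {
  if (any(ra_treat < 0) || any(ra_ref < 0)) {
    stop("enrichment_factor: abundances must be non-negative")
  }
  s <- ra_treat + ra_ref
  ifelse(s == 0, 0, (ra_treat - ra_ref) / s)
}

# Match sample indices against a named selector list,
# e.g. list(fraction = "boncat_pos", treatment = "lactulose").
match_samples <- function(meta, selector) {
  keep <- rep(TRUE, nrow(meta))
  for (field in names(selector)) {
    if (!field %in% names(meta)) {
      stop(sprintf("selector field '%s' not in metadata", field))
    }
    keep <- keep & meta[[field]] == selector[[field]]
  }
  which(keep)
}

# Shared scaffolding for ef_table / ef_permutation_test: per-donor column
# indices of treat and ref samples, plus the RA matrix.
.ef_design <- function(table, treat, ref, pairing = "donor") {
  stopifnot(inherits(table, "count_table"))
  meta <- table$meta
  t_idx <- match_samples(meta, treat)
  r_idx <- match_samples(meta, ref)
  if (!length(t_idx)) stop("ef_table: treatment selector matches no samples")
  if (!length(r_idx)) stop("ef_table: reference selector matches no samples")
  donors <- sort(unique(meta[[pairing]][c(t_idx, r_idx)]))
  per_donor <- lapply(donors, function(d) {
    list(treat = t_idx[meta[[pairing]][t_idx] == d],
         ref = r_idx[meta[[pairing]][r_idx] == d])
  })
  names(per_donor) <- donors
  ok <- vapply(per_donor, function(x) length(x$treat) >= 1L && length(x$ref) >= 1L,
               logical(1L))
  if (!all(ok)) {
    stop(sprintf("ef_table: donor(s) %s lack samples in one group",
                 paste(donors[!ok], collapse = ", ")))
  }
  list(ra = relative_abundance(table), donors = donors, per_donor = per_donor)
}

# EF per genus for one donor given RA column indices.
.donor_ef <- function(ra, treat_cols, ref_cols) {
  mt <- rowMeans(ra[, treat_cols, drop = FALSE])
  mr <- rowMeans(ra[, ref_cols, drop = FALSE])
  enrichment_factor(mt, mr)
}

#' Per-genus enrichment factors between two sorted fractions
#'
#' For every genus and donor, the EF of the donor's mean relative abundance
#' under the treatment selector versus the reference selector; the cohort EF
#' is the unweighted mean over donors (donors are the replication unit).
#' `baseline_ra` is the mean relative abundance across the reference
#' samples.
#'
#' @param table A `count_table`.
#' @param treat,ref Named selector lists matched against the metadata, e.g.
#'   `list(fraction = "boncat_pos", treatment = "lactulose")`.
#' @param pairing Metadata column defining the pairing unit (default
#'   `"donor"`).
#' @return data.frame: `genus`, `ef` (cohort), `baseline_ra`, `n_samples`,
#'   then one `ef_<donor>` column per donor.
#' @export
ef_table <- function(table, treat, ref, pairing = "donor") {
  d <- .ef_design(table, treat, ref, pairing)
  per <- vapply(d$per_donor,
                function(x) .donor_ef(d$ra, x$treat, x$ref),
                numeric(nrow(d$ra)))
  per <- matrix(per, nrow = nrow(d$ra),
                dimnames = list(rownames(d$ra), paste0("ef_", d$donors)))
  ref_cols <- unlist(lapply(d$per_donor, `[[`, "ref"))
  out <- data.frame(
    genus = rownames(d$ra),
    ef = rowMeans(per),
    baseline_ra = rowMeans(d$ra[, ref_cols, drop = FALSE]),
    n_samples = length(unlist(lapply(d$per_donor, unlist))),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(per))
}

# All ways to choose which of a donor's pooled samples count as "treat",
# as a list of index vectors into the pooled columns.
.donor_assignments <- function(pool_size, n_treat) {
  combos <- utils::combn(pool_size, n_treat)
  lapply(seq_len(ncol(combos)), function(j) combos[, j])
}

#' Permutation test on the cohort enrichment factor
#'
#' Significance of per-genus cohort EFs under a null that permutes the
#' treat/ref group assignment within each donor (donor structure is never
#' broken). Two-sided: the null counts permutations with `|EF| >= |EF_obs|`.
#' When the number of distinct within-donor reassignments is at most
#' `n_perm` the null is enumerated exhaustively (p = exceedance fraction
#' over all reassignments, the identity included); otherwise `n_perm`
#' random reassignments are drawn and the add-one estimator
#' `p = (1 + #exceed) / (1 + n_perm)` is used so p is never 0. P-values are
#' Benjamini-Hochberg adjusted across genera.
#'
#' This permutation test deliberately replaces a parametric count-model
#' (negative-binomial Wald) analysis: it makes no distributional assumption
#' beyond within-donor exchangeability of group labels.
#'
#' @inheritParams ef_table
#' @param n_perm Maximum number of permutations (>= 1).
#' @param seed Optional RNG seed for the sampled branch.
#' @param method `"auto"` (enumerate when the number of distinct
#'   reassignments is within `n_perm`), `"sample"`, or `"exhaustive"`.
#' @return data.frame as [ef_table()] plus `p`, `p_adj`, and attribute
#'   `n_permutations` / `exhaustive`.
#' @export
ef_permutation_test <- function(table, treat, ref, pairing = "donor",
                                n_perm = 999, seed = NULL,
                                method = c("auto", "sample", "exhaustive")) {
  method <- match.arg(method)
  if (n_perm < 1) stop("ef_permutation_test: n_perm must be >= 1")
  d <- .ef_design(table, treat, ref, pairing)
  obs <- ef_table(table, treat, ref, pairing)
  nd <- length(d$donors)
  pools <- lapply(d$per_donor, function(x) c(x$treat, x$ref))
  n_treat <- vapply(d$per_donor, function(x) length(x$treat), integer(1L))
  n_distinct <- prod(vapply(seq_len(nd),
                            function(i) choose(length(pools[[i]]), n_treat[i]),
                            numeric(1L)))
  if (n_distinct < 2) {
    stop("ef_permutation_test: degenerate design, fewer than 2 distinct permutations")
  }
  abs_obs <- abs(obs$ef)
  exceed <- integer(nrow(d$ra))

  ef_for <- function(assign) {
    # assign[[i]]: indices into pools[[i]] taken as treat
    per <- vapply(seq_len(nd), function(i) {
      pool <- pools[[i]]
      tr <- pool[assign[[i]]]
      rf <- pool[-assign[[i]]]
      .donor_ef(d$ra, tr, rf)
    }, numeric(nrow(d$ra)))
    rowMeans(matrix(per, nrow = nrow(d$ra)))
  }

  exhaustive <- method == "exhaustive" ||
    (method == "auto" && n_distinct <= n_perm)
  if (exhaustive && n_distinct > 1e6) {
    stop("ef_permutation_test: exhaustive enumeration infeasible for this design")
  }
  if (exhaustive) {
    per_donor_assign <- lapply(seq_len(nd), function(i) {
      .donor_assignments(length(pools[[i]]), n_treat[i])
    })
    grid <- expand.grid(lapply(per_donor_assign, seq_along))
    for (row in seq_len(nrow(grid))) {
      assign <- lapply(seq_len(nd),
                       function(i) per_donor_assign[[i]][[grid[row, i]]])
      ef_p <- ef_for(assign)
      exceed <- exceed + (abs(ef_p) >= abs_obs - 1e-12)
    }
    p <- exceed / nrow(grid)
    n_used <- nrow(grid)
  } else {
    if (!is.null(seed)) set.seed(seed)
    for (b in seq_len(n_perm)) {
      assign <- lapply(seq_len(nd), function(i) {
        sample.int(length(pools[[i]]), n_treat[i])
      })
      ef_p <- ef_for(assign)
      exceed <- exceed + (abs(ef_p) >= abs_obs - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  obs$p <- p
  obs$p_adj <- stats::p.adjust(p, method = "BH")
  attr(obs, "n_permutations") <- n_used
  attr(obs, "exhaustive") <- exhaustive
  obs
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / sum(x_i + y_i)` between sample
#' columns; identical profiles score 0, disjoint supports 1. Works on
#' counts or fractions (the statistic is scale-dependent, so pass
#' relative abundances for compositional comparisons).
#'
#' @param x Matrix, taxa in rows, samples in columns.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2L) stop("bray_curtis: need at least 2 samples")
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[which(tot == 0)[1L]]
    stop(sprintf("bray_curtis: sample '%s' is all zero", if (is.null(bad)) "?" else bad))
  }
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(pmin(m[, i], m[, j]))
      d[i, j] <- d[j, i] <- 1 - 2 * shared / (tot[i] + tot[j])
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square root of their (positive) eigenvalues. Negative eigenvalues --
#' which arise for non-Euclidean dissimilarities such as Bray-Curtis -- are
#' dropped (no Lingoes/Cailliez correction) and reported; variance explained
#' is taken over the positive spectrum.
#'
#' @param dist Square symmetric dissimilarity matrix with zero diagonal.
#' @return List: `coordinates` (samples x axes), `eigenvalues` (all, in
#'   non-increasing order), `variance_explained` (positive axes),
#'   `n_negative`.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) stop("pcoa: matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("pcoa: matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("pcoa: diagonal must be zero")
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = e$values,
       variance_explained = e$values[pos] / sum(e$values[pos]),
       n_negative = sum(e$values < -tol))
}

# Pseudo-F and R^2 for one labeling, from the precomputed squared-distance
# matrix. SS_total = sum_{i<j} d^2/n; SS_within analogously per group.
.permanova_stat <- function(d2, g) {
  n <- nrow(d2)
  k <- length(unique(g))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  c(f = f, r2 = ss_between / ss_total)
}

# All permutations of 1..n (n small), as a matrix with one row per
# permutation. Used for exhaustive PERMANOVA enumeration.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' PERMANOVA (one-way, from the distance partition)
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within`
#' from within-group pairs analogously, pseudo-F =
#' `(SS_between/(k-1)) / (SS_within/(n-k))`, `R^2 = SS_between/SS_total`.
#' Significance by permuting group labels; exhaustively (all `n!` label
#' orderings, p = exceedance fraction including the identity) when `n!` is
#' within `n_perm` and `n <= 8`, otherwise by `n_perm` random permutations
#' with the add-one estimator.
#'
#' @param dist Square symmetric dissimilarity matrix (or `dist`).
#' @param grouping Group labels, one per sample.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param method `"auto"` (enumerate when feasible), `"sample"`, or
#'   `"exhaustive"` (error if infeasible).
#' @return List of class `permanova`: `r2`, `f`, `p`, `n_permutations`,
#'   `exhaustive`.
#' @export
permanova <- function(dist, grouping, n_perm = 999, seed = NULL,
                      method = c("auto", "sample", "exhaustive")) {
  method <- match.arg(method)
  d <- as.matrix(dist)
  g <- as.character(grouping)
  n <- nrow(d)
  if (length(g) != n) stop("permanova: grouping length must match the matrix")
  k <- length(unique(g))
  if (k < 2L) stop("permanova: need at least 2 groups")
  if (n - k < 1L) {
    stop("permanova: degenerate design, no within-group degrees of freedom")
  }
  if (n_perm < 1) stop("permanova: n_perm must be >= 1")
  d2 <- d^2
  obs <- .permanova_stat(d2, g)
  feasible <- n <= 8L && factorial(n) <= n_perm
  if (method == "exhaustive" && !feasible && n > 8L) {
    stop("permanova: exhaustive enumeration infeasible for n > 8")
  }
  use_exhaustive <- method == "exhaustive" || (method == "auto" && feasible)
  if (use_exhaustive) {
    perms <- .all_perms(n)
    fs <- apply(perms, 1L, function(idx) .permanova_stat(d2, g[idx])["f"])
    p <- mean(fs >= obs["f"] - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      fs <- .permanova_stat(d2, g[sample.int(n)])["f"]
      exceed <- exceed + (fs >= obs["f"] - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(r2 = unname(obs["r2"]), f = unname(obs["f"]), p = p,
                 n_permutations = n_used, exhaustive = use_exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("<permanova: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%s, %d perms)>\n",
              x$r2, x$f, x$p,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Read a count table and metadata from tab-separated files
#'
#' Counts: first column genus, remaining columns samples. Metadata: one row
#' per sample keyed by `sample_id`.
#'
#' @param counts_path,meta_path File paths.
#' @return A `count_table`.
#' @export
read_count_table <- function(counts_path, meta_path) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(counts) <- raw[[1L]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  count_table(counts, meta)
}

#' Write a count table and metadata as tab-separated files
#'
#' @param table A `count_table`.
#' @param counts_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_table <- function(table, counts_path, meta_path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(genus = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, meta_path))
}
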