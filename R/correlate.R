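two_sided_t_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  ex <- ok & abs(r) >= 1
  p[ex] <- 0
  mid <- ok & !ex
  if (any(mid)) {
    tval <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
    p[mid] <- 2 * pt(-abs(tval), df = n - 2)
  }
  p
}

pair_pearson <- function(x, y) {
  n <- length(x)
  if (n < 3) return(c(r = NA_real_, p = NA_real_))
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) return(c(r = NA_real_, p = NA_real_))
  r <- sum(dx * dy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  c(r = r, p = two_sided_t_p(r, n))
}

pair_spearman <- function(x, y) pair_pearson(rank(x), rank(y))

pair_kendall <- function(x, y) {
  n <- length(x)
  if (n < 3) return(c(r = NA_real_, p = NA_real_))
  # S = C - D via the sign-product sum; tau-b with tie corrections
  S <- sum(sign(outer(x, x, "-")) * sign(outer(y, y, "-"))) / 2
  n0 <- n * (n - 1) / 2
  tx <- tabulate(match(x, unique(x)))
  ty <- tabulate(match(y, unique(y)))
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(c(r = NA_real_, p = NA_real_))
  tau <- max(-1, min(1, S / den))
  z <- 3 * S / sqrt(n * (n - 1) * (2 * n + 5) / 2)
  c(r = tau, p = 2 * pnorm(-abs(z)))
}

pair_cor <- function(x, y, method) {
  switch(method,
    pearson = pair_pearson(x, y),
    spearman = pair_spearman(x, y),
    kendall = pair_kendall(x, y),
    abort(sprintf("unknown correlation method '%s'", method))
  )
}

#' Pairwise correlation coefficients with parametric p-values
#'
#' Product-moment (Pearson), mid-rank (Spearman) and tie-corrected tau-b
#' (Kendall) coefficients. P-values are two-sided parametric
#' approximations: a t statistic `r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom for Pearson and Spearman, and the normal
#' approximation `z = 3S / sqrt(n(n-1)(2n+5)/2)` (with `S = C - D`) for
#' Kendall. A constant vector makes the coefficient undefined: `r` and `p`
#' are returned as `NA` rather than a fabricated 0.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with `r`, `p`, `n` and `method`.
#' @export
pearson_cor <- function(x, y) cor_wrap(x, y, "pearson")

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) cor_wrap(x, y, "spearman")

#' @rdname pearson_cor
#' @export
kendall_tau_b <- function(x, y) cor_wrap(x, y, "kendall")

cor_wrap <- function(x, y, method) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  est <- pair_cor(x, y, method)
  list(r = unname(est[1]), p = unname(est[2]), n = length(x), method = method)
}

# Full-matrix coefficient fast path for whole-profile policies: rows are
# taxa. Own crossprod implementation (kept independent of stats::cor so that
# the latter remains an external oracle in the tests).
cor_matrix <- function(mat, method) {
  X <- if (method == "spearman") t(apply(mat, 1, rank)) else mat
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / (n - 1)
  sds <- sqrt(diag(S))
  R <- S / tcrossprod(sds)
  R[!is.finite(R)] <- NA_real_
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- ifelse(sds > 0, 1, NA_real_)
  R
}

#' Sequential pairwise correlation over all taxon pairs
#'
#' For every unordered taxon pair the chosen zero policy is applied via the
#' pair-level masking rules, then the chosen coefficient is computed.
#' Pairs failing the minimum-overlap rule (strictly more than `min_overlap`
#' paired valid observations; applied to policies 4-6 unless
#' `apply_min_overlap_all`) and pairs with undefined coefficients are
#' omitted and tallied in the skip log (see [skip_log()]). Profiles should
#' already be profile-level treated for policies 1-3 (for policy 3 an
#' untreated profile is pseudo-filled on the fly, which is equivalent). On
#' CLR-transformed profiles the pre-transform zero mask recorded by
#' [clr_transform()] drives the masking, and no pseudo-fill is applied
#' (any fill happened before the transform).
#'
#' Output is canonical: taxon IDs sorted within and across pairs, hence
#' independent of input row order.
#'
#' @param profile a profile tibble.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param policy policy code/name 1-6.
#' @param min_overlap strict overlap bound (default 30).
#' @param pseudo_value fill value for policies 3 and 4.
#' @param apply_min_overlap_all extend the overlap rule to policies 1-3.
#' @return Tibble with columns `taxon_i`, `taxon_j`, `r`, `p`, `n_valid`,
#'   `method`, `policy`, one row per retained pair.
#' @export
correlate_all <- function(profile,
                          method = c("pearson", "spearman", "kendall"),
                          policy = 1,
                          min_overlap = 30,
                          pseudo_value = 0.01,
                          apply_min_overlap_all = FALSE) {
  method <- match.arg(method)
  pol <- filter_policy(policy, pseudo_value)
  mat <- profile_matrix(profile)
  meta <- profile_meta(profile)
  ord <- order(rownames(mat))
  mat <- mat[ord, , drop = FALSE]
  is_clr <- identical(meta$transform, "clr")
  zmask <- if (is_clr && !is.null(meta$zero_mask)) {
    meta$zero_mask[ord, , drop = FALSE]
  } else {
    mat == 0
  }
  fill_unpaired <- !is_clr
  D <- nrow(mat)
  n <- ncol(mat)
  ids <- rownames(mat)
  empty <- tibble::tibble(
    taxon_i = character(0), taxon_j = character(0),
    r = double(0), p = double(0), n_valid = integer(0),
    method = character(0), policy = integer(0)
  )
  if (D < 2) return(structure(empty, skip_log = skip_log_tbl(0L, 0L)))

  pairs <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  nv <- n_valid_matrix(zmask, pol$code)
  nv_pair <- nv[pairs]
  overlap_applies <- pol$code %in% 4:6 || apply_min_overlap_all
  eligible <- if (overlap_applies) nv_pair > min_overlap else rep(TRUE, nrow(pairs))
  n_skip_overlap <- sum(!eligible)

  r <- rep(NA_real_, nrow(pairs))
  p <- rep(NA_real_, nrow(pairs))

  whole_profile <- pol$code %in% 1:3
  if (whole_profile && method %in% c("pearson", "spearman")) {
    work <- mat
    if (pol$code == 3 && fill_unpaired) work[zmask] <- pol$pseudo_value
    R <- cor_matrix(work, method)
    r[eligible] <- R[pairs][eligible]
    p[eligible] <- two_sided_t_p(r[eligible], n)
  } else {
    for (idx in which(eligible)) {
      i <- pairs[idx, 1]; j <- pairs[idx, 2]
      f <- policy_xy(mat[i, ], mat[j, ], pol$code, pol$pseudo_value,
        zero_x = zmask[i, ], zero_y = zmask[j, ],
        fill_unpaired = fill_unpaired
      )
      est <- pair_cor(f$x, f$y, method)
      r[idx] <- est[1]
      p[idx] <- est[2]
    }
  }

  undef <- eligible & is.na(r)
  keep <- eligible & !is.na(r)
  out <- tibble::tibble(
    taxon_i = ids[pairs[keep, 1]],
    taxon_j = ids[pairs[keep, 2]],
    r = r[keep],
    p = p[keep],
    n_valid = as.integer(nv_pair[keep]),
    method = method,
    policy = pol$code
  )
  out <- dplyr::arrange(out, .data$taxon_i, .data$taxon_j)
  structure(out, skip_log = skip_log_tbl(n_skip_overlap, sum(undef)))
}

skip_log_tbl <- function(n_overlap, n_undefined) {
  tibble::tibble(
    reason = c("below_min_overlap", "undefined_coefficient"),
    n = as.integer(c(n_overlap, n_undefined))
  )
}

#' Skip log of a correlation run
#'
#' @param results tibble returned by [correlate_all()].
#' @return Tibble with columns `reason` and `n` counting omitted pairs.
#' @export
skip_log <- function(results) {
  attr(results, "skip_log") %||% skip_log_tbl(0L, 0L)
}

#' Randomly subsample correlation records
#'
#' Uniform sampling without replacement, deterministic given `seed`; the
#' returned rows keep the canonical pair order.
#'
#' @param results tibble of pair correlations.
#' @param m number of records to keep (`m <=` available rows).
#' @param seed optional integer seed.
#' @return Tibble with `m` rows.
#' @export
subsample_pairs <- function(results, m, seed = NULL) {
  if (m > nrow(results)) {
    abort(sprintf("m = %d exceeds the %d available pairs", m, nrow(results)))
  }
  pick <- function() sort(sample.int(nrow(results), m))
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  results[idx, , drop = FALSE]
}

#' Write pair correlations as a TSV edge list
#'
#' @param results tibble from [correlate_all()] or [tidy()] on a SparCC
#'   fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
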