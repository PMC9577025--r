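#' SparCC compositional correlation
#'
#' From-scratch estimator of basis correlations for compositional count
#' data. Per resampling iteration, sample fractions are drawn from a
#' per-sample Dirichlet posterior with a pseudocount prior (default 1 added
#' to each element), the log-ratio variance matrix
#' `t_ij = var(log(f_i / f_j))` is computed, and the basis variances `w`
#' are solved from the sparsity approximation
#' `t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j)` with most `rho_ij ~ 0`
#' (row-sum linear system). The most strongly correlated pair above
#' `exclusion_threshold` is then iteratively excluded from the system and
#' the basis re-solved, up to `max_exclusion_rounds` times. Final
#' correlations aggregate the resamples by median (or mean). Estimates are
#' clipped to `[-1, 1]`; a negative solved basis variance is clamped with a
#' warning rather than aborting.
#'
#' The raw, zero-containing count profile is the intended input — the
#' pair-level zero policies do not apply to SparCC.
#'
#' @param profile integer-count profile tibble with at least 4 taxa (the
#'   basis decomposition is ill-posed below).
#' @param n_resamples number of Dirichlet resampling iterations (default
#'   20).
#' @param exclusion_threshold absolute correlation above which the
#'   strongest pair is excluded each round (default 0.1).
#' @param max_exclusion_rounds maximum exclusion/re-solve rounds per
#'   resample (default 10).
#' @param pseudocount Dirichlet prior added to every count (default 1).
#' @param aggregate `"median"` (default) or `"mean"` across resamples.
#' @param seed optional integer; the estimate is deterministic given the
#'   seed.
#' @return A `sparcc_fit`: list with `taxon_ids`, `rho` (symmetric matrix,
#'   unit diagonal), `n_iterations_used`, `excluded_pairs` (tibble:
#'   `taxon_i`, `taxon_j`, `n_resamples_excluded`), `aggregate`.
#' @export
sparcc_estimate <- function(profile,
                            n_resamples = 20,
                            exclusion_threshold = 0.1,
                            max_exclusion_rounds = 10,
                            pseudocount = 1,
                            aggregate = c("median", "mean"),
                            seed = NULL) {
  aggregate <- match.arg(aggregate)
  mat <- profile_matrix(profile)
  D <- nrow(mat)
  if (D < 4) abort("SparCC needs at least 4 taxa")
  if (any(mat < 0) || any(mat != round(mat))) {
    abort("SparCC expects non-negative integer counts")
  }
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (n_resamples < 1) abort("n_resamples must be >= 1")

  run <- function() {
    arr <- array(NA_real_, c(D, D, n_resamples))
    excl <- matrix(0L, D, D)
    any_neg <- FALSE
    shape <- mat + pseudocount
    for (b in seq_len(n_resamples)) {
      fr <- apply(shape, 2, function(a) {
        g <- rgamma(D, shape = a)
        g / sum(g)
      })
      lf <- log(fr)
      cv <- cov(t(lf))
      dv <- diag(cv)
      V <- outer(dv, dv, "+") - 2 * cv
      sol <- sparcc_basis(V, exclusion_threshold, max_exclusion_rounds)
      arr[, , b] <- sol$rho
      excl <- excl + sol$excluded
      any_neg <- any_neg || sol$neg_basis
    }
    if (any_neg) {
      warn("negative basis variance encountered; affected correlations clamped")
    }
    rho <- apply(arr, c(1, 2), if (aggregate == "median") median else mean)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    dimnames(rho) <- list(rownames(mat), rownames(mat))
    ut <- which(upper.tri(excl) & excl > 0, arr.ind = TRUE)
    structure(
      list(
        taxon_ids = rownames(mat),
        rho = rho,
        n_iterations_used = n_resamples,
        excluded_pairs = tibble::tibble(
          taxon_i = rownames(mat)[ut[, 1]],
          taxon_j = rownames(mat)[ut[, 2]],
          n_resamples_excluded = excl[ut]
        ),
        aggregate = aggregate
      ),
      class = "sparcc_fit"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Solve the basis system for one log-ratio variance matrix, with iterative
# exclusion of the strongest pair.
sparcc_basis <- function(V, threshold, max_rounds) {
  D <- nrow(V)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  trow <- rowSums(V)
  excluded <- matrix(FALSE, D, D)
  neg <- FALSE
  rho <- NULL
  for (round in 0:max_rounds) {
    w <- solve(M, trow)
    if (any(w <= 0)) {
      neg <- TRUE
      w[w <= 0] <- .Machine$double.eps
    }
    rho <- (outer(w, w, "+") - V) / (2 * sqrt(outer(w, w)))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (round == max_rounds) break
    cand <- abs(rho)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    mx <- max(cand)
    if (mx <= threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    # keep the linear system well-posed
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    trow[i] <- trow[i] - V[i, j]
    trow[j] <- trow[j] - V[i, j]
    excluded[i, j] <- excluded[j, i] <- TRUE
  }
  list(rho = rho, excluded = excluded, neg_basis = neg)
}

#' Permutation p-values for a SparCC fit
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples, re-estimates the correlation matrix (with a reduced number of
#' resamples for speed) and compares magnitudes; two-sided add-one
#' estimator `p = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_permutations)`.
#'
#' @param profile the count profile used for `observed`.
#' @param observed a `sparcc_fit`.
#' @param n_permutations number of permutations (>= 1).
#' @param seed optional integer seed.
#' @param n_resamples resampling iterations per permutation (default 5).
#' @return Symmetric matrix of p-values in `[0, 1]` (`NA` diagonal).
#' @export
sparcc_pvalues <- function(profile, observed, n_permutations,
                           seed = NULL, n_resamples = 5) {
  if (!inherits(observed, "sparcc_fit")) abort("observed must be a sparcc_fit")
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    abort("n_permutations must be >= 1")
  }
  mat <- profile_matrix(profile)
  D <- nrow(mat)
  obs_abs <- abs(observed$rho)
  run <- function() {
    count <- matrix(0L, D, D)
    for (b in seq_len(n_permutations)) {
      perm <- t(apply(mat, 1, sample))
      dimnames(perm) <- dimnames(mat)
      fit <- sparcc_estimate(as_profile(perm),
        n_resamples = n_resamples, seed = NULL
      )
      count <- count + (abs(fit$rho) >= obs_abs)
    }
    p <- (1 + count) / (1 + n_permutations)
    diag(p) <- NA_real_
    dimnames(p) <- dimnames(observed$rho)
    p
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat(sprintf(
    "<sparcc_fit: %d taxa, %d resampling iterations, %s aggregate, %d pair(s) excluded>\n",
    length(x$taxon_ids), x$n_iterations_used, x$aggregate,
    nrow(x$excluded_pairs)
  ))
  invisible(x)
}

#' @describeIn sparcc_estimate tidy the fit into one row per unordered
#'   taxon pair (columns `taxon_i`, `taxon_j`, `r`, `method`).
#' @param x a `sparcc_fit`.
#' @param ... unused.
#' @method tidy sparcc_fit
#' @export
tidy.sparcc_fit <- function(x, ...) {
  ut <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(
    taxon_i = x$taxon_ids[ut[, 1]],
    taxon_j = x$taxon_ids[ut[, 2]],
    r = x$rho[ut],
    method = "sparcc"
  )
  dplyr::arrange(out, .data$taxon_i, .data$taxon_j)
}

#' @describeIn sparcc_estimate one-row summary of the fit.
#' @method glance sparcc_fit
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  tibble::tibble(
    n_taxa = length(x$taxon_ids),
    n_iterations_used = x$n_iterations_used,
    n_excluded_pairs = nrow(x$excluded_pairs),
    mean_abs_rho = mean(abs(off)),
    max_abs_rho = if (length(off)) max(abs(off)) else NA_real_
  )
}

#' @describeIn sparcc_estimate heatmap of the estimated correlation matrix.
#' @param object a `sparcc_fit`.
#' @method autoplot sparcc_fit
#' @export
autoplot.sparcc_fit <- function(object, ...) {
  df <- tidyr::expand_grid(
    taxon_i = object$taxon_ids,
    taxon_j = object$taxon_ids
  )
  df$rho <- as.vector(t(object$rho))
  ggplot2::ggplot(df, ggplot2::aes(.data$taxon_j, .data$taxon_i, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
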