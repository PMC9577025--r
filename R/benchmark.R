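#' Benchmark zero policies against the paired-exclusion standard
#'
#' Reproduces the comparative experiment at the heart of the toolkit: on a
#' zero-inflated profile, pairwise coefficients are computed under every
#' requested policy for a common random subset of taxon pairs, and compared
#' against policy 5 (paired-zero exclusion, unpaired zeros kept) as the
#' standard. Pairs are drawn from those eligible under the standard
#' (strictly more than `min_overlap` paired valid observations). Policy 2
#' applies [knn_impute()] to the whole profile first; if imputation is not
#' applicable (e.g. too few taxa) that policy is dropped with a message.
#'
#' @param profile a count profile tibble.
#' @param methods character vector of correlation methods.
#' @param policies integer vector of policy codes (5 is always included as
#'   the standard).
#' @param min_overlap strict overlap bound for pair eligibility (default
#'   30).
#' @param pseudo_value fill value for policies 3 and 4.
#' @param n_pairs number of random pairs to evaluate (default 10000,
#'   capped at availability).
#' @param r_cutoff absolute-coefficient cutoff used for the strong
#'   association counts (default 0.6).
#' @param k neighbour count for policy 2.
#' @param seed optional integer seed for the pair subsample.
#' @return A `zeronet_benchmark`: list with `pairs` (long tibble: pair,
#'   method, policy, `r`, `r_standard`, `deviation`) and `summary` (per
#'   method/policy: `mad` mean absolute deviation from the standard,
#'   `mean_abs_r`, strong positive/negative counts at `r_cutoff`,
#'   `n_pairs`). Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_benchmark <- function(profile,
                          methods = "spearman",
                          policies = 1:6,
                          min_overlap = 30,
                          pseudo_value = 0.01,
                          n_pairs = 10000,
                          r_cutoff = 0.6,
                          k = 10,
                          seed = NULL) {
  methods <- match.arg(methods, c("pearson", "spearman", "kendall"),
    several.ok = TRUE
  )
  policies <- sort(unique(c(as.integer(policies), 5L)))
  mat <- profile_matrix(profile)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  ids <- rownames(mat)
  zmask <- mat == 0
  D <- nrow(mat)
  n <- ncol(mat)
  if (D < 2) abort("benchmark needs at least 2 taxa")

  nv5 <- n - tcrossprod(zmask * 1)
  pairs <- which(upper.tri(nv5), arr.ind = TRUE)
  eligible <- nv5[pairs] > min_overlap
  pairs <- pairs[eligible, , drop = FALSE]
  if (nrow(pairs) == 0) abort("no pairs pass the minimum-overlap rule")
  m <- min(n_pairs, nrow(pairs))
  pick <- function() sort(sample.int(nrow(pairs), m))
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  pairs <- pairs[sel, , drop = FALSE]

  imputed <- NULL
  if (2L %in% policies) {
    imputed <- tryCatch(
      profile_matrix(knn_impute(profile, k = k))[rownames(mat), , drop = FALSE],
      error = function(e) {
        inform(sprintf("dropping policy 2: %s", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(imputed)) policies <- setdiff(policies, 2L)
  }

  pair_r <- function(i, j, code, method) {
    if (code == 2L) {
      est <- pair_cor(imputed[i, ], imputed[j, ], method)
    } else {
      f <- policy_xy(mat[i, ], mat[j, ], code, pseudo_value,
        zero_x = zmask[i, ], zero_y = zmask[j, ]
      )
      est <- pair_cor(f$x, f$y, method)
    }
    est[1]
  }

  rows <- list()
  for (method in methods) {
    r_std <- vapply(seq_len(nrow(pairs)), function(t) {
      pair_r(pairs[t, 1], pairs[t, 2], 5L, method)
    }, double(1))
    for (code in policies) {
      r_pol <- if (code == 5L) r_std else vapply(seq_len(nrow(pairs)), function(t) {
        pair_r(pairs[t, 1], pairs[t, 2], code, method)
      }, double(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon_i = ids[pairs[, 1]],
        taxon_j = ids[pairs[, 2]],
        method = method,
        policy = code,
        r = r_pol,
        r_standard = r_std,
        deviation = r_pol - r_std
      )
    }
  }
  long <- dplyr::bind_rows(rows)
  summary <- long |>
    dplyr::group_by(.data$method, .data$policy) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mad = mean(abs(.data$deviation), na.rm = TRUE),
      mean_abs_r = mean(abs(.data$r), na.rm = TRUE),
      n_strong_pos = sum(.data$r > r_cutoff, na.rm = TRUE),
      n_strong_neg = sum(.data$r < -r_cutoff, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(
      pairs = long, summary = summary,
      standard_policy = 5L, r_cutoff = r_cutoff,
      methods = methods, policies = policies,
      min_overlap = min_overlap
    ),
    class = "zeronet_benchmark"
  )
}

#' @export
print.zeronet_benchmark <- function(x, ...) {
  cat(sprintf(
    "<zeronet_benchmark: %d pair(s) x methods {%s} x policies {%s}; standard = policy %d>\n",
    dplyr::n_distinct(paste(x$pairs$taxon_i, x$pairs$taxon_j)),
    paste(x$methods, collapse = ", "),
    paste(x$policies, collapse = ", "),
    x$standard_policy
  ))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_benchmark per-pair coefficients and deviations.
#' @param x a `zeronet_benchmark`.
#' @param ... unused.
#' @method tidy zeronet_benchmark
#' @export
tidy.zeronet_benchmark <- function(x, ...) x$pairs

#' @describeIn run_benchmark per method/policy summary statistics.
#' @method glance zeronet_benchmark
#' @export
glance.zeronet_benchmark <- function(x, ...) x$summary

#' @describeIn run_benchmark scatter of each policy's coefficients against
#'   the policy-5 standard, faceted by method and policy.
#' @param object a `zeronet_benchmark`.
#' @method autoplot zeronet_benchmark
#' @export
autoplot.zeronet_benchmark <- function(object, ...) {
  df <- dplyr::filter(object$pairs, .data$policy != object$standard_policy)
  ggplot2::ggplot(df, ggplot2::aes(.data$r_standard, .data$r)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::facet_grid(method ~ policy, labeller = ggplot2::label_both) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(
      x = sprintf("r (policy %d standard)", object$standard_policy),
      y = "r (policy)"
    ) +
    ggplot2::theme_bw()
}
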