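policy_names <- c(
  "ZERO_AS_IS", "KNN_IMPUTE", "FILL_PSEUDO",
  "DROP_PAIRED_FILL", "DROP_PAIRED_KEEP", "COMPLETE_CASE"
)

#' Zero-value filtering policies
#'
#' Six strategies for handling zeros (treated as missing values) in
#' abundance profiles prior to pairwise correlation:
#'
#' 1. `ZERO_AS_IS` — keep zeros as 0.
#' 2. `KNN_IMPUTE` — replace zeros by k-nearest-neighbour expectations
#'    (profile level, see [knn_impute()]).
#' 3. `FILL_PSEUDO` — replace zeros by a pseudo-value (default 0.01).
#' 4. `DROP_PAIRED_FILL` — per pair, drop samples where both taxa are zero;
#'    remaining (unpaired) zeros become the pseudo-value.
#' 5. `DROP_PAIRED_KEEP` — as 4, but unpaired zeros are kept as 0.
#' 6. `COMPLETE_CASE` — per pair, drop any sample with a zero in either
#'    taxon.
#'
#' Policies 1-3 transform the whole profile; policies 4-6 act per taxon
#' pair.
#'
#' @param policy integer code 1-6 or one of the names above (a
#'   `filter_policy` object is passed through).
#' @param pseudo_value positive fill value used by policies 3 and 4.
#' @return A `filter_policy` object with fields `code`, `name`,
#'   `pseudo_value`.
#' @export
filter_policy <- function(policy, pseudo_value = 0.01) {
  if (inherits(policy, "filter_policy")) return(policy)
  if (is.character(policy)) {
    code <- match(toupper(policy), policy_names)
    if (is.na(code)) abort(sprintf("unknown filter policy '%s'", policy))
  } else {
    code <- as.integer(policy)
    if (is.na(code) || code < 1 || code > 6) {
      abort("filter policy code must be an integer in 1..6")
    }
  }
  if (!is.numeric(pseudo_value) || pseudo_value <= 0) {
    abort("pseudo_value must be > 0")
  }
  structure(
    list(code = code, name = policy_names[code], pseudo_value = pseudo_value),
    class = "filter_policy"
  )
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf("<filter_policy %d: %s (pseudo_value = %g)>\n",
    x$code, x$name, x$pseudo_value))
  invisible(x)
}

#' Apply a profile-level zero policy
#'
#' Policies 1-3 act on the whole profile: 1 is the identity, 2 imputes zeros
#' via [knn_impute()], 3 replaces every zero with `pseudo_value`. Non-zero
#' cells are never altered. Pair-level policies (4-6) are rejected here; use
#' [pair_filter()] or [correlate_all()] for those.
#'
#' @param profile a profile tibble.
#' @param policy policy code/name in 1-3 (see [filter_policy()]).
#' @param pseudo_value fill value for policy 3.
#' @param k neighbour count for policy 2.
#' @return Treated profile; for policies 2 and 3 the original zero mask is
#'   recorded in the metadata.
#' @export
treat_profile <- function(profile, policy, pseudo_value = 0.01, k = 10) {
  pol <- filter_policy(policy, pseudo_value)
  if (pol$code %in% 4:6) {
    abort(sprintf(
      "policy %d (%s) is pair-level; use pair_filter() or correlate_all()",
      pol$code, pol$name
    ))
  }
  if (pol$code == 1) {
    return(set_profile_meta(profile, filter_policy = pol$code))
  }
  if (pol$code == 2) {
    out <- knn_impute(profile, k = k)
    return(set_profile_meta(out, filter_policy = 2L))
  }
  mat <- profile_matrix(profile)
  mask <- mat == 0
  mat[mask] <- pol$pseudo_value
  as_profile(mat, meta = modifyList(
    profile_meta(profile),
    list(state = "pseudo_filled", filter_policy = 3L, zero_mask = mask)
  ))
}

#' k-nearest-neighbour imputation of zeros
#'
#' Zeros are treated as missing. Taxa are the cases: a missing value for
#' taxon i in sample s is replaced by the Gaussian-kernel-weighted mean of
#' the values at s of the k taxa nearest to i. Distance between two taxa is
#' the root-mean-square difference of `log1p` abundances over their mutually
#' observed (both non-zero) samples; kernel weight is `exp(-d^2 / 2)`.
#' Donors must be observed at the target sample and share at least one
#' mutually observed sample with the target taxon. If fewer than `k` donors
#' exist the available ones are used; a cell with no eligible donor stays 0
#' and its taxon is listed in the non-imputable report (frequent for rare
#' taxa). Observed values are returned bit-identical.
#'
#' @param profile a profile tibble.
#' @param k neighbour count (>= 1; default 10).
#' @return Imputed profile; the non-imputable report (tibble with columns
#'   `taxon_id`, `reason`) is available via [non_imputable_report()].
#' @export
knn_impute <- function(profile, k = 10) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("k must be a positive integer")
  k <- as.integer(k)
  mat <- profile_matrix(profile)
  obs <- mat > 0
  D <- nrow(mat)
  if (D < 2) abort("knn_impute() needs at least 2 taxa")
  # pairwise RMS distance over mutually observed entries, log1p scale
  L <- log1p(mat) * obs
  B <- obs * 1
  sq <- (L * L) %*% t(B) + B %*% t(L * L) - 2 * (L %*% t(L))
  cnt <- B %*% t(B)
  dmat <- sqrt(pmax(sq, 0) / pmax(cnt, 1))
  dmat[cnt == 0] <- Inf
  diag(dmat) <- Inf

  out <- mat
  reasons <- character(0)
  bad_ids <- character(0)
  for (i in seq_len(D)) {
    zs <- which(!obs[i, ])
    if (!length(zs)) next
    if (!any(obs[i, ])) {
      bad_ids <- c(bad_ids, rownames(mat)[i])
      reasons <- c(reasons, "no observed values (all-zero row)")
      next
    }
    di <- dmat[i, ]
    ord <- order(di)
    ord <- ord[is.finite(di[ord])]
    missing_cells <- 0L
    for (s in zs) {
      donors <- ord[obs[ord, s]]
      if (!length(donors)) {
        missing_cells <- missing_cells + 1L
        next
      }
      sel <- head(donors, k)
      w <- exp(-di[sel]^2 / 2)
      if (sum(w) == 0) w <- rep(1, length(sel))
      out[i, s] <- sum(w * mat[sel, s]) / sum(w)
    }
    if (missing_cells > 0L) {
      bad_ids <- c(bad_ids, rownames(mat)[i])
      reasons <- c(reasons, sprintf("no eligible donors for %d sample(s)", missing_cells))
    }
  }
  report <- tibble::tibble(taxon_id = bad_ids, reason = reasons)
  prof <- as_profile(out, meta = modifyList(
    profile_meta(profile),
    list(state = "knn_imputed", zero_mask = !obs, knn_k = k)
  ))
  attr(prof, "non_imputable") <- report
  prof
}

#' Report of taxa that could not be (fully) imputed
#'
#' @param profile a profile returned by [knn_impute()].
#' @return Tibble with columns `taxon_id` and `reason` (empty when all zeros
#'   were imputable).
#' @export
non_imputable_report <- function(profile) {
  attr(profile, "non_imputable") %||%
    tibble::tibble(taxon_id = character(0), reason = character(0))
}

#' Write the non-imputable-taxon report as TSV
#'
#' @param profile a profile returned by [knn_impute()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_non_imputable <- function(profile, path) {
  readr::write_tsv(non_imputable_report(profile), path, progress = FALSE)
  invisible(path)
}

# Core pair-level masking shared by pair_filter(), correlate_all() and the
# benchmark. zero_x/zero_y identify original zeros (they can differ from
# x == 0 after a CLR transform); fill_unpaired is switched off for CLR data,
# where the pseudo fill happened before the transform.
policy_xy <- function(x, y, code, pseudo_value,
                      zero_x = NULL, zero_y = NULL, fill_unpaired = TRUE) {
  zx <- zero_x %||% (x == 0)
  zy <- zero_y %||% (y == 0)
  keep <- switch(as.character(code),
    "1" = ,
    "2" = ,
    "3" = rep(TRUE, length(x)),
    "4" = ,
    "5" = !(zx & zy),
    "6" = !(zx | zy)
  )
  xf <- x[keep]; yf <- y[keep]
  if (code == 3 && fill_unpaired) {
    xf[zx[keep]] <- pseudo_value
    yf[zy[keep]] <- pseudo_value
  }
  if (code == 4 && fill_unpaired) {
    xf[zx[keep]] <- pseudo_value
    yf[zy[keep]] <- pseudo_value
  }
  list(x = xf, y = yf, keep = keep)
}

#' Apply a zero policy to one taxon pair
#'
#' @param x,y aligned abundance vectors for two taxa over the same samples.
#' @param policy policy code/name 1-6 (see [filter_policy()]). Policy 2 is
#'   the identity here because imputation happens at profile level.
#' @param pseudo_value fill value for policies 3 and 4.
#' @param sample_ids optional sample labels aligned with `x`.
#' @return A `filtered_pair`: list with `x`, `y`, `kept_sample_ids`,
#'   `n_valid`.
#' @export
pair_filter <- function(x, y, policy, pseudo_value = 0.01, sample_ids = NULL) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  pol <- filter_policy(policy, pseudo_value)
  ids <- sample_ids %||% as.character(seq_along(x))
  if (length(ids) != length(x)) abort("sample_ids must align with x")
  f <- policy_xy(x, y, pol$code, pol$pseudo_value)
  structure(
    list(
      x = f$x, y = f$y,
      kept_sample_ids = ids[f$keep],
      n_valid = sum(f$keep),
      policy = pol$code
    ),
    class = "filtered_pair"
  )
}

#' @export
print.filtered_pair <- function(x, ...) {
  cat(sprintf("<filtered_pair: policy %d, n_valid = %d>\n", x$policy, x$n_valid))
  invisible(x)
}

# n_valid for every unordered pair, as a D x D matrix (vectorised via
# indicator cross-products).
n_valid_matrix <- function(zmask, code) {
  n <- ncol(zmask)
  switch(as.character(code),
    "1" = ,
    "2" = ,
    "3" = matrix(n, nrow(zmask), nrow(zmask)),
    "4" = ,
    "5" = n - tcrossprod(zmask * 1),
    "6" = tcrossprod((!zmask) * 1)
  )
}

#' Count taxon pairs eligible for correlation under a policy
#'
#' A pair is eligible when its number of paired valid observations after
#' [pair_filter()] is strictly larger than `min_overlap`. By default the
#' overlap rule applies only to the pair-level policies 4-6; for policies
#' 1-3 every pair is eligible by construction (set
#' `apply_min_overlap_all = TRUE` to extend the rule).
#'
#' @param profile a profile tibble.
#' @param policy policy code/name 1-6.
#' @param min_overlap strict lower bound on paired valid observations
#'   (default 30, i.e. pairs need >= 31).
#' @param apply_min_overlap_all apply the overlap rule to policies 1-3 too.
#' @return Integer count of unordered eligible pairs.
#' @export
count_eligible_pairs <- function(profile, policy, min_overlap = 30,
                                 apply_min_overlap_all = FALSE) {
  pol <- filter_policy(policy)
  mat <- profile_matrix(profile)
  meta <- profile_meta(profile)
  zmask <- if (identical(meta$transform, "clr") && !is.null(meta$zero_mask)) {
    meta$zero_mask
  } else {
    mat == 0
  }
  D <- nrow(mat)
  if (D < 2) return(0L)
  nv <- n_valid_matrix(zmask, pol$code)
  ut <- upper.tri(nv)
  if (pol$code %in% 4:6 || apply_min_overlap_all) {
    sum(nv[ut] > min_overlap)
  } else {
    sum(ut)
  }
}
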