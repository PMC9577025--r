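#' Abundance profiles as tibbles
#'
#' A profile is a tibble whose first column, `taxon_id`, holds unique taxon
#' labels and whose remaining columns are samples (unique names, numeric,
#' non-negative). Provenance (source file, rarefaction depth, transform
#' state, the pre-transform zero mask) travels in the `zeronet_meta`
#' attribute; [profile_meta()] reads it. Note that generic data-frame verbs
#' may drop attributes, so apply zeronet transformations before ad-hoc
#' wrangling.
#'
#' @name profile
NULL

#' Construct an abundance profile from a matrix
#'
#' @param mat numeric matrix, taxa in rows (rownames = taxon IDs), samples in
#'   columns (colnames = sample IDs).
#' @param meta named list of provenance notes.
#' @return A profile tibble (see [profile]).
#' @export
as_profile <- function(mat, meta = list()) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("taxon_%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("sample_%d", seq_len(ncol(mat)))
  cols <- c(
    list(taxon_id = rownames(mat)),
    setNames(lapply(seq_len(ncol(mat)), function(j) mat[, j]), colnames(mat))
  )
  out <- tibble::new_tibble(cols, nrow = nrow(mat))
  attr(out, "zeronet_meta") <- meta
  validate_profile(out)
  out
}

#' Extract the numeric matrix of a profile
#'
#' @param profile a profile tibble.
#' @return Numeric matrix, taxa in rows with taxon IDs as rownames.
#' @export
profile_matrix <- function(profile) {
  stopifnot(is.data.frame(profile), ncol(profile) >= 1)
  m <- as.matrix(profile[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- profile[[1]]
  m
}

#' Read provenance metadata of a profile
#'
#' @param profile a profile tibble.
#' @return Named list (possibly empty).
#' @export
profile_meta <- function(profile) {
  attr(profile, "zeronet_meta") %||% list()
}

set_profile_meta <- function(profile, ...) {
  meta <- modifyList(profile_meta(profile), list(...))
  attr(profile, "zeronet_meta") <- meta
  profile
}

validate_profile <- function(profile) {
  ids <- profile[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate taxon IDs in profile: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  smp <- names(profile)[-1]
  if (anyDuplicated(smp)) {
    abort(sprintf(
      "duplicate sample IDs in profile: %s",
      paste(unique(smp[duplicated(smp)]), collapse = ", ")
    ))
  }
  vals <- profile_matrix(profile)
  meta <- profile_meta(profile)
  transformed <- identical(meta$transform, "clr") ||
    identical(meta$state, "transformed")
  if (!transformed && length(vals) && min(vals) < 0) {
    abort("abundance values must be non-negative before transformation")
  }
  invisible(profile)
}

#' Read a taxon-by-sample abundance table
#'
#' Reads a tab-separated table whose header row names the samples and whose
#' first column holds taxon IDs; lines starting with `#` are skipped. Cell
#' parsing failures are reported with the offending taxon and sample.
#'
#' @param path path to a TSV file.
#' @param format input format; only `"tsv"` is supported.
#' @return A profile tibble; dimensions and zero fraction are reported via
#'   [message()].
#' @export
read_profile <- function(path, format = "tsv") {
  format <- match.arg(format, "tsv")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 1) abort(sprintf("no columns in %s", path))
  ids <- raw[[1]]
  mat <- matrix(NA_real_, nrow(raw), ncol(raw) - 1,
    dimnames = list(ids, names(raw)[-1])
  )
  for (j in seq_len(ncol(raw) - 1)) {
    cell <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad)) {
      abort(sprintf(
        "cannot parse value '%s' (taxon '%s', sample '%s') in %s",
        cell[bad[1]], ids[bad[1]], names(raw)[j + 1], path
      ))
    }
    mat[, j] <- num
  }
  state <- if (length(mat) && min(mat) < 0) {
    "transformed" # e.g. a CLR table being re-read
  } else if (length(mat) && all(mat == round(mat))) {
    "counts"
  } else {
    "real"
  }
  prof <- as_profile(mat, meta = list(source = path, state = state))
  inform(sprintf(
    "read %d taxa x %d samples from %s (zero fraction %.3f)",
    nrow(mat), ncol(mat), path, if (length(mat)) mean(mat == 0) else NA_real_
  ))
  prof
}

#' Write a profile to a tab-separated file
#'
#' Values are written with shortest round-trip precision, so
#' `read_profile(write_profile(p, f))` reproduces the matrix losslessly.
#'
#' @param profile a profile tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(path)
}

#' Remove a taxon row by label
#'
#' Used e.g. to drop an "unclassified" aggregate row before analysis.
#'
#' @param profile a profile tibble.
#' @param label taxon ID to remove.
#' @param strict if `TRUE` (default) a missing label is an error; otherwise a
#'   warning is raised and the profile returned unchanged.
#' @return The profile without the row.
#' @export
drop_taxon <- function(profile, label, strict = TRUE) {
  present <- profile[[1]] == label
  if (!any(present)) {
    if (strict) abort(sprintf("taxon '%s' not found in profile", label))
    warn(sprintf("taxon '%s' not found; profile returned unchanged", label))
    return(profile)
  }
  out <- profile[!present, , drop = FALSE]
  attr(out, "zeronet_meta") <- profile_meta(profile)
  out
}

#' Rarefy counts to a common sequencing depth
#'
#' Each sample column is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped with a warning.
#'
#' @param profile integer-count profile tibble.
#' @param depth target reads per sample (> 0).
#' @param seed optional integer; given the same seed the draw is
#'   bit-identical across runs.
#' @return Rarefied profile; every retained sample sums to `depth`.
#' @export
rarefy <- function(profile, depth, seed = NULL) {
  mat <- profile_matrix(profile)
  if (length(mat) && any(mat != round(mat))) {
    abort("rarefy() requires integer counts")
  }
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0) {
    abort("depth must be a single positive number")
  }
  totals <- colSums(mat)
  low <- totals < depth
  if (any(low)) {
    warn(sprintf(
      "dropping %d sample(s) below depth %d: %s",
      sum(low), depth, paste(colnames(mat)[low], collapse = ", ")
    ))
    mat <- mat[, !low, drop = FALSE]
  }
  if (ncol(mat) == 0) abort("no samples at or above the requested depth")
  # vegan's "should be used for observed counts" heuristic misfires on
  # valid integer tables; counts are validated above, so silence it
  draw <- function() {
    withCallingHandlers(
      t(vegan::rrarefy(t(mat), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dimnames(res) <- dimnames(mat)
  as_profile(res, meta = modifyList(
    profile_meta(profile),
    list(state = "counts", rarefaction_depth = depth)
  ))
}

#' Retain taxa by sample-occurrence frequency
#'
#' Keeps taxa whose number of samples with a value > 0 lies within
#' `[min_samples, max_samples]` (inclusive). Presence is counted on the
#' profile as given, i.e. after any rarefaction already applied.
#'
#' @param profile a profile tibble.
#' @param min_samples minimum presence count (>= 0).
#' @param max_samples maximum presence count; `Inf` for unbounded.
#' @return Filtered profile.
#' @export
frequency_filter <- function(profile, min_samples, max_samples = Inf) {
  if (min_samples < 0) abort("min_samples must be >= 0")
  if (min_samples > max_samples) abort("min_samples must be <= max_samples")
  mat <- profile_matrix(profile)
  presence <- rowSums(mat > 0)
  keep <- presence >= min_samples & presence <= max_samples
  out <- profile[keep, , drop = FALSE]
  attr(out, "zeronet_meta") <- modifyList(
    profile_meta(profile),
    list(frequency_band = c(min_samples, max_samples))
  )
  out
}

#' Centered log-ratio transform
#'
#' Per sample column computes `y = log(x) - mean(log(x))` (natural log), the
#' standard compositional CLR. Zeros must be handled first: either the
#' profile was already zero-filled (`zero_handling = "pre-filled"`, e.g. by
#' [treat_profile()]) or zeros are replaced here by `pseudocount`. The
#' pre-transform zero mask is recorded in the profile metadata so pair-level
#' policies can still distinguish original zeros after the transform.
#'
#' @param profile a profile tibble with strictly positive values after zero
#'   handling.
#' @param zero_handling `"pre-filled"` or `"pseudocount"`.
#' @param pseudocount replacement for zeros when
#'   `zero_handling = "pseudocount"`.
#' @return CLR-transformed profile; each sample column sums to 0 (within
#'   1e-9).
#' @export
clr_transform <- function(profile,
                          zero_handling = c("pre-filled", "pseudocount"),
                          pseudocount = 0.01) {
  zero_handling <- match.arg(zero_handling)
  mat <- profile_matrix(profile)
  meta <- profile_meta(profile)
  mask <- meta$zero_mask
  if (zero_handling == "pseudocount") {
    if (pseudocount <= 0) abort("pseudocount must be > 0")
    mask <- mat == 0
    mat[mask] <- pseudocount
  } else if (is.null(mask)) {
    mask <- mat == 0
  }
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-positive value reaching log: taxon '%s', sample '%s'",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ))
  }
  lg <- log(mat)
  lg <- sweep(lg, 2, colMeans(lg))
  as_profile(lg, meta = modifyList(
    meta,
    list(state = "clr", transform = "clr", zero_mask = mask)
  ))
}

#' Fraction of zero cells in a profile
#'
#' @param profile a profile tibble with at least one cell.
#' @return Real in `[0, 1]`.
#' @export
zero_fraction <- function(profile) {
  mat <- profile_matrix(profile)
  if (length(mat) == 0) abort("zero_fraction() is undefined for an empty profile")
  mean(mat == 0)
}
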