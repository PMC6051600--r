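#' Rescale an ordinal category rank to [0, 1]
#'
#' Maps category rank `r` of a `K`-category ordinal item to
#' `(r - 1) / (K - 1)`, so a 5-category item takes values 0, 0.25, 0.5,
#' 0.75, 1 and a dichotomous item maps to 0 and 1. This is the Burden
#' model's equal-interval rescaling; it treats ordinal ranks as interval
#' data, an assumption the bias decomposition is designed to audit.
#'
#' @param rank Integer vector of category ranks in `1..n_categories`.
#'   `NA` is passed through.
#' @param n_categories Number of categories (scalar, >= 2).
#' @return Numeric vector in [0, 1].
#' @export
#' @examples
#' rescale_ordinal(1:5, 5)  # 0 0.25 0.5 0.75 1
rescale_ordinal <- function(rank, n_categories) {
  if (length(n_categories) != 1L || is.na(n_categories) || n_categories < 2) {
    stop("`n_categories` must be a single integer >= 2", call. = FALSE)
  }
  ok <- is.na(rank) | (rank >= 1 & rank <= n_categories)
  if (!all(ok)) {
    stop("`rank` out of range 1..", n_categories, call. = FALSE)
  }
  (rank - 1) / (n_categories - 1)
}

#' Right-censored sum of binary indicators
#'
#' Sums binary indicators and caps the sum at `cap` (default 1). This is
#' how "any problem" domains are built (e.g. the sensory domain: fair or
#' poor hearing *or* eyesight); a participant with both problems has the
#' raw sum 2 reduced by one, which is precisely the manipulation that
#' creates a nonzero bias variable for the domain.
#'
#' @param x Binary vector (one participant's indicators) or matrix /
#'   data.frame (participants in rows, indicators in columns).
#' @param cap Positive censoring cap.
#' @return `min(sum, cap)` per participant. `NA` inputs propagate.
#' @export
#' @examples
#' censored_sum(c(1, 1))                    # 1, not 2
#' censored_sum(cbind(a = c(0, 1), b = c(0, 1)))
censored_sum <- function(x, cap = 1) {
  if (cap <= 0) stop("`cap` must be positive", call. = FALSE)
  if (is.data.frame(x)) x <- as.matrix(x)
  vals <- x[!is.na(x)]
  if (!all(vals %in% c(0, 1))) {
    stop("indicators must be 0/1", call. = FALSE)
  }
  if (is.matrix(x)) pmin(rowSums(x), cap) else min(sum(x), cap)
}

# internal: tie-deterministic (optionally weighted) quantile threshold.
# Returns the smallest value v such that the weighted fraction of
# observations <= v reaches q; all ties at v are flagged.
.fa_quantile_threshold <- function(values, weights, q) {
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][match(TRUE, cw >= q - 1e-12)]
}

#' Flag the extreme quantile tail within strata
#'
#' Within each stratum, flags participants whose value falls in the
#' stated extreme `q`-tail (e.g. weakest 20% grip strength stratified by
#' sex and BMI group, slowest 20% walk time stratified by sex and
#' height). The threshold is the smallest value at which the (optionally
#' survey-weighted) cumulative fraction reaches `q`; all ties at the
#' threshold are flagged, so with skewed weights or heavy ties the
#' flagged fraction can exceed `q` -- the over-coverage that unweighted
#' percentiles produce on weighted samples.
#'
#' @param values Numeric vector. `NA` values get an `NA` flag; thresholds
#'   are computed from the observed values in each stratum.
#' @param strata Vector, or list/data.frame of vectors, defining strata
#'   (crossed when several are given).
#' @param q Tail fraction in (0, 1).
#' @param direction `"lowest"` flags the lower tail, `"highest"` the
#'   upper tail.
#' @param weights Optional positive weights (e.g. survey weights) used to
#'   compute weighted quantile thresholds; `NULL` (default) for
#'   unweighted thresholds.
#' @return Integer 0/1 flag per participant.
#' @export
#' @examples
#' stratified_quantile_flag(1:10, rep(1, 10), q = 0.2)  # flags 1 and 2
stratified_quantile_flag <- function(values, strata, q = 0.2,
                                     direction = c("lowest", "highest"),
                                     weights = NULL) {
  direction <- match.arg(direction)
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  if (is.list(strata)) strata <- interaction(strata, drop = TRUE)
  strata <- as.factor(strata)
  if (length(strata) != length(values)) {
    stop("`strata` must match `values` in length", call. = FALSE)
  }
  if (anyNA(strata)) stop("every participant needs a stratum", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)

  flag <- rep(NA_integer_, length(values))
  for (s in levels(strata)) {
    in_s <- strata == s
    obs <- in_s & !is.na(values)
    if (!any(obs)) stop("stratum '", s, "' has no observed values",
                        call. = FALSE)
    v <- values[obs]
    w <- weights[obs]
    if (direction == "lowest") {
      thr <- .fa_quantile_threshold(v, w, q)
      flag[obs] <- as.integer(v <= thr)
    } else {
      thr <- -.fa_quantile_threshold(-v, w, q)
      flag[obs] <- as.integer(v >= thr)
    }
  }
  flag
}

#' Survey-weighted prevalence
#'
#' Weighted mean of a 0/1 status: `sum(w * status) / sum(w)`. With equal
#' weights this is the arithmetic prevalence.
#'
#' @param status 0/1 vector (NA dropped pairwise with its weight).
#' @param weights Positive weights of the same length.
#' @return Weighted prevalence in [0, 1].
#' @export
#' @examples
#' weighted_prevalence(c(1, 0), c(1, 3))  # 0.25
weighted_prevalence <- function(status, weights) {
  if (length(status) != length(weights)) {
    stop("`status` and `weights` must have equal length", call. = FALSE)
  }
  if (any(weights < 0, na.rm = TRUE) || all(weights == 0)) {
    stop("weights must be positive with a positive sum", call. = FALSE)
  }
  keep <- !is.na(status)
  sum(weights[keep] * status[keep]) / sum(weights[keep])
}
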