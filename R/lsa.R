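#' Rank-based normal-score transform
#'
#' Replaces each observed value by the standard-normal quantile of its rank,
#' `qnorm(rank / (n + 1))`, with average ranks for ties, where `n` is the
#' number of non-missing values. Missing values stay missing. The transform
#' is robust to the heavy-tailed distributions typical of kinetic
#' parameters and puts every variable on a common scale before local
#' similarity scoring.
#'
#' @param x Numeric vector, possibly with `NA`s; at least 6 non-missing,
#'   not all tied.
#' @return Numeric vector of normal scores, same length as `x`.
#' @examples
#' normal_scores(c(3, 1, 2, 5, 4, 6))
#' @export
normal_scores <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 6L) stop("need >= 6 non-missing values", call. = FALSE)
  v <- x[obs]
  if (diff(range(v)) == 0) stop("constant series cannot be normalized", call. = FALSE)
  out <- as.numeric(x)
  out[obs] <- qnorm(rank(v, ties.method = "average") / (n + 1))
  out
}

## |LS| only — hot path for permutation nulls. Kadane's maximum-subarray
## recursion, vectorized via prefix sums: the best segment ending at k has
## sum prefix[k] - min(prefix[0..k-1]).
ls_abs_max <- function(xh, yh, D) {
  n <- length(xh)
  best <- 0
  for (d in -D:D) {
    if (d >= 0) s <- xh[seq_len(n - d)] * yh[seq_len(n - d) + d]
    else        s <- xh[seq_len(n + d) - d] * yh[seq_len(n + d)]
    cp <- cumsum(s)
    lo <- cummin(c(0, cp[-length(cp)]))
    hi <- cummax(c(0, cp[-length(cp)]))
    best <- max(best, max(cp - lo), max(hi - cp))
  }
  best / n
}

#' Delay-limited local similarity of two normalized series
#'
#' Dynamic-programming search for the best contiguous, possibly time-shifted
#' co-varying segment of two series. For every alignment offset
#' `d = j - i` with `|d| <= D`, the recursions
#' `P(i,j) = max(0, P(i-1,j-1) + x[i]*y[j])` and
#' `N(i,j) = max(0, N(i-1,j-1) - x[i]*y[j])`
#' accumulate the best positively and negatively co-varying run ending at
#' each aligned pair. The local similarity score is the largest accumulated
#' sum divided by the series length `n`, signed by the direction of
#' covariation; the delay is the offset of the maximizing cell. Positive
#' delay means `x` precedes `y` (the pattern in `x` shows up in `y` one or
#' more sampling intervals later). Ties resolve toward smaller `|delay|`,
#' then positive sign, then positive delay.
#'
#' @param xh,yh Normalized series (see [normal_scores()]), equal length, no
#'   missing values.
#' @param D Maximum delay in sampling intervals (default 1, i.e. up to one
#'   month for monthly campaigns).
#' @return List with `score` (signed LS score), `delay`, `sign`, `start_x`,
#'   `start_y`, `length` (segment bounds of the maximizing run).
#' @export
local_similarity <- function(xh, yh, D = 1L) {
  n <- length(xh)
  if (length(yh) != n) stop("series lengths differ", call. = FALSE)
  if (anyNA(xh) || anyNA(yh)) stop("missing values must be handled upstream", call. = FALSE)
  D <- as.integer(D)
  if (D < 0L || D >= n) stop("'D' must satisfy 0 <= D < length", call. = FALSE)

  best <- list(score = 0, delay = 0L, sign = 1,
               start_x = 1L, start_y = 1L, length = 0L)
  tol <- 1e-12
  ## candidates visited in tie-break priority order:
  ## |delay| ascending, then positive sign, then positive delay
  for (a in 0:D) {
    ds <- if (a == 0L) 0L else c(a, -a)
    aligned <- lapply(ds, function(d) {
      if (d >= 0) { i <- seq_len(n - d); j <- i + d } else { j <- seq_len(n + d); i <- j - d }
      list(d = d, i = i, j = j, cp = cumsum(xh[i] * yh[j]))
    })
    for (sgn in c(1, -1)) {
      for (al in aligned) {
        cp2 <- sgn * al$cp
        pref <- c(0, cp2[-length(cp2)])
        run <- cp2 - cummin(pref)          # best run ending at each cell
        k <- which.max(run)
        sc <- max(run[k], 0) / n
        if (sc > best$score + tol) {
          st <- which.min(pref[seq_len(k)])
          best <- list(score = sc, delay = al$d, sign = sgn,
                       start_x = al$i[st], start_y = al$j[st],
                       length = k - st + 1L)
        }
      }
    }
  }
  best$score <- best$sign * best$score
  best
}

#' Permutation p-value for a local similarity score
#'
#' Permutes the second series uniformly at random, recomputes `|LS|` each
#' time, and reports the add-one smoothed exceedance probability
#' `p = (1 + #(|LS_perm| >= |LS_obs|)) / (n_perm + 1)`, which can never be
#' exactly zero at finite `n_perm`.
#'
#' @inheritParams local_similarity
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed; the p-value is deterministic given the seed.
#' @return The permutation p-value.
#' @export
ls_permutation_p <- function(xh, yh, D = 1L, n_perm = 1000L, seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("'n_perm' must be >= 100", call. = FALSE)
  obs <- ls_abs_max(xh, yh, D)
  n <- length(yh)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ls_abs_max(xh, yh[sample.int(n)], D) >= obs - 1e-12
    }, logical(1L)))
  })
  (1 + hits) / (n_perm + 1)
}

## fill NA values that are flanked by two observed neighbours (single
## isolated sampling gaps); longer runs are left missing
fill_single_gaps <- function(v) {
  idx <- which(is.na(v))
  for (i in idx) {
    if (i > 1L && i < length(v) && !is.na(v[i - 1L]) && !is.na(v[i + 1L])) {
      v[i] <- (v[i - 1L] + v[i + 1L]) / 2
    }
  }
  v
}

## longest contiguous stretch where both series are observed
longest_complete_run <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  cand <- which(r$values)
  if (length(cand) == 0L) return(integer(0))
  w <- cand[which.max(r$lengths[cand])]
  seq(ends[w] - r$lengths[w] + 1L, ends[w])
}

#' Local similarity analysis across all variable pairs
#'
#' Runs delay-limited local similarity analysis on every unordered pair of
#' eligible variables in a monthly time-series table, with permutation
#' p-values and Benjamini–Hochberg q-values across the full pair set.
#'
#' Eligibility: a variable needs at least 6 observed values, at most
#' `max_missing_frac` missing, and nonzero variance. Missing-value policy:
#' single isolated gaps are filled by linear interpolation of the raw series
#' before normalization; if longer gaps remain, the pair is truncated to the
#' longest contiguous stretch where both series are observed (keeping the
#' dynamic program contiguous without fabricating long stretches). The
#' number of timepoints actually scored is returned as `n_effective`.
#'
#' @param table Data frame with a `date` column plus one numeric column per
#'   variable (or a plain numeric data frame/matrix).
#' @param D Maximum delay in sampling intervals (default 1).
#' @param n_perm Permutations per pair (default 1000).
#' @param seed Integer seed; one sub-seed is drawn per pair so results are
#'   independent of pair evaluation order.
#' @param normalization `"normal_scores"` (default) or `"zscore"`.
#' @param max_missing_frac Maximum tolerated missing fraction per variable
#'   (default 0.25).
#' @return Tibble with columns `var_x`, `var_y`, `ls_score`, `delay`,
#'   `p_value`, `q_value`, `n_effective`, sorted by decreasing `|ls_score|`.
#' @export
lsa_all_pairs <- function(table, D = 1L, n_perm = 1000L, seed = 1L,
                          normalization = c("normal_scores", "zscore"),
                          max_missing_frac = 0.25) {
  normalization <- match.arg(normalization)
  tab <- as.data.frame(table)
  tab <- tab[, setdiff(names(tab), "date"), drop = FALSE]
  tab <- tab[, vapply(tab, is.numeric, logical(1L)), drop = FALSE]

  eligible <- vapply(names(tab), function(nm) {
    v <- tab[[nm]]
    nobs <- sum(!is.na(v))
    nobs >= 6L && mean(is.na(v)) <= max_missing_frac &&
      diff(range(v, na.rm = TRUE)) > 0
  }, logical(1L))
  dropped <- names(tab)[!eligible]
  if (length(dropped)) {
    message("dropping ineligible variable(s): ", paste(dropped, collapse = ", "))
  }
  tab <- tab[, eligible, drop = FALSE]
  vars <- names(tab)
  if (length(vars) < 2L) stop("need >= 2 eligible variables", call. = FALSE)

  filled <- lapply(tab, fill_single_gaps)
  pairs <- utils::combn(vars, 2L)
  pair_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                  ncol(pairs)))
  norm_fun <- if (normalization == "normal_scores") {
    normal_scores
  } else {
    function(v) as.numeric(scale(v))
  }

  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    vx <- pairs[1L, k]; vy <- pairs[2L, k]
    x <- filled[[vx]]; y <- filled[[vy]]
    idx <- seq_along(x)
    if (anyNA(x) || anyNA(y)) idx <- longest_complete_run(!is.na(x) & !is.na(y))
    if (length(idx) < 6L) {
      warning(sprintf("pair %s/%s: longest complete run < 6 points, skipped",
                      vx, vy), call. = FALSE)
      return(NULL)
    }
    xh <- norm_fun(x[idx]); yh <- norm_fun(y[idx])
    ls <- local_similarity(xh, yh, D = min(D, length(idx) - 1L))
    p <- ls_permutation_p(xh, yh, D = min(D, length(idx) - 1L),
                          n_perm = n_perm, seed = pair_seeds[k])
    tibble::tibble(var_x = vx, var_y = vy, ls_score = ls$score,
                   delay = ls$delay, p_value = p,
                   n_effective = length(idx))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no testable pairs", call. = FALSE)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(-abs(out$ls_score)), ]
  out[, c("var_x", "var_y", "ls_score", "delay", "p_value", "q_value",
          "n_effective")]
}

#' Read / write time-series CSV files
#'
#' First column `date` (ISO-8601), one numeric column per variable, blank
#' cells for missing values.
#'
#' @param path File path.
#' @return `read_timeseries()`: a data frame with a `Date`-class `date`
#'   column. `write_timeseries()`: `path`, invisibly.
#' @export
read_timeseries <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(d)) stop("CSV needs a 'date' column", call. = FALSE)
  d$date <- as.Date(d$date)
  if (is.unsorted(d$date, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  d
}

#' @param table Data frame as returned by [read_timeseries()].
#' @rdname read_timeseries
#' @export
write_timeseries <- function(table, path) {
  tab <- as.data.frame(table)
  tab$date <- as.character(tab$date)
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
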