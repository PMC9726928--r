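#' p(Earn) matrix over (time-spent, time-remaining) states
#'
#' Every accepted trial passes through a sequence of wait-zone states: after
#' waiting `s` seconds of an offer `D` it is in the state
#' (time-spent `s`, time-remaining `r = D - s`). A trial that earns
#' contributes an "earn" to every state `s = 0 .. D-1` it passed through; a
#' trial that quits at second `q` contributes a "not-earn" to the states
#' `s = 0 .. q-1` it passed through (the state from which it quit on the next
#' second counts as not earning; no state is recorded at `s = q` itself).
#' `p_earn(s, r)` is then the probability that a trial observed in state
#' `(s, r)` stays to the end of the countdown.
#'
#' @param trials A [session_set()] with at least one accepted trial.
#' @param min_count Minimum pass count for a cell's probability to be
#'   defined; below it `p_earn` is `NA` (never zero-filled). Default 1,
#'   appropriate for simulation-scale data; use ~5 for small behavioral
#'   sessions.
#' @return A `pearn_matrix`: integer matrices `n_pass` and `n_earn` and the
#'   probability matrix `p_earn`, rows indexed by time spent (`0 ..
#'   max(offer)-1`), columns by time remaining (`1 .. max(offer)`).
#' @export
build_pearn_matrix <- function(trials, min_count = 1L) {
  acc <- trials[trials$accepted %in% TRUE, ]
  if (nrow(acc) == 0) stop("no accepted trials", call. = FALSE)
  meta <- session_meta(trials)
  support <- if (!is.null(meta$offer_support)) meta$offer_support else 1:30
  dmax <- max(support, acc$offer_s)
  n_pass <- matrix(0L, nrow = dmax, ncol = dmax,
                   dimnames = list(spent = 0:(dmax - 1), remaining = 1:dmax))
  n_earn <- n_pass
  # a trial with endpoint e (= quit time, or the offer for earns) passes
  # through s = 0 .. e-1; tally per offer with a reverse cumulative count
  e <- acc$time_spent_s
  earned <- acc$outcome == "earn"
  for (D in sort(unique(acc$offer_s))) {
    i <- acc$offer_s == D
    ne <- sum(i & earned)
    ends <- tabulate(e[i & !earned], nbins = D)        # quits at q = 1..D-1
    ends[D] <- ends[D] + ne
    passing <- rev(cumsum(rev(ends)))                  # # trials with e > s
    s <- 0:(D - 1)
    cells <- cbind(s + 1L, D - s)
    n_pass[cells] <- n_pass[cells] + passing[s + 1L]
    n_earn[cells] <- n_earn[cells] + ne
  }
  p_earn <- ifelse(n_pass >= min_count, n_earn / n_pass, NA_real_)
  pearn_matrix(n_pass, n_earn, p_earn, min_count)
}

#' Low-level p(Earn) matrix constructor
#'
#' @param n_pass,n_earn Count matrices (rows: time spent from 0; columns:
#'   time remaining from 1).
#' @param p_earn Probability matrix; computed as `n_earn / n_pass` where
#'   `n_pass >= min_count` when omitted.
#' @param min_count Defined-cell threshold.
#' @return A `pearn_matrix` object.
#' @export
pearn_matrix <- function(n_pass, n_earn, p_earn = NULL, min_count = 1L) {
  stopifnot(all(dim(n_pass) == dim(n_earn)), all(n_earn <= n_pass))
  if (is.null(p_earn)) {
    p_earn <- ifelse(n_pass >= min_count, n_earn / n_pass, NA_real_)
  }
  structure(list(n_pass = n_pass, n_earn = n_earn, p_earn = p_earn,
                 spent = 0:(nrow(n_pass) - 1L), remaining = 1:ncol(n_pass),
                 min_count = as.integer(min_count)),
            class = "pearn_matrix")
}

#' @export
print.pearn_matrix <- function(x, ...) {
  defined <- sum(!is.na(x$p_earn))
  cat(sprintf("<pearn_matrix> %d x %d states, %d defined cells, %d passes\n",
              nrow(x$p_earn), ncol(x$p_earn), defined, sum(x$n_pass[1, ])))
  invisible(x)
}

#' Tidy cell table of a p(Earn) matrix
#'
#' @param m A `pearn_matrix`.
#' @param drop_undefined Drop cells whose probability is undefined.
#' @return Tibble with `spent`, `remaining`, `n_pass`, `n_earn`, `p_earn`.
#' @export
pearn_cells <- function(m, drop_undefined = TRUE) {
  out <- tibble::tibble(
    spent = rep(m$spent, times = length(m$remaining)),
    remaining = rep(m$remaining, each = length(m$spent)),
    n_pass = as.vector(m$n_pass),
    n_earn = as.vector(m$n_earn),
    p_earn = as.vector(m$p_earn)
  )
  if (drop_undefined) out <- out[!is.na(out$p_earn), ]
  out
}

#' Sunk-cost bubble
#'
#' For each time-spent `s >= 1`, sums the difference in earning probability
#' between the `s`-invested and the 0-invested condition over every
#' time-remaining point defined in both rows:
#' `B(s) = sum_r [p(s, r) - p(0, r)]`. The total bubble is `sum_s B(s)`.
#' Positive values are the sunk-cost signature — having waited longer, the
#' agent is more likely to stay for an identical remaining countdown.
#'
#' @param m A `pearn_matrix`.
#' @return List with `bubble_total` and `bubble_by_spent` (named numeric,
#'   `NA` where a row shares no defined cell with the 0-invested row).
#' @export
sunk_cost_bubble <- function(m) {
  p <- m$p_earn
  smax <- nrow(p) - 1L
  by_spent <- stats::setNames(rep(NA_real_, smax), 1:smax)
  for (s in seq_len(smax)) {
    ok <- !is.na(p[s + 1L, ]) & !is.na(p[1L, ])
    if (any(ok)) by_spent[s] <- sum(p[s + 1L, ok] - p[1L, ok])
  }
  if (all(is.na(by_spent))) {
    warning("sunk-cost bubble undefined: no time-spent row shares a ",
            "defined time-remaining cell with the 0-invested row",
            call. = FALSE)
    return(list(bubble_total = NA_real_, bubble_by_spent = by_spent))
  }
  list(bubble_total = sum(by_spent, na.rm = TRUE), bubble_by_spent = by_spent)
}

#' Baseline slope
#'
#' Ordinary least-squares slope of the 0-seconds-invested earning
#' probability against time remaining: how much less likely the agent is to
#' wait out the delay per extra second of countdown, before any time has
#' been sunk.
#'
#' @param m A `pearn_matrix`.
#' @return Slope in probability per second; `NA` (with a warning) when fewer
#'   than two cells are defined at zero investment.
#' @export
baseline_slope <- function(m) {
  p0 <- m$p_earn[1L, ]
  ok <- !is.na(p0)
  if (sum(ok) < 2) {
    warning("baseline slope undefined: fewer than 2 defined cells at 0 s",
            call. = FALSE)
    return(NA_real_)
  }
  r <- m$remaining[ok]
  unname(stats::coef(stats::lm(p0[ok] ~ r))[2])
}

#' Latency to sunk-cost accrual
#'
#' The delay, in seconds of time spent, before the sunk-cost bubble begins
#' to grow: the smallest `s` whose bubble contribution `B(s)` exceeds
#' `kappa_frac` of the maximum contribution, with the next bin also above
#' (two-bin persistence, guarding against single noisy bins). Latencies
#' above 15 s are flagged as outliers (attribute `"outlier"`).
#'
#' @param bubble_by_spent Per-time-spent bubble contributions, as returned
#'   by [sunk_cost_bubble()] (element `bubble_by_spent`).
#' @param kappa_frac Detection fraction of the maximum contribution;
#'   default 0.10.
#' @return Integer latency (s), with attribute `outlier`; `NA` when the
#'   bubble never crosses the detection level.
#' @export
latency_to_accrual <- function(bubble_by_spent, kappa_frac = 0.10) {
  b <- as.numeric(bubble_by_spent)
  if (all(is.na(b)) || max(b, na.rm = TRUE) <= 0) return(NA_integer_)
  level <- kappa_frac * max(b, na.rm = TRUE)
  above <- !is.na(b) & b > level
  hit <- which(above & c(above[-1], FALSE))
  if (!length(hit)) return(NA_integer_)
  structure(hit[1], outlier = hit[1] > 15L)
}

#' Value-conditioned change in p(Earn)
#'
#' Recasts the bubble by the economic value left in the countdown:
#' `v = threshold - remaining`. For every cell with time spent `s >= 1`
#' defined in both its own row and the 0-invested row, tabulates
#' `delta_p = p(s, r) - p(0, r)` and compares the pooled `delta_p` for
#' economically bad states (`v < 0`, remaining delay above threshold)
#' against good states (`v > 0`) with a two-sample Wilcoxon rank-sum test
#' (cells at exactly `v = 0` are excluded). Sunk-cost sensitivity
#' concentrated on correcting bad deals appears as larger `delta_p` at
#' negative value.
#'
#' @param m A `pearn_matrix`.
#' @param threshold Site threshold in seconds (see [estimate_threshold()]).
#' @return List: `table` (tibble of `value`, `spent`, `remaining`,
#'   `delta_p`), `p_value`, `median_neg`, `median_pos`, and `test`, a label
#'   naming the test applied.
#' @export
value_conditioned_deltas <- function(m, threshold) {
  p <- m$p_earn
  rows <- which(rowSums(!is.na(p)) > 0)
  tab <- list()
  for (s in setdiff(rows - 1L, 0L)) {
    ok <- which(!is.na(p[s + 1L, ]) & !is.na(p[1L, ]))
    if (length(ok)) {
      tab[[length(tab) + 1]] <- tibble::tibble(
        value = threshold - m$remaining[ok], spent = s,
        remaining = m$remaining[ok],
        delta_p = p[s + 1L, ok] - p[1L, ok])
    }
  }
  tab <- if (length(tab)) do.call(rbind, tab) else
    tibble::tibble(value = numeric(), spent = integer(),
                   remaining = integer(), delta_p = numeric())
  neg <- tab$delta_p[tab$value < 0]
  pos <- tab$delta_p[tab$value > 0]
  p_value <- NA_real_
  if (length(neg) && length(pos)) {
    if (length(unique(c(neg, pos))) == 1L) {
      p_value <- 1  # all deltas identical: no evidence of any difference
    } else {
      p_value <- suppressWarnings(
        stats::wilcox.test(neg, pos, exact = NULL)$p.value)
    }
  }
  list(table = tab, p_value = p_value,
       median_neg = if (length(neg)) stats::median(neg) else NA_real_,
       median_pos = if (length(pos)) stats::median(pos) else NA_real_,
       test = "two-sample Wilcoxon rank-sum, delta_p at value<0 vs value>0")
}

#' Linear model of p(Earn) on time remaining, time spent and their interaction
#'
#' Fits `p_earn ~ remaining + spent + remaining:spent` by OLS over the
#' defined cells. A pure approach-to-goal account predicts the remaining
#' term only; a sunk-cost-sensitive process shows a time-spent effect and an
#' interaction.
#'
#' @param m A `pearn_matrix`.
#' @return List: `coefficients` (tibble with estimate, t, p per term),
#'   `f_vs_constant`, `f_p_value`, `adj_r2`, `df_residual`.
#' @export
interaction_model <- function(m) {
  cells <- pearn_cells(m)
  if (nrow(cells) < 5) stop("need at least 5 defined cells", call. = FALSE)
  fit <- stats::lm(p_earn ~ remaining * spent, data = cells)
  if (any(is.na(stats::coef(fit)))) {
    stop("interaction model is rank deficient: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  }
  s <- summary(fit)
  fstat <- s$fstatistic
  coefs <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = unname(s$coefficients[, "Estimate"]),
    t = unname(s$coefficients[, "t value"]),
    p = unname(s$coefficients[, "Pr(>|t|)"])
  )
  list(coefficients = coefs,
       f_vs_constant = unname(fstat[1]),
       f_p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
       adj_r2 = s$adj.r.squared,
       df_residual = fit$df.residual)
}

#' Linear versus quadratic fit of sensitivity against decision time
#'
#' Fits `y ~ x` and `y ~ x + x^2` by OLS and reports both adjusted R-squared
#' values, the quadratic coefficient, and the curvature sign (positive
#' quadratic coefficient = convex/concave-up, negative = concave/
#' concave-down). Used to discriminate the two reset hypotheses, whose total
#' sunk-cost sensitivity bends differently as a function of the imposed
#' decision time.
#'
#' @param x Predictor (decision times).
#' @param y Response (total sunk-cost sensitivities).
#' @return List: `linear_adj_r2`, `quad_adj_r2`, `quad_coef`, `curvature`
#'   (`"convex"` or `"concave"`).
#' @export
linquad_convexity_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) {
    stop("quadratic fit refused: need at least 4 points", call. = FALSE)
  }
  fl <- stats::lm(y ~ x)
  fq <- stats::lm(y ~ x + I(x^2))
  qc <- unname(stats::coef(fq)[3])
  list(linear_adj_r2 = summary(fl)$adj.r.squared,
       quad_adj_r2 = summary(fq)$adj.r.squared,
       quad_coef = qc,
       curvature = if (qc >= 0) "convex" else "concave")
}
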