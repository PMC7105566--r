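#' Kruskal-Wallis test for a main effect of phase
#'
#' Rank-based test across the 12 phase bins, applied to the per-block
#' (per-pulse) responses grouped by realised stimulation-phase bin.
#'
#' @param samples list of numeric vectors (one per phase bin) or a
#'   `response_curve` whose per-bin sample lists are used.
#' @return p-value.  If all observations are identical the convention
#'   `p = 1` is returned with attribute `flag = "degenerate"`.
#' @export
kruskal_wallis_phase <- function(samples) {
  if (inherits(samples, "response_curve")) samples <- samples$samples
  samples <- samples[vapply(samples, length, integer(1)) > 0]
  if (length(samples) < 2 || sum(lengths(samples)) < 4) {
    stop("need at least 2 non-empty groups with >= 2 observations overall")
  }
  x <- unlist(samples, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(structure(1, flag = "degenerate"))
  }
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kruskal.test(x, g)$p.value
}

#' Fit the cosine model to a response curve
#'
#' Least-squares fit of `y = c1 + |c2| cos(x + c3)` to the per-bin means.
#' Solved in closed form through the equivalent linear first-harmonic
#' regression `y = c1 + a cos(x) + b sin(x)` with `c2 = sqrt(a^2 + b^2)`
#' and `c3 = atan2(-b, a)`, which is the global optimum.
#'
#' @param x bin-centre phases (radians).
#' @param y per-bin means.
#' @return An object of class `cosine_fit` with `c1`, `c2 >= 0`,
#'   `c3` in `[0, 2*pi)`, `rss_cosine`, `rss_flat`, `n`.
#' @export
fit_cosine <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 points to fit the cosine model")
  X <- cbind(1, cos(x), sin(x))
  cf <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% cf
  c2 <- sqrt(cf[2]^2 + cf[3]^2)
  c3 <- atan2(-cf[3], cf[2]) %% (2 * pi)
  structure(list(c1 = cf[1], c2 = c2, c3 = c3,
                 rss_cosine = sum(resid^2),
                 rss_flat = sum((y - mean(y))^2),
                 n = length(x)),
            class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine fit: y = %.4g + %.4g cos(x + %.4g), RSS %.3g (flat %.3g)\n",
              x$c1, x$c2, x$c3, x$rss_cosine, x$rss_flat))
  invisible(x)
}

#' F-test of the cosine model against a flat line
#'
#' Tests whether the cosine model describes the curve better than a
#' horizontal line at the mean:
#' `F = ((rss_flat - rss_cosine)/2) / (rss_cosine/(n - 3))` referred to
#' `F(2, n - 3)`.
#'
#' @param fit a [fit_cosine()] result.
#' @return p-value; an exact fit (`rss_cosine = 0`) returns the `p = 0`
#'   convention with attribute `flag = "perfect_fit"`.
#' @export
cosine_f_test <- function(fit) {
  stopifnot(inherits(fit, "cosine_fit"), fit$n > 3)
  if (fit$rss_cosine <= .Machine$double.eps * fit$rss_flat) {
    return(structure(0, flag = "perfect_fit"))
  }
  Fstat <- ((fit$rss_flat - fit$rss_cosine) / 2) /
    (fit$rss_cosine / (fit$n - 3))
  pf(Fstat, 2, fit$n - 3, lower.tail = FALSE)
}

#' Storey-type estimate of the number of true null hypotheses
#'
#' `m0_hat = (#\{p_i > lambda\} + 1) / (1 - lambda)`, capped at the number
#' of tests.
#'
#' @param pvalues numeric p-values.
#' @param lambda tuning parameter in (0, 1); the default equals the FDR
#'   level used throughout.
#' @return Estimated number of true nulls.
#' @export
storey_m0 <- function(pvalues, lambda = 0.05) {
  stopifnot(length(pvalues) > 0, lambda > 0, lambda < 1,
            all(pvalues >= 0 & pvalues <= 1))
  min(length(pvalues), (sum(pvalues > lambda) + 1) / (1 - lambda))
}

#' Adaptive linear step-up FDR procedure
#'
#' Benjamini-Hochberg-type step-up with the threshold rescaled by an
#' estimate of the number of true nulls: reject the hypotheses with the
#' `k*` smallest p-values where
#' `k* = max\{i : p_(i) <= i q / m0_hat\}` (none if no such `i`).
#'
#' @param pvalues numeric p-values.
#' @param q FDR level in (0, 1).
#' @param m0_hat estimate of the number of true nulls; defaults to the
#'   Storey estimate with `lambda = q`.
#' @return Logical rejection flags in the original order.
#' @export
adaptive_step_up <- function(pvalues, q = 0.05,
                             m0_hat = storey_m0(pvalues, lambda = q)) {
  stopifnot(q > 0, q < 1)
  m <- length(pvalues)
  o <- order(pvalues)
  ps <- pvalues[o]
  ok <- which(ps <= seq_len(m) * q / m0_hat)
  flags <- logical(m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

#' Statistics battery for one dataset's response curves
#'
#' Runs the Kruskal-Wallis test (per-block responses grouped by bin) and
#' the cosine-model F-test on a bPRC and a bARC.
#'
#' @param bprc,barc `response_curve` objects from [bin_responses()] or
#'   [extract_response_curves()].
#' @return List with per-curve p-values (`p_kw_prc`, `p_kw_arc`,
#'   `p_f_prc`, `p_f_arc`) and the two cosine fits.
#' @export
response_curve_tests <- function(bprc, barc) {
  fit_p <- fit_cosine(bprc$bin_center, bprc$mean)
  fit_a <- fit_cosine(barc$bin_center, barc$mean)
  list(p_kw_prc = as.numeric(kruskal_wallis_phase(bprc)),
       p_kw_arc = as.numeric(kruskal_wallis_phase(barc)),
       p_f_prc = as.numeric(cosine_f_test(fit_p)),
       p_f_arc = as.numeric(cosine_f_test(fit_a)),
       fit_prc = fit_p, fit_arc = fit_a)
}

#' Dataset significance criterion
#'
#' A dataset is selected when both its bPRC and its bARC are deemed
#' significant under FDR control by at least one of the two tests, the
#' tests being evaluated within their own FDR family (all ANOVA p-values
#' form one family, all F-test p-values another).
#'
#' @param kw_rejected,f_rejected logical length-2 vectors
#'   `(bPRC, bARC)` of FDR rejection flags for the Kruskal-Wallis and
#'   F-test families.
#' @return `TRUE` if the criterion is met.
#' @export
significance_criterion <- function(kw_rejected, f_rejected) {
  stopifnot(length(kw_rejected) == 2, length(f_rejected) == 2,
            !anyNA(kw_rejected), !anyNA(f_rejected))
  all(kw_rejected) || all(f_rejected)
}

#' PRC-ARC phase shift
#'
#' Circular difference `(c3_prc - c3_arc) mod 2*pi` of the cosine-fit
#' phase parameters.  Only meaningful when the cosine model is significant
#' for both curves, which the caller asserts through `qualifying`.
#'
#' @param c3_prc,c3_arc cosine phase parameters (radians).
#' @param qualifying were both cosine F-tests rejected under FDR control?
#' @return Shift in `[0, 2*pi)`.
#' @export
prc_arc_shift <- function(c3_prc, c3_arc, qualifying = TRUE) {
  if (!isTRUE(qualifying)) {
    stop("PRC-ARC shift is not meaningful unless both cosine F-tests ",
         "are rejected under FDR control")
  }
  (c3_prc - c3_arc) %% (2 * pi)
}

#' Full FDR analysis of a family of datasets
#'
#' Given per-dataset ANOVA and F-test p-values for both response curves,
#' runs separate Storey-adaptive step-up FDR analyses per test type,
#' evaluates the significance criterion for each dataset, and reports a
#' table mirroring the per-patient summary.
#'
#' @param pvals data frame with columns `dataset`, `curve`
#'   (`"bPRC"`/`"bARC"`), `anova_p`, `f_p` (two rows per dataset).
#' @param q FDR level.
#' @param lambda Storey tuning parameter.
#' @return List with `m0_anova`, `m0_f`, `n_rejected_anova`,
#'   `n_rejected_f`, the augmented `table` (rejection flags per cell) and
#'   `selected` (dataset identifiers satisfying the criterion).
#' @export
fdr_battery <- function(pvals, q = 0.05, lambda = 0.05) {
  stopifnot(all(c("dataset", "curve", "anova_p", "f_p") %in% names(pvals)))
  m0_a <- storey_m0(pvals$anova_p, lambda)
  m0_f <- storey_m0(pvals$f_p, lambda)
  rej_a <- adaptive_step_up(pvals$anova_p, q, m0_a)
  rej_f <- adaptive_step_up(pvals$f_p, q, m0_f)
  tab <- cbind(pvals, anova_rejected = rej_a, f_rejected = rej_f)
  sel <- vapply(unique(tab$dataset), function(d) {
    rows <- tab[tab$dataset == d, ]
    prc <- rows[rows$curve == "bPRC", ]; arc <- rows[rows$curve == "bARC", ]
    significance_criterion(
      c(prc$anova_rejected, arc$anova_rejected),
      c(prc$f_rejected, arc$f_rejected))
  }, logical(1))
  list(m0_anova = m0_a, m0_f = m0_f,
       n_rejected_anova = sum(rej_a), n_rejected_f = sum(rej_f),
       table = tab, selected = unique(tab$dataset)[sel])
}
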