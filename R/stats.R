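# nested-replicate (SuperPlot) aggregation, Dunnett many-to-one test,
# Mann-Whitney U

#' Summarise per-cell values into a SuperPlot table
#'
#' The SuperPlot convention separates technical replicates (individual
#' cells) from biological replicates (batches of cells): plots show both,
#' and statistics run on the replicate means, never on pooled cells —
#' avoiding pseudoreplication.
#'
#' @param rows a tibble with columns `value` (numeric, per cell),
#'   `cell_id`, `replicate` (biological replicate label) and `condition`.
#' @return A list of class `superplot_table`: `cells` (the input rows) and
#'   `replicates` (tibble `condition`, `replicate`, `mean`, `n_cells`).
#' @export
#' @examples
#' rows <- tibble::tibble(value = rnorm(30), cell_id = 1:30,
#'                        replicate = rep(c("r1", "r2", "r3"), each = 10),
#'                        condition = rep(c("ctrl", "treat"), 15))
#' superplot_summarize(rows)
superplot_summarize <- function(rows) {
  req <- c("value", "cell_id", "replicate", "condition")
  if (!all(req %in% names(rows))) {
    stop_bleb("`rows` must have columns %s", paste(req, collapse = ", "))
  }
  if (nrow(rows) == 0L) stop_bleb("`rows` is empty")
  if (any(!is.finite(rows$value))) stop_bleb("`value` must be finite")
  reps <- rows %>%
    dplyr::group_by(.data$condition, .data$replicate) %>%
    dplyr::summarise(mean = mean(.data$value), n_cells = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(.data$condition, .data$replicate)
  structure(list(cells = tibble::as_tibble(rows), replicates = reps),
            class = "superplot_table")
}

#' @export
print.superplot_table <- function(x, ...) {
  cat(sprintf("<superplot_table> %d cells, %d replicate means, %d conditions\n",
              nrow(x$cells), nrow(x$replicates),
              length(unique(x$replicates$condition))))
  print(x$replicates)
  invisible(x)
}

#' Dunnett's many-to-one comparisons against a control
#'
#' Compares every treatment condition to a designated control with
#' multiplicity-adjusted two-sided p-values from the multivariate-t
#' reference distribution (pooled within-group variance; balanced or
#' unbalanced group sizes). Given a `superplot_table`, the test consumes
#' the biological-replicate means (the SuperPlot convention); per-cell
#' input requires an explicit opt-in and warns about pseudoreplication.
#'
#' For each treatment i, `t_i = (m_i - m_0) / (s * sqrt(1/n_i + 1/n_0))`
#' with pooled SD `s` on `N - k - 1` degrees of freedom, and the adjusted
#' p-value is `1 - P(max_j |T_j| <= |t_i|)` under the k-variate t
#' distribution with correlations
#' `rho_ij = sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`. With a single
#' treatment this reduces exactly to the pooled two-sample t-test.
#'
#' @param x a `superplot_table`, or a data frame with columns `condition`
#'   and `value` (one row per experimental unit).
#' @param control the control condition label.
#' @param unit `"replicate"` (default; requires a `superplot_table`) or
#'   `"cell"` (pools cells — pseudoreplication warning).
#' @return A tibble of class `dunnett_test`: `condition`, `estimate`
#'   (treatment minus control mean), `statistic`, `df`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_test <- function(x, control, unit = c("replicate", "cell")) {
  unit <- match.arg(unit)
  if (inherits(x, "superplot_table")) {
    df <- if (unit == "replicate") {
      tibble(condition = x$replicates$condition, value = x$replicates$mean)
    } else {
      warning("testing pooled cells treats technical replicates as independent (pseudoreplication)")
      tibble(condition = x$cells$condition, value = x$cells$value)
    }
  } else {
    df <- tibble::as_tibble(x)[, c("condition", "value")]
  }
  if (!control %in% df$condition) stop_bleb("control condition '%s' not found", control)
  grp <- split(df$value, df$condition)
  if (any(lengths(grp) < 2L)) {
    stop_bleb("every condition needs >= 2 units for a within-group variance (got: %s)",
              paste(sprintf("%s=%d", names(grp), lengths(grp)), collapse = ", "))
  }
  treats <- setdiff(names(grp), control)
  k <- length(treats)
  if (k < 1L) stop_bleb("no treatment condition besides the control")
  ns <- lengths(grp)
  means <- vapply(grp, mean, numeric(1))
  N <- sum(ns)
  dfree <- N - (k + 1L)
  s2 <- sum(vapply(grp, function(v) sum((v - mean(v))^2), numeric(1))) / dfree
  n0 <- ns[[control]]
  tstat <- vapply(treats, function(g) {
    (means[[g]] - means[[control]]) / sqrt(s2 * (1 / ns[[g]] + 1 / n0))
  }, numeric(1))
  lam <- sqrt(ns[treats] / (ns[treats] + n0))
  p_unadj <- 2 * pt(-abs(tstat), dfree)
  p_adj <- vapply(abs(tstat), function(q) {
    1 - pmvt_box(q, lam, dfree)
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, p_unadj), 1) # quadrature guard: adjusted >= raw
  res <- tibble(condition = treats,
                estimate = unname(means[treats] - means[[control]]),
                statistic = unname(tstat), df = dfree,
                p_unadjusted = unname(p_unadj), p_adjusted = unname(p_adj))
  attr(res, "control") <- control
  attr(res, "unit") <- unit
  class(res) <- c("dunnett_test", class(res))
  res
}

# P(max_j |T_j| <= q) under the Dunnett multivariate t with product
# correlation rho_ij = lambda_i * lambda_j and df degrees of freedom.
# Deterministic 2-D Gauss-Legendre quadrature over the latent factor Z0 and
# the pooled-SD scale W = sqrt(chisq_df / df):
#   T_j = (lambda_j Z0 + sqrt(1 - lambda_j^2) E_j) / W
# so conditionally on (Z0, W) the |T_j| <= q events are independent.
pmvt_box <- function(q, lambda, df, n_nodes = 64L) {
  k <- length(lambda)
  if (k == 1L) return(pt(q, df) - pt(-q, df))
  gz <- gauss_legendre(n_nodes, -8, 8)
  wmax <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  gw <- gauss_legendre(n_nodes, 1e-9, wmax)
  cj <- sqrt(pmax(1 - lambda^2, 1e-12))
  # chi density of W: 2 (df/2)^(df/2) / Gamma(df/2) w^(df-1) exp(-df w^2 / 2)
  log_fw <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(gw$nodes) - df * gw$nodes^2 / 2
  fw <- exp(log_fw)
  # grid over (z, w); conditional independence makes the integrand a product
  qw <- rep(q * gw$nodes, each = n_nodes)          # length nz*nw
  prod_grid <- matrix(1, n_nodes, n_nodes)
  for (j in seq_len(k)) {
    lz <- rep(lambda[j] * gz$nodes, times = n_nodes)
    pj <- stats::pnorm((qw - lz) / cj[j]) - stats::pnorm((-qw - lz) / cj[j])
    prod_grid <- prod_grid * matrix(pj, n_nodes, n_nodes)
  }
  inner <- as.numeric(crossprod(gz$weights * stats::dnorm(gz$nodes), prod_grid))
  min(max(sum(gw$weights * fw * inner), 0), 1)
}

# Gauss-Legendre nodes/weights on [a, b] by Golub-Welsch
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  bk <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- bk
  J[cbind(i + 1, i)] <- bk
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. `U` is the number of
#' pairs `(x_i, y_j)` with `x_i > y_j` (ties counting 1/2), so
#' `U_x + U_y = n_x * n_y`. The exact two-sided p-value is computed by
#' enumerating all `choose(n_x + n_y, n_x)` group labelings when
#' `n_x + n_y <= 12` and there are no ties; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"` (exact when feasible), `"exact"` (error if ties or
#'   too large), or `"normal_approx"`.
#' @return A one-row tibble: `U` (for `x`), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mannwhitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) < 1L || length(y) < 1L) stop_bleb("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop_bleb("samples must be finite")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  U <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  exact_ok <- nx + ny <= 12L && !ties
  if (mode == "exact" && !exact_ok) {
    stop_bleb("exact mode requires n_x + n_y <= 12 and no ties")
  }
  use_exact <- mode == "exact" || (mode == "auto" && exact_ok)
  if (use_exact) {
    r <- rank(pooled)
    combos <- combn(nx + ny, nx)
    u_all <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
    dev <- abs(U - nx * ny / 2)
    p <- mean(abs(u_all - nx * ny / 2) >= dev - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    tie_tab <- table(pooled)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - nx * ny / 2) - 0.5) / sqrt(sig2)
      p <- if (z <= 0) 1 else 2 * stats::pnorm(-z)
    }
    method <- "tie-corrected normal approximation"
  }
  tibble(U = U, p_value = min(p, 1), method = method, n_x = nx, n_y = ny)
}
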