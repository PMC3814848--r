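#' Group effect from a general linear model with age and sex covariates
#'
#' Fits `value ~ 1 + group + age + sex` by ordinary least squares through a
#' QR decomposition of the design matrix and returns the group coefficient
#' with its two-sided t-test on `n - 4` residual degrees of freedom. Age and
#' sex enter as nuisance covariates so that a group contrast between
#' adjacent age groups is adjusted for the within-group age spread and the
#' sex composition.
#'
#' @param values Per-subject metric values.
#' @param group Binary indicator (0/1, logical, or two-level factor).
#' @param age Age in years.
#' @param sex Binary indicator (0/1, logical, or two-level factor).
#' @return A list with `coefficient`, `t_stat`, `p_value` and `df`.
#' @export
glm_group_effect <- function(values, group, age, sex) {
  group <- as.numeric(as.factor(group)) - 1
  sex <- as.numeric(as.factor(sex)) - 1
  n <- length(values)
  if (length(group) != n || length(age) != n || length(sex) != n)
    stop("all inputs must have one entry per subject")
  if (min(table(group)) < 2) stop("need at least two subjects per group")
  X <- cbind(intercept = 1, group = group, age = as.numeric(age), sex = sex)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, values)
  resid <- values - X %*% beta
  df <- n - ncol(X)
  if (df < 1) stop("not enough residual degrees of freedom")
  sigma2 <- sum(resid^2) / df
  if (sigma2 <= 0) {
    # degenerate response (no residual variance): no evidence either way
    return(list(coefficient = beta[["group"]], t_stat = NA_real_,
                p_value = NA_real_, df = df))
  }
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  t_stat <- beta[["group"]] / se
  list(coefficient = beta[["group"]], t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df), df = df)
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control: with p-values sorted ascending, the
#' largest i with `p_(i) <= i q / m` sets the cutoff and every hypothesis at
#' or below it is declared significant.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return A logical mask the length of `p_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mask <- stats::p.adjust(p_values, method = "BH") <= q
  mask & !is.na(mask)
}

#' Adjacent-group comparisons of global and nodal metrics
#'
#' For every adjacent pair in `group_order` and every metric column, fits
#' [glm_group_effect()] with the pair's subjects. Global metrics are
#' reported at the raw p-value; nodal metrics are corrected by
#' Benjamini-Hochberg FDR across regions within each (metric, transition)
#' cell at level `q`.
#'
#' @param global_metrics Data frame with one row per subject: columns
#'   `group`, `age`, `sex` plus one column per global metric.
#' @param nodal_metrics Optional long data frame with one row per subject
#'   and region: columns `group`, `age`, `sex`, `region`, `metric`, `value`.
#' @param group_order Character vector giving the developmental ordering of
#'   the group labels.
#' @param q FDR level for nodal metrics (default 0.05).
#' @return A data frame with columns `metric`, `region` (NA for global
#'   metrics), `transition`, `coefficient`, `t_stat`, `p_value`,
#'   `significant`.
#' @export
compare_adjacent_groups <- function(global_metrics, nodal_metrics = NULL,
                                    group_order, q = 0.05) {
  if (length(group_order) < 2) stop("need at least two ordered groups")
  meta_cols <- c("subject_id", "group", "age", "sex")
  metric_cols <- setdiff(names(global_metrics), meta_cols)
  if (length(metric_cols) == 0) stop("no metric columns found")
  rows <- list()
  for (t in seq_len(length(group_order) - 1)) {
    g1 <- group_order[t]
    g2 <- group_order[t + 1]
    transition <- paste0(g1, "->", g2)
    sub <- global_metrics[global_metrics$group %in% c(g1, g2), , drop = FALSE]
    grp <- as.integer(sub$group == g2)
    for (m in metric_cols) {
      fit <- glm_group_effect(sub[[m]], grp, sub$age, sub$sex)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, region = NA_character_, transition = transition,
        coefficient = fit$coefficient, t_stat = fit$t_stat,
        p_value = fit$p_value,
        significant = !is.na(fit$p_value) && fit$p_value <= 0.05)
    }
    if (!is.null(nodal_metrics)) {
      nsub <- nodal_metrics[nodal_metrics$group %in% c(g1, g2), , drop = FALSE]
      for (m in unique(nsub$metric)) {
        msub <- nsub[nsub$metric == m, , drop = FALSE]
        regions <- unique(msub$region)
        res <- lapply(regions, function(r) {
          rs <- msub[msub$region == r, , drop = FALSE]
          fit <- glm_group_effect(rs$value, as.integer(rs$group == g2),
                                  rs$age, rs$sex)
          data.frame(metric = m, region = r, transition = transition,
                     coefficient = fit$coefficient, t_stat = fit$t_stat,
                     p_value = fit$p_value, significant = NA)
        })
        res <- do.call(rbind, res)
        res$significant <- fdr_bh(res$p_value, q)
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
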