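.test_result <- function(statistic, p, method, posthoc = NULL, ...) {
  structure(list(statistic = statistic, p = p, posthoc = posthoc,
                 method = method, ...),
            class = "cda_test_result")
}

#' @export
print.cda_test_result <- function(x, ...) {
  cat("<cda_test_result>", x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p))
  if (!is.null(x$posthoc)) {
    cat("  post hoc comparisons:\n")
    print.data.frame(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

.check_matrix <- function(mat, min_cols) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("missing cells: repeated-measures procedures need a complete matrix")
  if (ncol(mat) < min_cols) stop("need at least ", min_cols, " conditions")
  if (nrow(mat) < 2) stop("need at least 2 subjects")
  mat
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the vetted [stats::shapiro.test()] routine with the
#' protocol's domain checks (3 <= n <= 50, non-degenerate series).
#'
#' @param x Numeric series.
#' @return A `cda_test_result` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 50) {
    stop("Shapiro-Wilk requires 3 <= n <= 50 (got n = ", length(x), ")")
  }
  if (stats::sd(x) == 0) stop("degenerate series: all values identical")
  sw <- stats::shapiro.test(x)
  .test_result(unname(sw$statistic), sw$p.value, "Shapiro-Wilk normality test")
}

#' Holm-Sidak step-down adjustment
#'
#' Orders the m raw p-values increasingly and adjusts the i-th as
#' `1 - (1 - p_(i))^(m - i + 1)`, enforcing step-down monotonicity
#' (running maximum) and capping at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Repeated-measures ANOVA with Holm-Sidak post hoc
#'
#' One-way within-subjects ANOVA on a complete subjects x conditions matrix
#' (classical partition: condition and subject sums of squares removed from
#' the total; F = MS_condition / MS_error on (k-1), (k-1)(n-1) df), followed
#' by pairwise paired t-tests with Holm-Sidak adjustment when requested.
#' No sphericity correction is applied.
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions.
#' @param posthoc Run the pairwise comparisons (default TRUE).
#' @return A `cda_test_result`: F statistic, p, and a post hoc table with
#'   raw and adjusted pairwise p-values.
#' @export
rm_anova_holm_sidak <- function(mat, posthoc = TRUE) {
  mat <- .check_matrix(mat, 2)
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- max(0, ss_tot - ss_cond - ss_subj)
  df_cond <- k - 1
  df_err <- (k - 1) * (n - 1)
  if (ss_cond <= 1e-12 * max(1, ss_tot)) {
    f <- 0; p <- 1
  } else {
    f <- (ss_cond / df_cond) / (ss_err / df_err)
    p <- stats::pf(f, df_cond, df_err, lower.tail = FALSE)
  }
  ph <- NULL
  if (posthoc && k >= 2) {
    pairs <- utils::combn(k, 2)
    raw <- apply(pairs, 2, function(ij) {
      d <- mat[, ij[1]] - mat[, ij[2]]
      if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
      stats::t.test(d)$p.value
    })
    cn <- colnames(mat) %||% paste0("C", seq_len(k))
    ph <- data.frame(group1 = cn[pairs[1, ]], group2 = cn[pairs[2, ]],
                     raw_p = raw, adj_p = holm_sidak(raw))
  }
  .test_result(f, p, "Repeated-measures ANOVA + Holm-Sidak", posthoc = ph,
               df = c(df_cond, df_err))
}

#' Friedman rank statistic
#'
#' `chi2_F = 12 / (n k (k+1)) * sum_j R_j^2 - 3 n (k+1)`, with mid-ranks for
#' ties within subjects.
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions.
#' @return The chi-squared-distributed Friedman statistic.
#' @export
friedman_statistic <- function(mat) {
  mat <- .check_matrix(mat, 2)
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

#' Friedman test with Dunn's multiple comparisons
#'
#' Omnibus Friedman test across conditions (asymptotic chi-squared p on k-1
#' df, or the exact within-row permutation distribution for small designs),
#' followed by Dunn's pairwise z-tests on mean ranks,
#' `z = |Rbar_i - Rbar_j| / sqrt(k (k+1) / (6 n))`, with Bonferroni family
#' correction (the common convention for "Dunn's multiple comparisons").
#'
#' @param mat Numeric matrix, rows = subjects, columns = conditions (>= 3).
#' @param p_method `"asymptotic"` (default) or `"exact"`; exact enumerates
#'   all within-subject rank permutations and is limited to small designs
#'   (k!^n <= 2e5).
#' @param posthoc Run Dunn's comparisons (default TRUE).
#' @return A `cda_test_result`: chi2_F, p, and Dunn's post hoc table.
#' @export
friedman_dunn <- function(mat, p_method = c("asymptotic", "exact"),
                          posthoc = TRUE) {
  p_method <- match.arg(p_method)
  mat <- .check_matrix(mat, 3)
  n <- nrow(mat); k <- ncol(mat)
  stat <- friedman_statistic(mat)
  if (p_method == "asymptotic") {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    n_perm <- factorial(k)^n
    if (n_perm > 2e5) stop("exact permutation p limited to k!^n <= 2e5")
    perms <- .permutations(k)
    ranks <- t(apply(mat, 1, rank))
    # enumerate one permutation choice per row
    choice <- rep(1L, n)
    stats_all <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      rj <- colSums(do.call(rbind, lapply(seq_len(n), function(r) {
        ranks[r, perms[choice[r], ]]
      })))
      stats_all[i] <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
      # odometer increment
      for (r in seq_len(n)) {
        choice[r] <- choice[r] + 1L
        if (choice[r] <= nrow(perms)) break
        choice[r] <- 1L
      }
    }
    p <- mean(stats_all >= stat - 1e-9)
  }
  ph <- NULL
  if (posthoc) {
    ranks <- t(apply(mat, 1, rank))
    rbar <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    z <- abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
    raw <- 2 * stats::pnorm(-z)
    cn <- colnames(mat) %||% paste0("C", seq_len(k))
    ph <- data.frame(group1 = cn[pairs[1, ]], group2 = cn[pairs[2, ]],
                     z = unname(z), raw_p = unname(raw),
                     adj_p = pmin(1, unname(raw) * m))
  }
  .test_result(stat, p, paste0("Friedman test (", p_method,
                               ") + Dunn's multiple comparisons"),
               posthoc = ph, df = k - 1)
}

# All permutations of 1..k as a matrix (k! x k).
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
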