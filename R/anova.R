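#' Repeated-measures ANOVA with sphericity handling
#'
#' One- or two-way fully within-subject ANOVA on a cell-means table (one
#' value per participant x cell). Mauchly's test is run for every effect with
#' more than two levels; when it indicates a sphericity violation
#' (p < `alpha_sphericity`) the Greenhouse-Geisser correction is applied to
#' the degrees of freedom and the corrected p-value is reported. When the
#' covariance matrix of the within-subject contrasts is singular (so
#' sphericity cannot be assessed), the one-way analysis falls back to the
#' non-parametric Friedman test.
#'
#' Only participants with complete cells enter the analysis; dropped
#' participants are listed in the result.
#'
#' @param data long-format data frame of cell means.
#' @param dv name of the dependent-variable column.
#' @param subject name of the participant identifier column.
#' @param within character vector of one or two within-subject factor columns.
#' @param eta `"total"` (effect SS / total SS, the default) or `"partial"`.
#' @param alpha_sphericity threshold on Mauchly's p for applying the
#'   correction.
#' @return an object of class `anova_result`: a list with `table` (one row
#'   per effect: `effect`, `F`, `df_num`, `df_den`, `p`, `eta_squared`,
#'   `mauchly_W`, `mauchly_p`, `gg_epsilon`, `corrected`), `fallback`
#'   (Friedman result when used, else `NULL`), `n_subjects` and
#'   `dropped_subjects`.
#' @export
rm_anova <- function(data, dv, subject, within, eta = c("total", "partial"),
                     alpha_sphericity = 0.05) {
  eta <- match.arg(eta)
  stopifnot(length(within) %in% 1:2,
            all(c(dv, subject, within) %in% names(data)))
  df <- tibble::as_tibble(data)[c(subject, within, dv)]
  names(df) <- c(".subject", paste0(".f", seq_along(within)), ".y")
  fcols <- paste0(".f", seq_along(within))
  for (f in fcols) df[[f]] <- factor(df[[f]])

  wide <- tidyr::pivot_wider(df, names_from = dplyr::all_of(fcols),
                             values_from = ".y", names_sep = "|")
  complete <- complete.cases(wide)
  dropped <- wide$.subject[!complete]
  wide <- wide[complete, ]
  n_sub <- nrow(wide)
  if (n_sub < 3L) stop("need at least 3 participants with complete cells")

  levels_list <- lapply(df[fcols], levels)
  cells <- rev(expand.grid(rev(levels_list), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE))
  names(cells) <- fcols
  cell_names <- do.call(paste, c(as.list(cells), sep = "|"))
  absent <- setdiff(cell_names, names(wide))
  if (length(absent) > 0L) {
    stop("no participant has data for cell(s): ", paste(absent, collapse = ", "))
  }
  Y <- as.matrix(wide[cell_names])

  effect_label <- function(eff) {
    lbl <- within[match(strsplit(eff, ":")[[1L]], fcols)]
    paste(lbl, collapse = ":")
  }

  ss <- ss_decomposition(Y, cells, within)

  # effects whose between-level variance is exactly zero are F = 0, p = 1
  # and need no sphericity machinery
  if (all(ss$table$ss_effect <= 1e-12 * max(ss$total, 1e-300))) {
    tab <- tibble::tibble(
      effect = vapply(ss$table$effect, effect_label, character(1)),
      F = 0, df_num = ss$table$df_num,
      df_den = ss$table$df_num * (n_sub - 1L), p = 1, eta_squared = 0,
      mauchly_W = NA_real_, mauchly_p = NA_real_, gg_epsilon = NA_real_,
      corrected = FALSE)
    return(new_anova_result(tab, NULL, n_sub, dropped))
  }

  if (contrast_cov_singular(Y)) {
    if (length(within) == 1L) {
      fb <- friedman_test(Y)
      return(new_anova_result(NULL, fb, n_sub, dropped))
    }
    stop(paste(
      "within-cell covariance matrix is singular; sphericity cannot be",
      "assessed for the two-way design -- run the one-way analyses",
      "(Friedman fallback) per factor instead"))
  }

  idata <- as.data.frame(lapply(cells, function(v)
    factor(v, levels = unique(v))))
  idesign <- stats::as.formula(paste("~", paste(fcols, collapse = "*")))
  fit <- lm(Y ~ 1)
  a <- car::Anova(fit, idata = idata, idesign = idesign, type = "III")
  s <- suppressWarnings(summary(a, multivariate = FALSE))  # HF eps > 1 notice
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  effects <- ss$table$effect
  rows <- lapply(effects, function(eff) {
    r <- uni[eff, ]
    k_df <- r[["num Df"]]
    mW <- if (!is.null(sph) && eff %in% rownames(sph))
      sph[eff, "Test statistic"] else NA_real_
    mp <- if (!is.null(sph) && eff %in% rownames(sph))
      sph[eff, "p-value"] else NA_real_
    eps <- if (!is.null(adj) && eff %in% rownames(adj))
      adj[eff, "GG eps"] else NA_real_
    p_gg <- if (!is.null(adj) && eff %in% rownames(adj))
      adj[eff, "Pr(>F[GG])"] else NA_real_
    if (k_df < 2L) { mW <- NA_real_; mp <- NA_real_; eps <- 1 }
    Fv <- r[["F value"]]
    pv <- r[["Pr(>F)"]]
    if (!is.finite(Fv) && r[["Sum Sq"]] <= 1e-12 * max(ss$total, 1e-300)) {
      Fv <- 0; pv <- 1
    }
    corrected <- is.finite(mp) && mp < alpha_sphericity
    tibble::tibble(
      effect = effect_label(eff), F = Fv,
      df_num = if (corrected) eps * k_df else k_df,
      df_den = if (corrected) eps * r[["den Df"]] else r[["den Df"]],
      p = if (corrected) p_gg else pv,
      eta_squared = if (eta == "total") r[["Sum Sq"]] / ss$total else
        r[["Sum Sq"]] / (r[["Sum Sq"]] + r[["Error SS"]]),
      mauchly_W = mW, mauchly_p = mp, gg_epsilon = eps,
      corrected = corrected)
  })
  new_anova_result(dplyr::bind_rows(rows), NULL, n_sub, dropped)
}

new_anova_result <- function(table, fallback, n_subjects, dropped) {
  structure(list(table = table, fallback = fallback,
                 n_subjects = n_subjects,
                 dropped_subjects = as.character(dropped)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %d participants", x$n_subjects))
  if (length(x$dropped_subjects) > 0L) {
    cat(sprintf(" (%d dropped: %s)", length(x$dropped_subjects),
                paste(x$dropped_subjects, collapse = ", ")))
  }
  cat("\n")
  if (!is.null(x$fallback)) {
    cat(sprintf(
      "Friedman fallback (singular covariance): chi2(%d) = %.3f, p = %.4g, Kendall's W = %.3f\n",
      x$fallback$df, x$fallback$chi2, x$fallback$p, x$fallback$kendalls_W))
  } else {
    print(as.data.frame(x$table))
  }
  invisible(x)
}

# balanced fully-within SS decomposition on the subject x cell matrix
ss_decomposition <- function(Y, cells, within) {
  grand <- mean(Y)
  total <- sum((Y - grand)^2)
  f1 <- cells[[1L]]
  tabs <- list()
  eff_ss <- function(means, reps) reps * sum((means - grand)^2)
  m1 <- tapply(colMeans(Y), f1, mean)
  tabs[[".f1"]] <- tibble::tibble(
    effect = ".f1", df_num = length(m1) - 1L,
    ss_effect = eff_ss(m1, nrow(Y) * ncol(Y) / length(m1)))
  if (ncol(cells) == 2L) {
    f2 <- cells[[2L]]
    m2 <- tapply(colMeans(Y), f2, mean)
    m12 <- tapply(colMeans(Y), list(f1, f2), mean)
    inter <- sweep(sweep(m12, 1L, m1), 2L, m2) + grand
    tabs[[".f2"]] <- tibble::tibble(
      effect = ".f2", df_num = length(m2) - 1L,
      ss_effect = eff_ss(m2, nrow(Y) * ncol(Y) / length(m2)))
    tabs[[".f1:.f2"]] <- tibble::tibble(
      effect = ".f1:.f2",
      df_num = (length(m1) - 1L) * (length(m2) - 1L),
      ss_effect = nrow(Y) * sum(inter^2))
  }
  list(table = dplyr::bind_rows(tabs), total = total)
}

contrast_cov_singular <- function(Y, tol = 1e-10) {
  k <- ncol(Y)
  C <- stats::contr.helmert(k)
  D <- Y %*% C
  S <- stats::cov(D)
  if (nrow(Y) <= k - 1L) return(TRUE)
  qr(S, tol = tol)$rank < (k - 1L)
}

#' Friedman test with Kendall's W
#'
#' Rank-based test of level differences across participants (ties-corrected
#' chi-square via [stats::friedman.test()]); Kendall's coefficient of
#' concordance is `W = chi2 / (n (k - 1))`.
#'
#' @param y a participants x levels matrix, or a long data frame together
#'   with `dv`, `subject` and `within` column names.
#' @param dv,subject,within column names when `y` is a long data frame.
#' @return a list with `chi2`, `df`, `p` and `kendalls_W`.
#' @export
friedman_test <- function(y, dv = NULL, subject = NULL, within = NULL) {
  if (is.data.frame(y) && !is.null(dv)) {
    wide <- tidyr::pivot_wider(tibble::as_tibble(y)[c(subject, within, dv)],
                               names_from = dplyr::all_of(within),
                               values_from = dplyr::all_of(dv))
    y <- as.matrix(wide[, -1L])
  }
  y <- as.matrix(y)
  stopifnot(nrow(y) >= 3L, ncol(y) >= 3L)
  ft <- friedman.test(y)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(chi2)) { chi2 <- 0; p <- 1 }   # every rank tied
  list(chi2 = chi2, df = unname(ft$parameter), p = p,
       kendalls_W = chi2 / (nrow(y) * (ncol(y) - 1L)))
}
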