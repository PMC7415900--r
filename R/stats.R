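#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor for a within-subject factor with k levels:
#' `eps = tr(S~)^2 / ((k - 1) * tr(S~^2))` where `S~` is the covariance of
#' the data projected onto any orthonormal basis of contrasts among the k
#' levels (the estimate is basis-invariant). Always lies in
#' `[1 / (k - 1), 1]`, with 1 under exact sphericity (and exactly 1 for
#' k = 2, where only a single contrast exists).
#'
#' @param values Numeric matrix, subjects in rows, factor levels in columns.
#' @return The epsilon estimate.
#' @export
gg_epsilon <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2L) abort("At least 2 within-subject levels are required.")
  if (nrow(values) < 2L) abort("At least 2 subjects are required.")
  S <- cov(values)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  St <- crossprod(C, S %*% C)
  tr <- sum(diag(St))
  tr2 <- sum(St * St)
  if (tr2 <= 0) return(1)
  min(1, max(1 / (k - 1), tr^2 / ((k - 1) * tr2)))
}

complete_rm_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("animal_id", "eye", "week", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("Table lacks columns: ", paste(miss, collapse = ", ")))
  cells <- tidyr::expand_grid(eye = sort(unique(data$eye)),
                              week = sort(unique(data$week)))
  counts <- data |>
    dplyr::distinct(.data$animal_id, .data$eye, .data$week) |>
    dplyr::count(.data$animal_id)
  full_n <- nrow(cells)
  incomplete <- counts$animal_id[counts$n < full_n]
  if (length(incomplete)) {
    warn(paste0("Dropping animals with incomplete designs: ",
                paste(incomplete, collapse = ", ")))
    data <- dplyr::filter(data, !.data$animal_id %in% incomplete)
  }
  if (length(unique(data$animal_id)) < 1L) abort("No animals with a complete design remain.")
  data
}

#' Two-way repeated-measures ANOVA (week x eye within animal)
#'
#' Univariate within-subject ANOVA with both factors repeated within animal.
#' Sums of squares are formed from subject-by-cell means; each within-subject
#' effect is tested against its own subject-interaction error stratum
#' (`F_week = MS_week / MS_(week x animal)`, and similarly for eye and the
#' week x eye interaction). Effects involving week are Greenhouse-Geisser
#' corrected: degrees of freedom are multiplied by the epsilon estimated from
#' the corresponding subject-level contrast data and the p-value recomputed
#' from the F distribution with the corrected degrees of freedom.
#'
#' Animals with incomplete designs are dropped with a warning. If an error
#' mean square is zero (degenerate data) the effect is reported as F = 0,
#' p = 1 when its own sum of squares is also zero, or F = Inf, p = 0
#' otherwise, with a warning.
#'
#' @param data Tibble with columns `animal_id`, `eye`, `week`, `value`.
#' @return A tibble of class `octa_rm_anova` with one row per effect
#'   (`week`, `eye`, `week:eye`): `df1`, `df2`, `ss`, `ss_error`, `statistic`
#'   (F), `epsilon_gg`, `p_uncorrected`, `p_gg`.
#' @export
rm_anova_week <- function(data) {
  data <- complete_rm_table(data)
  weeks <- sort(unique(data$week)); k <- length(weeks)
  eyes <- sort(unique(data$eye)); a <- length(eyes)
  animals <- sort(unique(data$animal_id)); n <- length(animals)
  if (k < 2L) abort("At least 2 weeks are required.")
  if (n < 3L) abort("At least 3 animals are required.")

  Y <- array(NA_real_, dim = c(n, a, k), dimnames = list(animals, eyes, weeks))
  Y[cbind(match(data$animal_id, animals), match(data$eye, eyes),
          match(data$week, weeks))] <- data$value
  if (anyNA(Y)) abort("Design is incomplete after dropping incomplete animals.")

  m <- mean(Y)
  m_s <- apply(Y, 1, mean); m_e <- apply(Y, 2, mean); m_w <- apply(Y, 3, mean)
  m_se <- apply(Y, c(1, 2), mean); m_sw <- apply(Y, c(1, 3), mean)
  m_ew <- apply(Y, c(2, 3), mean)

  ss_w <- n * a * sum((m_w - m)^2)
  ss_e <- n * k * sum((m_e - m)^2)
  ss_ew <- n * sum((m_ew - outer(m_e, rep(1, k)) - outer(rep(1, a), m_w) + m)^2)
  ss_sw <- a * sum((m_sw - outer(m_s, rep(1, k)) - outer(rep(1, n), m_w) + m)^2)
  ss_se <- k * sum((m_se - outer(m_s, rep(1, a)) - outer(rep(1, n), m_e) + m)^2)
  fit3 <- array(0, dim = dim(Y))
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(k)) {
    fit3[i, j, l] <- m_se[i, j] + m_sw[i, l] + m_ew[j, l] - m_s[i] - m_e[j] - m_w[l] + m
  }
  ss_res <- sum((Y - fit3)^2)

  eps_w <- gg_epsilon(m_sw)
  # week x eye: epsilon from the per-animal eye-difference profile across weeks
  eps_ew <- if (a == 2L) gg_epsilon(Y[, 2, , drop = TRUE] - Y[, 1, , drop = TRUE]) else NA_real_

  one_effect <- function(effect, ss, df1, ss_err, df2, eps) {
    if (ss_err <= 1e-300 * max(1, ss)) {
      if (ss <= 1e-300) {
        warn(sprintf("Degenerate data for effect '%s': zero effect and error variance.", effect))
        Fv <- 0; p <- 1
      } else {
        warn(sprintf("Zero error variance for effect '%s'.", effect))
        Fv <- Inf; p <- 0
      }
    } else {
      Fv <- (ss / df1) / (ss_err / df2)
      p <- pf(Fv, df1, df2, lower.tail = FALSE)
    }
    p_gg <- if (!is.na(eps) && is.finite(Fv) && Fv > 0) {
      pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    } else p
    tibble::tibble(effect = effect, df1 = df1, df2 = df2, ss = ss, ss_error = ss_err,
                   statistic = Fv, epsilon_gg = eps, p_uncorrected = p, p_gg = p_gg)
  }

  out <- dplyr::bind_rows(
    one_effect("week", ss_w, k - 1, ss_sw, (n - 1) * (k - 1), eps_w),
    one_effect("eye", ss_e, a - 1, ss_se, (n - 1) * (a - 1), NA_real_),
    one_effect("week:eye", ss_ew, (a - 1) * (k - 1), ss_res, (n - 1) * (a - 1) * (k - 1), eps_ew)
  )
  class(out) <- c("octa_rm_anova", class(out))
  attr(out, "n_animals") <- n
  attr(out, "weeks") <- weeks
  out
}

eye_averaged <- function(data) {
  tibble::as_tibble(data) |>
    dplyr::group_by(.data$animal_id, .data$week) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

paired_t <- function(d) {
  n <- length(d)
  s <- sd(d)
  est <- mean(d)
  if (s <= 0) {
    if (abs(est) <= 0) return(list(t = 0, df = n - 1, p = 1, estimate = est))
    warn("Zero-variance paired differences; reporting t = Inf.")
    return(list(t = Inf, df = n - 1, p = 0, estimate = est))
  }
  tv <- est / (s / sqrt(n))
  list(t = tv, df = n - 1, p = 2 * pt(abs(tv), n - 1, lower.tail = FALSE), estimate = est)
}

#' Consecutive-week pairwise contrasts
#'
#' Eye-averaged values per animal are compared between each pair of adjacent
#' weeks with a paired t-test across animals; the `k - 1` p-values are
#' Bonferroni-corrected (`p_adj = min(1, m * p)` with family size
#' `m = k - 1`).
#'
#' @param data Tibble with columns `animal_id`, `eye`, `week`, `value`.
#' @return Tibble of class `octa_contrasts`: `label`, `estimate`,
#'   `statistic`, `df`, `p_raw`, `p_bonferroni`, `family_size`.
#' @export
consecutive_contrasts <- function(data) {
  d <- eye_averaged(data)
  weeks <- sort(unique(d$week)); k <- length(weeks)
  if (k < 2L) abort("At least 2 weeks are required.")
  wide <- tidyr::pivot_wider(d, names_from = "week", values_from = "value") |>
    dplyr::arrange(.data$animal_id)
  M <- as.matrix(wide[, as.character(weeks)])
  if (anyNA(M)) abort("Incomplete week coverage across animals.")
  if (nrow(M) < 3L) abort("At least 3 animals are required for paired contrasts.")
  m <- k - 1L
  out <- purrr::map_dfr(seq_len(m), function(i) {
    tt <- paired_t(M[, i + 1L] - M[, i])
    tibble::tibble(
      label = sprintf("wk%d-wk%d", weeks[i], weeks[i + 1L]),
      estimate = tt$estimate, statistic = tt$t, df = tt$df,
      p_raw = tt$p, p_bonferroni = min(1, m * tt$p), family_size = m
    )
  })
  class(out) <- c("octa_contrasts", class(out))
  out
}

#' Orthogonal linear polynomial contrast coefficients
#'
#' Integer coefficients for k equally spaced levels: deviations from the
#' center, doubled when k is even so that all coefficients are whole numbers
#' (k = 6 gives -5, -3, -1, 1, 3, 5). They sum to zero and are orthogonal to
#' the constant.
#'
#' @param k Number of equally spaced levels (>= 2).
#' @return Integer coefficient vector of length k.
#' @export
linear_contrast_coefficients <- function(k) {
  if (k < 2L) abort("Need at least 2 levels.")
  d <- seq_len(k) - (k + 1) / 2
  if (k %% 2L == 0L) d <- 2 * d
  as.integer(d)
}

#' Linear trend contrast across weeks (P trend)
#'
#' Scores each animal's eye-averaged profile with the orthogonal linear
#' polynomial coefficients for equally spaced weeks and tests the scores
#' against zero with a one-sample t-test (two-sided). A negative estimate
#' means a decreasing trend.
#'
#' @param data Tibble with columns `animal_id`, `eye`, `week`, `value`;
#'   weeks must be equally spaced with k >= 3.
#' @return One-row tibble of class `octa_contrasts`: `label`, `estimate`,
#'   `statistic`, `df`, `p_raw`.
#' @export
linear_trend_contrast <- function(data) {
  d <- eye_averaged(data)
  weeks <- sort(unique(d$week)); k <- length(weeks)
  if (k < 3L) abort("At least 3 weeks are required for a trend contrast.")
  sp <- diff(weeks)
  if (max(sp) - min(sp) > 1e-9) abort("Weeks must be equally spaced.")
  cw <- linear_contrast_coefficients(k)
  wide <- tidyr::pivot_wider(d, names_from = "week", values_from = "value") |>
    dplyr::arrange(.data$animal_id)
  M <- as.matrix(wide[, as.character(weeks)])
  if (anyNA(M)) abort("Incomplete week coverage across animals.")
  L <- drop(M %*% cw)
  tt <- paired_t(L)
  out <- tibble::tibble(
    label = "linear trend", estimate = tt$estimate, statistic = tt$t,
    df = tt$df, p_raw = tt$p, p_bonferroni = tt$p, family_size = 1L
  )
  attr(out, "coefficients") <- cw
  class(out) <- c("octa_contrasts", class(out))
  out
}

#' One-way ANOVA across age groups with pairwise comparisons
#'
#' Standard between-groups F-test plus all pairwise Welch t-tests, Bonferroni
#' corrected with family size `choose(g, 2)`. Groups with fewer than 2 values
#' are dropped with a warning. Used for the cross-sectional control cohort,
#' with eyes averaged per animal beforehand.
#'
#' @param data Tibble with columns `group` (age group) and `value`.
#' @return List with `anova` (one-row tibble: `df1`, `df2`, `statistic`,
#'   `p_value`) and `contrasts` (pairwise tibble of class `octa_contrasts`).
#' @export
oneway_anova <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("group", "value") %in% names(data)))
  sizes <- table(data$group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warn(paste0("Dropping groups with fewer than 2 values: ", paste(small, collapse = ", ")))
    data <- dplyr::filter(data, !.data$group %in% small)
  }
  groups <- sort(unique(data$group)); g <- length(groups)
  if (g < 2L) abort("At least 2 groups with >= 2 values each are required.")
  N <- nrow(data)
  gm <- mean(data$value)
  means <- tapply(data$value, data$group, mean)
  ns <- tapply(data$value, data$group, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((data$value - means[as.character(data$group)])^2)
  df1 <- g - 1L; df2 <- N - g
  if (ss_w <= 1e-300 * max(1, ss_b)) {
    if (ss_b <= 1e-300) {
      warn("Degenerate one-way data: zero between- and within-group variance.")
      Fv <- 0; p <- 1
    } else {
      warn("Zero within-group variance; reporting F = Inf.")
      Fv <- Inf; p <- 0
    }
  } else {
    Fv <- (ss_b / df1) / (ss_w / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  anova_row <- tibble::tibble(df1 = df1, df2 = df2, statistic = Fv, p_value = p)

  m <- choose(g, 2)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    x <- data$value[data$group == pr[1]]
    y <- data$value[data$group == pr[2]]
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    est <- mean(y) - mean(x)
    if (vx + vy <= 0) {
      tv <- if (abs(est) <= 0) 0 else Inf
      df <- length(x) + length(y) - 2
      pr_p <- if (tv == 0) 1 else 0
    } else {
      tv <- est / sqrt(vx + vy)
      df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
      pr_p <- 2 * pt(abs(tv), df, lower.tail = FALSE)
    }
    tibble::tibble(label = sprintf("%s-%s", pr[1], pr[2]), estimate = est,
                   statistic = tv, df = df, p_raw = pr_p,
                   p_bonferroni = min(1, m * pr_p), family_size = m)
  })
  class(contrasts) <- c("octa_contrasts", class(contrasts))
  list(anova = anova_row, contrasts = contrasts)
}

#' @export
tidy.octa_rm_anova <- function(x, ...) {
  tibble::as_tibble(x)[, c("effect", "df1", "df2", "statistic",
                           "epsilon_gg", "p_uncorrected", "p_gg")]
}

#' @export
glance.octa_rm_anova <- function(x, ...) {
  wk <- x[x$effect == "week", ]
  tibble::tibble(n_animals = attr(x, "n_animals"),
                 n_weeks = length(attr(x, "weeks")),
                 f_week = wk$statistic, epsilon_gg = wk$epsilon_gg,
                 p_week_gg = wk$p_gg)
}

#' @export
tidy.octa_contrasts <- function(x, ...) {
  tibble::as_tibble(x)
}
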