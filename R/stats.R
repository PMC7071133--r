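# Inferential layer: Shapiro-Wilk normality screening, fully within-subject
# repeated-measures ANOVA with Greenhouse-Geisser / Huynh-Feldt sphericity
# corrections and partial eta squared, and Bonferroni-adjusted pairwise
# post-hoc comparisons. Sums of squares come from base aov() Error strata;
# the epsilon computation, the 0.75 selection rule, the effect sizes and the
# balanced-design guard live here.

#' Shapiro-Wilk normality screen per cell
#'
#' @param data long data.frame.
#' @param dv dependent-variable column.
#' @param cells character vector of columns defining the cells.
#' @return data.frame per cell with `n`, `W`, `p` (NA for undefined cells:
#'   n < 3 or constant values); attribute `"fraction_normal"` is the share
#'   of defined cells with p > 0.05.
#' @export
normality_screen <- function(data, dv, cells) {
  key <- interaction(data[cells], drop = TRUE)
  rows <- lapply(split(data, key), function(cell) {
    x <- cell[[dv]][!is.na(cell[[dv]])]
    base <- cell[1, cells, drop = FALSE]
    if (length(x) < 3)
      stop("normality screen needs at least 3 values per cell (got ",
           length(x), ")")
    if (stats::sd(x) == 0)
      return(data.frame(base, n = length(x), W = NA_real_, p = NA_real_,
                        row.names = NULL))
    sw <- stats::shapiro.test(x)
    data.frame(base, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$p)
  attr(out, "fraction_normal") <- if (any(ok)) mean(out$p[ok] > 0.05) else NA_real_
  out
}

# Orthonormal contrast rows for a k-level factor ((k-1) x k).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)          # k x (k-1), orthogonal columns
  C <- sweep(C, 2, sqrt(colSums(C^2)), `/`)
  t(C)
}

# GG / HF epsilons for one within-subject effect. Y is the n x p matrix of
# per-subject cell means over the factors in the effect (cells in a fixed
# factor order); `levels` gives the level counts of the involved factors.
effect_epsilons <- function(Y, levels) {
  n <- nrow(Y)
  M <- Reduce(kronecker, lapply(levels, orthonormal_contrasts))
  d <- nrow(M)
  S <- M %*% stats::cov(Y) %*% t(M)
  tr <- sum(diag(S))
  if (tr < 1e-300) return(c(gg = 1, hf = 1, d = d))  # no within-cell variance
  gg <- tr^2 / (d * sum(S * S))
  hf_num <- n * d * gg - 2
  hf_den <- d * (n - 1 - d * gg)
  hf <- if (hf_den <= 0) 1 else hf_num / hf_den
  hf <- min(1, max(hf, gg))
  c(gg = gg, hf = hf, d = d)
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' Fully within-subject ANOVA over crossed factors. Participants with any
#' missing or incomplete cell are dropped listwise with a warning (the
#' design must be balanced and complete for the classical partitioning).
#' For every effect whose numerator degrees of freedom exceed one,
#' Greenhouse-Geisser and Huynh-Feldt epsilons are computed from the
#' orthonormally contrast-transformed covariance; the Huynh-Feldt
#' correction is applied when the Greenhouse-Geisser epsilon exceeds 0.75
#' and the Greenhouse-Geisser correction otherwise. Effect sizes are
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long data.frame with one value per subject x cell.
#' @param dv dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param subject subject-identifier column.
#' @return an `rm_anova` data.frame: one row per effect with df, F,
#'   epsilons, applied correction, corrected df, p and partial eta
#'   squared; attribute `"dropped"` lists excluded subjects.
#' @export
rm_anova <- function(data, dv, within, subject = "participant") {
  data <- as.data.frame(data)
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  data <- data[, c(subject, within, dv)]

  levels_n <- vapply(data[within], nlevels, integer(1))
  p_cells <- prod(levels_n)
  # listwise completeness guard
  complete <- vapply(split(data, data[[subject]]), function(s) {
    !anyNA(s[[dv]]) &&
      nrow(unique(s[within])) == p_cells && nrow(s) == p_cells
  }, logical(1))
  dropped <- names(complete)[!complete]
  if (length(dropped)) {
    warning("dropping subject(s) with incomplete cells: ",
            paste(dropped, collapse = ", "))
    data <- data[data[[subject]] %in% names(complete)[complete], ]
    data[[subject]] <- droplevels(data[[subject]])
  }
  n <- nlevels(data[[subject]])
  if (n < 2) stop("need at least two complete subjects")

  f <- stats::as.formula(paste(dv, "~", paste(within, collapse = "*"),
                               "+ Error(", subject, "/(",
                               paste(within, collapse = "*"), "))"))
  fit <- stats::aov(f, data = data)
  smry <- summary(fit)

  # collect effect and residual SS per error stratum
  effects <- list()
  ss_all <- 0
  for (stratum in smry) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    ss_all <- ss_all + sum(tab[, "Sum Sq"])
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    ss_err <- tab[resid_i, "Sum Sq"]; df_err <- tab[resid_i, "Df"]
    for (i in seq_len(nrow(tab))) {
      if (i == resid_i || terms[i] == "Residuals") next
      effects[[terms[i]]] <- list(df = tab[i, "Df"], ss = tab[i, "Sum Sq"],
                                  df_err = df_err, ss_err = ss_err,
                                  F = tab[i, "F value"])
    }
  }

  rows <- lapply(names(effects), function(term) {
    ef <- effects[[term]]
    facs <- strsplit(term, ":")[[1]]
    Y <- subject_cell_matrix(data, dv, facs, subject)
    d <- ef$df
    if (d > 1) {
      eps <- effect_epsilons(Y, levels_n[facs])
      correction <- if (eps["gg"] > 0.75) "HF" else "GG"
      eps_used <- unname(if (correction == "HF") eps["hf"] else eps["gg"])
    } else {
      eps <- c(gg = 1, hf = 1)
      correction <- "none"
      eps_used <- 1
    }
    df1c <- ef$df * eps_used
    df2c <- ef$df_err * eps_used
    Fv <- ef$F
    pes <- ef$ss / (ef$ss + ef$ss_err)
    pv <- stats::pf(Fv, df1c, df2c, lower.tail = FALSE)
    # degenerate data: an effect SS at rounding-noise level is zero
    if (ef$ss <= 1e-12 * max(sum((data[[dv]] - mean(data[[dv]]))^2), 1e-12)) {
      Fv <- 0; pes <- 0; pv <- 1
    }
    data.frame(effect = term, df = ef$df, df_error = ef$df_err,
               ss = ef$ss, ss_error = ef$ss_err,
               F = Fv, eps_gg = unname(eps["gg"]), eps_hf = unname(eps["hf"]),
               correction = correction,
               df_corrected = df1c, df_error_corrected = df2c,
               p = pv, pes = pes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_subjects") <- n
  attr(out, "ss_strata_total") <- ss_all
  attr(out, "ss_grand_total") <- sum((data[[dv]] - mean(data[[dv]]))^2)
  class(out) <- c("rm_anova", class(out))
  out
}

# n x p matrix of per-subject means over the cells of `facs` (cells ordered
# by the factor-level expansion used by effect_epsilons).
subject_cell_matrix <- function(data, dv, facs, subject) {
  agg <- stats::aggregate(data[[dv]],
                          by = c(data[facs], data[subject]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- ".y"
  # kronecker(A, B) has B varying fastest, so sort with the last factor as
  # the last (fastest) key to match Reduce(kronecker, contrasts).
  ord <- do.call(order, c(agg[subject], agg[facs]))
  agg <- agg[ord, ]
  matrix(agg$.y, nrow = nlevels(data[[subject]]), byrow = TRUE)
}

#' Bonferroni-adjusted pairwise post-hoc comparisons
#'
#' Paired t-tests between all level pairs of one within-subject factor,
#' after averaging the dependent variable over the remaining factors per
#' subject; p values are multiplied by the number of comparisons and capped
#' at 1.
#'
#' @inheritParams rm_anova
#' @param factor factor column to compare.
#' @return data.frame per level pair: mean difference, t, df, raw and
#'   adjusted p.
#' @export
bonferroni_pairwise <- function(data, dv, factor, subject = "participant") {
  data <- as.data.frame(data)
  levs <- sort(unique(data[[factor]]))
  if (length(levs) < 2) stop("factor needs at least two levels")
  agg <- stats::aggregate(data[[dv]],
                          by = list(subject = data[[subject]],
                                    level = data[[factor]]),
                          FUN = mean, na.rm = TRUE)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "level",
                         direction = "wide")
  if (nrow(wide) < 2) stop("need at least two subjects")
  pairs <- utils::combn(seq_along(levs), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- wide[[paste0("x.", levs[pairs[1, k]])]]
    b <- wide[[paste0("x.", levs[pairs[2, k]])]]
    ok <- stats::complete.cases(a, b)
    d <- a[ok] - b[ok]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    }
    data.frame(level1 = levs[pairs[1, k]], level2 = levs[pairs[2, k]],
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_adjusted = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
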