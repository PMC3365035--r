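#' One-way ANOVA with Tukey-HSD pairwise comparisons
#'
#' Omnibus one-way ANOVA over treatment groups followed by Tukey honest
#' significant difference pairwise comparisons and a compact letter display:
#' treatments sharing a letter are NOT significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors (one per treatment), or a data
#'   frame with columns `value` and `group`.  At least 2 groups with >= 2
#'   values each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `treatment_comparison`: list with `method`,
#'   `statistic`, `p_value`, `pairwise` (data frame `group1`, `group2`,
#'   `estimate`, `p_adj`, `significant`), `letters` (named character vector),
#'   `alpha`, `degenerate` (TRUE when within-group variance is zero
#'   everywhere).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  d <- as_grouped_df(groups)
  fit <- stats::aov(value ~ group, data = d)
  tab <- suppressWarnings(stats::anova(fit))  # zero-residual fits warn
  degenerate <- tab["Residuals", "Sum Sq"] < .Machine$double.eps^0.5 *
    max(1, sum(d$value^2))
  if (degenerate) {
    means <- tapply(d$value, d$group, mean)
    pw <- pairwise_frame(levels(d$group))
    pw$estimate <- means[pw$group2] - means[pw$group1]
    pw$p_adj <- ifelse(abs(pw$estimate) < .Machine$double.eps^0.5, 1, 0)
    statistic <- tab["group", "F value"]
    p_value <- if (all(pw$p_adj == 1)) 1 else 0
  } else {
    hsd <- stats::TukeyHSD(fit)$group
    # TukeyHSD rows follow the lower triangle column-major, i.e. the same
    # unordered-pair order as combn over the factor levels; labels are not
    # parsed because group names may themselves contain "-"
    pw <- pairwise_frame(levels(d$group))
    pw$estimate <- unname(hsd[, "diff"])
    pw$p_adj <- unname(hsd[, "p adj"])
    statistic <- tab["group", "F value"]
    p_value <- tab["group", "Pr(>F)"]
  }
  finish_comparison("anova_tukey", statistic, p_value, pw, alpha, degenerate)
}

#' Kruskal-Wallis with Tukey-type rank comparisons
#'
#' Nonparametric omnibus Kruskal-Wallis test followed by all-pairs
#' comparisons of average ranks against the studentized range distribution
#' (Nemenyi procedure), and a compact letter display.  Intended for heavily
#' non-normal responses such as noncumulative stemminess.
#'
#' @inheritParams anova_tukey
#' @return A `treatment_comparison` (see [anova_tukey()]); `degenerate` is
#'   TRUE when all observations are tied.
#' @export
kruskal_tukey <- function(groups, alpha = 0.05) {
  d <- as_grouped_df(groups)
  degenerate <- length(unique(d$value)) == 1L
  if (degenerate) {
    pw <- pairwise_frame(levels(d$group))
    pw$estimate <- 0
    pw$p_adj <- 1
    return(finish_comparison("kruskal_tukey", 0, 1, pw, alpha, TRUE))
  }
  kw <- stats::kruskal.test(value ~ group, data = d)
  r <- rank(d$value)
  rbar <- tapply(r, d$group, mean)
  ni <- tapply(r, d$group, length)
  N <- nrow(d)
  pw <- pairwise_frame(levels(d$group))
  pw$estimate <- unname(rbar[pw$group2] - rbar[pw$group1])
  se <- sqrt(N * (N + 1) / 12 * (1 / ni[pw$group1] + 1 / ni[pw$group2]))
  q <- abs(pw$estimate) / se
  pw$p_adj <- stats::ptukey(q * sqrt(2), nmeans = nlevels(d$group), df = Inf,
                            lower.tail = FALSE)
  finish_comparison("kruskal_tukey", unname(kw$statistic),
                    unname(kw$p.value), pw, alpha, FALSE)
}

as_grouped_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    d <- data.frame(value = as.numeric(groups$value),
                    group = factor(groups$group))
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    d <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)),
                     levels = names(groups))
    )
  }
  sizes <- table(d$group)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  if (any(!is.finite(d$value))) stop("values must be finite")
  d
}

pairwise_frame <- function(lv) {
  cmb <- utils::combn(lv, 2L)
  data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
             stringsAsFactors = FALSE)
}

finish_comparison <- function(method, statistic, p_value, pw, alpha,
                              degenerate) {
  pw$significant <- pw$p_adj < alpha
  out <- list(method = method, statistic = statistic, p_value = p_value,
              pairwise = pw,
              letters = compact_letters(unique(c(pw$group1, pw$group2)), pw,
                                        alpha),
              alpha = alpha, degenerate = degenerate)
  class(out) <- "treatment_comparison"
  out
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat("<treatment_comparison>", x$method,
      "| statistic =", signif(x$statistic, 5),
      "| p =", signif(x$p_value, 4),
      if (x$degenerate) "| degenerate" else "", "\n")
  lt <- x$letters
  cat(paste0("  ", names(lt), ": ", lt, collapse = "\n"), "\n")
  invisible(x)
}

# Compact letter display by insert-and-absorb: start with one set holding all
# groups; every significantly different pair (i, j) splits each set holding
# both into set\{i} and set\{j}; subsets of other sets are absorbed.  Groups
# sharing a letter are not significantly different; groups sharing no letter
# differ.  Symmetric under group relabelling up to letter names.
compact_letters <- function(groups, pairwise, alpha = 0.05) {
  sets <- list(groups)
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    i <- sig$group1[k]; j <- sig$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    lab <- make_letter_label(s)
    for (g in sets[[s]])
      letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

make_letter_label <- function(i) {
  out <- ""
  repeat {
    out <- paste0(letters[(i - 1L) %% 26L + 1L], out)
    i <- (i - 1L) %/% 26L
    if (i == 0L) break
  }
  out
}
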