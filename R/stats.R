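#' Choose the parametric or rank-based comparison branch
#'
#' The decision gate applied before every group comparison: the parametric
#' branch (ANOVA with Holm-Sidak post hoc) is used only when every group
#' passes a Shapiro-Wilk normality test at `alpha` AND every group has at
#' least `parametric_min_n` replicates; otherwise the rank-based branch
#' (Kruskal-Wallis with Mann-Whitney post hoc) is used. Groups too small for
#' a normality test (n < 3) or with zero variance force the rank-based
#' branch with a warning.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param alpha Significance level for the normality gate; default 0.05.
#' @param parametric_min_n Minimum replicates per group for the parametric
#'   branch; default 6.
#' @return List with `branch` (`"parametric"` or `"rank"`), `normality`
#'   (data frame: `group`, `n`, `shapiro_p`) and `reasons` (character).
#' @export
choose_branch <- function(values, groups, alpha = 0.05,
                          parametric_min_n = 6L) {
  stopifnot(length(values) == length(groups), alpha > 0, alpha < 1)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need at least 2 groups", call. = FALSE)
  norm <- data.frame(group = gl, n = NA_integer_, shapiro_p = NA_real_,
                     stringsAsFactors = FALSE)
  reasons <- character()
  for (i in seq_along(gl)) {
    v <- values[groups == gl[i]]
    if (length(v) == 0L) stop("group '", gl[i], "' is empty", call. = FALSE)
    norm$n[i] <- length(v)
    if (length(v) < 3L) {
      reasons <- c(reasons, paste0("group '", gl[i],
                                   "' has n < 3: normality untestable"))
      warning("group '", gl[i], "' has fewer than 3 replicates; ",
              "normality untestable, forcing rank-based branch",
              call. = FALSE)
    } else if (stats::var(v) == 0) {
      reasons <- c(reasons, paste0("group '", gl[i],
                                   "' is constant: normality untestable"))
    } else {
      norm$shapiro_p[i] <- stats::shapiro.test(v)$p.value
    }
  }
  normal_ok <- !is.na(norm$shapiro_p) & norm$shapiro_p > alpha
  size_ok <- norm$n >= parametric_min_n
  if (!all(size_ok)) {
    reasons <- c(reasons, paste0("group(s) with fewer than ",
                                 parametric_min_n, " replicates"))
  }
  if (!all(normal_ok)) {
    reasons <- c(reasons, "at least one group failed the normality test")
  }
  branch <- if (all(normal_ok) && all(size_ok)) "parametric" else "rank"
  list(branch = branch, normality = norm,
       reasons = if (branch == "rank") unique(reasons) else character())
}

# Holm-Sidak step-down adjustment of m p-values.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare groups with the normality- and replicate-gated procedure
#'
#' Runs [choose_branch()] (unless a branch is forced), then either a one-way
#' ANOVA omnibus with all-pairs pooled-SD t comparisons under Holm-Sidak
#' adjustment, or a Kruskal-Wallis omnibus with all-pairs Mann-Whitney
#' (Wilcoxon rank-sum) comparisons reported unadjusted. Pairwise
#' significance is flagged at `alpha`. Identical constant groups yield a
#' degenerate report (omnibus `NA`) instead of an error.
#'
#' @inheritParams choose_branch
#' @param branch `"auto"` (default) to apply the gate, or `"parametric"` /
#'   `"rank"` to force a branch.
#' @return Object of class `"group_comparison"`: `branch`, `normality`,
#'   `omnibus` (list: `test`, `statistic`, `p_value`), `pairwise` (data
#'   frame: `group1`, `group2`, `p_raw`, `p_adjusted`, `significant`),
#'   `procedure`, `degenerate`, `alpha`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           parametric_min_n = 6L,
                           branch = c("auto", "parametric", "rank")) {
  branch <- match.arg(branch)
  groups <- as.character(groups)
  gl <- unique(groups)
  gate <- NULL
  if (branch == "auto") {
    gate <- choose_branch(values, groups, alpha, parametric_min_n)
    branch <- gate$branch
  } else {
    gate <- list(normality = data.frame(group = gl,
                                        n = as.integer(table(groups)[gl]),
                                        shapiro_p = NA_real_),
                 reasons = paste0("branch forced: ", branch))
  }

  degenerate <- stats::var(values) == 0
  pairs <- utils::combn(gl, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   p_raw = NA_real_, p_adjusted = NA_real_,
                   significant = NA, stringsAsFactors = FALSE)

  if (degenerate) {
    omnibus <- list(test = if (branch == "parametric") "one-way ANOVA"
                    else "Kruskal-Wallis", statistic = NA_real_,
                    p_value = NA_real_)
    pw$significant <- FALSE
    procedure <- "degenerate input: all observations identical; no test run"
  } else if (branch == "parametric") {
    g <- factor(groups, levels = gl)
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1L]]
    omnibus <- list(test = "one-way ANOVA",
                    statistic = an[["F value"]][1L],
                    p_value = an[["Pr(>F)"]][1L])
    raw <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
    for (i in seq_len(nrow(pw))) {
      a <- pw$group1[i]; b <- pw$group2[i]
      p <- NA_real_
      if (b %in% rownames(raw) && a %in% colnames(raw)) p <- raw[b, a]
      if (is.na(p) && a %in% rownames(raw) && b %in% colnames(raw)) {
        p <- raw[a, b]
      }
      pw$p_raw[i] <- p
    }
    pw$p_adjusted <- holm_sidak_adjust(pw$p_raw)
    pw$significant <- pw$p_adjusted < alpha
    procedure <- paste("Shapiro-Wilk gate -> one-way ANOVA omnibus ->",
                       "all-pairs pooled-SD t tests, Holm-Sidak adjusted")
  } else {
    kw <- stats::kruskal.test(values, factor(groups, levels = gl))
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic),
                    p_value = kw$p.value)
    for (i in seq_len(nrow(pw))) {
      va <- values[groups == pw$group1[i]]
      vb <- values[groups == pw$group2[i]]
      if (stats::var(c(va, vb)) == 0) {
        pw$p_raw[i] <- 1
      } else {
        pw$p_raw[i] <- suppressWarnings(
          stats::wilcox.test(va, vb)$p.value)
      }
    }
    pw$p_adjusted <- pw$p_raw        # reported unadjusted, flagged below
    pw$significant <- pw$p_raw < alpha
    procedure <- paste("Shapiro-Wilk gate -> Kruskal-Wallis omnibus ->",
                       "all-pairs Mann-Whitney tests (p-values unadjusted)")
  }

  structure(list(branch = branch, normality = gate$normality,
                 gate_reasons = gate$reasons, omnibus = omnibus,
                 pairwise = pw, procedure = procedure,
                 degenerate = degenerate, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$branch, " branch, alpha = ", x$alpha, ")\n",
      sep = "")
  cat("  procedure:", x$procedure, "\n")
  if (x$degenerate) {
    cat("  degenerate input: omnibus undefined\n")
  } else {
    cat(sprintf("  omnibus %s: statistic %.4g, p = %.4g\n",
                x$omnibus$test, x$omnibus$statistic, x$omnibus$p_value))
  }
  cat("  normality (Shapiro-Wilk p):\n")
  print(x$normality, row.names = FALSE, digits = 4)
  cat("  pairwise:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
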