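#' Per-group trait summaries with coefficient of variation
#'
#' For each group and each trait column: n, mean, sd, min, max and the
#' coefficient of variation `CV = sd/mean * 100` (percent).  A trait
#' with zero mean has an undefined CV, reported as `NA` with a warning.
#'
#' @param data data.frame of per-seed measurements.
#' @param group name of the grouping column.
#' @param traits character vector of numeric trait columns (default:
#'   all numeric columns except `group`).
#' @return data.frame with one row per group x trait.
#' @examples
#' d <- data.frame(sp = rep(c("a", "b"), each = 3), A = c(1, 2, 3, 4, 5, 6))
#' summarize_populations(d, "sp")
#' @export
summarize_populations <- function(data, group, traits = NULL) {
  if (!group %in% names(data)) stop("grouping column not found: ", group)
  if (is.null(traits))
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      group)
  g <- factor(data[[group]])
  out <- list()
  for (tr in traits) {
    v <- data[[tr]]
    for (lev in levels(g)) {
      x <- v[g == lev]
      if (length(x) < 1) next
      m <- mean(x)
      s <- if (length(x) > 1) stats::sd(x) else 0
      cv <- if (abs(m) < .Machine$double.eps * 100) {
        warning(sprintf("zero mean for trait %s in group %s: CV undefined",
                        tr, lev), call. = FALSE)
        NA_real_
      } else 100 * s / m
      out[[length(out) + 1]] <-
        data.frame(group = lev, trait = tr, n = length(x), mean = m, sd = s,
                   min = min(x), max = max(x), cv = cv,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$trait, out$group), , drop = FALSE]
}

# compact letter display: groups not significantly different share a
# letter.  Insert-and-absorb construction: start from one set holding
# all groups, split it for every significant pair, drop subsets, then
# letter the surviving sets in group order.
letter_codes <- function(groups, signif_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(signif_pairs))) {
    a <- signif_pairs[k, 1]; b <- signif_pairs[k, 2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    sets <- unique(lapply(new_sets, sort))
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  # drop sets strictly contained in another
  if (length(sets) > 1) {
    keep <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j) {
        j != i && length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]])
      }, logical(1)))
    }, logical(1))
    sets <- sets[keep]
  }
  # order sets by the first group they contain
  first <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first)]
  codes <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (gname in sets[[i]])
      codes[gname] <- paste0(codes[gname], letters[i])
  codes
}

#' Nonparametric comparison of groups for one trait
#'
#' Omnibus Kruskal--Wallis test for three or more groups (two-sample
#' Wilcoxon rank-sum for exactly two), followed by pairwise rank-sum
#' tests with Holm correction and a compact letter display: groups
#' sharing a letter do not differ significantly at `alpha`.  The
#' letter display is the package's documented stand-in for the
#' stepwise stepdown post hoc of the reference workflow, preserving
#' the shared-letter output contract.
#'
#' @param data data.frame of per-seed measurements.
#' @param trait name of the numeric trait column.
#' @param group name of the grouping column (>= 2 groups).
#' @param alpha significance level (default 0.05, two-sided).
#' @return object of class `group_comparison`: list with `trait`,
#'   `method`, `statistic` (Kruskal--Wallis H, or W for two groups),
#'   `p.value`, `pairwise` (Holm-adjusted p matrix) and `letters`.
#' @export
compare_groups <- function(data, trait, group, alpha = 0.05) {
  v <- data[[trait]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (nlevels(g) == 2) {
    wt <- stats::wilcox.test(v ~ g, exact = FALSE)
    lv <- levels(g)
    lets <- if (wt$p.value < alpha) c(a = "a", b = "b") else c("a", "a")
    names(lets) <- lv
    pw <- matrix(wt$p.value, 1, 1, dimnames = list(lv[2], lv[1]))
    return(structure(list(trait = trait, method = "Wilcoxon rank-sum",
                          statistic = unname(wt$statistic),
                          p.value = wt$p.value,
                          pairwise = pw, letters = lets, alpha = alpha),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(v, g)
  pw <- stats::pairwise.wilcox.test(v, g, p.adjust.method = "holm",
                                    exact = FALSE)$p.value
  lv <- levels(g)
  sig <- list()
  for (i in rownames(pw)) for (j in colnames(pw))
    if (!is.na(pw[i, j]) && pw[i, j] < alpha)
      sig[[length(sig) + 1]] <- c(i, j)
  sigm <- if (length(sig)) do.call(rbind, sig) else
    matrix(character(0), 0, 2)
  lets <- letter_codes(lv, sigm)
  structure(list(trait = trait, method = "Kruskal-Wallis",
                 statistic = unname(kw$statistic), p.value = kw$p.value,
                 pairwise = pw, letters = lets, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test for %s: statistic = %.3f, p = %.4g\n",
              x$method, x$trait, x$statistic, x$p.value))
  cat("letters (alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}

#' Species x model matrix of mean J index
#'
#' Aggregates a long table of per-seed J values into the matrix of
#' mean J per (species, model) cell, rows and columns sorted; cells
#' with no observations are `NA`.
#'
#' @param j_table data.frame with at least the columns named by
#'   `species_col`, `model_col` and `value_col`.
#' @param species_col,model_col,value_col column names (defaults
#'   `"species"`, `"model"`, `"J"`).
#' @return numeric matrix, species in rows, models in columns.
#' @export
model_affinity_matrix <- function(j_table, species_col = "species",
                                  model_col = "model", value_col = "J") {
  for (cn in c(species_col, model_col, value_col))
    if (!cn %in% names(j_table)) stop("column not found: ", cn)
  if (nrow(j_table) == 0) stop("empty J table")
  sp <- factor(j_table[[species_col]])
  mo <- factor(j_table[[model_col]])
  m <- tapply(j_table[[value_col]], list(sp, mo), mean)
  matrix(m, nrow = nrow(m), dimnames = dimnames(m))
}
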