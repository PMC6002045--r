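# Pearson cross-correlation screening of candidate predictors and greedy
# retention of one variable per correlated group.

#' Pairwise Pearson correlations over grid cells
#'
#' Computes the correlation matrix of the stack's layers over a set of
#' evaluation cells (default: all unmasked cells). A constant variable has
#' no defined correlation and is reported as an error naming it.
#'
#' @param stack a \linkS4class{GridStack}
#' @param cells optional vector of linear cell indices to evaluate over.
#' @return a list with \code{variables} (ordered labels) and \code{r}
#'   (symmetric correlation matrix, unit diagonal)
#' @export
correlationMatrix <- function(stack, cells = NULL) {
  m <- stackValues(stack, cells)
  if (nrow(m) < 3L) stop("need at least 3 evaluation cells")
  if (ncol(m) < 2L) stop("need at least 2 variables")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s) over the evaluation cells: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  r <- cor(m)
  diag(r) <- 1
  list(variables = colnames(m), r = r)
}

#' Write a correlation matrix to CSV
#' @param corr result of \code{\link{correlationMatrix}}
#' @param path output CSV path.
#' @export
writeCorrelationMatrix <- function(corr, path) {
  df <- data.frame(variable = corr$variables, corr$r, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Retain one variable per correlated group
#'
#' Scans variables in priority order and retains a variable iff its absolute
#' correlation with every already-retained variable is strictly below the
#' cutoff (|r| >= cutoff excludes). The priority list makes the otherwise
#' judgement-based choice of which group member survives an explicit,
#' auditable input.
#'
#' @param corr result of \code{\link{correlationMatrix}} (or any list with
#'   \code{variables} and \code{r}).
#' @param priority ordered character vector covering all variables; earlier
#'   wins. Default: the variables in their stack order.
#' @param cutoff exclusion threshold on |r| (default 0.75).
#' @return character vector of retained variables, in priority order
#' @export
selectVariables <- function(corr, priority = corr$variables, cutoff = 0.75) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (!setequal(priority, corr$variables))
    stop("priority list must cover exactly the correlated variables")
  retained <- character(0)
  for (v in priority) {
    if (!length(retained)) {
      retained <- v
      next
    }
    if (all(abs(corr$r[v, retained]) < cutoff))
      retained <- c(retained, v)
  }
  retained
}

#' Default priority order for bioclimatic variable retention
#'
#' Puts an explicit shortlist first (default: bio1, bio2, bio7, bio12,
#' bio14, bio15 — a common final set for insect pest and crop niche models),
#' then all remaining variables in natural order.
#'
#' @param variables all candidate variable names.
#' @param shortlist variables to favour, in order.
#' @return ordered character vector covering \code{variables}
#' @export
bioPriority <- function(variables,
                        shortlist = c("bio1", "bio2", "bio7", "bio12",
                                      "bio14", "bio15")) {
  first <- shortlist[shortlist %in% variables]
  rest <- setdiff(variables, first)
  num <- suppressWarnings(as.numeric(sub("^bio", "", rest)))
  rest <- rest[order(is.na(num), num, rest)]
  c(first, rest)
}
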