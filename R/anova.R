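#' Balanced factorial sum-of-squares decomposition of cell summaries
#'
#' Decomposes a response measured once per cell of a fully crossed, balanced
#' design into main-effect, 2-way and 3-way interaction sums of squares;
#' all higher-order interactions are pooled into the Error term. On a
#' balanced complete grid this is the classical orthogonal decomposition, so
#' the term sums add exactly to the corrected total.
#'
#' @param cells Data frame holding one row per design cell (e.g. the rows of
#'   [run_experiment()] output for a single estimator).
#' @param response Name of the response column (e.g. `"T_bias"`).
#' @param factors Names of the design-factor columns.
#' @return Data frame with columns `term`, `order` (0 = Error / total) and
#'   `ss`, including `Error` and `Corrected total` rows.
#' @examples
#' toy <- expand.grid(a = c("l", "h"), b = c("l", "h"))
#' toy$y <- c(0, 1, 1, 2)
#' factorial_ss(toy, "y", c("a", "b"))
#' @export
factorial_ss <- function(cells, response,
                         factors = c("hacking", "tail", "pb_strength",
                                     "tau", "theta", "k")) {
  stopifnot(response %in% names(cells), all(factors %in% names(cells)))
  d <- cells[, c(factors, response)]
  d[factors] <- lapply(d[factors], function(x) factor(as.character(x)))
  counts <- table(d[factors])
  if (any(counts != 1L)) {
    stop("grid is not a balanced complete crossing with one response per cell")
  }
  max_order <- min(3L, length(factors))
  form <- stats::as.formula(paste0(
    response, " ~ (", paste(factors, collapse = " + "), ")^", max_order))
  fit <- stats::aov(form, data = d)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  ss <- tab[, "Sum Sq"]
  ord <- vapply(strsplit(term, ":"), length, integer(1))
  is_resid <- term == "Residuals"
  y <- d[[response]]
  out <- data.frame(term = c(term[!is_resid], "Error", "Corrected total"),
                    order = c(ord[!is_resid], 0L, 0L),
                    ss = c(ss[!is_resid], sum(ss[is_resid]),
                           sum((y - mean(y))^2)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Headline summaries of an ANOVA decomposition
#'
#' Corrected totals per estimator (volatility), plus a named interaction's
#' share — used to check that p-hacking and publication-bias strength act
#' additively on heterogeneity bias.
#'
#' @param cells Combined cell summaries over several estimators.
#' @param response Response column name.
#' @param factors Design-factor columns.
#' @return Data frame per estimator with `corrected_total` and
#'   `hacking_pb_interaction` sums of squares.
#' @export
anova_by_estimator <- function(cells, response,
                               factors = c("hacking", "tail", "pb_strength",
                                           "tau", "theta", "k")) {
  ests <- unique(cells$estimator)
  rows <- lapply(ests, function(e) {
    tab <- factorial_ss(cells[cells$estimator == e, ], response, factors)
    inter <- tab$ss[tab$term %in% c("hacking:pb_strength", "pb_strength:hacking")]
    data.frame(estimator = e,
               corrected_total = tab$ss[tab$term == "Corrected total"],
               hacking_pb_interaction = if (length(inter)) inter else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
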