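#' @include AllClasses.R
NULL

.interval <- function(x) {
  if (methods::is(x, "IndexCI")) return(c(x@lower, x@upper))
  if (is.numeric(x) && length(x) == 2) return(x)
  stop("expected an IndexCI or a numeric c(lower, upper) interval")
}

#' Classify past selection from a Q versus F' comparison
#'
#' Compares the confidence interval of a quantitative-trait index (Q_RT or
#' Q_SR) with that of the matching neutral molecular index (F'_RT or
#' F'_SR). Trait differentiation significantly exceeding neutral
#' differentiation (Q interval entirely above the F' interval) indicates
#' diversifying selection; significantly lower differentiation indicates
#' unifying selection; overlapping intervals are compatible with drift
#' alone (`"neutral"`). Non-overlap of 95% intervals is a conservative
#' significance rule.
#'
#' @param q [IndexCI-class] (or `c(lower, upper)`) for the quantitative
#'   index.
#' @param f [IndexCI-class] (or `c(lower, upper)`) for the molecular
#'   index.
#' @return `"diversifying"`, `"unifying"` or `"neutral"`.
#' @examples
#' classifySelection(IndexCI("Q_RT", 0.371, 0.355, 0.387),
#'                   IndexCI("F'_RT", 0.092, 0.080, 0.105))
#' @export
classifySelection <- function(q, f) {
  qi <- .interval(q); fi <- .interval(f)
  stopifnot(all(is.finite(qi)), all(is.finite(fi)))
  if (qi[1] > fi[2]) "diversifying"
  else if (qi[2] < fi[1]) "unifying"
  else "neutral"
}

#' Compare differentiation between hierarchical levels
#'
#' CI non-overlap comparison of Q_RT (differentiation among regions,
#' read as formed during glacial survival) against Q_SR (differentiation
#' among populations within regions, formed after postglacial
#' recolonisation).
#'
#' @param qrt,qsr [IndexCI-class] objects (or `c(lower, upper)` vectors).
#' @return `"greater"`, `"less"` or `"equal"`.
#' @examples
#' compareLevels(c(0.698, 0.802), c(0.000, 0.284))  # "greater"
#' @export
compareLevels <- function(qrt, qsr) {
  a <- .interval(qrt); b <- .interval(qsr)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  if (a[1] > b[2]) "greater"
  else if (a[2] < b[1]) "less"
  else "equal"
}

#' Build a selection-call table for a set of traits
#'
#' Applies [classifySelection()] at both hierarchical levels and
#' [compareLevels()] across levels for each trait, given per-trait Q
#' intervals and shared molecular F' intervals, mirroring the layout of a
#' Q-F comparison table (estimate, CI, regime arrow, level comparison).
#'
#' @param qTable `data.frame` with columns `trait`, `q_rt`, `q_rt_lower`,
#'   `q_rt_upper`, `q_sr`, `q_sr_lower`, `q_sr_upper`.
#' @param fRT,fSR [IndexCI-class] objects for the molecular indices.
#' @return `data.frame` with one row per trait and columns `trait`,
#'   `call_among_regions`, `call_within_regions`, `level_comparison` plus
#'   the input estimates.
#' @export
selectionCalls <- function(qTable, fRT, fSR) {
  need <- c("trait", "q_rt", "q_rt_lower", "q_rt_upper",
            "q_sr", "q_sr_lower", "q_sr_upper")
  stopifnot(all(need %in% names(qTable)))
  out <- qTable[need]
  out$call_among_regions <- vapply(seq_len(nrow(qTable)), function(i) {
    classifySelection(c(qTable$q_rt_lower[i], qTable$q_rt_upper[i]), fRT)
  }, character(1))
  out$call_within_regions <- vapply(seq_len(nrow(qTable)), function(i) {
    classifySelection(c(qTable$q_sr_lower[i], qTable$q_sr_upper[i]), fSR)
  }, character(1))
  out$level_comparison <- vapply(seq_len(nrow(qTable)), function(i) {
    compareLevels(c(qTable$q_rt_lower[i], qTable$q_rt_upper[i]),
                  c(qTable$q_sr_lower[i], qTable$q_sr_upper[i]))
  }, character(1))
  out
}
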