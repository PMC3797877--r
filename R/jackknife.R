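#' @include AllClasses.R
NULL

#' Delete-one-population jackknife confidence interval for any index
#'
#' Recomputes an estimator on every leave-one-population-out subset and
#' forms pseudovalues `theta_i* = n * theta_hat - (n - 1) * theta_(-i)`.
#' The centre is the mean pseudovalue (the bias-corrected estimate), the
#' standard error `sd(pseudovalues) / sqrt(n)`, and the confidence
#' interval `centre +/- z * SE`, clamped to the index's natural range.
#' Subsets on which the estimator fails (e.g. a region losing its last
#' population) are skipped with a warning and `n` adjusted; more than 20%
#' failures is an error.
#'
#' @param x a [PhenotypeTable-class] or [GenotypeTable-class].
#' @param statistic function mapping an object like `x` to a single
#'   numeric value (e.g. a Q or F' estimator).
#' @param z critical multiplier for the CI; the default 1.96 gives
#'   normal-approximation 95% intervals.
#' @param range length-2 numeric natural range of the index used to clamp
#'   the CI (`c(0, 1)` for differentiation indices); `NULL` for no
#'   clamping.
#' @param name index name stored in the result.
#' @return an [IndexCI-class] object.
#' @examples
#' ph <- simulatePhenotypes(seed = 1)
#' est <- function(p) mean(tapply(as.data.frame(p)$trait,
#'                                as.data.frame(p)$population, mean))
#' jackknifePopulations(ph, est, range = NULL, name = "mean")
#' @export
jackknifePopulations <- function(x, statistic, z = 1.96, range = c(0, 1),
                                 name = "index") {
  stopifnot(is.function(statistic), z > 0)
  pops <- unique(as.data.frame(x)$population)
  n0 <- length(pops)
  if (n0 < 3) stop("jackknife over populations needs >= 3 populations")
  thetaHat <- statistic(x)
  if (!is.finite(thetaHat)) stop("estimator not finite on the full data")
  loo <- vapply(pops, function(p) {
    tryCatch(statistic(subsetPopulations(x, setdiff(pops, p))),
             error = function(e) NA_real_)
  }, numeric(1))
  failed <- !is.finite(loo)
  if (any(failed)) {
    warning(sum(failed), " delete-one subset(s) skipped (estimator failed): ",
            paste(pops[failed], collapse = ", "))
  }
  if (sum(failed) > 0.2 * n0) {
    stop("estimator failed on more than 20% of delete-one subsets")
  }
  loo <- loo[!failed]
  n <- length(loo)
  pseudo <- n * thetaHat - (n - 1) * loo
  center <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(n)
  lower <- center - z * se
  upper <- center + z * se
  if (!is.null(range)) {
    lower <- min(max(lower, range[1]), range[2])
    upper <- min(max(upper, range[1]), range[2])
  }
  methods::new("IndexCI", name = name, estimate = thetaHat, se = se,
               center = center, lower = lower, upper = upper,
               nPopulations = as.integer(n), nFailed = as.integer(sum(failed)))
}
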