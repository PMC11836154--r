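#' Poisson probability of n falls in one year
#'
#' Probability mass `lambda^n exp(-lambda) / n!` of observing `n` fall
#' events in a unit interval when falls occur as a homogeneous Poisson
#' process with mean rate `lambda` falls/year.
#'
#' @param lam Mean fall rate (falls/year), non-negative.
#' @param n Number of events, non-negative integer(s).
#' @return Probability in `[0, 1]`, vectorised over `n`.
#' @export
#' @examples
#' fall_pmf(0.65, 0) # exp(-0.65)
fall_pmf <- function(lam, n) {
  if (any(lam < 0)) stop("lam must be non-negative")
  if (any(n < 0) || any(n != round(n))) stop("n must be a non-negative integer")
  stats::dpois(n, lam)
}

#' Sample per-patient yearly fall counts
#'
#' Draws i.i.d. Poisson(`lam`) counts for every patient-year of follow-up.
#' The same fall rate applies to every patient and every year
#' (homogeneous-risk assumption); counts in disjoint years are independent.
#'
#' @param lam Mean fall rate (falls/year).
#' @param n_patients Number of patients.
#' @param years Follow-up duration (years), default 3.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A tibble with columns `patient_id`, `year` (1..years), `n_falls`.
#' @export
#' @examples
#' sample_fall_counts(0.65, n_patients = 4, years = 3, seed = 1)
sample_fall_counts <- function(lam, n_patients, years = 3, seed = NULL) {
  stopifnot(lam >= 0, n_patients >= 1, years >= 1)
  draw <- function() stats::rpois(n_patients * years, lam)
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tibble::tibble(
    patient_id = rep(sprintf("P%04d", seq_len(n_patients)), each = years),
    year = rep(seq_len(years), times = n_patients),
    n_falls = counts
  )
}
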