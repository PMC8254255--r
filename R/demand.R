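#' Age-group incident rates from national dispatch and sample data
#'
#' Annual EMS incident rates per 1,000 persons for the three age groups
#' 0-14, 15-64 and 65+, estimated by allocating the national dispatch
#' total `D` across age groups in proportion to their share in a patient
#' sample:
#' \deqn{rate_k = 1000 \cdot \frac{D \cdot sample_k}{pop_k \cdot sample_{total}}}
#'
#' @param D total annual ambulance dispatches nationwide.
#' @param sample_k patient counts per age group in the reference sample
#'   (length 3, ordered 0-14, 15-64, 65+).
#' @param sample_total total patients in the sample; must equal
#'   `sum(sample_k)`.
#' @param pop_k national population per age group (length 3, all > 0).
#' @return Numeric vector of length 3: annual cases per 1,000 persons.
#' @export
compute_incident_rates <- function(D, sample_k, sample_total, pop_k) {
  check_number(D, "D", lower = 0)
  if (length(sample_k) != 3L || any(sample_k < 0))
    ems_stop("'sample_k' must be 3 non-negative counts",
             "emsloc_validation_error")
  if (sample_total <= 0)
    ems_stop("'sample_total' must be positive (division by zero)",
             "emsloc_validation_error")
  if (abs(sum(sample_k) - sample_total) > 1e-8)
    ems_stop("'sample_total' must equal sum(sample_k)",
             "emsloc_validation_error")
  if (length(pop_k) != 3L || any(pop_k <= 0))
    ems_stop("'pop_k' must be 3 positive populations (division by zero)",
             "emsloc_validation_error")
  1000 * D * sample_k / (pop_k * sample_total)
}

#' Default age-group rates and FHQ shares
#'
#' The default annual incident rates per 1,000 persons are 26.09 (age
#' 0-14), 69.12 (15-64) and 267.07 (65+). The First Hour Quintet (FHQ)
#' share — the fraction of patients in the most severe diagnosis group —
#' defaults to a uniform 26.51% across age groups, matching the only
#' aggregate available; a per-group vector can be supplied.
#'
#' @param rate_k annual cases per 1,000 persons by age group (length 3).
#' @param fhq_share_k FHQ fraction per age group, each in \[0, 1\].
#' @return Object of class `ems_rates`.
#' @export
age_group_rates <- function(rate_k = c(26.09, 69.12, 267.07),
                            fhq_share_k = rep(0.2651, 3)) {
  if (length(rate_k) != 3L || any(rate_k < 0))
    ems_stop("'rate_k' must be 3 non-negative rates", "emsloc_validation_error")
  if (length(fhq_share_k) == 1L) fhq_share_k <- rep(fhq_share_k, 3)
  if (length(fhq_share_k) != 3L || any(fhq_share_k < 0 | fhq_share_k > 1))
    ems_stop("'fhq_share_k' must be 3 proportions in [0,1]",
             "emsloc_validation_error")
  structure(list(rate_k = as.numeric(rate_k),
                 fhq_share_k = as.numeric(fhq_share_k)),
            class = "ems_rates")
}

#' Annual EMS demand of a municipality
#'
#' Converts an age-structured population into expected annual patient
#' counts: `b = sum_k rate_k * pop_k / 1000` for all patients, and the
#' FHQ analogue weighting each term by the per-group FHQ share. Rates are
#' stored per 1,000 persons, hence the division.
#'
#' @param pop_k population per age group (length 3, persons).
#' @param rates an [age_group_rates()] object.
#' @return List with `b` (annual EMS patients) and `b_fhq` (annual FHQ
#'   patients), `b_fhq <= b`.
#' @export
estimate_annual_demand <- function(pop_k, rates = age_group_rates()) {
  if (length(pop_k) != 3L || any(!is.finite(pop_k)))
    ems_stop("'pop_k' must be 3 finite populations", "emsloc_validation_error")
  if (any(pop_k < 0))
    ems_stop("negative population", "emsloc_validation_error")
  b <- sum(rates$rate_k * pop_k) / 1000
  b_fhq <- sum(rates$fhq_share_k * rates$rate_k * pop_k) / 1000
  list(b = b, b_fhq = b_fhq)
}

#' Aging index of a territorial unit
#'
#' Ratio of inhabitants aged 65+ to inhabitants below 65.
#'
#' @param pop_65plus population aged 65 and over.
#' @param pop_under65 population below 65 (must be positive).
#' @return The ratio.
#' @export
aging_index <- function(pop_65plus, pop_under65) {
  if (any(pop_under65 <= 0))
    ems_stop("aging index undefined: population under 65 must be > 0",
             "emsloc_validation_error")
  pop_65plus / pop_under65
}

#' Demand table for a whole region
#'
#' Applies [estimate_annual_demand()] and [aging_index()] to every
#' municipality of a region.
#'
#' @param region an `ems_region` (see [generate_region()]).
#' @param rates an [age_group_rates()] object.
#' @return `data.frame` with columns `id`, `node_id`, `b`, `b_fhq`,
#'   `aging_index`.
#' @export
region_demand <- function(region, rates = age_group_rates()) {
  m <- region$municipalities
  out <- lapply(seq_len(nrow(m)), function(i) {
    pop <- c(m$pop_0_14[i], m$pop_15_64[i], m$pop_65plus[i])
    d <- estimate_annual_demand(pop, rates)
    data.frame(id = m$id[i], node_id = m$node_id[i],
               b = d$b, b_fhq = d$b_fhq,
               aging_index = aging_index(pop[3], pop[1] + pop[2]))
  })
  do.call(rbind, out)
}
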