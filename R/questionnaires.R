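#' KCCQ item responses
#'
#' Item-level responses for the four KCCQ domains used by the pipeline.
#' Physical-limitation items are rated on a 5-point ordinal scale
#' ("extremely limited" ... "not at all limited"); the instrument-standard
#' item sets are accepted for the other domains (8 symptom, 3 quality-of-life
#' and 4 social-limitation items by default, all on 1-5 scales here).
#' Missing items are allowed (`NA`).
#'
#' @param physical_limitation integer levels, length 6, in 1..5.
#' @param symptoms,quality_of_life,social_limitation integer levels in
#'   1..`max_level` for their domain.
#' @param max_levels named list of per-domain maximum levels (default 5).
#' @return list of class `kccq_response`.
#' @export
kccq_response <- function(physical_limitation, symptoms = NULL,
                          quality_of_life = NULL, social_limitation = NULL,
                          max_levels = list(physical_limitation = 5L,
                                            symptoms = 5L,
                                            quality_of_life = 5L,
                                            social_limitation = 5L)) {
  resp <- list(physical_limitation = physical_limitation,
               symptoms = symptoms,
               quality_of_life = quality_of_life,
               social_limitation = social_limitation)
  for (d in names(resp)) {
    v <- resp[[d]]
    if (is.null(v)) next
    mx <- max_levels[[d]]
    if (any(!is.na(v) & (v < 1 | v > mx))) {
      stop("validation error: ", d, " levels must lie in 1..", mx)
    }
  }
  structure(c(resp, list(max_levels = max_levels)), class = "kccq_response")
}

#' An EQ-5D-3L response
#'
#' Five domains (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression) graded 1 (no problems) to 3 (severe), plus a visual
#' analogue scale from 1 to 100. No tariff valuation is applied anywhere in
#' the package.
#'
#' @param mobility,self_care,usual_activities,pain_discomfort,anxiety_depression
#'   integer level in \{1, 2, 3\}.
#' @param vas integer in 1..100.
#' @return list of class `eq5d_response`.
#' @export
eq5d_response <- function(mobility, self_care, usual_activities,
                          pain_discomfort, anxiety_depression, vas) {
  lv <- c(mobility = mobility, self_care = self_care,
          usual_activities = usual_activities,
          pain_discomfort = pain_discomfort,
          anxiety_depression = anxiety_depression)
  if (any(!is.na(lv) & !(lv %in% 1:3))) {
    stop("validation error: EQ-5D-3L levels must be 1, 2 or 3")
  }
  if (!is.na(vas) && (vas < 1 || vas > 100)) {
    stop("validation error: VAS must lie in 1..100")
  }
  structure(list(levels = lv, vas = vas), class = "eq5d_response")
}

rescale_items <- function(v, mx) (v - 1) / (mx - 1) * 100

#' Score a KCCQ response
#'
#' Each item is rescaled linearly to 0-100 (worst level 1 -> 0, best level
#' -> 100) and each domain is the mean of its rescaled items; a domain is
#' missing unless at least half its items are answered. The Functional
#' Status Score (FSS) is the mean of the physical-limitation and symptom
#' domains; the Clinical Status Score is the mean of FSS, quality of life
#' and social limitation. A composite with any missing constituent is
#' missing.
#'
#' @param response a [kccq_response()].
#' @return list with `domains` (named numeric, 0-100), `fss` and
#'   `clinical_status`.
#' @export
score_kccq <- function(response) {
  stopifnot(inherits(response, "kccq_response"))
  dom <- function(d) {
    v <- response[[d]]
    if (is.null(v)) return(NA_real_)
    if (sum(!is.na(v)) * 2L < length(v)) return(NA_real_)
    mean(rescale_items(v[!is.na(v)], response$max_levels[[d]]))
  }
  domains <- c(physical_limitation = dom("physical_limitation"),
               symptoms = dom("symptoms"),
               quality_of_life = dom("quality_of_life"),
               social_limitation = dom("social_limitation"))
  comp_mean <- function(x) if (anyNA(x)) NA_real_ else mean(x)
  fss <- comp_mean(domains[c("physical_limitation", "symptoms")])
  cs <- comp_mean(c(fss, domains[["quality_of_life"]],
                    domains[["social_limitation"]]))
  list(domains = domains, fss = fss, clinical_status = cs)
}

#' Score an EQ-5D-3L response
#'
#' Validated passthrough: domain levels and the VAS, with no index-value
#' tariff.
#'
#' @param response an [eq5d_response()].
#' @return list with `domain_levels` and `vas`.
#' @export
score_eq5d <- function(response) {
  stopifnot(inherits(response, "eq5d_response"))
  list(domain_levels = response$levels, vas = response$vas)
}
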